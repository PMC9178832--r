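#' Demo pipeline configuration
#'
#' A small fully-synthetic run: two chromosomes, twenty genes, three planted
#' proviruses and five solo LTRs spanning the intergenic/intron/exon
#' contexts and a range of integration ages.
#'
#' @return A config list for [run_pipeline()].
#' @export
demo_config <- function() {
  plants <- bind_rows(
    plant_spec("full_provirus", true_age_my = 10, context_target = "intergenic"),
    plant_spec("full_provirus", true_age_my = 25, strand = "-", context_target = "intron"),
    plant_spec("deleted_provirus",
      true_age_my = 20, context_target = "intergenic",
      deletions = tibble(start = 3500L, end = 5500L)
    ),
    plant_spec("solo_LTR", true_age_my = 15, context_target = "intergenic"),
    plant_spec("solo_LTR", true_age_my = 30, strand = "-", context_target = "intron"),
    plant_spec("solo_LTR", true_age_my = 8, context_target = "exon"),
    plant_spec("solo_LTR", true_age_my = 22, context_target = "intergenic"),
    plant_spec("solo_LTR", true_age_my = 12, strand = "-", context_target = "intergenic")
  )
  list(
    synthetic = TRUE,
    chromosomes = c(chrA = 400000L, chrB = 300000L),
    n_genes = 20L,
    plants = plants,
    model = mutation_model()
  )
}

#' Read a pipeline configuration file
#'
#' YAML with the same fields as [demo_config()] (plus optional `genome`,
#' `genes`, `cytobands`, `trna_lib`, `pwms`, `categories` paths for
#' file-based runs and a `thresholds` block).
#'
#' @param path YAML path.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$chromosomes)) cfg$chromosomes <- unlist(cfg$chromosomes)
  if (!is.null(cfg$plants) && is.list(cfg$plants)) {
    cfg$plants <- bind_rows(map(cfg$plants, function(p) {
      do.call(plant_spec, p)
    }))
  }
  cfg
}

#' Run the full characterization pipeline
#'
#' Orchestrates discovery, structural annotation, dating, chromosomal
#' landscape, regulatory association and PBS typing over one genome, and
#' writes the report tables as TSVs.  Synthetic configs generate the genome
#' first; file configs load `genome`/`genes` paths.  Outputs are fully
#' deterministic for a fixed config and seed.
#'
#' @param config Config list ([demo_config()], [read_pipeline_config()]).
#' @param seed Integer seed controlling every random draw.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return An `erv_run_report`: list of result tables plus a `log` tibble of
#'   per-stage row counts and the parameter echo.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = NULL) {
  log <- list()
  note <- function(stage, n, detail = "") {
    log[[length(log) + 1L]] <<- tibble(stage = stage, rows = n, detail = detail)
    message(sprintf("[%s] %d %s", stage, n, detail))
  }
  reference <- config$reference %||% synthetic_reference()
  if (isTRUE(config$synthetic)) {
    sim <- generate_genome(config, seed = seed, reference = reference)
    genome <- sim$genome
    genes <- sim$genes
    truth <- sim$truth
  } else {
    for (p in c("genome", "genes")) {
      if (is.null(config[[p]]) || !file.exists(config[[p]])) {
        stop("config path missing or not found: ", p, " = ",
          config[[p]] %||% "<unset>",
          call. = FALSE
        )
      }
    }
    genome <- read_genome(config$genome)
    genes <- read_gene_annotation(config$genes)
    truth <- NULL
    sim <- NULL
  }
  note("genome", nrow(genome$info), "chromosomes")

  cytobands <- if (!is.null(config$cytobands)) read_cytobands(config$cytobands) else NULL
  loci <- discover_elements(genome, reference, cytobands = cytobands)
  note("discover", nrow(loci), "loci")

  seqs <- locus_sequences(genome, loci)
  annotation <- if (nrow(loci)) annotate_elements(seqs, reference) else NULL
  note("annotate", if (is.null(annotation)) 0L else nrow(annotation), "elements")

  dating <- if (!is.null(annotation)) {
    date_elements(annotation, reference, rate = (config$clock_rate %||% 0.2))
  } else {
    NULL
  }
  note("date", if (is.null(dating)) 0L else sum(!is.na(dating$age_ltr_my)), "LTR-datable")

  dist <- distribution_test(loci, genome)
  contexts <- classify_context(loci, genes)
  note("landscape", nrow(contexts), "contexts")

  domains <- build_domains(genes, genome)
  assoc <- associate_elements(loci, domains)
  note("regulate", nrow(assoc), "associations")

  trna <- read_trna_library(
    config$trna_lib %||%
      system.file("extdata", "trna_3prime_synthetic.fa", package = "ervscape")
  )
  pbs <- pbs_calls(loci, annotation, seqs, reference, trna)
  note("pbs", sum(pbs$found %||% logical()), "PBS calls")

  report <- structure(
    list(
      loci = loci, genes = genes, annotation = annotation, dating = dating,
      distribution = dist, contexts = contexts, domains = domains,
      associations = assoc, pbs = pbs, truth = truth,
      params = list(seed = seed, clock_rate = config$clock_rate %||% 0.2),
      log = bind_rows(log)
    ),
    class = "erv_run_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# PBS call per provirus locus whose 5' LTR is intact enough to anchor the
# downstream window
pbs_calls <- function(loci, annotation, seqs, reference, trna) {
  empty <- tibble(
    locus_id = character(), found = logical(), pbs_seq = character(),
    offset = integer(), trna_id = character(), trna_type = character(),
    identity = double()
  )
  if (is.null(annotation)) return(empty)
  ltr5_len <- diff(region_bounds(reference, "LTR5")) + 1L
  rows <- map(seq_len(nrow(annotation)), function(i) {
    id <- annotation$locus_id[i]
    cls <- loci$element_class[loci$locus_id == id]
    if (!length(cls) || cls[1L] != "provirus" || annotation$ltr5[i] < 90) {
      return(NULL)
    }
    aln <- annotation$alignment[[i]]
    # element position of the last 5' LTR base
    keep <- aln$classes %in% c("match", "mismatch") & aln$refpos <= ltr5_len
    if (!any(keep)) return(NULL)
    pat_pos <- cumsum(seq_chars(aln$pattern) != "-")
    ltr5_end <- max(pat_pos[keep])
    s <- seqs[[id]]
    if (nchar(s) < ltr5_end + 48L) return(NULL)
    bind_cols(tibble(locus_id = id), extract_pbs(s, ltr5_end, trna))
  })
  rows <- purrr::compact(rows)
  if (!length(rows)) return(empty)
  bind_rows(rows)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  drop_lists <- function(x) x[, !map_lgl(x, is.list), drop = FALSE]
  w <- function(x, name) {
    readr::write_tsv(drop_lists(x), file.path(out_dir, name), progress = FALSE)
  }
  w(report$loci, "loci.tsv")
  if (!is.null(report$annotation)) w(report$annotation, "integrity.tsv")
  if (!is.null(report$dating)) w(report$dating, "ages.tsv")
  w(report$distribution$table, "distribution.tsv")
  w(report$contexts, "contexts.tsv")
  w(report$associations, "associations.tsv")
  w(report$pbs, "pbs.tsv")
  if (!is.null(report$truth)) w(report$truth, "truth.tsv")
  w(report$log, "log.tsv")
  invisible(out_dir)
}

#' @export
print.erv_run_report <- function(x, ...) {
  cat("<erv_run_report>\n")
  print(x$log)
  invisible(x)
}

#' Replay the packaged HML-9 catalog summaries
#'
#' Recomputes, from the packaged catalog transcriptions alone, the headline
#' descriptive statistics of the genome-wide HML-9 survey: provirus length
#' strata, genomic-context percentages, the solo-LTR 90% length screen, and
#' every integration age (internal ages from the recorded unrounded
#' per-region divergences via `T = D/0.2`; twin-LTR ages via `T = D/0.2/2`)
#' together with their means and ranges.
#'
#' @return List: `tables` (recomputed per-locus tibbles) and `summary`
#'   (named numeric of the headline values).
#' @export
replay_catalog <- function() {
  prov <- hml9_catalog("provirus")
  solo <- hml9_catalog("solo_ltr")
  ages <- hml9_catalog("ages")

  strata <- stratify_lengths(prov$coverage_pct)
  ctx_prov <- summarize_context(prov$context)
  ctx_solo <- summarize_context(solo$context)
  solo_pass <- sum(solo$ltr_pct > 90)

  dated <- ages %>%
    rowwise() %>%
    mutate(
      recomputed_internal = date_internal(
        c(.data$d_gag, .data$d_pro, .data$d_pol, .data$d_env)
      )$age_internal_my,
      recomputed_ltr = date_ltr_pair_value(.data$d_ltr)
    ) %>%
    ungroup()

  ltr_ages <- dated$recomputed_ltr[!is.na(dated$recomputed_ltr)]
  int_ages <- dated$recomputed_internal[!is.na(dated$recomputed_internal)]
  pick <- function(tbl, ctx) {
    v <- tbl$pct[tbl$context == ctx]
    if (length(v)) v else 0
  }
  summary <- c(
    provirus_count = nrow(prov),
    solo_ltr_count = nrow(solo),
    stratum_gt70 = strata$n[strata$stratum == ">70%"],
    stratum_40_70 = strata$n[strata$stratum == "40-70%"],
    stratum_lt40 = strata$n[strata$stratum == "<40%"],
    provirus_intergenic_pct = pick(ctx_prov, "Intergenic"),
    provirus_intron_pct = pick(ctx_prov, "Intron"),
    provirus_exon_pct = pick(ctx_prov, "Exon_intron"),
    solo_intergenic_pct = pick(ctx_solo, "Intergenic"),
    solo_intron_pct = pick(ctx_solo, "Intron"),
    solo_screen_pass = solo_pass,
    solo_screen_pass_pct = round(100 * solo_pass / nrow(solo), 2L),
    n_ltr_dated = length(ltr_ages),
    mean_ltr_age_my = mean(ltr_ages),
    min_ltr_age_my = min(ltr_ages),
    max_ltr_age_my = max(ltr_ages),
    n_internal_dated = length(int_ages),
    mean_internal_age_my = mean(int_ages),
    min_internal_age_my = min(int_ages),
    max_internal_age_my = max(int_ages),
    ltr_age_16p12.3 = dated$recomputed_ltr[dated$locus == "16p12.3"],
    internal_age_8q24.3 = dated$recomputed_internal[dated$locus == "8q24.3"]
  )
  list(
    tables = list(
      strata = strata, context_provirus = ctx_prov,
      context_solo = ctx_solo, ages = dated
    ),
    summary = summary
  )
}

# scalar LTR-pair clock (divergence already measured)
date_ltr_pair_value <- function(d, rate = 0.2) {
  if (is.na(d)) NA_real_ else d * 100 / rate / 2
}
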