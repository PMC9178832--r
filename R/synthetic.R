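#' Substitution model for the synthetic-genome generator
#'
#' A Kimura two-parameter (K2P) substitution process: transitions occur
#' `kappa` times more often than each transversion.  `per_site_rate` is the
#' neutral clock in substitutions/site/million years (the 0.2%/nt/my figure
#' used for ERV dating).  Indels are off by default; when enabled, events
#' occur at `indel_rate` per site with geometric lengths (mean
#' `indel_mean_len`).
#'
#' @param per_site_rate Substitutions/site/million years.
#' @param kappa Transition/transversion rate ratio.
#' @param indel_rate Indel events per site.
#' @param indel_mean_len Mean indel length (geometric).
#' @return A `mutation_model` list.
#' @export
mutation_model <- function(per_site_rate = 0.002, kappa = 2, indel_rate = 0,
                           indel_mean_len = 3) {
  stopifnot(per_site_rate >= 0, kappa > 0, indel_rate >= 0)
  structure(
    list(
      per_site_rate = per_site_rate, kappa = kappa,
      indel_rate = indel_rate, indel_mean_len = indel_mean_len
    ),
    class = "mutation_model"
  )
}

# Probability a site differs after K2P "time" s (s = beta*t, transversion
# rate unit), kappa = alpha/beta.
k2p_p_differ <- function(s, kappa) {
  0.75 - 0.25 * exp(-4 * s) - 0.5 * exp(-2 * (kappa + 1) * s)
}

# Per-site outcome probabilities (stay, transition, each transversion) such
# that the total probability of change equals `d` exactly.
k2p_site_probs <- function(d, kappa) {
  if (d == 0) {
    return(c(stay = 1, ts = 0, tv = 0))
  }
  s <- uniroot(function(s) k2p_p_differ(s, kappa) - d,
    lower = 0, upper = 50, tol = 1e-12
  )$root
  p_ts <- 0.25 + 0.25 * exp(-4 * s) - 0.5 * exp(-2 * (kappa + 1) * s)
  p_tv <- 0.25 - 0.25 * exp(-4 * s) # each of the two transversions
  c(stay = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(
  A = c("C", "T"), G = c("C", "T"),
  C = c("A", "G"), T = c("A", "G")
)

#' Mutate a sequence to a target divergence
#'
#' Draws each site's new base from the exact K2P transition-probability
#' matrix whose off-diagonal mass equals `divergence_target`, so the
#' expected observed p-distance to the input equals the target (multiple
#' hits are implicit in the matrix).  Deterministic for a fixed seed.
#' Ambiguous bases are left unchanged.
#'
#' @param seq DNA string.
#' @param divergence_target Expected p-distance in `[0, 0.75)`.
#' @param model A [mutation_model()].
#' @param seed Integer seed.
#' @return Mutated DNA string of equal length (when `indel_rate` is 0).
#' @export
mutate_sequence <- function(seq, divergence_target, model = mutation_model(),
                            seed = 1L) {
  stopifnot(divergence_target >= 0)
  if (divergence_target >= 0.75) {
    stop("divergence_target at or beyond K2P saturation (0.75)", call. = FALSE)
  }
  if (divergence_target == 0 && model$indel_rate == 0) {
    return(seq)
  }
  probs <- k2p_site_probs(divergence_target, model$kappa)
  withr::with_seed(seed, {
    v <- seq_chars(seq)
    n <- length(v)
    known <- v %in% c("A", "C", "G", "T")
    u <- runif(n)
    ts_pick <- known & u < probs[["ts"]]
    tv1 <- known & u >= probs[["ts"]] & u < probs[["ts"]] + probs[["tv"]]
    tv2 <- known & u >= probs[["ts"]] + probs[["tv"]] &
      u < probs[["ts"]] + 2 * probs[["tv"]]
    v[ts_pick] <- TRANSITION_OF[v[ts_pick]]
    v[tv1] <- map_chr(v[tv1], ~ TRANSVERSIONS_OF[[.x]][1L])
    v[tv2] <- map_chr(v[tv2], ~ TRANSVERSIONS_OF[[.x]][2L])
    out <- paste(v, collapse = "")
    if (model$indel_rate > 0) out <- apply_indels(out, model)
    out
  })
}

# geometric-length indels; insertions copy random bases
apply_indels <- function(seq, model) {
  n_events <- rpois(1L, nchar(seq) * model$indel_rate)
  if (n_events == 0L) {
    return(seq)
  }
  for (i in seq_len(n_events)) {
    len <- rgeom_len(model$indel_mean_len)
    pos <- sample.int(max(nchar(seq) - len, 1L), 1L)
    if (runif(1L) < 0.5) {
      seq <- paste0(substr(seq, 1L, pos), random_dna(len), substr(seq, pos + 1L, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1L, pos - 1L), substr(seq, pos + len, nchar(seq)))
    }
  }
  seq
}

rgeom_len <- function(mean_len) stats::rgeom(1L, 1 / mean_len) + 1L

#' Specify an element to plant in a synthetic genome
#'
#' @param kind `"full_provirus"`, `"deleted_provirus"` or `"solo_LTR"`.
#' @param chrom Chromosome name.
#' @param insert_pos 1-based insertion point (in the pre-insertion
#'   coordinates of that chromosome), or `NA` to let the generator choose.
#' @param strand `"+"` or `"-"`.
#' @param true_age_my True integration age in million years (drives the
#'   per-lineage divergence via the model's clock rate).
#' @param deletions List/tibble of reference-coordinate intervals to excise
#'   (after mutation), or `NULL`.
#' @param context_target `"intergenic"`, `"intron"`, `"exon"` or `NA` (free).
#' @return A one-row tibble.
#' @export
plant_spec <- function(kind, chrom = NA_character_, insert_pos = NA_integer_,
                       strand = "+", true_age_my = 0, deletions = NULL,
                       context_target = NA_character_) {
  kind <- match.arg(kind, c("full_provirus", "deleted_provirus", "solo_LTR"))
  stopifnot(true_age_my >= 0)
  if (!is.null(deletions) && nrow(as_tibble(deletions))) {
    d <- arrange(as_tibble(deletions), .data$start)
    if (any(d$end < d$start) || (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)]))) {
      stop("deletion intervals must be non-overlapping and ordered", call. = FALSE)
    }
  }
  tibble(
    kind = kind, chrom = chrom, insert_pos = as.integer(insert_pos),
    strand = strand, true_age_my = true_age_my,
    deletions = list(deletions %||% tibble(start = integer(), end = integer())),
    context_target = context_target
  )
}

# build the element sequence for a plant spec (reference orientation)
build_element_seq <- function(reference, spec, model, seed) {
  rate <- model$per_site_rate
  d <- rate * spec$true_age_my
  ltr_anc <- region_seq(reference, "LTR5")
  ib <- internal_bounds(reference)
  if (spec$kind == "solo_LTR") {
    el <- mutate_sequence(ltr_anc, d, model, derive_seed(seed, 11L))
  } else {
    internal <- substr(reference$sequence, ib[["start"]], ib[["end"]])
    el <- paste0(
      mutate_sequence(ltr_anc, d, model, derive_seed(seed, 21L)),
      mutate_sequence(internal, d, model, derive_seed(seed, 22L)),
      mutate_sequence(ltr_anc, d, model, derive_seed(seed, 23L))
    )
    dels <- spec$deletions[[1L]]
    if (!is.null(dels) && nrow(dels)) {
      for (i in rev(seq_len(nrow(dels)))) { # right-to-left keeps coordinates valid
        el <- paste0(
          substr(el, 1L, dels$start[i] - 1L),
          substr(el, dels$end[i] + 1L, nchar(el))
        )
      }
    }
  }
  el
}

#' Plant one element into a genome
#'
#' For a full provirus the internal region is mutated once at
#' `rate x age`, and the two LTR copies are mutated independently from the
#' same ancestral LTR at `rate x age` each — so the expected LTR-LTR
#' divergence is about `2 x rate x age`, the premise of twin-LTR dating.
#' Solo LTRs get a single mutated LTR copy.  Deletions (reference
#' coordinates) are excised after mutation.  The insertion grows the
#' chromosome; the realized interval is recorded in the returned truth row.
#'
#' @param genome A `genome_assembly`.
#' @param reference A `proviral_reference`.
#' @param spec A [plant_spec()] row with `chrom` and `insert_pos` set.
#' @param model A [mutation_model()].
#' @param seed Integer seed.
#' @param existing_truth Optional truth tibble; planting inside a recorded
#'   element is an overlap error.
#' @return List with `genome` (updated) and `truth` (one-row tibble).
#' @export
plant_element <- function(genome, reference, spec, model = mutation_model(),
                          seed = 1L, existing_truth = NULL) {
  stopifnot(inherits(genome, "genome_assembly"), nrow(spec) == 1L)
  chrom <- spec$chrom
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom, call. = FALSE)
  pos <- spec$insert_pos
  clen <- nchar(genome$seq[[chrom]])
  if (is.na(pos) || pos < 1L || pos > clen + 1L) {
    stop("insert_pos outside chromosome", call. = FALSE)
  }
  if (!is.null(existing_truth) && nrow(existing_truth)) {
    hit <- existing_truth$chrom == chrom &
      pos >= existing_truth$start & pos <= existing_truth$end
    if (any(hit)) stop("insertion inside another planted element", call. = FALSE)
  }
  el <- build_element_seq(reference, spec, model, seed)
  oriented <- if (spec$strand == "-") revcomp(el) else el
  s <- genome$seq[[chrom]]
  genome$seq[[chrom]] <- paste0(
    substr(s, 1L, pos - 1L), oriented,
    substr(s, pos, nchar(s))
  )
  genome <- genome_assembly(genome$seq)
  dels <- spec$deletions[[1L]]
  truth <- tibble(
    element_id = paste0(spec$kind, "_", chrom, "_", pos),
    kind = spec$kind, chrom = chrom,
    start = pos, end = pos + nchar(oriented) - 1L,
    strand = spec$strand, true_age_my = spec$true_age_my,
    deletions = if (is.null(dels) || !nrow(dels)) "" else paste(dels$start, dels$end, sep = "-", collapse = ";"),
    context = spec$context_target
  )
  list(genome = genome, truth = truth)
}

#' Generate a synthetic annotated genome with planted elements
#'
#' Builds a seeded toy genome: i.i.d. uniform-ACGT chromosomes, gene models
#' with exons, and planted proviruses/solo LTRs with full ground truth.
#' Plant positions honor each spec's `context_target` (intergenic, intron or
#' exon, judged against the emitted annotation), never overlap each other,
#' and keep at least `min_gap` bp apart so downstream locus merging cannot
#' fuse two plants.  Identical `config` + `seed` give byte-identical outputs.
#'
#' @param config List with elements `chromosomes` (named integer lengths),
#'   `n_genes` (count; genes are placed uniformly with 3 exons each),
#'   `plants` (tibble of [plant_spec()] rows), and optionally `model`
#'   (a [mutation_model()]), `gene_length`, `min_gap`.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, writes `genome.fa`,
#'   `genes.gff3` and `truth.tsv` there.
#' @param reference A `proviral_reference`; defaults to
#'   [synthetic_reference()].
#' @return List: `genome` (`genome_assembly`), `genes` (tibble),
#'   `truth` (tibble), `reference`, and `paths` when `dir` was given.
#' @export
generate_genome <- function(config, seed = 1L, dir = NULL,
                            reference = synthetic_reference()) {
  chroms <- config$chromosomes
  stopifnot(!is.null(names(chroms)), all(chroms > 0))
  n_genes <- config$n_genes %||% 0L
  plants <- config$plants %||% tibble()
  model <- config$model %||% mutation_model()
  gene_length <- config$gene_length %||% 9000L
  min_gap <- config$min_gap %||% 15000L

  withr::with_seed(seed, {
    seqs <- setNames(map_chr(chroms, random_dna), names(chroms))
    genes <- place_genes(chroms, n_genes, gene_length)
    placed <- place_plants(plants, chroms, genes, min_gap)
    # apply insertions ascending, shifting downstream coordinates
    truth <- tibble()
    if (nrow(placed)) {
      placed <- arrange(placed, .data$chrom, .data$insert_pos)
      offset <- setNames(rep(0L, length(chroms)), names(chroms))
      rows <- vector("list", nrow(placed))
      for (i in seq_len(nrow(placed))) {
        sp <- placed[i, ]
        el <- build_element_seq(reference, sp, model, derive_seed(seed, 100L + i))
        oriented <- if (sp$strand == "-") revcomp(el) else el
        pos0 <- sp$insert_pos # original coordinates
        pos <- pos0 + offset[[sp$chrom]]
        s <- seqs[[sp$chrom]]
        seqs[[sp$chrom]] <- paste0(
          substr(s, 1L, pos - 1L), oriented,
          substr(s, pos, nchar(s))
        )
        rows[[i]] <- tibble(
          element_id = sprintf("el%02d", i), kind = sp$kind,
          chrom = sp$chrom, start = pos, end = pos + nchar(oriented) - 1L,
          strand = sp$strand, true_age_my = sp$true_age_my,
          deletions = {
            d <- sp$deletions[[1L]]
            if (is.null(d) || !nrow(d)) "" else paste(d$start, d$end, sep = "-", collapse = ";")
          },
          context = sp$context_target, insert_pos0 = pos0
        )
        # shift annotation at or beyond the insertion point
        len <- nchar(oriented)
        genes <- shift_genes(genes, sp$chrom, pos, len)
        offset[[sp$chrom]] <- offset[[sp$chrom]] + len
      }
      truth <- bind_rows(rows)
    }
    genome <- genome_assembly(seqs)
    out <- list(genome = genome, genes = genes, truth = truth, reference = reference)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        genome = file.path(dir, "genome.fa"),
        genes = file.path(dir, "genes.gff3"),
        truth = file.path(dir, "truth.tsv")
      )
      write_genome(genome, paths$genome)
      write_gene_annotation(genes, paths$genes)
      readr::write_tsv(truth, paths$truth, progress = FALSE)
      out$paths <- paths
    }
    out
  })
}

# uniform non-overlapping gene placement; 3 exons per gene
place_genes <- function(chroms, n_genes, gene_length) {
  empty <- tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), tss = integer(), exons = list()
  )
  if (n_genes == 0L) return(empty)
  per_chrom <- table(sample(names(chroms), n_genes, replace = TRUE, prob = chroms / sum(chroms)))
  rows <- list()
  gi <- 0L
  for (ch in names(per_chrom)) {
    k <- per_chrom[[ch]]
    L <- chroms[[ch]]
    slots <- floor((L - 2000L) / (gene_length + 4000L))
    if (slots < k) stop("requested genes exceed genome capacity", call. = FALSE)
    starts <- 1000L + (sort(sample.int(slots, k)) - 1L) * (gene_length + 4000L)
    for (s in starts) {
      gi <- gi + 1L
      e <- s + gene_length - 1L
      third <- gene_length %/% 5L
      exons <- tibble(
        start = c(s, s + 2L * third, s + 4L * third),
        end = c(s + third - 1L, s + 3L * third - 1L, e)
      )
      strand <- sample(c("+", "-"), 1L)
      rows[[gi]] <- tibble(
        gene_id = sprintf("gene%03d", gi), chrom = ch, strand = strand,
        start = s, end = e, tss = if (strand == "+") s else e,
        exons = list(exons)
      )
    }
  }
  bind_rows(rows)
}

# choose insertion points honoring context targets and spacing
place_plants <- function(plants, chroms, genes, min_gap) {
  if (!nrow(plants)) return(plants)
  taken <- tibble(chrom = character(), pos = integer())
  out <- vector("list", nrow(plants))
  for (i in seq_len(nrow(plants))) {
    sp <- plants[i, ]
    if (!is.na(sp$insert_pos) && !is.na(sp$chrom)) {
      out[[i]] <- sp
      taken <- bind_rows(taken, tibble(chrom = sp$chrom, pos = sp$insert_pos))
      next
    }
    ok <- FALSE
    for (try in 1:2000) {
      ch <- if (is.na(sp$chrom)) sample(names(chroms), 1L) else sp$chrom
      pos <- sample.int(chroms[[ch]] - 2000L, 1L) + 1000L
      ctx <- point_context(ch, pos, genes)
      want <- sp$context_target
      if (!is.na(want) && ctx != want) next
      if (nrow(taken)) {
        clash <- taken$chrom == ch & abs(taken$pos - pos) < min_gap
        if (any(clash)) next
      }
      sp$chrom <- ch
      sp$insert_pos <- pos
      out[[i]] <- sp
      taken <- bind_rows(taken, tibble(chrom = ch, pos = pos))
      ok <- TRUE
      break
    }
    if (!ok) stop("requested plants exceed genome capacity", call. = FALSE)
  }
  bind_rows(out)
}

# context of a single point against the gene annotation
point_context <- function(chrom, pos, genes) {
  if (!nrow(genes)) return("intergenic")
  g <- genes %>% filter(.data$chrom == !!chrom, .data$start < pos, .data$end > pos)
  if (!nrow(g)) return("intergenic")
  ex <- tidyr::unnest(g["exons"], "exons")
  # interior of an exon (not at its edge, so the insertion stays exon-flanked)
  if (nrow(ex) && any(ex$start < pos & ex$end > pos)) return("exon")
  "intron"
}

shift_genes <- function(genes, chrom, pos, len) {
  if (!nrow(genes)) return(genes)
  idx <- genes$chrom == chrom
  shift1 <- function(x) ifelse(x >= pos, x + len, x)
  genes$start[idx] <- shift1(genes$start[idx])
  genes$end[idx] <- shift1(genes$end[idx])
  genes$tss[idx] <- shift1(genes$tss[idx])
  genes$exons[idx] <- map(genes$exons[idx], function(e) {
    e$start <- shift1(e$start)
    e$end <- shift1(e$end)
    e
  })
  genes
}
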