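#' Expected insertion counts per chromosome
#'
#' Under random integration, the expected number of insertions on a
#' chromosome is `e = Cl x n / Tl` with `Cl` the chromosome's ungapped
#' length, `n` the total number of observed loci and `Tl` the summed
#' ungapped length.  Expectations sum to `n` exactly.
#'
#' @param chrom_lengths Named numeric of ungapped chromosome lengths (or a
#'   `genome_assembly`).
#' @param n Total observed locus count.
#' @return Named numeric of expected counts.
#' @export
expected_counts <- function(chrom_lengths, n) {
  if (inherits(chrom_lengths, "genome_assembly")) {
    chrom_lengths <- setNames(
      chrom_lengths$info$ungapped_length,
      chrom_lengths$info$chrom
    )
  }
  stopifnot(n >= 0, all(chrom_lengths > 0))
  tl <- sum(chrom_lengths)
  if (tl == 0) stop("total ungapped length is zero", call. = FALSE)
  chrom_lengths * n / tl
}

#' Test the randomness of the chromosomal distribution
#'
#' Compares observed per-chromosome locus counts against `e = Cl x n / Tl`
#' with (1) an overall Pearson goodness-of-fit chi-square
#' (`df = #chromosomes - 1`) and (2) per-chromosome two-sided exact binomial
#' tests of `o` against `Binomial(n, Cl/Tl)`, BH-adjusted across
#' chromosomes.  Both views are reported because a single goodness-of-fit
#' statistic cannot attribute the departure to one chromosome.
#'
#' @param observed Named integer counts per chromosome (chromosomes absent
#'   from `observed` but present in `chrom_lengths` count as zero), or a
#'   locus tibble with a `chrom` column.
#' @param chrom_lengths Named ungapped lengths (or a `genome_assembly`).
#' @return An `erv_chrom_distribution`: list with `table` (per-chromosome
#'   tibble), `statistic`, `df`, `p.value`, `n`.
#' @export
distribution_test <- function(observed, chrom_lengths) {
  if (inherits(chrom_lengths, "genome_assembly")) {
    chrom_lengths <- setNames(
      chrom_lengths$info$ungapped_length,
      chrom_lengths$info$chrom
    )
  }
  if (is.data.frame(observed)) {
    observed <- table(factor(observed$chrom, levels = names(chrom_lengths)))
    observed <- setNames(as.integer(observed), names(chrom_lengths))
  }
  extra <- setdiff(names(observed), names(chrom_lengths))
  if (length(extra)) {
    stop("observed chromosomes not in chrom_lengths: ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  o <- setNames(rep(0L, length(chrom_lengths)), names(chrom_lengths))
  o[names(observed)] <- observed
  n <- sum(o)
  e <- expected_counts(chrom_lengths, n)
  contribution <- ifelse(e > 0, (o - e)^2 / e, NA_real_)
  usable <- e > 0
  if (any(!usable & o > 0)) {
    warning("chromosome(s) with zero expectation but observed loci excluded from chi-square")
  }
  stat <- sum(contribution[usable])
  df <- sum(usable) - 1L
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  binom_p <- map_dbl(seq_along(o), function(i) {
    if (n == 0L) {
      return(1)
    }
    binom.test(o[[i]], n, chrom_lengths[[i]] / sum(chrom_lengths))$p.value
  })
  tab <- tibble(
    chrom = names(o), observed = as.integer(o), expected = unname(e),
    contribution = unname(contribution),
    binom_p = binom_p, binom_q = p.adjust(binom_p, method = "BH")
  )
  structure(
    list(table = tab, statistic = stat, df = df, p.value = p, n = n),
    class = "erv_chrom_distribution"
  )
}

#' @export
print.erv_chrom_distribution <- function(x, ...) {
  cat(
    "<erv_chrom_distribution> n = ", x$n, ", chi-square = ",
    format(x$statistic, digits = 5), " on ", x$df, " df, p = ",
    format(x$p.value, digits = 3), "\n",
    sep = ""
  )
  print(x$table, ...)
  invisible(x)
}

#' Classify the genomic context of loci
#'
#' Categories (closed set, matching the survey tables):
#' `Intergenic` — no overlap with any gene span; `Intron` — inside gene(s)
#' touching no exon; `Exon_intron` — inside gene(s) and touching exonic
#' sequence (whether or not it also spans an intron boundary);
#' `Exonic_intergenic` — overlapping a gene but extending beyond its span.
#' Transcriptional orientation is `same`/`opposite` relative to the
#' overlapping gene with the largest overlap, `NA` for intergenic loci.
#'
#' @param loci Locus tibble (`chrom`, `start`, `end`, `strand`).
#' @param genes Gene tibble from [read_gene_annotation()] or
#'   [generate_genome()].
#' @return `loci` plus columns `context`, `context_genes`,
#'   `orientation_relation`.
#' @export
classify_context <- function(loci, genes) {
  # never collide with pre-existing columns (e.g. a truth table's context)
  loci <- loci[, setdiff(
    names(loci), c("context", "context_genes", "orientation_relation")
  ), drop = FALSE]
  ex_all <- if (nrow(genes)) {
    genes %>%
      select("gene_id", "chrom", "exons") %>%
      tidyr::unnest("exons")
  } else {
    tibble(gene_id = character(), chrom = character(), start = integer(), end = integer())
  }
  res <- map(seq_len(nrow(loci)), function(i) {
    ls <- loci$start[i]
    le <- loci$end[i]
    g <- genes %>%
      filter(.data$chrom == loci$chrom[i], .data$start <= le, .data$end >= ls)
    if (!nrow(g)) {
      return(tibble(
        context = "Intergenic", context_genes = NA_character_,
        orientation_relation = NA_character_
      ))
    }
    inside <- any(g$start <= ls & g$end >= le)
    ex <- ex_all %>%
      filter(
        .data$gene_id %in% g$gene_id,
        .data$start <= le, .data$end >= ls
      )
    touches_exon <- nrow(ex) > 0L
    context <- if (!inside) {
      "Exonic_intergenic"
    } else if (touches_exon) {
      "Exon_intron"
    } else {
      "Intron"
    }
    ov <- pmin(g$end, le) - pmax(g$start, ls) + 1L
    main <- g[which.max(ov), ]
    tibble(
      context = context,
      context_genes = paste(g$gene_id, collapse = ","),
      orientation_relation = if (is.na(loci$strand[i]) || loci$strand[i] == ".") {
        NA_character_
      } else if (loci$strand[i] == main$strand) "same" else "opposite"
    )
  })
  bind_cols(loci, bind_rows(res))
}

#' Summarize genomic-context categories
#'
#' Counts and percentages (two decimals) per context category.  By default
#' `Exonic_intergenic` is folded into `Exon_intron`, matching the
#' exon-touching grouping used in published summaries.
#'
#' @param context Character vector of categories (or a tibble with a
#'   `context` column).
#' @param merge_exonic Fold `Exonic_intergenic` into `Exon_intron`?
#' @return Tibble `context`, `n`, `pct`.
#' @export
summarize_context <- function(context, merge_exonic = TRUE) {
  if (is.data.frame(context)) context <- context$context
  if (!length(context)) {
    return(tibble(context = character(), n = integer(), pct = double()))
  }
  if (merge_exonic) {
    context[context == "Exonic_intergenic"] <- "Exon_intron"
  }
  tibble(context = context) %>%
    count(.data$context, name = "n") %>%
    mutate(pct = round(100 * .data$n / sum(.data$n), 2L)) %>%
    arrange(desc(.data$n))
}
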