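# broom-style tidiers for the fitted/result objects

#' Tidy a chromosomal-distribution test
#'
#' @param x An `erv_chrom_distribution`.
#' @param ... Unused.
#' @return Per-chromosome tibble (observed, expected, chi-square
#'   contribution, exact binomial p and BH q).
#' @exportS3Method generics::tidy
tidy.erv_chrom_distribution <- function(x, ...) x$table

#' @rdname tidy.erv_chrom_distribution
#' @return `glance()`: one-row tibble `statistic`, `df`, `p.value`, `n`.
#' @exportS3Method generics::glance
glance.erv_chrom_distribution <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value, n = x$n)
}

#' Tidy an over-representation analysis
#'
#' @param x An `erv_ora`.
#' @param ... Unused.
#' @return All tested categories, ranked by FDR.
#' @exportS3Method generics::tidy
tidy.erv_ora <- function(x, ...) x$result

#' @rdname tidy.erv_ora
#' @exportS3Method generics::glance
glance.erv_ora <- function(x, ...) {
  tibble(
    n_tested = nrow(x$result),
    n_top = nrow(x$top),
    min_fdr = if (nrow(x$result)) min(x$result$fdr) else NA_real_
  )
}

#' Tidy a PBS conservation profile
#'
#' @param x An `erv_pbs_profile`.
#' @param ... Unused.
#' @return Tibble `position`, `A`, `C`, `G`, `T` (frequencies), `ic`,
#'   `consensus_base`.
#' @exportS3Method generics::tidy
tidy.erv_pbs_profile <- function(x, ...) {
  f <- t(x$freq)
  tibble(
    position = seq_len(nrow(f)),
    A = f[, "A"], C = f[, "C"], G = f[, "G"], T = f[, "T"],
    ic = unname(x$ic),
    consensus_base = seq_chars(x$consensus)
  )
}

#' Tidy a pairwise element-reference alignment
#'
#' @param x An `erv_alignment`.
#' @param ... Unused.
#' @return `glance()`: one-row tibble of column-class counts, score and the
#'   aligned reference window.
#' @exportS3Method generics::glance
glance.erv_alignment <- function(x, ...) {
  tab <- table(factor(x$classes,
    levels = c("match", "mismatch", "element_gap", "reference_gap")
  ))
  tibble(
    match = tab[["match"]], mismatch = tab[["mismatch"]],
    element_gap = tab[["element_gap"]], reference_gap = tab[["reference_gap"]],
    score = x$score, ref_start = x$ref_start, ref_end = x$ref_end
  )
}
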