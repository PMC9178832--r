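# ggplot2 views of the main result types

#' Plot observed vs expected chromosomal distribution
#'
#' @param x An `erv_chrom_distribution`.
#' @return A ggplot.
#' @export
plot_chromosome_distribution <- function(x) {
  stopifnot(inherits(x, "erv_chrom_distribution"))
  tidy(x) %>%
    tidyr::pivot_longer(c("observed", "expected"),
      names_to = "kind", values_to = "count"
    ) %>%
    ggplot2::ggplot(ggplot2::aes(
      x = .data$chrom, y = .data$count, fill = .data$kind
    )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "loci",
      title = sprintf(
        "chi-square = %.2f (df = %d), p = %.3g",
        x$statistic, x$df, x$p.value
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-region integrity of annotated elements
#'
#' @param annotation Output of [annotate_elements()] (or the packaged
#'   integrity catalog).
#' @return A ggplot heat map (elements x regions).
#' @export
plot_region_integrity <- function(annotation) {
  idcol <- intersect(c("locus_id", "locus"), names(annotation))[1L]
  long <- annotation %>%
    select(dplyr::all_of(c(idcol, "ltr5", "gag", "pro", "pol", "env", "ltr3"))) %>%
    tidyr::pivot_longer(-dplyr::all_of(idcol),
      names_to = "region", values_to = "integrity_pct"
    ) %>%
    mutate(region = factor(.data$region,
      levels = c("ltr5", "gag", "pro", "pol", "env", "ltr3")
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$region, y = .data[[idcol]], fill = .data$integrity_pct
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey95", high = "steelblue4", limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "integrity (%)") +
    ggplot2::theme_minimal()
}

#' Plot integration-age estimates
#'
#' @param dating Output of [date_elements()] (or the recomputed catalog age
#'   table from [replay_catalog()], columns `age_ltr_my` /
#'   `age_internal_my`).
#' @return A ggplot dot plot of LTR-based vs internal-region ages.
#' @export
plot_integration_ages <- function(dating) {
  long <- dating %>%
    select(dplyr::any_of(c("locus_id", "locus", "age_ltr_my", "age_internal_my"))) %>%
    tidyr::pivot_longer(dplyr::any_of(c("age_ltr_my", "age_internal_my")),
      names_to = "method", values_to = "age_my"
    ) %>%
    filter(!is.na(.data$age_my))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$age_my, y = .data[[names(long)[1L]]], colour = .data$method
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "integration age (my)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the TSS-distance bin counts
#'
#' @param associations Output of [associate_elements()].
#' @return A ggplot bar chart over the four canonical bins.
#' @export
plot_distance_bins <- function(associations) {
  bin_distances(associations) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::labs(x = "absolute distance to TSS", y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot a PBS conservation profile
#'
#' Information content per position with the consensus base as label — the
#' numeric content of a sequence logo.
#'
#' @param profile An `erv_pbs_profile`.
#' @return A ggplot.
#' @export
plot_pbs_logo <- function(profile) {
  stopifnot(inherits(profile, "erv_pbs_profile"))
  tb <- tidy(profile)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$position, y = .data$ic)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$consensus_base),
      vjust = -0.3, size = 3
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 2.2)) +
    ggplot2::labs(x = "PBS position", y = "information content (bits)") +
    ggplot2::theme_minimal()
}
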