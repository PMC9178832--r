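#' Align an element to the proviral reference
#'
#' Affine-gap pairwise alignment of one element against the full reference
#' with free end gaps on the reference side, so terminal truncations of
#' fragmentary elements are not penalized (and are excluded from query-gap
#' accounting).  Defaults: match +2, mismatch -3, gap open 12, gap
#' extend 1.  Elements with more than 25% ambiguous bases trigger a
#' warning; ambiguous positions score as mismatches.
#'
#' Each alignment column is classified as `match`, `mismatch`,
#' `element_gap` (reference base absent from the element — a deletion) or
#' `reference_gap` (element base absent from the reference — an insertion).
#'
#' @param element_seq DNA string (reference orientation; at least 50 bp).
#' @param reference A `proviral_reference`.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return An `erv_alignment`: aligned strings, per-column class, the
#'   aligned reference window (`ref_start`, `ref_end`), a per-column
#'   reference-position map, and the score.
#' @export
align_to_reference <- function(element_seq, reference, match = 2,
                               mismatch = -3, gap_open = 12, gap_extend = 1) {
  el <- toupper(element_seq)
  if (nchar(el) < 50L) stop("element shorter than 50 bp", call. = FALSE)
  if (ambiguous_frac(el) > 0.25) {
    warning("element has >25% ambiguous bases; they score as mismatches")
  }
  el <- gsub("[^ACGT]", "N", el)
  bases <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5L, 5L, dimnames = list(bases, bases))
  diag(mat) <- match
  mat["N", "N"] <- mismatch # ambiguity never rewards
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(el),
    subject = Biostrings::DNAString(reference$sequence),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  pv <- seq_chars(p)
  sv <- seq_chars(s)
  cls <- dplyr::case_when(
    sv == "-" ~ "reference_gap",
    pv == "-" ~ "element_gap",
    pv == sv ~ "match",
    TRUE ~ "mismatch"
  )
  ref_start <- Biostrings::start(Biostrings::subject(pa))
  refpos <- ref_start - 1L + cumsum(sv != "-")
  structure(
    list(
      element = element_seq, pattern = p, subject = s,
      classes = cls, refpos = refpos,
      ref_start = ref_start, ref_end = ref_start - 1L + sum(sv != "-"),
      score = Biostrings::score(pa),
      params = c(
        match = match, mismatch = mismatch,
        gap_open = gap_open, gap_extend = gap_extend
      )
    ),
    class = "erv_alignment"
  )
}

#' @export
print.erv_alignment <- function(x, ...) {
  tab <- table(factor(x$classes,
    levels = c("match", "mismatch", "element_gap", "reference_gap")
  ))
  cat(
    "<erv_alignment> ", length(x$classes), " columns vs reference ",
    x$ref_start, "-", x$ref_end, ": ",
    paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-region integrity and indel annotation
#'
#' Integrity of a region is the percentage of its reference positions
#' aligned to a non-gap element base (match or mismatch) — a presence
#' measure, deliberately not an identity measure, since diverged but intact
#' regions should read near 100%.  Indels are reported in reference
#' coordinates, tagged with the region containing their midpoint.
#'
#' @param alignment An [align_to_reference()] result.
#' @param reference The same `proviral_reference`.
#' @return List: `integrity` (tibble `region`, `integrity_pct`) and
#'   `indels` (tibble `type`, `ref_start`, `ref_end`, `length`, `region`).
#' @export
annotate_regions <- function(alignment, reference) {
  present <- alignment$refpos[alignment$classes %in% c("match", "mismatch")]
  integrity <- reference$regions %>%
    mutate(
      integrity_pct = map2_dbl(.data$start, .data$end, function(s, e) {
        100 * sum(present >= s & present <= e) / (e - s + 1L)
      })
    ) %>%
    select("region", "integrity_pct")
  indels <- indel_table(alignment, reference)
  list(integrity = integrity, indels = indels)
}

indel_table <- function(alignment, reference) {
  cls <- alignment$classes
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    if (!v %in% c("element_gap", "reference_gap")) next
    rs <- alignment$refpos[starts[i]]
    re <- alignment$refpos[ends[i]]
    len <- r$lengths[i]
    if (v == "reference_gap") {
      re <- rs # insertion sits between reference bases
    }
    mid <- (rs + re) %/% 2L
    reg <- alignment_region_of(mid, reference)
    rows[[length(rows) + 1L]] <- tibble(
      type = if (v == "element_gap") "deletion" else "insertion",
      ref_start = rs, ref_end = re, length = len, region = reg
    )
  }
  if (!length(rows)) {
    return(tibble(
      type = character(), ref_start = integer(),
      ref_end = integer(), length = integer(), region = character()
    ))
  }
  bind_rows(rows)
}

alignment_region_of <- function(pos, reference) {
  hit <- reference$regions %>%
    filter(.data$start <= pos, .data$end >= pos)
  if (nrow(hit)) hit$region[1L] else "leader"
}

#' Coverage metrics of an alignment
#'
#' `coverage_pct` = 100 x (match + mismatch columns)/(reference length);
#' `qgap_pct` = 100 x (element-gap columns)/(match + mismatch + element-gap
#' columns).  Terminal truncations fall outside the locally aligned
#' reference window and therefore never count as query gaps.
#'
#' @inheritParams annotate_regions
#' @return One-row tibble `coverage_pct`, `qgap_pct`, `aligned_bp`.
#' @export
coverage_metrics <- function(alignment, reference) {
  mm <- sum(alignment$classes %in% c("match", "mismatch"))
  qg <- sum(alignment$classes == "element_gap")
  tibble(
    coverage_pct = 100 * mm / ref_length(reference),
    qgap_pct = if (mm + qg > 0L) 100 * qg / (mm + qg) else 0,
    aligned_bp = mm
  )
}

#' Annotate a set of element sequences against the reference
#'
#' Aligns each sequence, computes coverage metrics and per-region integrity,
#' and keeps the alignments for downstream dating.
#'
#' @param seqs Named character vector of element sequences (reference
#'   orientation), e.g. from [locus_sequences()].
#' @param reference A `proviral_reference`.
#' @return Tibble with one row per element: `locus_id`, `coverage_pct`,
#'   `qgap_pct`, `aligned_bp`, one integrity column per region (`ltr5`,
#'   `gag`, `pro`, `pol`, `env`, `ltr3`), plus list-columns `indels` and
#'   `alignment`.
#' @export
annotate_elements <- function(seqs, reference) {
  rows <- imap(seqs, function(s, id) {
    aln <- align_to_reference(s, reference)
    ann <- annotate_regions(aln, reference)
    cm <- coverage_metrics(aln, reference)
    wide <- setNames(
      as.list(ann$integrity$integrity_pct),
      c("ltr5", "gag", "pro", "pol", "env", "ltr3")
    )
    bind_cols(
      tibble(locus_id = id), cm, as_tibble(wide),
      tibble(indels = list(ann$indels), alignment = list(aln))
    )
  })
  bind_rows(rows)
}
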