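# Molecular-clock dating of ERV elements.
#
# The clock: a provirus's twin LTRs are identical at integration and then
# diverge independently, so with neutral rate r (%/nt/my) the LTR-LTR
# divergence D gives age T = D/r/2; internal regions are compared to the
# group consensus (a stand-in for the ancestral state) with T = D/r.

#' p-distance between two aligned sequences
#'
#' Fraction of differing sites over columns where both sequences carry an
#' unambiguous base (pairwise deletion of gaps/ambiguity).
#'
#' @param seq_a,seq_b Aligned sequences of equal length (gaps allowed).
#' @return One-row tibble `D`, `sites_compared`, `model`, `P`, `Q`.
#' @export
p_distance <- function(seq_a, seq_b) {
  cmp <- comparable_sites(seq_a, seq_b)
  if (cmp$n == 0L) stop("no comparable sites; distance undefined", call. = FALSE)
  tibble(
    D = mean(cmp$a != cmp$b), sites_compared = cmp$n,
    model = "p_distance", P = NA_real_, Q = NA_real_
  )
}

#' Kimura two-parameter distance
#'
#' With transition fraction `P` and transversion fraction `Q` over
#' comparable sites, `D = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))`.  Saturated
#' pairs (non-positive log argument) are an error.
#'
#' @inheritParams p_distance
#' @return One-row tibble `D`, `sites_compared`, `model`, `P`, `Q`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  cmp <- comparable_sites(seq_a, seq_b)
  if (cmp$n == 0L) stop("no comparable sites; distance undefined", call. = FALSE)
  transitions <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)
  pair <- paste0(cmp$a, cmp$b)
  is_diff <- cmp$a != cmp$b
  is_ts <- is_diff & !is.na(transitions[pair])
  P <- mean(is_ts)
  Q <- mean(is_diff & !is_ts)
  w <- 1 - 2 * P - Q
  x <- 1 - 2 * Q
  if (w <= 0 || x <= 0) stop("K2P saturation: distance undefined", call. = FALSE)
  tibble(
    D = -0.5 * log(w * sqrt(x)), sites_compared = cmp$n,
    model = "K2P", P = P, Q = Q
  )
}

comparable_sites <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) seq_chars(seq_a) else seq_a
  b <- if (length(seq_b) == 1L) seq_chars(seq_b) else seq_b
  if (length(a) != length(b)) {
    stop("sequences must be pre-aligned (equal length)", call. = FALSE)
  }
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  list(a = a[ok], b = b[ok], n = sum(ok))
}

#' Majority-rule consensus of aligned sequences
#'
#' Per column, the most frequent base wins; a gap wins only when gaps exceed
#' half the column; ties are broken by the reference base at that column
#' when given (and among the tied bases), otherwise alphabetically.
#'
#' @param aligned Character vector of >= 2 aligned sequences (equal length).
#' @param reference_seq Optional aligned reference string for tie-breaking.
#' @return Consensus string (may contain `-`).
#' @export
build_consensus <- function(aligned, reference_seq = NULL) {
  stopifnot(length(aligned) >= 2L)
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) stop("sequences must be aligned", call. = FALSE)
  if (lens[1L] == 0L) stop("empty column set", call. = FALSE)
  m <- do.call(rbind, lapply(aligned, seq_chars))
  refv <- if (!is.null(reference_seq)) seq_chars(reference_seq) else NULL
  cons <- map_chr(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gaps <- sum(col == "-")
    if (gaps > length(col) / 2) {
      return("-")
    }
    bases <- col[col %in% c("A", "C", "G", "T")]
    if (!length(bases)) {
      return(if (is.null(refv)) "N" else refv[j])
    }
    tab <- table(bases)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L && !is.null(refv) && refv[j] %in% top) {
      return(refv[j])
    }
    sort(top)[1L]
  })
  paste(cons, collapse = "")
}

#' Internal-region clock dating
#'
#' Mean of the available per-region divergences (NA-skipping), converted to
#' an age with `T = D / rate` (rate in %/nt/my; divergences as fractions, so
#' age in my = mean D x 100 / rate).
#'
#' @param region_Ds Named numeric of per-region divergences (NAs allowed).
#' @param rate Neutral substitution rate in %/nt/my.
#' @return One-row tibble `mean_D`, `age_internal_my` (NA when every D is
#'   NA).
#' @export
date_internal <- function(region_Ds, rate = 0.2) {
  ds <- unlist(region_Ds)
  if (all(is.na(ds))) {
    return(tibble(mean_D = NA_real_, age_internal_my = NA_real_))
  }
  m <- mean(ds, na.rm = TRUE)
  tibble(mean_D = m, age_internal_my = m * 100 / rate)
}

#' Twin-LTR clock dating
#'
#' The two LTRs of one provirus were identical at integration and diverge
#' independently, so `T = D / rate / 2`.
#'
#' @param ltr5_seq,ltr3_seq The element's two LTR sequences (aligned to a
#'   common coordinate frame, or unaligned — unequal lengths are aligned
#'   globally first), or `NA` when absent.
#' @param rate Neutral substitution rate in %/nt/my.
#' @param model `"p_distance"` (default, the linear arithmetic of published
#'   dating tables) or `"K2P"`, which corrects for multiple hits — the
#'   better-centred choice when the true substitution process is
#'   transition-biased, at the cost of slightly higher variance.
#' @return One-row tibble `ltr_D`, `age_ltr_my` (NA when an LTR is
#'   missing).
#' @export
date_ltr_pair <- function(ltr5_seq, ltr3_seq, rate = 0.2,
                          model = "p_distance") {
  if (is.na(ltr5_seq) || is.na(ltr3_seq)) {
    return(tibble(ltr_D = NA_real_, age_ltr_my = NA_real_))
  }
  if (nchar(ltr5_seq) != nchar(ltr3_seq)) {
    al <- align_pair(ltr5_seq, ltr3_seq)
    ltr5_seq <- al[1L]
    ltr3_seq <- al[2L]
  }
  dist_fun <- if (model == "K2P") k2p_distance else p_distance
  d <- dist_fun(ltr5_seq, ltr3_seq)$D
  tibble(ltr_D = d, age_ltr_my = d * 100 / rate / 2)
}

# global alignment of two sequences -> gapped strings
align_pair <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(gsub("[^ACGT]", "N", toupper(a))),
    subject = Biostrings::DNAString(gsub("[^ACGT]", "N", toupper(b))),
    type = "global"
  )
  c(
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa))
  )
}

# reference-coordinate projection of an element alignment: one base (or "-")
# per reference position
project_to_reference <- function(alignment, reference) {
  out <- rep("-", ref_length(reference))
  keep <- alignment$classes %in% c("match", "mismatch")
  out[alignment$refpos[keep]] <- seq_chars(alignment$pattern)[keep]
  out
}

#' Date a set of annotated elements
#'
#' Full dating workflow over an [annotate_elements()] table: per coding
#' region, elements whose region integrity exceeds `region_min_pct` are
#' projected onto reference coordinates, a majority-rule consensus is built
#' from the screened set (reference base breaking ties), and each element's
#' divergence from that consensus gives `T = D/rate`; per element, the two
#' projected LTR windows (both at least half present) give the twin-LTR age
#' `T = D/rate/2`.
#'
#' @param annotation Output of [annotate_elements()].
#' @param reference The `proviral_reference` used there.
#' @param rate Neutral substitution rate (%/nt/my).
#' @param region_min_pct Integrity screen for consensus/dating membership.
#' @param model `"p_distance"` (default) or `"K2P"`.
#' @return Tibble: `locus_id`, `d_gag`, `d_pro`, `d_pol`, `d_env`,
#'   `mean_d`, `age_internal_my`, `d_ltr`, `age_ltr_my`.
#' @export
date_elements <- function(annotation, reference, rate = 0.2,
                          region_min_pct = 90, model = "p_distance") {
  dist_fun <- if (model == "K2P") k2p_distance else p_distance
  profiles <- map(annotation$alignment, project_to_reference, reference = reference)
  names(profiles) <- annotation$locus_id
  n <- nrow(annotation)
  region_d <- matrix(NA_real_, n, 4L,
    dimnames = list(annotation$locus_id, c("gag", "pro", "pol", "env"))
  )
  refv <- seq_chars(reference$sequence)
  for (reg in c("gag", "pro", "pol", "env")) {
    b <- region_bounds(reference, reg)
    idx <- b[[1L]]:b[[2L]]
    sel <- which(annotation[[reg]] > region_min_pct)
    if (length(sel) < 2L) next # consensus needs at least two members
    seqs <- map_chr(profiles[sel], ~ paste(.x[idx], collapse = ""))
    cons <- build_consensus(seqs, paste(refv[idx], collapse = ""))
    for (i in sel) {
      region_d[i, reg] <- dist_fun(
        paste(profiles[[i]][idx], collapse = ""), cons
      )$D
    }
  }
  b5 <- region_bounds(reference, "LTR5")
  b3 <- region_bounds(reference, "LTR3")
  i5 <- b5[[1L]]:b5[[2L]]
  i3 <- b3[[1L]]:b3[[2L]]
  rows <- map(seq_len(n), function(i) {
    ds <- region_d[i, ]
    internal <- date_internal(ds, rate)
    l5 <- profiles[[i]][i5]
    l3 <- profiles[[i]][i3]
    have5 <- mean(l5 != "-") >= 0.5
    have3 <- mean(l3 != "-") >= 0.5
    ltr <- if (have5 && have3) {
      d <- dist_fun(l5, l3)$D
      tibble(ltr_D = d, age_ltr_my = d * 100 / rate / 2)
    } else {
      tibble(ltr_D = NA_real_, age_ltr_my = NA_real_)
    }
    tibble(
      locus_id = annotation$locus_id[i],
      d_gag = ds[["gag"]], d_pro = ds[["pro"]],
      d_pol = ds[["pol"]], d_env = ds[["env"]],
      mean_d = internal$mean_D, age_internal_my = internal$age_internal_my,
      d_ltr = ltr$ltr_D, age_ltr_my = ltr$age_ltr_my
    )
  })
  bind_rows(rows)
}

#' Neighbor-joining clustering
#'
#' Standard neighbor joining with deterministic tie-breaking (lowest index
#' pair), implemented directly so the agglomeration order is reproducible.
#' Intended as a light clustering tool for intragroup structure (e.g. the
#' two pro/pol subtypes), not a substitute for model-based phylogenetics.
#'
#' @param d Symmetric distance matrix with zero diagonal and labelled rows.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_cluster <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-9)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  labs <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2L) stop("need at least two taxa", call. = FALSE)
  if (n == 2L) {
    return(ape::read.tree(text = sprintf(
      "(%s:%.10g,%s:%.10g);", labs[1L], d[1L, 2L] / 2, labs[2L], d[1L, 2L] / 2
    )))
  }
  frag <- labs
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- t(apply(idx, 1L, sort))
    idx <- unique(idx)
    ord <- order(idx[, 1L], idx[, 2L])
    i <- idx[ord[1L], 1L]
    j <- idx[ord[1L], 2L]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], bi, frag[j], bj)
    others <- setdiff(seq_len(m), c(i, j))
    dnew <- 0.5 * (D[i, others] + D[j, others] - D[i, j])
    D2 <- rbind(cbind(D[others, others, drop = FALSE], dnew), c(dnew, 0))
    frag <- c(frag[others], newfrag)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
  }
  x <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  y <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
  z <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  ape::read.tree(text = sprintf(
    "(%s:%.10g,%s:%.10g,%s:%.10g);", frag[1L], x, frag[2L], y, frag[3L], z
  ))
}
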