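#' Build a stepped k-mer seed index of a genome
#'
#' Indexes every k-mer starting at positions 1, 1+step, 1+2*step, ... of each
#' chromosome (the classic 11-mer / step-5 whole-genome index of BLAT-style
#' search).  Words containing ambiguous bases are skipped; chromosomes
#' shorter than `k` are skipped with a warning.
#'
#' @param genome A `genome_assembly`.
#' @param k Word size (>= 8).
#' @param step Index stride (>= 1).
#' @return A `seed_index` object.
#' @export
build_index <- function(genome, k = 11L, step = 5L) {
  stopifnot(inherits(genome, "genome_assembly"), k >= 8L, step >= 1L)
  lens <- setNames(genome$info$length, genome$info$chrom)
  cum <- cumsum(as.double(lens))
  base <- c(0, cum[-length(cum)])
  names(base) <- names(lens)
  km_all <- list()
  pos_all <- list()
  for (ch in names(genome$seq)) {
    L <- lens[[ch]]
    if (L < k) {
      warning("chromosome ", ch, " shorter than k; skipped")
      next
    }
    starts <- seq.int(1L, L - k + 1L, by = step)
    km <- substring(genome$seq[[ch]], starts, starts + k - 1L)
    ok <- !grepl("[^ACGT]", km)
    km_all[[ch]] <- km[ok]
    pos_all[[ch]] <- base[[ch]] + starts[ok]
  }
  kk <- unlist(km_all, use.names = FALSE)
  pp <- unlist(pos_all, use.names = FALSE)
  env <- new.env(hash = TRUE, parent = emptyenv(), size = max(16L, length(kk)))
  if (length(kk)) list2env(split(pp, kk), envir = env)
  structure(
    list(
      env = env, k = as.integer(k), step = as.integer(step),
      chrom = names(lens), lengths = lens, base = base, cum = cum,
      n_entries = length(kk)
    ),
    class = "seed_index"
  )
}

#' @export
print.seed_index <- function(x, ...) {
  cat(
    "<seed_index> k=", x$k, " step=", x$step, ", ", x$n_entries,
    " indexed positions over ", length(x$chrom), " chromosome(s)\n",
    sep = ""
  )
  invisible(x)
}

# decode global encoded positions to (chrom index, position)
decode_positions <- function(index, enc) {
  ci <- findInterval(enc - 0.5, c(0, index$cum))
  list(ci = ci, pos = as.integer(enc - index$base[ci]))
}

#' Search a genome for reference-homologous chains
#'
#' Seed-and-extend local search: reference k-mers (both orientations, stride
#' 1) are looked up in the genome index; diagonals collecting at least
#' `min_seed_hits` seeds are extended without gaps under an x-drop rule
#' (match +2, mismatch -3, stop when the score falls `xdrop` below its
#' maximum); blocks are then chained colinearly per chromosome and strand.
#' Chains are scored by `matches - mismatches`.  Minus-strand chains are
#' reported in plus-strand genome coordinates with reference coordinates in
#' reference orientation.
#'
#' @param reference A `proviral_reference`.
#' @param index A [build_index()] result over `genome`.
#' @param genome The same `genome_assembly` the index was built from.
#' @param min_seed_hits Minimum seeds on a diagonal before extension.
#' @param xdrop X-drop threshold for ungapped extension.
#' @param max_chain_gap Maximum genomic or reference gap bridged inside one
#'   chain.
#' @return Tibble of chains: `chrom`, `strand`, `g_start`, `g_end`,
#'   `ref_start`, `ref_end`, `matches`, `mismatches`, `score`, `n_blocks`,
#'   and a list-column `blocks` of per-block coordinates.
#' @export
search_chains <- function(reference, index, genome, min_seed_hits = 2L,
                          xdrop = 18L, max_chain_gap = 10000L) {
  k <- index$k
  Lq <- ref_length(reference)
  gchar <- lapply(genome$seq, seq_chars) # cached per chromosome
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") reference$sequence else revcomp(reference$sequence)
    qv <- seq_chars(q)
    qs <- seq_len(Lq - k + 1L)
    qk <- substring(q, qs, qs + k - 1L)
    ok <- !grepl("[^ACGT]", qk)
    if (!any(ok)) next
    hits <- mget(qk[ok], envir = index$env, ifnotfound = list(NULL))
    nh <- lengths(hits)
    if (sum(nh) == 0L) next
    qpos <- rep(qs[ok], nh)
    enc <- unlist(hits, use.names = FALSE)
    dec <- decode_positions(index, enc)
    hit_tbl <- tibble(ci = dec$ci, gpos = dec$pos, qpos = qpos) %>%
      mutate(diag = .data$gpos - .data$qpos)
    grp <- hit_tbl %>%
      group_by(.data$ci, .data$diag) %>%
      filter(n() >= min_seed_hits) %>%
      ungroup()
    if (!nrow(grp)) next
    blocks <- grp %>%
      group_by(.data$ci, .data$diag) %>%
      group_map(~ extend_diagonal(
        qv, gchar[[index$chrom[.y$ci]]], sort(.x$qpos), .y$diag, k, xdrop
      ) %>% mutate(ci = .y$ci, diag = .y$diag)) %>%
      bind_rows()
    if (!nrow(blocks)) next
    chains <- blocks %>%
      group_by(.data$ci) %>%
      group_map(~ chain_blocks(.x, max_chain_gap) %>% mutate(ci = .y$ci)) %>%
      bind_rows()
    if (!nrow(chains)) next
    chains$chrom <- index$chrom[chains$ci]
    chains$strand <- strand
    if (strand == "+") {
      chains$ref_start <- chains$q_start
      chains$ref_end <- chains$q_end
    } else {
      chains$ref_start <- Lq - chains$q_end + 1L
      chains$ref_end <- Lq - chains$q_start + 1L
      chains$blocks <- map(chains$blocks, function(b) {
        tibble(
          qs = Lq - b$qe + 1L, qe = Lq - b$qs + 1L,
          gs = b$gs, ge = b$ge
        ) %>% arrange(.data$qs)
      })
    }
    out[[strand]] <- select(
      chains,
      "chrom", "strand", "g_start", "g_end", "ref_start", "ref_end",
      "matches", "mismatches", "score", "n_blocks", "blocks"
    )
  }
  if (!length(out)) {
    return(tibble(
      chrom = character(), strand = character(), g_start = integer(),
      g_end = integer(), ref_start = integer(), ref_end = integer(),
      matches = integer(), mismatches = integer(), score = integer(),
      n_blocks = integer(), blocks = list()
    ))
  }
  bind_rows(out) %>% arrange(.data$chrom, .data$g_start)
}

# ungapped x-drop extension of all seeds on one diagonal
extend_diagonal <- function(qv, gv, seed_qpos, diag, k, xdrop) {
  Lq <- length(qv)
  Lg <- length(gv)
  res <- list()
  covered_to <- 0L
  for (q0 in seed_qpos) {
    if (q0 <= covered_to) next
    g0 <- q0 + diag
    qe <- q0 + k - 1L
    ge <- g0 + k - 1L
    # rightward
    m <- min(Lq - qe, Lg - ge)
    ext_r <- 0L
    if (m > 0L) {
      cmp <- qv[(qe + 1L):(qe + m)] == gv[(ge + 1L):(ge + m)]
      ext_r <- xdrop_extent(cmp, xdrop)
    }
    # leftward
    m <- min(q0 - 1L, g0 - 1L)
    ext_l <- 0L
    if (m > 0L) {
      cmp <- qv[(q0 - 1L):(q0 - m)] == gv[(g0 - 1L):(g0 - m)]
      ext_l <- xdrop_extent(cmp, xdrop)
    }
    bqs <- q0 - ext_l
    bqe <- qe + ext_r
    bgs <- g0 - ext_l
    bge <- ge + ext_r
    cmp_all <- qv[bqs:bqe] == gv[bgs:bge]
    res[[length(res) + 1L]] <- tibble(
      qs = bqs, qe = bqe, gs = bgs, ge = bge,
      matches = sum(cmp_all), mismatches = sum(!cmp_all)
    )
    covered_to <- bqe
  }
  bind_rows(res)
}

# how far an ungapped extension runs before the x-drop rule stops it
xdrop_extent <- function(cmp, xdrop) {
  s <- cumsum(ifelse(cmp, 2L, -3L))
  best <- cummax(s)
  stop_at <- which(best - s > xdrop)[1L]
  lim <- if (is.na(stop_at)) length(s) else stop_at - 1L
  if (lim == 0L) {
    return(0L)
  }
  w <- s[seq_len(lim)]
  if (max(w) <= 0L) {
    return(0L)
  }
  which.max(w)
}

# colinear chaining of gapless blocks (query coordinates) by dynamic
# programming; each block joins at most one chain
chain_blocks <- function(blocks, max_chain_gap) {
  b <- arrange(blocks, .data$qs, .data$gs)
  n <- nrow(b)
  bscore <- b$matches - b$mismatches
  total <- bscore
  parent <- rep(NA_integer_, n)
  if (n > 1L) {
    for (i in 2:n) {
      for (j in 1:(i - 1L)) {
        if (b$qs[i] >= b$qe[j] - 10L && b$gs[i] >= b$ge[j] - 10L &&
          b$qs[i] - b$qe[j] <= max_chain_gap &&
          b$gs[i] - b$ge[j] <= max_chain_gap) {
          cand <- total[j] + bscore[i]
          if (cand > total[i]) {
            total[i] <- cand
            parent[i] <- j
          }
        }
      }
    }
  }
  used <- rep(FALSE, n)
  chains <- list()
  for (i in order(total, decreasing = TRUE)) {
    if (used[i]) next
    path <- integer()
    j <- i
    while (!is.na(j) && !used[j]) {
      path <- c(j, path)
      used[j] <- TRUE
      j <- parent[j]
    }
    bb <- b[path, , drop = FALSE]
    chains[[length(chains) + 1L]] <- tibble(
      g_start = min(bb$gs), g_end = max(bb$ge),
      q_start = min(bb$qs), q_end = max(bb$qe),
      matches = sum(bb$matches), mismatches = sum(bb$mismatches),
      score = sum(bb$matches) - sum(bb$mismatches),
      n_blocks = nrow(bb),
      blocks = list(select(bb, "qs", "qe", "gs", "ge"))
    )
  }
  bind_rows(chains)
}

#' Merge alignment chains into element loci
#'
#' Chains on the same chromosome and strand whose genomic gaps are at most
#' `max_locus_gap` merge into one locus.  Chains whose genomic interval
#' largely duplicates a higher-scoring chain (a solo LTR matching both
#' reference LTRs, or a provirus LTR cross-matching the opposite reference
#' LTR) are dropped before grouping.  Loci covering fewer than `min_aligned`
#' reference bases are discarded — isolated 11-mer coincidences in random
#' sequence extend to ~30-40 bp pseudo-chains, far below any genuine
#' element fragment.
#'
#' Per locus: `coverage_pct` is 100 x (aligned reference bases)/(reference
#' length) for proviruses and 100 x (aligned bases, LTR coordinates)/(LTR5
#' length) for solo LTRs; `qgap_pct` is 100 x qgap/(aligned + qgap), where
#' qgap counts reference bases spanned but unaligned inside the locus.
#'
#' @param chains Output of [search_chains()].
#' @param reference The `proviral_reference` searched.
#' @param max_locus_gap Maximum genomic gap merged into one locus.
#' @param min_aligned Minimum aligned reference bases for a locus.
#' @return Tibble of loci: `locus_id`, `chrom`, `strand`, `start`, `end`,
#'   `length`, `element_class`, `coverage_pct`, `qgap_pct`, `ref_start`,
#'   `ref_end`, `aligned_bp`, `name`, plus a `blocks` list-column.
#' @export
merge_chains_to_loci <- function(chains, reference, max_locus_gap = 10000L,
                                 min_aligned = 100L) {
  empty <- tibble(
    locus_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), length = integer(),
    element_class = character(), coverage_pct = double(),
    qgap_pct = double(), ref_start = integer(), ref_end = integer(),
    aligned_bp = integer(), name = character(), blocks = list()
  )
  if (!nrow(chains)) return(empty)
  loci <- chains %>%
    group_by(.data$chrom, .data$strand) %>%
    group_map(function(ch, key) {
      ch <- dedup_chains(ch)
      ch <- arrange(ch, .data$g_start)
      grp <- cumsum(c(
        TRUE,
        ch$g_start[-1L] - cummax(ch$g_end)[-nrow(ch)] > max_locus_gap
      ))
      ch$grp <- grp
      ch %>%
        group_by(.data$grp) %>%
        group_map(~ locus_from_chains(.x, key$chrom, key$strand, reference)) %>%
        bind_rows()
    }) %>%
    bind_rows()
  if (!nrow(loci)) return(empty)
  loci <- loci %>%
    filter(.data$aligned_bp >= min_aligned) %>%
    arrange(.data$chrom, .data$start)
  if (!nrow(loci)) return(empty)
  loci %>% mutate(name = paste0(.data$chrom, ":", .data$start, "-", .data$end))
}

# drop chains that mostly duplicate a better chain's genomic interval
dedup_chains <- function(ch) {
  ch <- arrange(ch, desc(.data$score))
  keep <- rep(TRUE, nrow(ch))
  for (i in seq_len(nrow(ch))[-1L]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      ov <- min(ch$g_end[i], ch$g_end[j]) - max(ch$g_start[i], ch$g_start[j]) + 1L
      if (ov > 0.5 * (ch$g_end[i] - ch$g_start[i] + 1L)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  ch[keep, , drop = FALSE]
}

locus_from_chains <- function(ch, chrom, strand, reference) {
  blocks <- bind_rows(ch$blocks)
  rng <- IRanges::reduce(IRanges::IRanges(blocks$qs, blocks$qe))
  aligned <- sum(IRanges::width(rng))
  rs <- min(IRanges::start(rng))
  re <- max(IRanges::end(rng))
  qgap <- (re - rs + 1L) - aligned
  cls <- classify_locus(rng, reference)
  cov <- if (cls == "provirus") {
    100 * aligned / ref_length(reference)
  } else {
    100 * solo_ltr_aligned(rng, reference) /
      (diff(region_bounds(reference, "LTR5")) + 1L)
  }
  start <- min(ch$g_start)
  end <- max(ch$g_end)
  tibble(
    locus_id = paste0(chrom, ":", start, "-", end, "(", strand, ")"),
    chrom = chrom, strand = strand, start = start, end = end,
    length = end - start + 1L, element_class = cls,
    coverage_pct = cov,
    qgap_pct = if (aligned + qgap > 0L) 100 * qgap / (aligned + qgap) else 0,
    ref_start = rs, ref_end = re, aligned_bp = aligned,
    name = NA_character_, blocks = list(blocks)
  )
}

#' Classify a locus as provirus or solo LTR
#'
#' A locus is a solo LTR iff every aligned reference base falls within the
#' LTR5 or LTR3 coordinates; any aligned base in the internal region
#' (leader, gag..env, trailer) makes it a provirus — internal-only fragments
#' with no LTR coverage are proviral remnants, not solo LTRs.
#'
#' A `min_internal_bp` margin (default 20) absorbs the few bases by which
#' x-drop extension can overshoot an LTR boundary by chance; genuine
#' internal fragments align hundreds of internal bases.
#'
#' @param aligned_ranges `IRanges` of aligned reference positions (or a
#'   locus row's `blocks` tibble).
#' @param reference A `proviral_reference`.
#' @param min_internal_bp Aligned internal bases required to call a
#'   provirus.
#' @return `"provirus"` or `"solo_LTR"`.
#' @export
classify_locus <- function(aligned_ranges, reference, min_internal_bp = 20L) {
  if (is.data.frame(aligned_ranges)) {
    aligned_ranges <- IRanges::reduce(
      IRanges::IRanges(aligned_ranges$qs, aligned_ranges$qe)
    )
  }
  ib <- internal_bounds(reference)
  internal <- IRanges::IRanges(ib[["start"]], ib[["end"]])
  ov <- IRanges::intersect(aligned_ranges, internal)
  if (sum(IRanges::width(ov)) >= min_internal_bp) "provirus" else "solo_LTR"
}

# aligned bases of a solo LTR mapped onto LTR5 coordinates (LTR3 matches
# are translated so a copy matching either reference LTR scores the same)
solo_ltr_aligned <- function(rng, reference) {
  b5 <- region_bounds(reference, "LTR5")
  b3 <- region_bounds(reference, "LTR3")
  in5 <- IRanges::intersect(rng, IRanges::IRanges(b5[[1L]], b5[[2L]]))
  in3 <- IRanges::intersect(rng, IRanges::IRanges(b3[[1L]], b3[[2L]]))
  shift3 <- IRanges::shift(in3, b5[[1L]] - b3[[1L]])
  sum(IRanges::width(IRanges::reduce(c(in5, shift3))))
}

#' Name loci from a cytoband table
#'
#' Each locus is named by the cytoband containing its midpoint, in the
#' conventional `16p12.3` style (chromosome without the `chr` prefix plus
#' band label).  Without a cytoband table — or when the midpoint falls in no
#' band — the fallback is `chrom:start-end`.  Two loci in one band share the
#' band name; `locus_id` disambiguates.
#'
#' @param loci Locus tibble (needs `chrom`, `start`, `end`).
#' @param cytobands Tibble from [read_cytobands()], or `NULL`.
#' @return `loci` with its `name` column filled.
#' @export
name_loci <- function(loci, cytobands = NULL) {
  fallback <- paste0(loci$chrom, ":", loci$start, "-", loci$end)
  if (is.null(cytobands) || !nrow(loci)) {
    loci$name <- fallback
    return(loci)
  }
  mid <- (loci$start + loci$end) %/% 2L
  nm <- map_chr(seq_len(nrow(loci)), function(i) {
    hit <- cytobands %>%
      filter(
        .data$chrom == loci$chrom[i],
        .data$start <= mid[i], .data$end >= mid[i]
      )
    if (!nrow(hit)) {
      warning("locus midpoint in no cytoband: ", fallback[i])
      return(fallback[i])
    }
    paste0(sub("^chr", "", hit$chrom[1L]), hit$band[1L])
  })
  loci$name <- nm
  loci
}

#' Discover reference-homologous element loci in a genome
#'
#' End-to-end discovery: build the stepped k-mer index, run the
#' seed-extend-chain search on both strands, merge chains into loci,
#' classify each as provirus or solo LTR, and name them.
#'
#' @inheritParams build_index
#' @inheritParams search_chains
#' @inheritParams merge_chains_to_loci
#' @param cytobands Optional cytoband tibble for naming.
#' @return Locus tibble (see [merge_chains_to_loci()]).
#' @export
discover_elements <- function(genome, reference, cytobands = NULL,
                              k = 11L, step = 5L, min_seed_hits = 2L,
                              xdrop = 18L, max_locus_gap = 10000L,
                              min_aligned = 100L) {
  index <- build_index(genome, k = k, step = step)
  chains <- search_chains(reference, index, genome,
    min_seed_hits = min_seed_hits, xdrop = xdrop,
    max_chain_gap = max_locus_gap
  )
  loci <- merge_chains_to_loci(chains, reference,
    max_locus_gap = max_locus_gap, min_aligned = min_aligned
  )
  name_loci(loci, cytobands)
}

#' Extract the oriented sequence of each locus
#'
#' Minus-strand loci are reverse-complemented so every returned sequence is
#' in reference orientation.
#'
#' @param genome A `genome_assembly`.
#' @param loci Locus tibble.
#' @return Named character vector (names = `locus_id`).
#' @export
locus_sequences <- function(genome, loci) {
  out <- map_chr(seq_len(nrow(loci)), function(i) {
    s <- substr(genome$seq[[loci$chrom[i]]], loci$start[i], loci$end[i])
    if (loci$strand[i] == "-") revcomp(s) else s
  })
  setNames(out, loci$locus_id)
}

#' Stratify provirus loci by reference coverage
#'
#' Bins: coverage strictly above 70%, 40-70% inclusive, and below 40% of the
#' reference length.
#'
#' @param coverage_pct Numeric coverage percentages (or a locus tibble with
#'   that column).
#' @return Tibble `stratum`, `n` (three rows; counts sum to the input size).
#' @export
stratify_lengths <- function(coverage_pct) {
  if (is.data.frame(coverage_pct)) coverage_pct <- coverage_pct$coverage_pct
  tibble(
    stratum = c(">70%", "40-70%", "<40%"),
    n = c(
      sum(coverage_pct > 70),
      sum(coverage_pct >= 40 & coverage_pct <= 70),
      sum(coverage_pct < 40)
    )
  )
}

#' Screen elements for downstream analyses
#'
#' Applies the standard length screens before phylogenetic/dating analyses:
#' solo LTRs retained when their LTR coverage exceeds `solo_min_pct` of the
#' reference LTR; proviruses retained when their reference coverage exceeds
#' `provirus_min_pct`; and, per coding region, elements whose region
#' integrity exceeds `region_min_pct`.
#'
#' @param loci Locus tibble with `element_class` and `coverage_pct` (solo
#'   rows may instead carry `ltr_pct`).
#' @param integrity Optional per-region integrity tibble (columns `ltr5`,
#'   `gag`, `pro`, `pol`, `env`, `ltr3` plus an id column).
#' @param solo_min_pct,provirus_min_pct,region_min_pct Thresholds (%).
#' @return List: `solo_ltr`, `provirus` (filtered tibbles) and `regions`
#'   (named list of id vectors per region) when `integrity` is given.
#' @export
screen_for_analysis <- function(loci, integrity = NULL, solo_min_pct = 90,
                                provirus_min_pct = 80, region_min_pct = 90) {
  solo <- loci %>% filter(.data$element_class == "solo_LTR")
  solo_metric <- solo$ltr_pct %||% solo$coverage_pct
  prov <- loci %>% filter(.data$element_class == "provirus")
  out <- list(
    solo_ltr = solo[solo_metric > solo_min_pct, , drop = FALSE],
    provirus = prov[prov$coverage_pct > provirus_min_pct, , drop = FALSE]
  )
  if (!is.null(integrity)) {
    idcol <- intersect(c("locus_id", "locus"), names(integrity))[1L]
    out$regions <- map(
      setNames(nm = c("gag", "pro", "pol", "env")),
      ~ integrity[[idcol]][integrity[[.x]] > region_min_pct]
    )
  }
  out
}
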