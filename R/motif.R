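#' Read JASPAR-style PWM text
#'
#' Parses the plain-text matrix format: a `>ID name` header followed by
#' four rows of counts, either bare numbers or `A  [ 1 2 3 ]` style.
#'
#' @param path Path to the matrix file (may hold several matrices).
#' @return List of `erv_pwm` objects (`id`, `name`, `counts` 4 x L matrix
#'   with rows A/C/G/T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no matrix headers found", call. = FALSE)
  map(seq_along(starts), function(i) {
    from <- starts[i] + 1L
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    header <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(header, "\\s+")[[1L]][1L]
    name <- sub("^\\S+\\s*", "", header)
    body <- lines[from:to]
    if (length(body) != 4L) stop("expected 4 count rows for ", id, call. = FALSE)
    rows <- map(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    })
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (ncol(counts) < 4L) stop("PWM must have length >= 4", call. = FALSE)
    structure(list(id = id, name = trimws(name), counts = counts),
      class = "erv_pwm"
    )
  })
}

#' @export
print.erv_pwm <- function(x, ...) {
  cat("<erv_pwm> ", x$id, " ", x$name, " (length ", ncol(x$counts), ")\n", sep = "")
  invisible(x)
}

# per-column probabilities with a background-proportional pseudocount
# totalling `pseudocount` per column
pwm_probs <- function(pwm, background = rep(0.25, 4L), pseudocount = 0.8) {
  counts <- pwm$counts
  sweep(counts + pseudocount * background, 2L,
    colSums(counts) + pseudocount, "/"
  )
}

# log2-odds score matrix, with an extra zero row for ambiguous bases (an N
# contributes the background probability, i.e. log2(bg/bg) = 0)
pwm_score_matrix <- function(pwm, background = rep(0.25, 4L), pseudocount = 0.8) {
  s <- log2(pwm_probs(pwm, background, pseudocount) / background)
  rbind(s, N = 0)
}

#' Scan a sequence with a PWM at a relative profile score threshold
#'
#' Every window on both strands is scored by the summed log2-odds of the
#' matrix; the relative profile score rescales between the minimum and
#' maximum attainable scores, `(S - S_min)/(S_max - S_min)`, and windows at
#' or above `threshold` are reported (sorted by position; antisense hits in
#' plus-strand coordinates with `strand = "-"`).  A uniform (information-
#' free) matrix has `S_max = S_min`; its relative score is defined as 1
#' everywhere and the result is flagged degenerate.
#'
#' @param pwm An `erv_pwm`.
#' @param sequence DNA string (length >= matrix length).
#' @param threshold Relative profile score threshold in `[0, 1]`.
#' @param background Base frequencies (A, C, G, T).
#' @param pseudocount Total pseudocount per column.
#' @return Tibble `matrix_id`, `start`, `strand`, `score`, `rel_score`;
#'   attribute `degenerate` when `S_max == S_min`.
#' @export
pwm_scan <- function(pwm, sequence, threshold = 0.95,
                     background = rep(0.25, 4L), pseudocount = 0.8) {
  sm <- pwm_score_matrix(pwm, background, pseudocount)
  w <- ncol(sm)
  L <- nchar(sequence)
  if (L < w) stop("sequence shorter than the matrix", call. = FALSE)
  smax <- sum(apply(sm[1:4, , drop = FALSE], 2L, max))
  smin <- sum(apply(sm[1:4, , drop = FALSE], 2L, min))
  degenerate <- isTRUE(all.equal(smax, smin))
  scan_one <- function(seq) {
    v <- seq_chars(toupper(seq))
    v[!v %in% c("A", "C", "G", "T")] <- "N"
    code <- match(v, c("A", "C", "G", "T", "N"))
    np <- L - w + 1L
    s <- numeric(np)
    for (j in seq_len(w)) {
      s <- s + sm[cbind(code[j:(j + np - 1L)], j)]
    }
    s
  }
  fwd <- scan_one(sequence)
  rev <- scan_one(revcomp(sequence))
  rel <- function(s) if (degenerate) rep(1, length(s)) else (s - smin) / (smax - smin)
  hits <- bind_rows(
    tibble(
      start = seq_along(fwd), strand = "+",
      score = fwd, rel_score = rel(fwd)
    ),
    tibble(
      start = L - (seq_along(rev) + w - 1L) + 1L, strand = "-",
      score = rev, rel_score = rel(rev)
    )
  ) %>%
    filter(.data$rel_score >= threshold) %>%
    arrange(.data$start, .data$strand) %>%
    mutate(matrix_id = pwm$id, .before = 1L)
  attr(hits, "degenerate") <- degenerate
  hits
}

#' Extract and type the primer binding site
#'
#' The primer binding site (PBS) sits a few nucleotides downstream of the
#' 5' LTR and is complementary to the 3' end of the host tRNA that primes
#' reverse transcription.  Within the search window of offsets after the
#' LTR, the 18-mer maximizing identity to the reverse complement of any
#' library tRNA's 3'-terminal 18-mer is reported, with ties broken by
#' smaller offset then library order.  Below `min_identity` the PBS is
#' reported as not found: with ~200-odd candidate windows a 50% identity
#' floor is reachable by chance, so the default bar is set where random
#' sequence passes with probability below 1e-3.
#'
#' @param provirus_seq Element sequence in reference orientation.
#' @param ltr5_end Position of the last 5' LTR base within `provirus_seq`.
#' @param trna_lib Tibble from [read_trna_library()].
#' @param window Offset window after the LTR to search (bp).
#' @param pbs_len PBS length (bp).
#' @param min_identity Minimum identity for a call.
#' @return One-row tibble: `found`, `pbs_seq`, `offset`, `trna_id`,
#'   `trna_type`, `identity`.
#' @export
extract_pbs <- function(provirus_seq, ltr5_end, trna_lib,
                        window = c(1L, 30L), pbs_len = 18L,
                        min_identity = 0.75) {
  if (!nrow(trna_lib)) stop("tRNA library is empty", call. = FALSE)
  if (nchar(provirus_seq) < ltr5_end + window[2L] + pbs_len) {
    stop("sequence too short for the PBS search window", call. = FALSE)
  }
  targets <- map_chr(trna_lib$seq, function(s) {
    revcomp(substr(s, nchar(s) - pbs_len + 1L, nchar(s)))
  })
  target_chars <- map(targets, seq_chars)
  best <- tibble(
    found = FALSE, pbs_seq = NA_character_, offset = NA_integer_,
    trna_id = NA_character_, trna_type = NA_character_, identity = 0
  )
  for (off in window[1L]:window[2L]) {
    cand <- substr(provirus_seq, ltr5_end + off, ltr5_end + off + pbs_len - 1L)
    cv <- seq_chars(cand)
    for (t in seq_along(targets)) {
      id_frac <- mean(cv == target_chars[[t]])
      if (id_frac > best$identity + 1e-12) {
        best <- tibble(
          found = TRUE, pbs_seq = cand, offset = off,
          trna_id = trna_lib$id[t], trna_type = trna_lib$type[t],
          identity = id_frac
        )
      }
    }
  }
  if (best$identity < min_identity) {
    best$found <- FALSE
    best$trna_id <- NA_character_
    best$trna_type <- NA_character_
  }
  best
}

#' Conservation profile (logo matrix) of a PBS set
#'
#' Per-position base frequencies, Shannon entropy `H` and information
#' content `IC = 2 - H` (bits), plus the modal consensus (ties broken
#' alphabetically).
#'
#' @param pbs_seqs Character vector of equal-length PBS sequences.
#' @return An `erv_pbs_profile`: `counts` (4 x L), `freq`, `ic` (length L),
#'   `consensus`, `n`.
#' @export
pbs_logo <- function(pbs_seqs) {
  stopifnot(length(pbs_seqs) >= 1L)
  lens <- nchar(pbs_seqs)
  if (length(unique(lens)) != 1L) {
    stop("PBS sequences must share one length", call. = FALSE)
  }
  m <- do.call(rbind, lapply(toupper(pbs_seqs), seq_chars))
  counts <- apply(m, 2L, function(col) {
    table(factor(col, levels = c("A", "C", "G", "T")))
  })
  freq <- sweep(counts, 2L, pmax(colSums(counts), 1L), "/")
  ic <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  consensus <- paste(rownames(counts)[apply(counts, 2L, which.max)], collapse = "")
  structure(
    list(
      counts = counts, freq = freq, ic = ic,
      consensus = consensus, n = length(pbs_seqs)
    ),
    class = "erv_pbs_profile"
  )
}

#' @export
print.erv_pbs_profile <- function(x, ...) {
  cat(
    "<erv_pbs_profile> ", x$n, " sequence(s), consensus ", x$consensus,
    ", mean IC ", round(mean(x$ic), 3L), " bits\n",
    sep = ""
  )
  invisible(x)
}
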