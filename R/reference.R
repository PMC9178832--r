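#' Canonical proviral region names
#'
#' The six regions of a canonical betaretrovirus-like provirus, in genomic
#' order: the two long terminal repeats flanking the gag, pro, pol and env
#' coding regions.
#'
#' @return Character vector of region names.
#' @export
canonical_regions <- function() c("LTR5", "gag", "pro", "pol", "env", "LTR3")

#' Default HML-9 reference region table
#'
#' Region coordinates of the assembled LTR14C-HERVK14C-LTR14C proviral
#' reference (Dfam annotation): 5' LTR 1-587, gag CDS 758-2548, pro CDS
#' 2548-3435, pol CDS 3411-6060, env CDS 5975-8020, 3' LTR 8022-8608.
#' pro and pol overlap by design (ribosomal frameshift), as do gag/pro and
#' pol/env boundaries.
#'
#' @return A tibble with columns `region`, `start`, `end` (1-based inclusive).
#' @export
hml9_regions <- function() {
  tibble(
    region = canonical_regions(),
    start = c(1L, 758L, 2548L, 3411L, 5975L, 8022L),
    end = c(587L, 2548L, 3435L, 6060L, 8020L, 8608L)
  )
}

#' Construct a validated proviral reference
#'
#' A proviral reference couples one DNA sequence with an ordered region
#' coordinate map (LTR5/gag/pro/pol/env/LTR3, 1-based inclusive).  Validation
#' enforces: all six canonical regions present; all coordinates within the
#' sequence; LTR5 starting at position 1; non-decreasing region starts; and
#' twin LTR lengths within 5% of each other (twin LTRs are identical at
#' integration, so a reference whose LTRs differ grossly in length is
#' malformed).
#'
#' @param sequence DNA string (or `DNAString`).
#' @param regions Data frame with columns `region`, `start`, `end`.
#' @param name Label for the reference.
#' @return An object of class `proviral_reference`.
#' @export
proviral_reference <- function(sequence, regions = hml9_regions(),
                               name = "reference") {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L, is.data.frame(regions))
  regions <- as_tibble(regions)
  if (!all(c("region", "start", "end") %in% names(regions))) {
    stop("region table needs columns region/start/end", call. = FALSE)
  }
  missing <- setdiff(canonical_regions(), regions$region)
  if (length(missing)) {
    stop("region table is missing: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  regions <- regions[match(canonical_regions(), regions$region), c("region", "start", "end")]
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  len <- nchar(sequence)
  if (any(regions$start < 1L) || any(regions$end > len)) {
    stop("region coordinates exceed the reference sequence length", call. = FALSE)
  }
  if (any(regions$end < regions$start)) {
    stop("region end before start", call. = FALSE)
  }
  if (regions$start[regions$region == "LTR5"] != 1L) {
    stop("LTR5 must start at position 1", call. = FALSE)
  }
  if (is.unsorted(regions$start)) {
    stop("region starts must be non-decreasing", call. = FALSE)
  }
  l5 <- diff(unlist(regions[regions$region == "LTR5", c("start", "end")])) + 1L
  l3 <- diff(unlist(regions[regions$region == "LTR3", c("start", "end")])) + 1L
  if (abs(l5 - l3) / max(l5, l3) >= 0.05) {
    stop("twin LTR lengths differ by 5% or more", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence, regions = regions),
    class = "proviral_reference"
  )
}

#' @export
print.proviral_reference <- function(x, ...) {
  cat(
    "<proviral_reference> ", x$name, ": ", nchar(x$sequence), " bp, regions ",
    paste0(
      x$regions$region, " ", x$regions$start, "-", x$regions$end,
      collapse = "; "
    ), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a proviral reference from FASTA plus a region table
#'
#' The FASTA must contain exactly one record.  The region table is plain
#' text, `region<TAB>start<TAB>end`, with or without a header line, and must
#' name all six canonical regions.
#'
#' @param fasta_path Path to a single-record FASTA.
#' @param region_table_path Path to the region table.
#' @return A `proviral_reference`.
#' @export
read_reference <- function(fasta_path, region_table_path) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L) {
    stop("reference FASTA must contain exactly one record", call. = FALSE)
  }
  regions <- read_region_table(region_table_path)
  proviral_reference(as.character(dna[[1L]]), regions,
    name = sub("\\s.*$", "", names(dna)[1L])
  )
}

#' Read a region table
#'
#' @param path Path to a `region<TAB>start<TAB>end` file (header optional).
#' @return Tibble with columns `region`, `start`, `end`.
#' @export
read_region_table <- function(path) {
  raw <- readr::read_tsv(path,
    col_names = FALSE, col_types = readr::cols(.default = "c"),
    progress = FALSE
  )
  if (ncol(raw) < 3L) stop("region table needs three columns", call. = FALSE)
  if (!raw[[1L]][1L] %in% canonical_regions()) raw <- raw[-1L, ] # header line
  tibble(
    region = raw[[1L]],
    start = as.integer(raw[[2L]]),
    end = as.integer(raw[[3L]])
  )
}

#' Write a region table
#'
#' @param regions Tibble with columns `region`, `start`, `end` (or a
#'   `proviral_reference`).
#' @param path Output path.
#' @export
write_region_table <- function(regions, path) {
  if (inherits(regions, "proviral_reference")) regions <- regions$regions
  readr::write_tsv(regions[, c("region", "start", "end")], path, progress = FALSE)
}

#' Region coordinates or sequence of a reference
#'
#' @param reference A `proviral_reference`.
#' @param region One canonical region name.
#' @return `region_bounds()`: integer `c(start, end)`;
#'   `region_seq()`: the region's DNA string; `ref_length()`: reference
#'   length in bp.
#' @export
region_bounds <- function(reference, region) {
  row <- reference$regions[reference$regions$region == region, ]
  if (nrow(row) != 1L) stop("unknown region: ", region, call. = FALSE)
  c(start = row$start, end = row$end)
}

#' @rdname region_bounds
#' @export
region_seq <- function(reference, region) {
  b <- region_bounds(reference, region)
  substr(reference$sequence, b[[1L]], b[[2L]])
}

#' @rdname region_bounds
#' @export
ref_length <- function(reference) nchar(reference$sequence)

# interval strictly between the LTRs (leader + coding + trailer)
internal_bounds <- function(reference) {
  c(
    start = unname(region_bounds(reference, "LTR5")[[2L]]) + 1L,
    end = unname(region_bounds(reference, "LTR3")[[1L]]) - 1L
  )
}

#' Build a synthetic proviral reference
#'
#' Generates a seeded random stand-in for a proviral reference with the
#' default HML-9 region layout (8,608 bp; LTRs of 587 bp).  The 3' LTR is a
#' lightly diverged copy of the 5' LTR, as in a real consensus, and an 18-nt
#' primer binding site complementary to the 3' end of the chosen tRNA is
#' planted 3 nt downstream of the 5' LTR.  This is a synthetic sequence for
#' simulation and testing; only its region geometry matches the published
#' reference.
#'
#' @param seed Integer seed (fully determines the sequence).
#' @param pbs_trna Amino-acid code of the tRNA whose 3' end the planted PBS
#'   complements (must exist in the bundled synthetic tRNA library), or `NA`
#'   to skip planting.
#' @return A `proviral_reference`.
#' @export
synthetic_reference <- function(seed = 20101L, pbs_trna = "Lys") {
  regions <- hml9_regions()
  withr::with_seed(seed, {
    ltr <- random_dna(587L)
    internal <- random_dna(8021L - 588L + 1L)
    ltr3 <- mutate_sequence(ltr, 0.02, seed = derive_seed(seed, 3L))
    if (!is.na(pbs_trna)) {
      lib <- read_trna_library(system.file("extdata", "trna_3prime_synthetic.fa",
        package = "ervscape"
      ))
      hit <- lib[lib$type == pbs_trna, ]
      if (nrow(hit) == 0L) stop("no ", pbs_trna, " tRNA in bundled library", call. = FALSE)
      pbs <- revcomp(substr(hit$seq[1L], nchar(hit$seq[1L]) - 17L, nchar(hit$seq[1L])))
      # leader offset 3 after the 5' LTR: internal positions 3..20
      substr(internal, 3L, 20L) <- pbs
    }
    proviral_reference(paste0(ltr, internal, ltr3), regions,
      name = "synthetic_provirus"
    )
  })
}
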