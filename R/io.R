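#' Build a genome assembly object
#'
#' A light container for a multi-chromosome genome: the sequences plus a
#' per-chromosome table of total and ungapped length.  Ungapped length is
#' the chromosome length minus the number of `N` bases (assembly gaps are
#' N-runs), the quantity used as `Cl` in expected-insertion-count
#' calculations.
#'
#' @param seqs Named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @return An object of class `genome_assembly` with elements `seq` (named
#'   character) and `info` (tibble: `chrom`, `length`, `ungapped_length`).
#' @export
genome_assembly <- function(seqs) {
  if (is(seqs, "DNAStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  seqs <- toupper(seqs)
  n_count <- map_int(seqs, ~ sum(seq_chars(.x) == "N"))
  info <- tibble(
    chrom = names(seqs),
    length = nchar(seqs),
    ungapped_length = nchar(seqs) - unname(n_count)
  )
  structure(list(seq = seqs, info = info), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(
    "<genome_assembly> ", nrow(x$info), " chromosome(s), ",
    sum(x$info$length), " bp (", sum(x$info$ungapped_length), " ungapped)\n",
    sep = ""
  )
  invisible(x)
}

#' Read / write a genome FASTA
#'
#' @param path FASTA path.
#' @return `read_genome()`: a `genome_assembly`.
#' @export
read_genome <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  genome_assembly(dna)
}

#' @rdname read_genome
#' @param genome A `genome_assembly`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$seq), path
  )
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features (1-based inclusive coordinates), attaches
#' exons to their parent genes, and derives the transcription start site from
#' the strand (span start on `+`, span end on `-`).  Exons outside their
#' gene's span are a parse error.
#'
#' @param path GFF3 path.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `tss`, and a list-column `exons` of tibbles
#'   (`start`, `end`, sorted and non-overlapping).
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  empty <- tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), tss = integer(), exons = list()
  )
  if (length(gr) == 0L) return(empty)
  md <- as.data.frame(gr)
  md$type <- as.character(md$type)
  genes <- md[md$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) return(empty)
  gid <- as.character(genes$ID)
  if (anyNA(gid)) stop("gene feature without ID attribute", call. = FALSE)
  out <- tibble(
    gene_id = gid,
    chrom = as.character(genes$seqnames),
    strand = as.character(genes$strand),
    start = as.integer(genes$start),
    end = as.integer(genes$end)
  ) %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end))
  exons <- md[md$type == "exon", , drop = FALSE]
  parent <- if (nrow(exons)) map_chr(exons$Parent, ~ as.character(.x)[1L]) else character()
  ex_tbl <- tibble(
    gene_id = parent,
    start = as.integer(exons$start),
    end = as.integer(exons$end)
  )
  out$exons <- map(out$gene_id, function(g) {
    e <- ex_tbl %>%
      filter(.data$gene_id == g) %>%
      select("start", "end") %>%
      arrange(.data$start)
    span <- out[out$gene_id == g, ]
    if (nrow(e) && (min(e$start) < span$start || max(e$end) > span$end)) {
      stop("exon outside gene span for ", g, call. = FALSE)
    }
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)])) {
      stop("overlapping exons for ", g, call. = FALSE)
    }
    e
  })
  out
}

#' Write gene models to GFF3
#'
#' @param genes Gene tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @export
write_gene_annotation <- function(genes, path) {
  if (nrow(genes) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  ex <- genes %>%
    select("gene_id", "chrom", "strand", "exons") %>%
    tidyr::unnest("exons")
  gene_gr <- GenomicRanges_make(
    genes$chrom, genes$start, genes$end, genes$strand,
    type = "gene", ID = genes$gene_id, Parent = NA_character_
  )
  ex_gr <- if (nrow(ex)) {
    GenomicRanges_make(ex$chrom, ex$start, ex$end, ex$strand,
      type = "exon",
      ID = paste0(ex$gene_id, ":exon", ave(seq_len(nrow(ex)), ex$gene_id, FUN = seq_along)),
      Parent = ex$gene_id
    )
  } else {
    NULL
  }
  gr <- if (is.null(ex_gr)) gene_gr else c(gene_gr, ex_gr)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

GenomicRanges_make <- function(chrom, start, end, strand, type, ID, Parent) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  gr$type <- type
  gr$ID <- ID
  gr$Parent <- ifelse(is.na(Parent), "", Parent)
  gr
}

#' Load the packaged HML-9 locus catalog
#'
#' TSV transcriptions of the published genome-wide HML-9 survey tables are
#' shipped with the package: the 23-provirus catalog, the 47 solo-LTR
#' catalog, the per-region integrity table, and the integration-age table
#' (20 dated proviruses).  Coordinates are 1-based inclusive; every row is
#' checked against the `length = end - start + 1` invariant on load.
#'
#' @param table One of `"provirus"`, `"solo_ltr"`, `"integrity"`, `"ages"`.
#' @return A tibble.
#' @export
hml9_catalog <- function(table = c("provirus", "solo_ltr", "integrity", "ages")) {
  table <- match.arg(table)
  file <- switch(table,
    provirus = "hml9_provirus_catalog.tsv",
    solo_ltr = "hml9_solo_ltr_catalog.tsv",
    integrity = "hml9_region_integrity.tsv",
    ages = "hml9_integration_ages.tsv"
  )
  path <- system.file("extdata", file, package = "ervscape")
  out <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (table %in% c("provirus", "solo_ltr")) {
    bad <- out$length_bp != out$end - out$start + 1L
    if (any(bad)) {
      stop(
        "fixture transcription error (length != end - start + 1): ",
        paste(out$locus[bad], collapse = ", "),
        call. = FALSE
      )
    }
  }
  out
}

#' Convert between locus tables and BED intervals
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open.
#' The two functions are exact inverses.
#'
#' @param loci Tibble with `chrom`, `start`, `end`, and optionally `name`,
#'   `strand`.
#' @return `loci_to_bed()`: tibble with BED columns; `bed_to_loci()`: tibble
#'   with 1-based inclusive `start`/`end`.
#' @export
loci_to_bed <- function(loci) {
  tibble(
    chrom = loci$chrom,
    start = loci$start - 1L,
    end = loci$end,
    name = loci$name %||% paste0(loci$chrom, ":", loci$start, "-", loci$end),
    score = 0L,
    strand = loci$strand %||% "."
  )
}

#' @rdname loci_to_bed
#' @param bed Tibble with BED columns (`chrom`, `start`, `end`, ...).
#' @export
bed_to_loci <- function(bed) {
  out <- as_tibble(bed)
  out$start <- out$start + 1L
  out
}

#' Read / write a BED file
#'
#' @param path BED path (3-6 columns, no header).
#' @return `read_bed()`: tibble with 0-based half-open coordinates as stored.
#' @export
read_bed <- function(path) {
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  raw <- readr::read_tsv(path,
    col_names = FALSE, col_types = readr::cols(.default = "c"),
    progress = FALSE
  )
  names(raw) <- nm[seq_len(ncol(raw))]
  raw$start <- as.integer(raw$start)
  raw$end <- as.integer(raw$end)
  as_tibble(raw)
}

#' @rdname read_bed
#' @param bed Tibble of BED columns.
#' @export
write_bed <- function(bed, path) {
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a cytoband table
#'
#' BED-like four-column file (`chrom`, 0-based start, end, band label, e.g.
#' `p12.3`).  Returned 1-based inclusive.
#'
#' @param path Path to the cytoband table.
#' @return Tibble `chrom`, `start`, `end`, `band`.
#' @export
read_cytobands <- function(path) {
  raw <- read_bed(path)
  tibble(
    chrom = raw$chrom, start = raw$start + 1L, end = raw$end,
    band = raw$name
  )
}

#' Read a tRNA 3'-end library
#'
#' FASTA whose record names encode the amino-acid type as a leading token,
#' e.g. `Lys-tRNA-1`.  Used for primer-binding-site typing; only the
#' 3'-terminal 18-mer of each entry matters.
#'
#' @param path FASTA path.
#' @return Tibble `id`, `type`, `seq`.
#' @export
read_trna_library <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dna))
  tibble(
    id = ids,
    type = sub("[-_].*$", "", ids),
    seq = unname(as.character(dna))
  )
}
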