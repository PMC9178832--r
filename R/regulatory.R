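#' Build GREAT-style basal-plus-extension regulatory domains
#'
#' Every gene gets a basal domain around its TSS — 5,000 bp upstream and
#' 1,000 bp downstream in the gene's reading direction — which is then
#' extended on each side to the nearer of the closest neighboring basal
#' domain boundary and `max_extension` (1 Mb), clipped to the chromosome.
#' A gene's own basal domain is never truncated by a neighbor, and
#' intergenic stretches between two basal domains are covered by both
#' flanking genes' extensions (which is why elements typically associate
#' with two genes).
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `tss`).
#' @param chrom_lengths Named chromosome lengths (or a `genome_assembly`).
#' @param basal_upstream,basal_downstream Basal window, bp from the TSS.
#' @param max_extension Maximum extension per side, bp.
#' @return Tibble: `gene_id`, `chrom`, `strand`, `tss`, `basal_start`,
#'   `basal_end`, `ext_start`, `ext_end`.
#' @export
build_domains <- function(genes, chrom_lengths, basal_upstream = 5000L,
                          basal_downstream = 1000L, max_extension = 1000000L) {
  if (inherits(chrom_lengths, "genome_assembly")) {
    chrom_lengths <- setNames(chrom_lengths$info$length, chrom_lengths$info$chrom)
  }
  if (!nrow(genes)) {
    return(tibble(
      gene_id = character(), chrom = character(), strand = character(),
      tss = integer(), basal_start = integer(), basal_end = integer(),
      ext_start = integer(), ext_end = integer()
    ))
  }
  bad <- genes$tss < 1L | genes$tss > chrom_lengths[genes$chrom]
  if (any(bad)) {
    stop("TSS outside chromosome for: ", paste(genes$gene_id[bad], collapse = ", "),
      call. = FALSE
    )
  }
  d <- genes %>%
    select("gene_id", "chrom", "strand", "tss") %>%
    mutate(
      basal_start = pmax(1L, ifelse(.data$strand == "+",
        .data$tss - basal_upstream, .data$tss - basal_downstream
      )),
      basal_end = pmin(
        unname(chrom_lengths[.data$chrom]),
        ifelse(.data$strand == "+",
          .data$tss + basal_downstream, .data$tss + basal_upstream
        )
      )
    )
  d %>%
    group_by(.data$chrom) %>%
    group_modify(function(g, key) {
      clen <- chrom_lengths[[key$chrom]]
      g$ext_start <- map_int(seq_len(nrow(g)), function(i) {
        left_limit <- max(1L, g$basal_start[i] - max_extension)
        nb <- g$basal_end[-i]
        nb <- nb[nb < g$basal_start[i]]
        if (length(nb)) left_limit <- max(left_limit, max(nb) + 1L)
        as.integer(min(left_limit, g$basal_start[i]))
      })
      g$ext_end <- map_int(seq_len(nrow(g)), function(i) {
        right_limit <- min(clen, g$basal_end[i] + max_extension)
        nb <- g$basal_start[-i]
        nb <- nb[nb > g$basal_end[i]]
        if (length(nb)) right_limit <- min(right_limit, min(nb) - 1L)
        as.integer(max(right_limit, g$basal_end[i]))
      })
      g
    }) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$tss)
}

#' Associate elements with regulatory domains
#'
#' An element associates with every gene whose extended domain contains the
#' element midpoint.  The signed distance is midpoint minus TSS in the
#' gene's reading direction (positive downstream of the TSS), binned by
#' absolute value into `[0,5k)`, `[5k,50k)`, `[50k,500k)`, `[500k,Inf)`.
#'
#' @param elements Tibble with `chrom`, `start`, `end` and an id column
#'   (`locus_id` or `element_id` or `name`).
#' @param domains Output of [build_domains()].
#' @return Tibble of associations: `element_id`, `gene_id`, `distance`,
#'   `abs_distance`, `bin`.
#' @export
associate_elements <- function(elements, domains) {
  idcol <- intersect(c("locus_id", "element_id", "name"), names(elements))[1L]
  if (is.na(idcol)) stop("elements need an id column", call. = FALSE)
  el <- tibble(
    element_id = elements[[idcol]],
    chrom = elements$chrom,
    midpoint = (elements$start + elements$end) %/% 2L
  )
  out <- el %>%
    inner_join(domains, by = "chrom", relationship = "many-to-many") %>%
    filter(.data$midpoint >= .data$ext_start, .data$midpoint <= .data$ext_end) %>%
    mutate(
      distance = ifelse(.data$strand == "+",
        .data$midpoint - .data$tss, .data$tss - .data$midpoint
      ),
      abs_distance = abs(.data$distance),
      bin = distance_bin(.data$abs_distance)
    ) %>%
    select("element_id", "gene_id", "distance", "abs_distance", "bin")
  out
}

distance_bin_levels <- function() c("<5 kb", "5-50 kb", "50-500 kb", ">500 kb")

distance_bin <- function(abs_distance) {
  cut(abs_distance,
    breaks = c(0, 5000, 50000, 500000, Inf),
    labels = distance_bin_levels(), right = FALSE, include.lowest = TRUE
  )
}

#' Count associated genes per element
#'
#' @param elements Element tibble passed to [associate_elements()].
#' @param associations Its output.
#' @return Tibble `element_id`, `n_genes` (zeros included).
#' @export
count_genes_per_element <- function(elements, associations) {
  idcol <- intersect(c("locus_id", "element_id", "name"), names(elements))[1L]
  tibble(element_id = elements[[idcol]]) %>%
    left_join(
      count(associations, .data$element_id, name = "n_genes"),
      by = "element_id"
    ) %>%
    mutate(n_genes = tidyr::replace_na(.data$n_genes, 0L))
}

#' Bin TSS distances
#'
#' @param associations Output of [associate_elements()] (or a numeric vector
#'   of absolute distances).
#' @return Tibble `bin`, `n` over the four canonical bins.
#' @export
bin_distances <- function(associations) {
  if (is.data.frame(associations)) {
    b <- associations$bin
  } else {
    b <- distance_bin(abs(associations))
  }
  tibble(bin = factor(b, levels = distance_bin_levels())) %>%
    count(.data$bin, name = "n", .drop = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Tests a gene list against category sets over a universe: categories
#' whose size (after intersection with the universe) falls outside
#' `[min_size, max_size]` are excluded; the upper-tail hypergeometric
#' p-value `P(X >= k)` is computed per remaining category;
#' Benjamini-Hochberg adjustment is applied across tested categories; the
#' `top` categories by FDR (ties by p, then category id) are flagged.
#'
#' @param gene_list Character vector (must be a subset of `universe`).
#' @param categories Tibble `category_id`, `gene_id`.
#' @param universe Character vector of all eligible genes.
#' @param min_size,max_size Category size window.
#' @param top How many top categories to flag/return.
#' @return An `erv_ora`: list with `result` (all tested categories, ranked)
#'   and `top` (the leading `top` rows).
#' @export
ora <- function(gene_list, categories, universe, min_size = 5L,
                max_size = 2000L, top = 10L) {
  if (!length(gene_list)) stop("empty gene list", call. = FALSE)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (!all(gene_list %in% universe)) {
    stop("gene_list must be a subset of the universe", call. = FALSE)
  }
  cats <- categories %>%
    filter(.data$gene_id %in% universe) %>%
    distinct(.data$category_id, .data$gene_id)
  sizes <- count(cats, .data$category_id, name = "K")
  keep <- sizes$category_id[sizes$K >= min_size & sizes$K <= max_size]
  cats <- filter(cats, .data$category_id %in% keep)
  N <- length(universe)
  n <- length(gene_list)
  res <- cats %>%
    group_by(.data$category_id) %>%
    summarise(
      K = n(),
      k = sum(.data$gene_id %in% gene_list),
      .groups = "drop"
    ) %>%
    mutate(
      N = N, n = n,
      enrichment_ratio = (.data$k / n) / (.data$K / N),
      p = phyper(.data$k - 1L, .data$K, N - .data$K, n, lower.tail = FALSE),
      fdr = p.adjust(.data$p, method = "BH")
    ) %>%
    arrange(.data$fdr, .data$p, .data$category_id) %>%
    mutate(rank = row_number())
  structure(
    list(result = res, top = head(res, top)),
    class = "erv_ora"
  )
}

#' @export
print.erv_ora <- function(x, ...) {
  cat("<erv_ora> ", nrow(x$result), " categories tested; top ",
    nrow(x$top), ":\n",
    sep = ""
  )
  print(x$top, ...)
  invisible(x)
}
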