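make_gene <- function(id, chrom, strand, tss, clen) {
  tibble::tibble(
    gene_id = id, chrom = chrom, strand = strand, tss = as.integer(tss),
    start = as.integer(tss), end = as.integer(tss),
    exons = list(tibble::tibble(start = integer(), end = integer()))
  )
}

test_that("basal and extension rules follow the worked geometry", {
  # lone + strand gene at 2 Mb on a 10 Mb chromosome
  g <- make_gene("g1", "c1", "+", 2000000L, 1e7)
  d <- build_domains(g, c(c1 = 10000000L))
  expect_equal(d$basal_start, 1995000L)
  expect_equal(d$basal_end, 2001000L)
  expect_equal(d$ext_start, 995000L)
  expect_equal(d$ext_end, 3001000L)

  # the upstream extension of gene 2 stops at gene 1's basal boundary
  g2 <- dplyr::bind_rows(
    make_gene("g1", "c1", "+", 1000000L, 1e7),
    make_gene("g2", "c1", "+", 1010000L, 1e7)
  )
  d2 <- build_domains(g2, c(c1 = 10000000L))
  expect_equal(d2$ext_start[d2$gene_id == "g2"], 1001001L)
  expect_equal(d2$ext_end[d2$gene_id == "g1"], 1004999L)
  # basal inviolability: basal always inside the extended interval
  expect_true(all(d2$ext_start <= d2$basal_start))
  expect_true(all(d2$ext_end >= d2$basal_end))

  # TSS near the chromosome start clips at 1
  g3 <- make_gene("g3", "c1", "+", 3000L, 1e7)
  d3 <- build_domains(g3, c(c1 = 10000000L))
  expect_equal(d3$basal_start, 1L)
  expect_equal(d3$ext_start, 1L)

  # minus strand flips upstream/downstream
  g4 <- make_gene("g4", "c1", "-", 2000000L, 1e7)
  d4 <- build_domains(g4, c(c1 = 10000000L))
  expect_equal(d4$basal_start, 1999000L)
  expect_equal(d4$basal_end, 2005000L)

  expect_error(build_domains(make_gene("g", "c1", "+", 2e7, 1e7),
    c(c1 = 10000000L)
  ), "outside")
})

test_that("domain assignment equals a per-base brute-force scan", {
  clen <- 1000000L
  withr::with_seed(91L, {
    tss <- sort(sample.int(clen - 20000L, 7L) + 10000L)
    strands <- sample(c("+", "-"), 7L, replace = TRUE)
  })
  genes <- dplyr::bind_rows(purrr::map(seq_along(tss), function(i) {
    make_gene(paste0("g", i), "c1", strands[i], tss[i], clen)
  }))
  domains <- build_domains(genes, c(c1 = clen))
  # basal inviolability against every neighbor
  for (i in seq_len(nrow(domains))) {
    others <- domains[-i, ]
    expect_true(all(
      domains$basal_start[i] >= domains$ext_start[i] &
        domains$basal_end[i] <= domains$ext_end[i]
    ))
  }
  # brute force: for sampled bases, the genes whose extended domain covers
  # the base, computed directly from the interval table
  withr::with_seed(92L, {
    probes <- sort(sample.int(clen, 400L))
  })
  elements <- tibble::tibble(
    element_id = paste0("e", seq_along(probes)), chrom = "c1",
    start = probes, end = probes
  )
  assoc <- associate_elements(elements, domains)
  got <- split(assoc$gene_id, assoc$element_id)
  for (p in seq_along(probes)) {
    cover <- domains$gene_id[
      domains$ext_start <= probes[p] & domains$ext_end >= probes[p]
    ]
    mine <- got[[paste0("e", p)]] %||% character()
    expect_setequal(mine, cover)
  }
})

test_that("association distances are signed by reading direction and
          binned left-closed", {
  domains <- build_domains(
    make_gene("g1", "c1", "-", 600000L, 2e6), c(c1 = 2000000L)
  )
  # element midpoint 590,000 is downstream of a minus-strand TSS at 600,000
  el <- tibble::tibble(element_id = "e1", chrom = "c1", start = 589000L, end = 591000L)
  a <- associate_elements(el, domains)
  expect_equal(a$distance, 10000L)

  # bin boundaries are left-closed at 5k/50k/500k
  bins <- ervscape:::distance_bin(c(1000, 4999, 5000, 49999, 50000, 499999, 500000))
  expect_equal(
    as.character(bins),
    c("<5 kb", "<5 kb", "5-50 kb", "5-50 kb", "50-500 kb", "50-500 kb", ">500 kb")
  )
  counts <- bin_distances(c(1000, 10000, 100000, 600000))
  expect_equal(counts$n, c(1L, 1L, 1L, 1L))
  expect_equal(bin_distances(numeric())$n, rep(0L, 4L))

  # gene-desert element: no associations, counted as zero genes
  far <- tibble::tibble(element_id = "far", chrom = "c1", start = 1900000L, end = 1900100L)
  a2 <- associate_elements(far, domains)
  expect_equal(nrow(a2), 0L)
  counts2 <- count_genes_per_element(far, a2)
  expect_equal(counts2$n_genes, 0L)
})

test_that("hypergeometric ORA matches exhaustive enumeration", {
  universe <- paste0("G", 1:20)
  cats <- dplyr::bind_rows(
    tibble::tibble(category_id = "c5", gene_id = paste0("G", 1:5)),
    tibble::tibble(category_id = "tiny", gene_id = paste0("G", 1:4)),
    tibble::tibble(category_id = "all", gene_id = universe)
  )
  gene_list <- paste0("G", c(1:3, 10, 11))
  res <- ora(gene_list, cats, universe, min_size = 5L, max_size = 2000L)
  tab <- tidy(res)
  # size-4 category excluded by the minimum-size rule
  expect_false("tiny" %in% tab$category_id)
  # category == universe -> p = 1
  expect_equal(tab$p[tab$category_id == "all"], 1)
  # N=20, K=5, n=5, k=3 equals the enumeration sum
  p_manual <- sum(sapply(3:5, function(i) {
    choose(5, i) * choose(15, 5 - i)
  })) / choose(20, 5)
  expect_equal(tab$p[tab$category_id == "c5"], p_manual)

  # random instances with N <= 25: p equals enumeration each time
  for (s in 1:10) {
    withr::with_seed(200L + s, {
      N <- sample(10:25, 1L)
      uni <- paste0("u", seq_len(N))
      K <- sample(5:min(9, N), 1L)
      n <- sample(3:8, 1L)
      cat_genes <- sample(uni, K)
      gl <- sample(uni, n)
    })
    k <- sum(gl %in% cat_genes)
    r <- ora(gl, tibble::tibble(category_id = "c", gene_id = cat_genes), uni)
    p_enum <- sum(sapply(k:min(n, K), function(i) {
      choose(K, i) * choose(N - K, n - i)
    })) / choose(N, n)
    expect_equal(tidy(r)$p, p_enum, tolerance = 1e-12)
  }

  # BH monotonicity after ranking by p; adjusted values capped at 1
  many <- dplyr::bind_rows(purrr::map(1:12, function(i) {
    withr::with_seed(300L + i, {
      tibble::tibble(category_id = paste0("m", i), gene_id = sample(universe, 6L))
    })
  }))
  r2 <- tidy(ora(gene_list, many, universe, min_size = 2L))
  expect_true(all(diff(r2$fdr[order(r2$p)]) >= -1e-12))
  expect_true(all(r2$fdr <= 1))

  expect_error(ora(character(), cats, universe), "empty")
  expect_error(ora("G1", cats, character()), "empty")
  expect_error(ora("X9", cats, universe), "subset")
})
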