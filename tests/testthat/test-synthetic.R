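test_that("mutate_sequence hits its divergence target and is deterministic", {
  withr::with_seed(99L, {
    s <- random_dna(10000L)
  })
  # zero divergence is the identity
  expect_identical(mutate_sequence(s, 0, seed = 7L), s)
  # realized p-distance within 3 binomial standard errors of the target
  m <- mutate_sequence(s, 0.10, seed = 7L)
  p <- mean(seq_chars(s) != seq_chars(m))
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(p - 0.10), 3 * se)
  # determinism for a fixed seed
  expect_identical(mutate_sequence(s, 0.10, seed = 7L), m)
  expect_false(identical(mutate_sequence(s, 0.10, seed = 8L), m))
  # saturation guard
  expect_error(mutate_sequence(s, 0.80, seed = 1L), "saturation")
})

test_that("transition bias follows the K2P kappa", {
  withr::with_seed(5L, {
    s <- random_dna(50000L)
  })
  m <- mutate_sequence(s, 0.30, model = mutation_model(kappa = 2), seed = 3L)
  a <- seq_chars(s)
  b <- seq_chars(m)
  diffs <- a != b
  ts <- diffs & paste0(a, b) %in% c("AG", "GA", "CT", "TC")
  # kappa = 2 puts transitions at half of all changes (alpha = 2*beta,
  # two transversion targets): P_ts/P_tv_total depends on time, but at
  # moderate divergence stays near 1:1; allow a generous band
  frac_ts <- sum(ts) / sum(diffs)
  expect_gt(frac_ts, 0.40)
  expect_lt(frac_ts, 0.60)
})

test_that("planted proviruses realize the twin-LTR clock premise", {
  ref <- test_reference()
  model <- mutation_model() # 0.002 subs/site/my
  # expected LTR-LTR p-distance for age 20 my: ~2 x 0.002 x 20 = 0.08
  dists <- purrr::map_dbl(1:60, function(i) {
    el <- ervscape:::build_element_seq(
      ref, plant_spec("full_provirus", true_age_my = 20), model,
      seed = 5000L + i
    )
    l5 <- substr(el, 1L, 587L)
    l3 <- substr(el, nchar(el) - 586L, nchar(el))
    p_distance(l5, l3)$D
  })
  expect_lt(abs(mean(dists) - 0.08) / 0.08, 0.05)
})

test_that("plant_element records truth and enforces overlap and bounds", {
  ref <- test_reference()
  g <- genome_assembly(c(chrT = withr::with_seed(1L, random_dna(30000L))))
  sp <- plant_spec("solo_LTR", chrom = "chrT", insert_pos = 10000L,
    true_age_my = 5
  )
  res <- plant_element(g, ref, sp, seed = 2L)
  expect_equal(res$truth$end - res$truth$start + 1L, 587L)
  expect_equal(nchar(res$genome$seq[["chrT"]]), 30587L)
  # inserting inside the recorded element is an overlap error
  sp2 <- plant_spec("solo_LTR", chrom = "chrT", insert_pos = 10200L)
  expect_error(
    plant_element(res$genome, ref, sp2, seed = 3L, existing_truth = res$truth),
    "overlap|inside"
  )
  expect_error(
    plant_element(g, ref, plant_spec("solo_LTR", chrom = "chrT",
      insert_pos = 99999L
    ), seed = 3L),
    "outside"
  )
  # full deletion of pol forces zero pol integrity downstream
  spdel <- plant_spec("deleted_provirus", chrom = "chrT", insert_pos = 5000L,
    true_age_my = 5, deletions = tibble::tibble(start = 3411L, end = 6060L)
  )
  resd <- plant_element(g, ref, spdel, seed = 4L)
  el <- substr(resd$genome$seq[["chrT"]], resd$truth$start, resd$truth$end)
  ann <- annotate_regions(align_to_reference(el, ref), ref)
  # at most a stray junction base may land inside pol (alignment tie)
  expect_lt(ann$integrity$integrity_pct[ann$integrity$region == "pol"], 0.1)
})

test_that("generate_genome is deterministic, respects contexts and books
          every plant", {
  cfg <- list(
    chromosomes = c(c1 = 120000L, c2 = 90000L),
    n_genes = 6L,
    plants = dplyr::bind_rows(
      plant_spec("full_provirus", true_age_my = 10, context_target = "intergenic"),
      plant_spec("solo_LTR", true_age_my = 5, context_target = "intron"),
      plant_spec("solo_LTR", true_age_my = 8, context_target = "intergenic")
    )
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sim1 <- generate_genome(cfg, seed = 11L, dir = d1, reference = test_reference())
  sim2 <- generate_genome(cfg, seed = 11L, dir = d2, reference = test_reference())
  for (f in c("genome.fa", "genes.gff3", "truth.tsv")) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f))
    )
  }
  expect_equal(nrow(sim1$truth), 3L)
  # the intron-targeted solo LTR lies inside an intron of some gene
  tr <- sim1$truth[sim1$truth$context == "intron", ]
  g <- sim1$genes %>%
    dplyr::filter(.data$chrom == tr$chrom, .data$start <= tr$start, .data$end >= tr$end)
  expect_gte(nrow(g), 1L)
  ex <- tidyr::unnest(g["exons"], "exons")
  expect_false(any(ex$start <= tr$end & ex$end >= tr$start))
  # no planted element overlaps another or crosses a chromosome end
  truth <- dplyr::arrange(sim1$truth, .data$chrom, .data$start)
  by_chrom <- split(truth, truth$chrom)
  for (tt in by_chrom) {
    if (nrow(tt) > 1L) {
      expect_true(all(tt$start[-1L] > tt$end[-nrow(tt)]))
    }
    expect_true(all(tt$end <= nchar(sim1$genome$seq[[tt$chrom[1L]]])))
  }
  # empty config: two bare chromosomes, no genes, no truth rows
  sim0 <- generate_genome(list(chromosomes = c(a = 5000L, b = 5000L)), seed = 1L)
  expect_equal(nrow(sim0$genes), 0L)
  expect_equal(nrow(sim0$truth %||% tibble::tibble()), 0L)
})

test_that("clock consistency holds across replicates", {
  # across >= 50 replicates the mean realized LTR-LTR p-distance stays
  # within 5% relative error of 2 x rate x age (age 25 my here)
  ref <- test_reference()
  model <- mutation_model()
  target <- 2 * 0.002 * 25
  dists <- purrr::map_dbl(1:50, function(i) {
    el <- ervscape:::build_element_seq(
      ref, plant_spec("full_provirus", true_age_my = 25), model,
      seed = 9000L + i
    )
    p_distance(substr(el, 1L, 587L), substr(el, nchar(el) - 586L, nchar(el)))$D
  })
  expect_lt(abs(mean(dists) - target) / target, 0.05)
})
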