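# shared fixtures: one reference and a couple of planted genomes, built once
# per test run

test_reference <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- synthetic_reference()
    ref
  }
})

test_trna <- function() {
  read_trna_library(system.file("extdata", "trna_3prime_synthetic.fa",
    package = "ervscape"
  ))
}

test_pwms <- function() {
  read_jaspar(system.file("extdata", "pwm_synthetic.jaspar",
    package = "ervscape"
  ))
}

# a small genome with two proviruses and two solo LTRs planted
planted_genome <- local({
  cache <- list()
  function(seed = 42L, divergences = c(20, 30, 10, 35)) {
    key <- paste(seed, paste(divergences, collapse = ","))
    if (is.null(cache[[key]])) {
      cfg <- list(
        chromosomes = c(chr1 = 200000L, chr2 = 150000L),
        n_genes = 8L,
        plants = dplyr::bind_rows(
          plant_spec("full_provirus",
            true_age_my = divergences[1],
            context_target = "intergenic"
          ),
          plant_spec("full_provirus",
            true_age_my = divergences[2],
            strand = "-", context_target = "intron"
          ),
          plant_spec("solo_LTR",
            true_age_my = divergences[3],
            context_target = "intergenic"
          ),
          plant_spec("solo_LTR",
            true_age_my = divergences[4],
            strand = "-", context_target = "intergenic"
          )
        )
      )
      cache[[key]] <<- generate_genome(cfg, seed = seed,
        reference = test_reference()
      )
    }
    cache[[key]]
  }
})

# reciprocal-overlap matching of discovered loci to truth intervals
match_truth <- function(loci, truth, min_reciprocal = 0.9) {
  hits <- logical(nrow(truth))
  matched_locus <- rep(NA_integer_, nrow(loci))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(loci))) {
      if (loci$chrom[j] != truth$chrom[i]) next
      ov <- min(loci$end[j], truth$end[i]) - max(loci$start[j], truth$start[i]) + 1L
      if (ov <= 0L) next
      r1 <- ov / (truth$end[i] - truth$start[i] + 1L)
      r2 <- ov / (loci$end[j] - loci$start[j] + 1L)
      if (r1 >= min_reciprocal && r2 >= min_reciprocal) {
        hits[i] <- TRUE
        matched_locus[j] <- i
      }
    }
  }
  list(recall = mean(hits), precision = mean(!is.na(matched_locus)),
    matched_locus = matched_locus, hit = hits)
}
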