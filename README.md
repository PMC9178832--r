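# ervscape

Characterization of endogenous retrovirus (ERV) groups in genome
assemblies: discovery, structural annotation, molecular-clock dating,
genomic landscape, regulatory association, and primer-binding-site typing.

## The scientific problem

Endogenous retroviruses are germline-fixed proviral remnants of ancient
infections, canonically structured `5'LTR–gag–pro–pol–env–3'LTR`;
recombination between the twin LTRs leaves solo LTRs behind.  Surveys of a
single ERV group (here modelled on the HERV-K HML-9 group) answer a fixed
set of questions: where are the group's proviruses and solo LTRs, how
structurally intact is each provirus, when did each integrate, is the
chromosomal and genic distribution random, which genes fall in the LTRs'
regulatory reach, and which host tRNA primed replication?

`ervscape` implements that workflow for anyone studying LTR
retroelements — as plain R functions over tibbles, so each stage can be
used, inspected, and tested on its own:

* **Discovery** — BLAT-style seed search (all genomic 11-mers at stride 5),
  ungapped x-drop extension, colinear chaining, locus merging, and
  provirus/solo-LTR classification (`discover_elements()`).
* **Structure** — affine-gap alignment to the region-annotated reference,
  per-region integrity (presence of `LTR5/gag/pro/pol/env/LTR3`), indel
  annotation, coverage and Qgap metrics (`annotate_elements()`).
* **Dating** — the molecular clock `T = D / r` for internal regions against
  the group consensus and `T = D / r / 2` for twin-LTR pairs, with
  `r = 0.2 %/nt/my`; p-distance (default) or K2P; neighbor-joining
  clustering (`date_elements()`, `nj_cluster()`).
* **Landscape** — expected insertions per chromosome `e = Cl × n / Tl`
  (ungapped lengths), overall chi-square plus per-chromosome exact binomial
  tests with BH adjustment, and intergenic/intron/exon context
  classification (`distribution_test()`, `classify_context()`).
* **Regulation** — GREAT-style basal+extension regulatory domains (5 kb
  up / 1 kb down, ≤1 Mb extension to the nearest basal domain), TSS-distance
  binning, and hypergeometric over-representation analysis with BH FDR
  (`build_domains()`, `associate_elements()`, `ora()`).
* **Motifs & PBS** — PWM scanning on both strands at a relative profile
  score threshold (default 95%), and primer-binding-site extraction with
  tRNA typing and a conservation-logo matrix (`pwm_scan()`,
  `extract_pbs()`, `pbs_logo()`).
* **Synthetic data** — a seeded generator that plants proviruses and solo
  LTRs with known age, deletions and genomic context for parameter-recovery
  validation (`generate_genome()`).
* **Catalog replay** — packaged TSV transcriptions of a published
  genome-wide HML-9 locus catalog (23 proviruses, 47 solo LTRs, integrity
  and dating tables) and `replay_catalog()`, which recomputes its summary
  statistics from the raw rows.

## Worked example

Replaying the packaged catalog:

```r
library(ervscape)
r <- replay_catalog()
r$tables$strata
#> # A tibble: 3 × 2
#>   stratum     n
#>   <chr>   <int>
#> 1 >70%        6
#> 2 40-70%      9
#> 3 <40%        8
round(r$summary[c("mean_ltr_age_my", "min_ltr_age_my", "max_ltr_age_my")], 2)
#>      mean_ltr_age_my       min_ltr_age_my       max_ltr_age_my
#>                28.83                17.50                48.50
```

Six of the 23 catalog proviruses retain more than 70% of the reference;
twin-LTR dating puts their integrations at 17.5–48.5 million years ago
(mean 28.83 my), while internal-region dating against the consensus averages
76 my — the expected inflation, since internal regions also accumulate
replication-cycle errors.

A synthetic genome with a 20-my provirus and a 10-my solo LTR planted in it:

```r
ref <- synthetic_reference()
sim <- generate_genome(list(
  chromosomes = c(chr1 = 200000L, chr2 = 150000L), n_genes = 8L,
  plants = dplyr::bind_rows(
    plant_spec("full_provirus", true_age_my = 20, context_target = "intergenic"),
    plant_spec("solo_LTR", true_age_my = 10, context_target = "intron")
  )
), seed = 21, reference = ref)

loci <- discover_elements(sim$genome, ref)
loci |> dplyr::select(chrom, strand, start, end, element_class, coverage_pct)
#> # A tibble: 2 × 6
#>   chrom strand  start    end element_class coverage_pct
#>   <chr> <chr>   <int>  <int> <chr>                <dbl>
#> 1 chr1  +      186483 187069 solo_LTR             100
#> 2 chr2  +       99572 108174 provirus              99.9

ann <- annotate_elements(locus_sequences(sim$genome, loci), ref)
dat <- date_elements(ann, ref)
dat |> dplyr::select(locus_id, d_ltr, age_ltr_my)
#> # A tibble: 2 × 3
#>   locus_id                d_ltr age_ltr_my
#>   <chr>                   <dbl>      <dbl>
#> 1 chr1:186483-187069(+) NA            NA
#> 2 chr2:99572-108174(+)   0.0876       21.9
```

Both plants are recovered at the planted coordinates and classes; the
provirus's LTR-pair divergence of 0.0876 dates it at 21.9 my against a
planted age of 20 my (a solo LTR has one LTR, so its twin-LTR age is `NA`).
`run_pipeline(demo_config(), seed = 1, out_dir = "out")` chains every stage
over a larger synthetic genome and writes the report tables as TSVs;
`plot_chromosome_distribution()`, `plot_region_integrity()`,
`plot_integration_ages()`, `plot_distance_bins()` and `plot_pbs_logo()`
visualize the results, and `tidy()`/`glance()` methods cover the test and
enrichment objects.

See `vignettes/ervscape-methods.Rmd` for the models, parameter choices and
limitations.

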