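---
title: "Methods: ERV group characterization with ervscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERV group characterization with ervscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervscape)
```

# The problem

Endogenous retroviruses (ERVs) are germline-fixed remnants of ancient
retroviral infections.  A provirus carries the canonical
`5'LTR – gag – pro – pol – env – 3'LTR` architecture; recombination between
the twin LTRs leaves a solo LTR behind.  Characterizing one ERV group in a
genome assembly means: finding every homologous locus, classifying it as
provirus or solo LTR, describing each provirus's structural decay (which
regions survive, which are deleted), dating its integration, asking whether
insertions are randomly distributed over chromosomes and gene
neighbourhoods, predicting which genes the LTRs might regulate, and typing
the primer binding site (PBS) that once primed reverse transcription.

`ervscape` implements that entire workflow as composable, tibble-in /
tibble-out functions, together with a seeded synthetic-genome generator that
plants elements with known ground truth so every stage can be validated by
parameter recovery.

# Discovery: seed, extend, chain

The search mirrors the classic whole-genome index strategy: all genomic
11-mers at stride 5 are hashed (`build_index()`); reference k-mers (both
orientations, stride 1) are looked up; diagonals that collect at least two
seeds are extended without gaps under an x-drop rule (match +2,
mismatch −3, stop when the running score falls 18 below its maximum);
gapless blocks are chained colinearly per chromosome and strand, and chains
within 10 kb merge into loci (`discover_elements()`).

Two robustness margins are deliberate and worth knowing about:

* **`min_aligned = 100` bp per locus.**  In uniform random sequence, two
  11-mer hits occasionally share a diagonal and extend into a ~30–40 bp
  pseudo-chain.  Any genuine element fragment aligns far more than 100
  reference bases, so this floor removes chance loci without touching
  sensitivity.
* **`min_internal_bp = 20` for provirus calls.**  A locus is a solo LTR iff
  its aligned reference footprint lies within the LTR coordinates.  X-drop
  extension can overshoot an LTR boundary by a few chance-matching bases,
  so the provirus call requires at least 20 aligned bases between the LTRs;
  internal-only fragments in real catalogs align hundreds.

Coverage follows the catalog conventions: for proviruses,
`100 × aligned bp / reference length`; for solo LTRs, aligned bases are
mapped onto 5'-LTR coordinates (a copy matching either reference LTR scores
the same) and divided by the LTR length.  `Qgap` counts reference bases
spanned but unaligned *inside* the locus — terminal truncations never count,
which is the only reading consistent with published rows that combine low
coverage with near-zero Qgap.

The published locus list itself depends on the exact scoring and stitching
of the original browser-based search; the thresholds here are exposed as
arguments and validated on synthetic data (100% recall and precision at
≤15% divergence, reciprocal overlap ≥ 0.9 over five seeds), not claimed to
replicate the original list base-for-base.

# Structural integrity

`align_to_reference()` performs an affine-gap alignment of each element
against the full reference with free end gaps on the reference side
(match +2, mismatch −3, gap open 12, gap extend 1), so fragments align where
they belong without being charged for missing ends.  Tie-breaking among
equal-scoring alignments is whatever the aligner's deterministic dynamic
program produces; the scoring parameters are recorded on the result object.

Per-region **integrity** is the percentage of the region's reference
positions aligned to a non-gap element base — a *presence* measure, not an
identity measure.  This is deliberate: intact but anciently diverged regions
should read near 100% even at 6–10% nucleotide divergence, which is exactly
how published integrity tables behave.  Indels are reported in reference
coordinates tagged by region; on synthetic plants, reported deletion bounds
match planted intervals within ±5 bp at ≤10% divergence (a one-base slip can
occur where the sequence at a junction is locally ambiguous).

# Molecular-clock dating

The clock rests on two facts: the twin LTRs are identical at integration and
diverge independently afterwards, and internal regions can be compared with
the group consensus as a stand-in for the ancestral state.  With neutral
rate `r = 0.2 %/nt/my` and divergence `D` (a fraction):

* internal regions: `T = D × 100 / r` (mean over available regions,
  NA-skipping, computed from unrounded per-region divergences);
* LTR pairs: `T = D × 100 / r / 2` (both copies diverge).

The default divergence measure is the **p-distance with pairwise deletion**:
published dating arithmetic is exactly linear in D, which a corrected
distance would not be.  The Kimura two-parameter distance
(`-1/2 ln((1-2P-Q)√(1-2Q))`) is available as an option for both
`date_ltr_pair()` and `date_elements()`; it removes multiple-hit attenuation
at old ages but inflates variance, and under this package's generator
(which calibrates *observed* per-branch divergence) it over-corrects, so
p-distance remains the default everywhere.

The consensus is majority-rule per column (gap only when gaps exceed half
the column; ties broken by the reference base, then alphabetically), built
from the elements whose region integrity exceeds 90% — the same screen used
before published per-region analyses.  Majority rule stands in for
likelihood-based ancestral reconstruction: at the ≤20% divergences involved,
the two agree within test tolerance on simulated sets, and majority rule is
exactly reproducible.  Elements are projected onto reference coordinates
(insertion columns dropped) so that region windows and the two LTR windows
are directly comparable column-by-column.

`nj_cluster()` provides neighbor joining with deterministic lowest-index
tie-breaking as a light intragroup clustering tool (it reproduces additive
trees exactly and separates simulated clades); it is not a substitute for
model-based phylogenetics, which is out of scope.

# Chromosomal distribution and genomic context

Expected insertions per chromosome follow `e = Cl × n / Tl` with `Cl` the
*ungapped* chromosome length (length minus N bases).  Because a single
goodness-of-fit statistic cannot attribute a departure to one chromosome,
`distribution_test()` reports both the overall Pearson chi-square
(`df = C − 1`) and per-chromosome two-sided exact binomial tests with
Benjamini–Hochberg adjustment.  Under uniform synthetic placement the
chi-square p-values are calibrated and the BH-adjusted flags stay silent in
≥90% of seeds.

Context classification uses a closed four-category set matching the catalog
tables: `Intergenic`, `Intron` (inside genes, touching no exon),
`Exon_intron` (inside genes, touching exonic sequence), and
`Exonic_intergenic` (overlapping a gene but extending beyond it).  A locus
wholly inside an exon is labelled `Exon_intron` — the set has no pure-exon
class, and published summaries group all exon-touching genic insertions
together (the 26.09% figure counts the one `Exonic_intergenic` row with the
`Exon_intron` rows, which `summarize_context(merge_exonic = TRUE)`
reproduces).  Orientation is reported relative to the overlapping gene with
the largest overlap.

# Regulatory domains and enrichment

`build_domains()` implements the basal-plus-extension association rule:
basal = 5 kb upstream / 1 kb downstream of the TSS (strand-aware), extended
per side to the nearer of the closest neighboring basal-domain boundary and
1 Mb, clipped to the chromosome.  A gene's basal domain is never truncated;
extensions stop one base short of a neighbour's basal domain, so the stretch
between two basal domains is covered by both flanking genes — which is why
elements typically associate with two genes.  Curated domain overrides used
by the original web tool cannot be reproduced offline and are omitted.

Element–gene membership is decided by the element **midpoint** (the
convention of single-point TSS-distance plots); signed distances are
reported in the gene's reading direction and binned left-closed at
5 kb / 50 kb / 500 kb.  The implementation agrees with a per-base brute-force
domain scan on chromosomes up to 1 Mb.

`ora()` is a plain hypergeometric over-representation test: categories
outside 5–2000 genes (after intersection with the universe) are dropped,
`P(X ≥ k)` per category, BH across tested categories, top 10 flagged.
P-values match exhaustive enumeration for universes up to 25 genes.

# Motifs and the primer binding site

`pwm_scan()` scores every window on both strands with log2 odds against a
uniform background (background-proportional pseudocount totalling 0.8 per
column) and reports windows whose **relative profile score**
`(S − S_min)/(S_max − S_min)` reaches the threshold (default 0.95).  A
uniform matrix has `S_max = S_min`; its relative score is defined as 1 and
the result is flagged degenerate.  Ambiguous bases contribute the background
probability (zero log-odds).  All windows passing threshold are reported;
overlapping hits are not merged.

`extract_pbs()` searches offsets 1–30 after the 5' LTR (a superset of the
canonical "approximately 3–20 nt downstream") for the 18-mer most similar to
the reverse complement of any library tRNA's 3'-terminal 18-mer — the
retroviral priming determinant; full tRNA alignment adds nothing for typing.
The call threshold is `min_identity = 0.75`: with ~240 candidate
window/tRNA combinations, a 50% identity floor is reached by random sequence
almost always (the expected maximum of Binomial(18, 0.25) matches over 240
draws is about 9–10/18), whereas 0.75 keeps the false-call rate below 1e-3
while a genuine PBS with two mutations (16/18 = 0.89) still passes
comfortably.  `pbs_logo()` computes the per-position information content
`IC = 2 − H` in bits and the modal consensus — the numeric content of a
sequence logo; rendering is left to `plot_pbs_logo()`.

# The synthetic-genome generator

`generate_genome()` emulates the statistical structure the analysis assumes:
uniform-ACGT background chromosomes (the simplest null for seed-match
specificity), gene models with exons, and planted elements with full ground
truth.  Mutation follows a Kimura two-parameter process with κ = 2
(matching the K2-family model selection reported for LTR data):
`mutate_sequence()` draws each site from the exact K2P transition matrix
whose off-diagonal mass equals the requested divergence, so the expected
observed p-distance equals the target and multiple hits are implicit.  A
full provirus mutates its internal region once and its two LTR copies
independently from the same ancestral LTR, each at `rate × age` — the
twin-LTR clock premise — so the expected LTR–LTR p-distance is slightly
below `2 × rate × age` (cross-lineage coincident hits; ≈5% relative at
40 my, within the 5% clock-consistency tolerance at the ages used).
Deletions are excised after mutation; indels are off by default (geometric
lengths, mean 3 bp, when enabled).  Context targets (intergenic / intron /
exon) are honoured by rejection-sampling insertion points against the
emitted annotation, with ≥15 kb spacing so locus merging cannot fuse plants.

What the generator does **not** emulate: real base composition (GC
isochores), repeat background, selection, orthologous flanks for
cross-species dating.  Passing tests therefore demonstrate correctness of
the algorithms under the stated model, not performance on real genomes —
in particular, real repeat-rich backgrounds would demand the repeat-masking
step that production aligners apply to their indexes.

The default proviral reference for simulation, `synthetic_reference()`, is a
seeded random sequence with the canonical region geometry (8,608 bp, LTRs
1–587 and 8022–8608, gag 758–2548, pro 2548–3435, pol 3411–6060, env
5975–8020, with pro/pol overlapping by construction) and a lysine-tRNA PBS
planted at leader offset 3.  It is a synthetic stand-in: the published
analyses' actual reference sequence is not redistributable here, and only
its geometry — which every printed coordinate in the packaged catalog uses —
is reproduced.

# Packaged catalog and replay

`hml9_catalog()` loads TSV transcriptions of the published genome-wide HML-9
locus tables (23 proviruses, 47 solo LTRs, per-region integrity, 20 dating
rows); every row is validated against `length = end − start + 1` on load.
`replay_catalog()` recomputes from those fixtures alone: the 6/9/8 length
strata, the 56.52/17.39/26.09 and 59.57/40.43 context percentages, the
44-of-47 (93.62%) solo-LTR screen, every integration age from the recorded
divergences, and the headline summaries (LTR ages 17.5–48.5 my, mean
28.83 my; internal ages 37.5–151.5 my, mean 76 my).  The dating table's
printed ages are re-derived exactly from the unrounded per-region
divergences — which is also the only way the printed 60.83 my row can be
obtained.

# Numerical and size choices

* Coordinates are 1-based inclusive everywhere internally (the convention
  the length invariant confirms for the printed tables); BED I/O converts at
  the boundary, losslessly.
* All randomness flows from explicit integer seeds; sub-seeds are derived
  deterministically, and identical config + seed gives byte-identical
  generator and pipeline outputs.
* Test problem sizes: synthetic genomes of 0.35 Mb across two chromosomes
  (five seeds) for discovery properties, 50 planted proviruses for clock
  recovery, 1 Mb random genomes for false-positive checks, 0.8–1 Mb
  chromosomes for the per-base regulatory-domain oracle.  These sizes give
  the properties enough power (e.g. binomial standard errors well below the
  tolerances tested) while keeping the whole suite to a few minutes.
* Degenerate inputs are defined, not accidental: empty GFF3 → empty gene
  table; zero observed loci → chi-square on zero counts with p = 1 per
  binomial test; uniform PWM → degenerate flag with relative score 1;
  all-NA divergences → NA ages (NA propagates exactly as published tables
  do).

# Known limitations

* The discovery thresholds are tuned for desk-scale genomes; whole-genome
  human runs would need repeat masking and a compiled extension loop.
* Integrity is presence-based by definition; it cannot distinguish a
  diverged-but-intact region from one riddled with small in-frame indels.
* Majority-rule consensus underestimates ancestral states in the presence of
  strongly asymmetric lineage sampling.
* The ORA implementation tests user-supplied category tables; it ships no
  ontology, so results are only as good as the supplied gene sets.
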