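---
title: "Testing runoff-driven diversity loss in sediment MAG communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing runoff-driven diversity loss in sediment MAG communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divshift)
```

## The scientific question

Glacierized high-latitude watersheds deliver meltwater, sediment and
nutrients to downstream lakes very unevenly: some lakebed sites sit under
large glacial inflows (a high-runoff regime, H), others under small ones
(low runoff, L), and some receive essentially none (control, C), with the
surrounding tributary soils (S) supplying the terrestrial end-member.
Treating this spatial contrast as a proxy for what warming-driven increases
in runoff will do over time, the question becomes: *does moving from a low-
to a high-runoff regime reduce the taxonomic and functional diversity of the
dominant sediment microbes?*

"Dominant microbes" are operationalized as metagenome-assembled genomes
(MAGs): draft genomes binned from co-assembled sediment metagenomes. The
pipeline starts downstream of assembly and binning; its inputs are plain
tables — genome-by-sample mapped-read counts, genome taxonomy, genome
quality (completeness/contamination), genome function annotations, pathway
definitions, porewater geochemistry, and a sample-to-location-class design.

## The headline statistic

The core procedure, implemented in `run_divshift()`, is deliberately simple
and fully reproducible:

1. **Filter** genomes to MIMAG medium/high quality: completeness ≥ 50 %
   (inclusive) and contamination < 10 % (strict). The inclusive completeness
   bound follows the standard MIMAG phrasing "at least 50 % complete"; both
   bounds are configurable.
2. **Normalize** mapped-read counts by sequencing depth: each genome's reads
   divided by the total reads mapped in that sample.
3. **Pool** samples into their location classes (by summing counts and
   renormalizing — depth-aware — or by averaging proportions) and **tally**
   genome proportions by phylum, giving a phylum × class proportion matrix
   whose columns each sum to 1.
4. **Order the classes** by agglomerative clustering of the class columns
   (Euclidean distance, average linkage by default; both recorded in the
   report). Among all leaf orders consistent with the merge tree the one
   minimizing the sum of adjacent-column distances is taken, oriented so the
   tightest pair comes first and the last-joining class last. A nested
   structure with d(L,C) smallest, then H, then S therefore yields the
   ordering L → C → H → S.
5. **Regress** each phylum's proportion on the class rank x = 0, 1, …, m−1
   by ordinary least squares. With one pooled value per class this is a
   single-point-per-class design: the slope is estimable but no within-class
   error is, so no per-phylum p-value is attempted — only the slope's sign
   is used.
6. **Test for sign enrichment**: if runoff had no directional effect, each
   phylum would be equally likely to increase or decrease along the
   ordering, so the number of negative slopes among n informative ones is
   Binomial(n, ½) under the null. `sign_enrichment()` computes the exact
   one-sided upper tail P(X ≥ k) as a sum of exact integer binomial
   coefficients divided by 2ⁿ once. For example, 19 negative slopes out of
   25 phyla give P = 245506/2²⁵ ≈ 0.0073, and 22 of 25 give
   P = 2626/2²⁵ ≈ 7.8 × 10⁻⁵.

Zero slopes (|slope| ≤ 10⁻¹²) are excluded from both k and n: a sign test is
only defined on informative signs. The test is one-sided for *negative*
enrichment by default; reversing the class ordering negates every slope and
maps k to n − k, a property the test suite checks exactly.

### A numerical note on the exact tail

For n ≤ 50 the binomial coefficients and their partial sums are integers
below 2⁵³, so the tail is exact in double precision; beyond that the sum is
accumulated on the log scale. Published analyses of this kind occasionally
print tail exponents inconsistent with the exact Binomial(n, ½) tail for the
stated k and n; this implementation always reports the exact tail, which is
the quantity the test actually defines.

## The functional arm

Functional potential is profiled per genome and compared across regimes:

- `include_genomes_per_site()` keeps, at each site, only the most abundant
  genomes, using a cutoff of 0.25 on a −log₁₀ scale. The scale's reference
  is genuinely ambiguous in the field's usage, so both readings are
  implemented: the default `"max_scaled"` rule includes a genome where its
  abundance is within 10^0.25 ≈ 1.78-fold of its own across-site maximum;
  the alternative `"raw"` rule reads −log₁₀(proportion) ≤ 0.25, which would
  require a genome to exceed ~56 % of a sample — implausible for a
  300-genome community, which is why it is not the default. The rule used is
  recorded on the result.
- `minpath_infer()` maps a genome's observed enzymes to a
  minimum-cardinality set of pathways covering them (the parsimony principle
  of MinPath-style inference). Candidate sets of ≤ 20 pathways are solved
  exactly by branch and bound (branching on the enzyme covered by the
  fewest pathways, pruned by a covering-size bound, seeded with the greedy
  solution); larger instances fall back to the greedy cover, whose size
  exceeds the optimum by at most a logarithmic factor. Pathways supported by
  a single observed enzyme are flagged as weak calls.
- `build_pathway_profile()` counts, per location class, the presence of
  each (taxon, function-or-pathway) combination among included genomes —
  once per genome, so duplicated annotations cannot inflate a profile — and
  renormalizes columns. Proteobacteria are split by taxonomic class here,
  the usual convention when one phylum dominates the genome set.
- `functional_divshift()` then reuses the ordering/slope/sign-enrichment
  machinery unchanged on this profile.
- `compare_nutrient_processes()` groups functions into processes (carbon,
  nitrogen, sulfur cycling, …; the mapping ships as an editable table
  because marker-gene panels are study-specific) and tests each process's
  presence/absence contrast between the L and H transects with a two-sided
  Fisher exact test (minimum-likelihood rule). Site clustering on
  process-level counts is scored by bootstrap resampling of functions:
  ordinary bootstrap probabilities (BP) plus approximately unbiased (AU)
  support from a multiscale bootstrap over resample sizes r·n,
  r ∈ {0.5, …, 1.4}, fitting z(r) = v√r + c/√r by weighted least squares
  and reporting AU = 1 − Φ(v − c). Scales with degenerate (0 or 1) BP carry
  no quantile information and are dropped; with fewer than three informative
  scales the BP nearest r = 1 is reported unchanged — AU ≥ BP is *not* a
  theorem and is not asserted anywhere.

## The geochemistry arm

Porewater and sediment chemistry get the standard ordination treatment:
`pca_unit_variance()` (correlation-matrix PCA, deterministic sign
convention), `pam_silhouette()` (Partitioning Around Medoids with k chosen
by maximum mean silhouette width, ties toward smaller k),
`dunn_bh()` (rank-based Dunn pairwise z with tie correction,
Benjamini-Hochberg adjustment, flags at α = 0.025), and `nmds_envfit()`
(2-D NMDS on Bray–Curtis dissimilarities with ≥ 20 random restarts, then
least-squares environmental vectors with permutation p-values using the
add-one estimator P = (1 + #{r²ₚₑᵣₘ ≥ r²})/(1 + nₚₑᵣₘ), so P is never 0).
Bray–Curtis is a choice, not a given — it is the community-ecology default
for abundance data and is configurable.

## The synthetic watershed generator

Because the original sequencing data are not needed to exercise any of this
arithmetic, `simulate_watershed()` generates complete, statistically
structured inputs. Its defaults mirror the targeted study design: 300
genomes over 25 phyla; samples L1, L2, H1, H2, C, S1–S3 in classes L/H/C/S;
Poisson sequencing depth with mean 10⁶ mapped reads per sample.

The generative model:

- Base phylum proportions are symmetric Dirichlet with total concentration
  25 (shape 1 per phylum at 25 phyla), giving realistic uneven, long-tailed
  phylum profiles. L, C and S classes share these base proportions; only H
  is perturbed (the model injects a *runoff* effect, not a soil signature —
  so the generator does not emulate the distinct soil communities real
  watersheds show, and dendrogram topologies involving S are exercised with
  constructed profiles instead).
- The **runoff tilt** δ multiplies phylum p's proportion by
  exp(−δ·(rank(p) − 1)), ranks by decreasing base proportion, and
  renormalizes. Mass moves monotonically toward already-dominant phyla, so
  the expected Pielou evenness H/ln(n_phyla) of the H class is strictly
  non-increasing in δ — the injected effect is analytically available from
  the `truth` record via `effective_evenness()`, and `calibrate_tilt()`
  inverts it to hit a requested evenness ratio.
- Genomes are assigned to phyla by a stick-breaking split (Beta(1, 4)
  sticks) with every phylum guaranteed one genome, so several phyla are
  singletons — matching the long tail of real MAG sets and exercising
  tie/edge handling. Within a phylum, genome weights are symmetric
  Dirichlet(1): uneven, but without stick-breaking's geometric decay, so
  members of dominant phyla stay detectable at realistic depths. The
  within-phylum structure is a modelling stand-in, not an inference about
  any particular dataset.
- Counts are Multinomial(depth, class-proportion × within-weight) per
  sample, so columns sum exactly to the drawn depth.
- About 10 % of genomes are drawn to fail the MIMAG screen (low
  completeness or contamination ≥ 10 %), making the filter observable in
  every run.
- Each phylum gets a pool of functions from a 120-id vocabulary, 30 % of it
  designated "oxidative"; a genome carries a pool function with probability
  completeness/100 (annotation incompleteness tracks genome
  incompleteness). Genomes of H-dominant phyla lose a configurable fraction
  of oxidative functions, emulating the loss of oxidative metabolism under
  a high-sedimentation, low-oxygen regime.
- Geochemistry is drawn Normal around class-specific means — H-class
  sediments higher in ammonia, sulfate and carbonate; L/C higher in oxygen,
  nitrate/nitrite and redox potential — with a deep-tier offset within each
  transect, for sediment samples only (soil chemistry is typically not
  measurable in such designs). Values are generated at the sample level
  because the pipeline consumes per-site means.

One global seed drives a single RNG stream, so a configuration reproduces
byte-identical datasets.

### What passing tests do and do not show

The generator's phylum proportions are exactly Dirichlet and its counts
exactly multinomial; real MAG abundances are over-dispersed, spatially
autocorrelated, and compositionally coupled to mapping artefacts. The test
suite therefore demonstrates that the pipeline's arithmetic is correct and
that the test is calibrated *under the stated model* — rejection in ≤ 7 %
of null (δ = 0) datasets, reflecting the conservatism of a discrete
binomial test at n = 25, and ≥ 90 % power when δ is set so that the H/L
evenness ratio is 0.6. It does not validate the ecological interpretation
of any particular field dataset.

## Problem sizes and numerical choices

The packaged checks run the full pipeline at study scale (300 genomes, 8
samples, ~10⁶ reads per sample) for single runs, and 200 replicates per
condition for the calibration/power study; bootstrap support uses 10 scales
and defaults to 1000 resamples (smaller in the unit tests). Slope signs use
a 10⁻¹² tolerance; proportion columns are validated to 10⁻⁹; PCA
reconstruction holds to 10⁻⁸. Degenerate inputs are handled explicitly:
all-zero sample columns, all-zero genome rows, identical class columns
(warned, deterministic order), empty inclusion sets (error naming the
class), and all-zero slopes (error: a sign test needs informative signs).

## Limitations

- With one pooled value per class, the per-taxon regressions have no
  residual degrees of freedom; inference rests entirely on the exact sign
  test across taxa, which ignores the magnitude of slopes and the
  compositional coupling between them (proportions sum to 1, so slopes sum
  to 0 — making the test conservative rather than anticonservative under
  the null, as the calibration study shows).
- The class ordering is estimated from the same profile that is then
  regressed; a forced ordering (`forced_order =`) is the honest sensitivity
  check and is part of the standard report.
- Greedy set cover beyond 20 candidate pathways is an approximation;
  the exact solver bound can be raised at a (worst-case exponential) cost.
- AU support values rest on an asymptotic normal-quantile model; with few
  sites and strong structure most scales are degenerate and the reported
  value falls back to the ordinary bootstrap proportion.
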