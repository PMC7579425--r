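# divshift

Does a shift from a low- to a high-runoff hydrological regime reduce the
taxonomic and functional diversity of the dominant microbes in lake
sediments? `divshift` implements a complete, tested R pipeline for asking
that question from tables derived from metagenome-assembled genomes (MAGs):
genome × sample mapped-read counts, genome taxonomy and quality,
function/enzyme annotations, pathway definitions, porewater geochemistry,
and a sample → location-class design (L = low runoff, H = high runoff,
C = negligible-runoff control, S = tributary soils).

It is aimed at microbial ecologists who have finished assembly, binning and
annotation and want the downstream statistics to be explicit, exact where
exactness is cheap, and reproducible from a single seed.

## The statistic at the core

After MIMAG quality filtering (completeness ≥ 50 %, contamination < 10 %)
and depth normalization (reads mapped to a genome / total reads mapped in
that sample), genome proportions are pooled by location class and tallied by
phylum, giving a phylum × class proportion matrix **Y**. The classes are
ordered by hierarchical clustering of the class columns; each phylum's
proportion is regressed on the class rank x = 0, 1, …, m − 1 by ordinary
least squares,

    slope_i = Σ (x − x̄)(y_i − ȳ_i) / Σ (x − x̄)²,

and the number k of negative slopes among the n informative ones is tested
against Binomial(n, ½) with the exact one-sided tail

    P = Σ_{j ≥ k} C(n, j) / 2^n ,

computed with exact integer binomial coefficients. With 19 of 25 phyla
declining, P = 245506/2²⁵ ≈ 0.0073; with 22 of 25, P = 2626/2²⁵ ≈ 7.8 × 10⁻⁵.
A functional arm repeats the test on function/pathway profiles built through
a per-site abundance cutoff and parsimony (minimal set cover) pathway
inference, and a geochemistry arm provides unit-variance PCA, PAM clustering
with silhouette-selected k, Dunn/Benjamini-Hochberg post-hoc tests, and NMDS
with permutation-tested environmental vectors.

A synthetic watershed generator (Dirichlet-multinomial communities with a
tunable runoff-driven evenness loss, matched annotations and geochemistry)
makes the whole pipeline testable without any sequencing data.

## Worked example

```r
library(divshift)

# a synthetic watershed: 300 MAGs, 25 phyla, 8 samples, strong runoff tilt
cfg <- watershed_config(runoff_tilt = 0.45, seed = 11)
ds  <- simulate_watershed(cfg)
ds
#> watershed_dataset: 300 genomes, 25 phyla, 8 samples (classes L/H/C/S)
#> runoff tilt delta = 0.45, seed = 11

report <- run_pipeline(ds, stages = c("profile", "stat"))
report$taxa
#> class ordering (clustered): L -> S -> C -> H
#> sign enrichment: 22 of 24 informative slopes negative (0 zero excluded)
#> one-sided exact binomial P = 1.794e-05 (alternative: greater)

effective_evenness(ds$truth, "L")   # 0.803
effective_evenness(ds$truth, "H")   # 0.402
```

The clustering places the tilted high-runoff class H last; 22 of the 24
informative phylum slopes are negative along that ordering, and the exact
binomial tail rejects the fair-coin null — the pipeline recovers the
evenness loss injected by the generator (Pielou evenness 0.80 in L against
0.40 in H). Forcing a different ordering (`run_pipeline(..., forced_order =
c("L","C","H","S"))`) is the built-in sensitivity check; reversing an
ordering maps k to n − k exactly.

Datasets round-trip through plain TSVs with `write_dataset()` /
`read_dataset()`, and `run_pipeline(..., out_dir = "out/")` writes the
profile, slopes, Newick dendrogram and a JSON run report.

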