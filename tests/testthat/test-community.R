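# Community arm: quality filter boundaries, depth normalization,
# max-abundance assignment, and class/taxon aggregation.

test_that("MIMAG filter is inclusive at 50% complete, strict below 10% contamination", {
  q <- data.frame(genome = c("a", "b", "c", "d"),
                  completeness = c(50.0, 49.9, 99.0, 80),
                  contamination = c(9.9, 0.0, 10.0, 2))
  expect_identical(filter_mags(q), c("a", "d"))
  expect_error(filter_mags(q[0, ]), "empty")
  q$completeness[1] <- 101
  expect_error(filter_mags(q), "a")
})

test_that("pipeline rejects genomes counted but missing from quality", {
  ds <- simulate_watershed(small_config(seed = 2))
  ds$quality <- ds$quality[-3, ]
  expect_error(validate_dataset(ds), ds$taxonomy$genome[3])
})

test_that("depth normalization divides by the column totals", {
  m <- matrix(c(10, 30, 60), ncol = 1,
              dimnames = list(paste0("g", 1:3), "L1"))
  p <- normalize_abundance(counts_tab(m))
  expect_equal(unname(unclass(p)[, 1]), c(0.1, 0.3, 0.6))
  expect_identical(abundance_units(p), "proportions")

  one <- matrix(c(5, 17), nrow = 1, dimnames = list("g1", c("A", "B")))
  expect_equal(unname(unclass(normalize_abundance(counts_tab(one)))),
               matrix(1, 1, 2), ignore_attr = TRUE)

  set.seed(1)
  r <- matrix(rpois(160, 40), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
  expect_true(all(abs(colSums(normalize_abundance(counts_tab(r))) - 1)
                  < 1e-12))
  r[, 3] <- 0
  expect_error(normalize_abundance(counts_tab(r)), "s3")
})

test_that("max-site assignment takes the argmax and breaks ties lexicographically", {
  m <- matrix(c(0.01, 0.99, 0.5, 0.5, 0.02, 0.98), nrow = 2,
              dimnames = list(c("g1", "g2"), c("C", "H1", "L1")))
  a <- assign_max_site(abundance_table(m, "proportions"))
  expect_identical(a$sample[a$genome == "g1"], "H1")

  tied <- matrix(c(0.5, 0.5, 0.5, 0.5), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("H2", "H1")))
  at <- assign_max_site(abundance_table(tied, "proportions"))
  expect_identical(at$sample, c("H1", "H1"))
  expect_true(all(at$tie))

  zero <- matrix(c(0, 1, 0, 1), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_error(assign_max_site(abundance_table(zero, "proportions")), "g1")
})

test_that("max-site assignment matches a brute-force per-row scan", {
  ds <- simulate_watershed(watershed_config(seed = 13, n_genomes = 300L,
                                            depth_per_sample = 1e5))
  props <- normalize_abundance(ds$counts)
  m <- unclass(props)
  m <- m[rowSums(m) > 0, ]
  got <- assign_max_site(abundance_table(m, "proportions"))
  samples_sorted <- sort(colnames(m))
  brute <- vapply(rownames(m), function(g) {
    row <- m[g, samples_sorted]
    samples_sorted[which(row == max(row))[1]]
  }, character(1))
  expect_identical(got$sample, unname(brute[got$genome]))
})

test_that("scaling a count column before normalization leaves assignments unchanged", {
  ds <- simulate_watershed(small_config(seed = 4))
  m <- unclass(ds$counts)
  m <- m[rowSums(m) > 0, ]
  base <- assign_max_site(normalize_abundance(counts_tab(m)))
  m2 <- m; m2[, 2] <- m2[, 2] * 7
  scaled <- assign_max_site(normalize_abundance(counts_tab(m2)))
  expect_identical(base$sample, scaled$sample)
})

test_that("aggregation sums within taxa and conserves class mass", {
  counts <- matrix(c(10, 20, 70, 30, 30, 40), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("L1", "L2")))
  tax <- data.frame(genome = c("g1", "g2", "g3"),
                    phylum = c("A", "A", "B"))
  des <- data.frame(sample = c("L1", "L2"), class = c("L", "L"))
  prof <- aggregate_profile(counts_tab(counts), tax, des)
  expect_equal(prof["A", "L"], (10 + 20 + 30 + 30) / 200)
  expect_equal(colSums(prof), c(L = 1))

  # one phylum only: column collapses to 1
  tax$phylum <- "A"
  prof1 <- aggregate_profile(counts_tab(counts), tax, des)
  expect_equal(unname(prof1[1, 1]), 1)

  tax$phylum <- c("A", "A", "B")
  expect_error(aggregate_profile(counts_tab(counts), tax[-1, ], des), "g1")
  expect_error(aggregate_profile(counts_tab(counts), tax, des[-1, ]), "L1")
})

test_that("sum-counts pooling is depth-aware, mean-props pooling is not", {
  counts <- matrix(c(90, 10, 1, 9), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("L1", "L2")))
  tax <- data.frame(genome = c("g1", "g2"), phylum = c("A", "B"))
  des <- data.frame(sample = c("L1", "L2"), class = c("L", "L"))
  pooled <- aggregate_profile(counts_tab(counts), tax, des)
  expect_equal(pooled["A", "L"], 91 / 110)
  meaned <- aggregate_profile(counts_tab(counts), tax, des,
                              pooling = "mean_props")
  expect_equal(meaned["A", "L"], (0.9 + 0.1) / 2)
})

test_that("aggregated class proportions recover the generator truth", {
  ds <- simulate_watershed(watershed_config(seed = 21, runoff_tilt = 0.5))
  prof <- aggregate_profile(ds$counts, ds$taxonomy, ds$design)
  for (cl in c("L", "H")) {
    truth <- ds$truth$class_props[[cl]]
    got <- prof[names(truth), cl]
    expect_true(all(abs(got - truth) < 0.01))
  }
})

test_that("Proteobacteria split by class replaces the phylum label", {
  counts <- matrix(c(50, 30, 20), ncol = 1,
                   dimnames = list(c("g1", "g2", "g3"), "L1"))
  tax <- data.frame(genome = c("g1", "g2", "g3"),
                    phylum = c("Proteobacteria", "Proteobacteria", "B"),
                    class = c("Alphaproteobacteria", "Gammaproteobacteria",
                              NA))
  des <- data.frame(sample = "L1", class = "L")
  prof <- aggregate_profile(counts_tab(counts), tax, des,
                            split_proteobacteria_by_class = TRUE)
  expect_setequal(rownames(prof),
                  c("Alphaproteobacteria", "Gammaproteobacteria", "B"))
})

test_that("normalizing after filtering equals filtering then renormalizing", {
  ds <- simulate_watershed(small_config(seed = 6))
  kept <- filter_mags(ds$quality)
  kept <- intersect(rownames(ds$counts), kept)
  a <- normalize_abundance(ds$counts[kept, ])
  full <- unclass(normalize_abundance(ds$counts))[kept, ]
  b <- sweep(full, 2, colSums(full), "/")
  expect_equal(unclass(a), b, tolerance = 1e-12, ignore_attr = TRUE)
})
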