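# Functional arm: inclusion cutoff, parsimony set cover, pathway profiles,
# nutrient-process contingency tests and bootstrap cluster support.

test_that("max-scaled inclusion keeps genomes near their own maximum", {
  m <- matrix(c(0.10, 0.90, 0.09, 0.91, 0.01, 0.99), nrow = 2,
              dimnames = list(c("g1", "pad"), c("s1", "s2", "s3")))
  props <- abundance_table(m, "proportions")
  inc <- include_genomes_per_site(props, cutoff = 0.25)
  # -log10 of (0.10, 0.09, 0.01)/0.10 = (0, 0.046, 1): sites 1 and 2 only
  expect_true("g1" %in% inc$s1)
  expect_true("g1" %in% inc$s2)
  expect_false("g1" %in% inc$s3)

  inc0 <- include_genomes_per_site(props, cutoff = 0)
  expect_true("g1" %in% inc0$s1)    # its maximum site
  expect_false("g1" %in% inc0$s2)   # below the maximum, excluded at cutoff 0

  incInf <- include_genomes_per_site(props, cutoff = Inf)
  expect_setequal(incInf$s3, c("g1", "pad"))
  expect_error(include_genomes_per_site(props, cutoff = -1), "non-negative")
})

test_that("raw-proportion transform reads the cutoff against the abundance itself", {
  m <- matrix(c(0.6, 0.4, 0.7, 0.3), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  props <- abundance_table(m, "proportions")
  inc <- include_genomes_per_site(props, cutoff = 0.25, transform = "raw")
  # -log10(0.6) = 0.22 and -log10(0.7) = 0.15 pass; 0.4 and 0.3 do not
  expect_identical(inc$s1, "g1")
  expect_identical(inc$s2, "g1")
})

test_that("zero-everywhere genomes are excluded with a warning", {
  m <- matrix(c(0, 1, 0, 1), nrow = 2,
              dimnames = list(c("gz", "g2"), c("s1", "s2")))
  props <- abundance_table(m, "proportions")
  expect_warning(inc <- include_genomes_per_site(props), "gz")
  expect_false("gz" %in% unlist(inc))
})

test_that("parsimony prefers one covering pathway over two partial ones", {
  defs <- list(P1 = "e1", P2 = "e2", P3 = c("e1", "e2"))
  call <- minpath_infer(c("e1", "e2"), defs)
  expect_identical(call$pathways, "P3")
  expect_identical(call$method, "exact")
  expect_length(call$single_hit, 0)

  expect_identical(minpath_infer(character(), defs)$pathways, character(0))

  single <- minpath_infer("e1", list(P1 = c("e1", "e2", "e3")))
  expect_identical(single$pathways, "P1")
  expect_identical(single$single_hit, "P1")

  expect_warning(dropped <- minpath_infer(c("e1", "zz"), defs), "zz")
  expect_identical(dropped$dropped, "zz")
  expect_error(minpath_infer("e1", list()), "empty")
  expect_error(minpath_infer("e1", list(P1 = character())), "P1")
})

test_that("greedy cover always covers; exact cover matches exhaustive search", {
  set.seed(42)
  for (rep in 1:1000) {
    n_enz <- sample(4:12, 1)
    enz <- paste0("e", seq_len(n_enz))
    n_pwy <- sample(3:25, 1)
    defs <- setNames(lapply(seq_len(n_pwy), function(i) {
      sample(enz, sample(1:4, 1))
    }), paste0("P", sprintf("%02d", seq_len(n_pwy))))
    observed <- sample(enz, sample(2:n_enz, 1))
    coverable <- intersect(observed, unique(unlist(defs)))
    call <- suppressWarnings(minpath_infer(observed, defs))
    expect_setequal(call$covered, coverable)
    covered_by_choice <-
      intersect(as.character(unlist(defs[call$pathways])), coverable)
    expect_setequal(as.character(covered_by_choice), coverable)
  }
})

test_that("exact cover size equals exhaustive-minimum size for small instances", {
  set.seed(17)
  for (rep in 1:150) {
    n_enz <- sample(4:10, 1)
    enz <- paste0("e", seq_len(n_enz))
    n_pwy <- sample(3:12, 1)
    defs <- setNames(lapply(seq_len(n_pwy), function(i) {
      sample(enz, sample(1:4, 1))
    }), paste0("P", sprintf("%02d", seq_len(n_pwy))))
    observed <- sample(enz, sample(2:n_enz, 1))
    call <- suppressWarnings(minpath_infer(observed, defs))
    coverable <- call$covered
    if (length(coverable) == 0) next
    # exhaustive: smallest subset of definitions covering the coverables
    ids <- names(defs)
    exhaustive <- Inf
    for (size in seq_along(ids)) {
      hit <- FALSE
      for (cc in combn(ids, size, simplify = FALSE)) {
        if (all(coverable %in% unlist(defs[cc]))) { hit <- TRUE; break }
      }
      if (hit) { exhaustive <- size; break }
    }
    expect_identical(length(call$pathways), as.integer(exhaustive))
  }
})

make_functional_fixture <- function(seed = 31, oxidative_drop = 0.9) {
  ds <- simulate_watershed(watershed_config(
    seed = seed, runoff_tilt = 0.8, oxidative_drop = oxidative_drop,
    n_genomes = 120L, n_phyla = 10L, depth_per_sample = 1e5))
  props <- normalize_abundance(ds$counts)
  inc <- suppressWarnings(include_genomes_per_site(props))
  list(ds = ds, inc = inc)
}

test_that("pathway profile normalizes presence counts per class", {
  inc <- list(s1 = "g1")
  ann <- list(g1 = c("f1"))
  calls <- list(g1 = "PW1")
  tax <- data.frame(genome = "g1", phylum = "A")
  des <- data.frame(sample = "s1", class = "L")
  prof <- build_pathway_profile(inc, ann, tax, des, pathway_calls = calls)
  expect_equal(unname(prof[, "L"]), c(0.5, 0.5))
  expect_setequal(rownames(prof), c("A|f1", "A|PW1"))

  # duplicated annotations must not change set-semantics proportions
  ann_dup <- list(g1 = c("f1", "f1"))
  prof2 <- build_pathway_profile(inc, ann_dup, tax, des,
                                 pathway_calls = calls)
  expect_equal(prof, prof2)

  des2 <- data.frame(sample = c("s1", "s2"), class = c("L", "H"))
  inc2 <- list(s1 = "g1", s2 = character())
  expect_error(build_pathway_profile(inc2, ann, tax, des2,
                                     pathway_calls = calls), "H")
})

test_that("oxidative function share drops in the high-runoff class", {
  fx <- make_functional_fixture()
  ds <- fx$ds
  prof <- build_pathway_profile(fx$inc, ds$annotations, ds$taxonomy,
                                ds$design)
  item <- attr(prof, "item")
  ox_share <- colSums(prof[item %in% ds$oxidative_functions, ])
  expect_lt(ox_share["H"], ox_share["L"])
})

test_that("functional shift delegates to the sign-enrichment machinery", {
  fx <- make_functional_fixture()
  ds <- fx$ds
  prof <- build_pathway_profile(fx$inc, ds$annotations, ds$taxonomy,
                                ds$design)
  fwd <- functional_divshift(prof, forced_order = c("L", "C", "S", "H"))
  rev <- functional_divshift(prof, forced_order = c("H", "S", "C", "L"))
  expect_lt(fwd$enrichment$p_value, 0.05)
  expect_equal(rev$enrichment$k, fwd$enrichment$n - fwd$enrichment$k)

  flat <- matrix(0.25, nrow = 4, ncol = 3,
                 dimnames = list(paste0("r", 1:4), c("L", "C", "H")))
  expect_error(
    suppressWarnings(functional_divshift(flat, forced_order = c("L", "C", "H"))),
    "no informative slopes")
})

test_that("per-process Fisher tests match exhaustive enumeration", {
  sites <- c("L1", "L2", "H1", "H2")
  pres <- matrix(0, 15, 4, dimnames = list(
    c(paste0("cx", 1:5), paste0("cy", 1:5), paste0("bz", 1:5)), sites))
  pres[1:5, c("H1", "H2")] <- 1    # carbon: present in H only
  pres[6:10, c("L1", "L2")] <- 1   # nitrogen: present in L only
  pres[11:15, c("L1", "H1")] <- 1  # balanced: present in both transects
  pmap <- data.frame(fun = rownames(pres),
                     process = rep(c("carbon", "nitrogen", "balanced"),
                                   each = 5))
  des <- data.frame(sample = sites, class = c("L", "L", "H", "H"))
  res <- compare_nutrient_processes(pres, pmap, des, B = 50, seed = 2)
  carbon <- res$fisher[res$fisher$process == "carbon", ]
  # carbon table [[0,5],[5,0]]: two-sided exact tail is 2/252
  expect_equal(carbon$present_L, 0)
  expect_equal(carbon$present_H, 5)
  expect_equal(carbon$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(carbon$p_value,
               fisher_enum(matrix(c(0, 5, 5, 0), 2, byrow = TRUE)),
               tolerance = 1e-12)
  # identical presence rows across transects -> p = 1
  balanced <- res$fisher[res$fisher$process == "balanced", ]
  expect_equal(balanced$p_value, 1)
})

test_that("Fisher p equals enumeration across random small-margin tables", {
  set.seed(5)
  for (rep in 1:60) {
    repeat {
      tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    expect_equal(stats::fisher.test(tab)$p.value, fisher_enum(tab),
                 tolerance = 1e-9)
  }
})

test_that("bootstrap support finds a clean transect split and AU tracks flat BP", {
  set.seed(9)
  sites <- c("L1", "L2", "H1", "H2")
  pres <- matrix(0, 40, 4, dimnames = list(paste0("f", 1:40), sites))
  pres[1:20, c("L1", "L2")] <- 1
  pres[21:40, c("H1", "H2")] <- 1
  # jitter a little so distances are not all ties
  flip <- cbind(sample(40, 6), sample(4, 6, replace = TRUE))
  pres[flip] <- 1 - pres[flip]
  pmap <- data.frame(fun = rownames(pres),
                     process = rep(c("carbon", "nitrogen", "sulfur",
                                     "carbon"), each = 10))
  des <- data.frame(sample = sites, class = c("L", "L", "H", "H"))
  res <- compare_nutrient_processes(pres, pmap, des, B = 400, seed = 4)
  lsplit <- res$support[res$support$split %in% c("L1,L2", "H1,H2"), ]
  expect_gt(max(lsplit$bp), 0.9)
  strong <- res$support[res$support$bp > 0.95, ]
  if (nrow(strong)) expect_true(all(abs(strong$au - strong$bp) < 0.1))
})

test_that("a process with no observed functions is skipped with a warning", {
  sites <- c("L1", "H1")
  pres <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("f1", "f2"), sites))
  pmap <- data.frame(fun = c("f1", "f2", "ghost"),
                     process = c("carbon", "carbon", "mercury"))
  des <- data.frame(sample = sites, class = c("L", "H"))
  expect_warning(res <- compare_nutrient_processes(pres, pmap, des, B = 20,
                                                   seed = 1),
                 "mercury")
  expect_identical(res$fisher$process, "carbon")
})
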