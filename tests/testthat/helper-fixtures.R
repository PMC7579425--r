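# Small fixtures shared across test files; everything is generated in code.

# a reduced watershed: fast to simulate yet structurally complete
small_config <- function(seed = 1, ...) {
  watershed_config(n_genomes = 40L, n_phyla = 8L, depth_per_sample = 2e4,
                   function_pool_size = 40L, n_pathways = 12L,
                   seed = seed, ...)
}

# abundance table from a bare matrix of counts
counts_tab <- function(m) abundance_table(m, "counts")

# proportion-mode table, normalizing the columns of m
props_tab <- function(m) {
  abundance_table(sweep(m, 2, colSums(m), "/"), "proportions")
}

# class-profile matrix whose columns are points along a line in taxon space:
# d(L,C) < d({L,C},H) < d({L,C,H},S), the nested low/control/high/soil
# pattern
nested_profile <- function() {
  base <- c(0.40, 0.30, 0.20, 0.10)
  shift <- c(1, -1, 1, -1) * 0.01
  cols <- list(L = base, C = base + 1 * shift, H = base + 5 * shift,
               S = base + 20 * shift)
  m <- sapply(cols, function(x) x / sum(x))
  rownames(m) <- paste0("ph", 1:4)
  m
}

# exact upper binomial tail via Pascal's triangle (integer arithmetic only);
# independent of binom_tail()'s choose()-based route
pascal_tail <- function(k, n) {
  row <- 1
  for (i in seq_len(n)) row <- c(0, row) + c(row, 0)
  sum(row[(k + 1):(n + 1)]) / 2^n
}

# two-sided Fisher p by full enumeration over tables with fixed margins,
# minimum-likelihood rule; probabilities from binomial coefficients directly
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  pr <- vapply(lo:hi, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- pr[a - lo + 1]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
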