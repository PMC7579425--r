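# Geochemistry arm: unit-variance PCA, PAM + silhouette model selection,
# Dunn post-hoc tests with BH adjustment, NMDS with envfit permutations.

#' Principal component analysis scaled to unit variance
#'
#' Centers every geochemical feature and scales it to unit variance before
#' the eigen-decomposition, so features measured in different units (pH,
#' mV, percent dry weight, umol/L) contribute equally. A deterministic sign
#' convention is applied: within each component the largest-magnitude
#' loading is made positive.
#'
#' @param table numeric sample-by-feature matrix or data frame; at least 2
#'   samples and 2 features, every feature with non-zero variance.
#' @return List with `scores` (samples x components), `loadings`
#'   (features x components), `variance_fraction` (sums to 1) and `sdev`.
#' @export
pca_unit_variance <- function(table) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("geochemistry table must be numeric")
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 samples and >= 2 features")
  v <- apply(x, 2L, var)
  if (any(v == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(x)[v == 0], collapse = ", "))
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  list(scores = p$x, loadings = p$rotation,
       variance_fraction = p$sdev^2 / sum(p$sdev^2), sdev = p$sdev)
}

#' PAM clustering with silhouette-based choice of k
#'
#' Partitioning Around Medoids at each candidate number of clusters, keeping
#' the k that maximizes the mean silhouette width. PAM's build + swap
#' algorithm is deterministic, so results are reproducible without a seed.
#' Ties in mean silhouette (within `1e-12`) are broken toward the smaller k.
#'
#' @param x numeric matrix of points (e.g. PCA scores) or a `dist` object.
#' @param k_range candidate cluster counts; defaults to `2:(n-1)`.
#' @return List with `k` (chosen), `clustering` (named integer vector),
#'   `medoids`, `avg_silhouette` (named by k) and `pam` (the chosen
#'   [cluster::pam()] fit).
#' @export
pam_silhouette <- function(x, k_range = NULL) {
  n <- if (inherits(x, "dist")) attr(x, "Size") else nrow(x)
  if (n < 3L) stop("need at least 3 points to choose k from silhouettes")
  if (is.null(k_range)) k_range <- 2:(n - 1L)
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (length(k_range) == 0L) stop("empty k_range")
  fits <- lapply(k_range, function(k) cluster::pam(x, k))
  sil <- vapply(fits, function(f) f$silinfo$avg.width, numeric(1))
  names(sil) <- k_range
  best <- which(sil >= max(sil) - 1e-12)[1L]  # ties toward smaller k
  fit <- fits[[best]]
  list(k = k_range[best], clustering = fit$clustering,
       medoids = fit$medoids, avg_silhouette = sil, pam = fit)
}

#' Dunn post-hoc rank test with Benjamini-Hochberg adjustment
#'
#' Nonparametric pairwise comparisons following a Kruskal-Wallis setting:
#' ranks are taken over all observations jointly, and for each pair of
#' groups the Dunn z statistic
#' z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)) is computed,
#' with tie correction T = sum(t^3 - t) / (12 (N - 1)) over tied-value
#' groups. Two-sided normal p-values are adjusted by the Benjamini-Hochberg
#' step-up procedure and flagged at `alpha`.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`; every group needs at
#'   least 2 observations.
#' @param alpha significance level for the flags. Default 0.025.
#' @return Data frame with one row per group pair: `group1`, `group2`, `z`,
#'   `p_raw`, `p_adj`, `significant`. The Kruskal-Wallis p-value is attached
#'   as attribute `kruskal_p`.
#' @export
dunn_bh <- function(values, groups, alpha = 0.025) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  glev <- unique(groups)
  if (length(glev) < 2L) stop("need at least 2 groups")
  ng <- table(groups)
  if (any(ng < 2L))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(ng)[ng < 2L], collapse = ", "))
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  pairs <- combn(glev, 2L, simplify = FALSE)
  res <- do.call(rbind, lapply(pairs, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / ng[[i]] + 1 / ng[[j]]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    data.frame(group1 = i, group2 = j, z = z,
               p_raw = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  res$p_adj <- p.adjust(res$p_raw, method = "BH")
  res$significant <- res$p_adj < alpha
  attr(res, "kruskal_p") <-
    kruskal.test(values, factor(groups))$p.value
  res
}

#' NMDS ordination with permutation-tested environmental vectors
#'
#' Two-dimensional non-metric multidimensional scaling of the community
#' table on Bray-Curtis dissimilarities (multiple random restarts, best
#' stress kept), followed by a least-squares fit of each geochemical feature
#' onto the ordination. Each feature's squared correlation r2 is tested by
#' permuting samples: P = (1 + number of permuted r2 >= observed) /
#' (1 + n_perm), so P can never be exactly zero.
#'
#' @param community sample-by-taxon numeric matrix (samples in rows), or an
#'   [abundance_table()] / taxon profile with samples in columns (it is
#'   transposed automatically when its columns match `env`'s rows).
#' @param env numeric sample-by-feature geochemistry matrix or data frame;
#'   row names must match the community's sample ids.
#' @param n_perm number of permutations. Default 999.
#' @param seed integer seed governing restarts and permutations.
#' @param distance dissimilarity index for [vegan::metaMDS()]. Default
#'   `"bray"`.
#' @param trymax random restarts for the NMDS. Default 20.
#' @return List with `ordination` (`points`, `stress`, `converged`) and
#'   `vectors`: data frame with `feature`, direction cosines `dim1`/`dim2`,
#'   `r2` and permutation `p_value`.
#' @export
nmds_envfit <- function(community, env, n_perm = 999L, seed = 1L,
                        distance = "bray", trymax = 20L) {
  env <- as.matrix(env)
  if (any(apply(env, 2L, var) == 0))
    stop("zero-variance environmental feature(s): ",
         paste(colnames(env)[apply(env, 2L, var) == 0], collapse = ", "))
  comm <- if (inherits(community, "abundance_table")) {
    t(abund_matrix(community))
  } else {
    as.matrix(community)
  }
  if (!all(rownames(env) %in% rownames(comm)) &&
      all(rownames(env) %in% colnames(comm))) {
    comm <- t(comm)
  }
  missing <- setdiff(rownames(env), rownames(comm))
  if (length(missing))
    stop("sample(s) in env absent from community: ",
         paste(missing, collapse = ", "))
  comm <- comm[rownames(env), , drop = FALSE]
  if (nrow(comm) < 3L) stop("need at least 3 samples for NMDS")
  set.seed(seed)
  ord <- vegan::metaMDS(comm, distance = distance, k = 2, trymax = trymax,
                        trace = 0, autotransform = FALSE)
  if (!isTRUE(ord$converged))
    warning("NMDS did not converge within ", trymax, " restarts; ",
            "best stress ", signif(ord$stress, 4), " kept")
  fit <- vegan::envfit(ord, env, permutations = n_perm)
  arr <- fit$vectors$arrows
  vectors <- data.frame(feature = rownames(arr),
                        dim1 = arr[, 1], dim2 = arr[, 2],
                        r2 = fit$vectors$r,
                        p_value = fit$vectors$pvals,
                        row.names = NULL, stringsAsFactors = FALSE)
  list(ordination = list(points = vegan::scores(ord, display = "sites"),
                         stress = ord$stress,
                         converged = isTRUE(ord$converged)),
       vectors = vectors)
}
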