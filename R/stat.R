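# Diversity-shift statistic: cluster-derived class ordering, per-taxon
# least-squares slopes along the ordering, exact binomial sign enrichment.

#' Order location classes by hierarchical clustering
#'
#' Clusters the class columns of a taxon profile agglomeratively and reads a
#' linear ordering of the classes off the merge tree. Among all leaf orders
#' consistent with the tree (one left/right flip per internal node), the one
#' minimizing the sum of distances between adjacent leaves is chosen; ties
#' are broken deterministically toward the order whose leaves appear earliest
#' in the profile's column order. For the nested pattern where d(L,C) is the
#' tightest pair, then H, then S, this reproduces the L, C, H, S ordering.
#'
#' @param profile numeric taxon-by-class matrix (e.g. from
#'   [aggregate_profile()]) with at least two class columns.
#' @param metric distance between class columns; any method accepted by
#'   [stats::dist()]. Default `"euclidean"`.
#' @param linkage agglomeration method for [stats::hclust()]. Default
#'   `"average"`.
#' @return A `class_ordering`: list with `order` (character vector of
#'   classes), `provenance` (`"clustered"`), `tree` (the `hclust` object),
#'   `newick` (dendrogram as a Newick string), `metric` and `linkage`.
#' @export
order_classes <- function(profile, metric = "euclidean", linkage = "average") {
  if (ncol(profile) < 2L) stop("need at least 2 location classes")
  classes <- colnames(profile)
  d <- dist(t(profile), method = metric)
  if (all(as.matrix(d)[upper.tri(as.matrix(d))] < 1e-12))
    warning("all class columns identical; ordering is arbitrary but deterministic")
  if (ncol(profile) == 2L) {
    ord <- classes
    tree <- hclust(d, method = linkage)
  } else {
    tree <- hclust(d, method = linkage)
    ord <- classes[best_leaf_order(tree, as.matrix(d))]
  }
  nwk <- tryCatch(ape::write.tree(ape::as.phylo(tree)),
                  error = function(e) NA_character_)
  structure(list(order = ord, provenance = "clustered", tree = tree,
                 newick = nwk, metric = metric, linkage = linkage),
            class = "class_ordering")
}

#' @export
print.class_ordering <- function(x, ...) {
  cat("class ordering (", x$provenance, "): ",
      paste(x$order, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# Enumerate the 2^(k-1) leaf orders consistent with an hclust merge tree and
# return the index order minimizing the sum of adjacent-leaf distances.
# Ties (notably every order against its own reversal) are broken by placing
# the earliest-merged (tightest) pair first, then toward the smallest
# column indices.
best_leaf_order <- function(tree, dmat) {
  merge <- tree$merge
  orders_of <- function(node) {
    if (node < 0) return(list(-node))
    left <- orders_of(merge[node, 1])
    right <- orders_of(merge[node, 2])
    out <- list()
    for (a in left) for (b in right) {
      out[[length(out) + 1L]] <- c(a, b)
      out[[length(out) + 1L]] <- c(b, a)
    }
    out
  }
  cand <- orders_of(nrow(merge))
  score <- vapply(cand, function(o) {
    sum(dmat[cbind(o[-length(o)], o[-1])])
  }, numeric(1))
  best <- cand[score <= min(score) + 1e-12]
  first_pair <- -merge[1, ]  # agglomerative first merge joins two leaves
  pair_pos <- vapply(best, function(o) min(match(first_pair, o)), numeric(1))
  best <- best[pair_pos == min(pair_pos)]
  # append semantics: the side of the final merge not holding the tightest
  # pair joined last, so it goes to the end of the ordering
  leaves_of <- function(node) {
    if (node < 0) return(-node)
    c(leaves_of(merge[node, 1]), leaves_of(merge[node, 2]))
  }
  root <- nrow(merge)
  side1 <- leaves_of(merge[root, 1])
  late <- if (first_pair[1] %in% side1) leaves_of(merge[root, 2]) else side1
  late_pos <- vapply(best, function(o) mean(match(late, o)), numeric(1))
  best <- best[late_pos >= max(late_pos) - 1e-12]
  keys <- vapply(best, function(o) paste(sprintf("%04d", o), collapse = ""),
                 character(1))
  best[[order(keys)[1L]]]
}

#' Force a class ordering supplied by the analyst
#'
#' @param classes character vector of class labels in the desired order.
#' @return A `class_ordering` with provenance `"forced"`.
#' @export
forced_ordering <- function(classes) {
  structure(list(order = as.character(classes), provenance = "forced",
                 tree = NULL, newick = NA_character_,
                 metric = NA_character_, linkage = NA_character_),
            class = "class_ordering")
}

#' Per-taxon least-squares slopes along an ordered set of classes
#'
#' Regresses each taxon's proportion on the integer rank of the location
#' class in the ordering (x = 0, 1, ..., m-1) by ordinary least squares:
#' slope = sum((x - mean(x)) (y - mean(y))) / sum((x - mean(x))^2). With one
#' pooled value per class this is a single-point-per-class design, so only
#' the slope (not a within-class error) is estimable. The slope's sign is
#' classified with tolerance `tol`.
#'
#' @param profile numeric taxon-by-class matrix.
#' @param ordering a `class_ordering` (from [order_classes()] or
#'   [forced_ordering()]) covering exactly the profile's columns.
#' @param tol absolute tolerance below which a slope is classed `"zero"`.
#' @return Data frame with columns `taxon`, `slope`, `sign`
#'   (`"neg"`, `"zero"`, `"pos"`).
#' @export
fit_slopes <- function(profile, ordering, tol = 1e-12) {
  ord <- ordering$order
  if (length(ord) < 2L) stop("need at least 2 classes to fit slopes")
  if (!setequal(ord, colnames(profile)) || length(ord) != ncol(profile))
    stop("ordering must be a permutation of the profile's classes")
  y <- profile[, ord, drop = FALSE]
  x <- seq_len(length(ord)) - 1
  xc <- x - mean(x)
  slope <- as.vector(y %*% xc) / sum(xc^2)
  sign <- ifelse(abs(slope) <= tol, "zero", ifelse(slope < 0, "neg", "pos"))
  data.frame(taxon = rownames(profile), slope = slope, sign = sign,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact one-sided binomial test for enrichment in negative slopes
#'
#' Counts the negative slopes among the informative (non-zero) ones and
#' computes the exact upper tail P(X >= k) for X ~ Binomial(n, 1/2): under
#' the null that a taxon is equally likely to increase or decrease along the
#' ordering, signs are fair coin flips. The tail is accumulated as a sum of
#' exact binomial coefficients, divided by 2^n once at the end. Zero slopes
#' carry no sign information and are excluded from both k and n (their count
#' is reported).
#'
#' @param slopes data frame from [fit_slopes()] (columns `slope`, `sign`),
#'   or a factor/character vector of signs.
#' @param alternative `"greater"` (default; enrichment in negative slopes)
#'   or `"two.sided"`.
#' @return A `sign_enrichment`: list with `k` (negative slopes), `n`
#'   (informative slopes), `n_zero` (excluded), `p_value`, `alternative`.
#' @examples
#' binom_tail(19, 25)                       # 0.00732, the low/high contrast
#' binom_tail(22, 25)                       # 7.83e-05
#' @export
sign_enrichment <- function(slopes, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  sgn <- if (is.data.frame(slopes)) slopes$sign else as.character(slopes)
  if (!all(sgn %in% c("neg", "zero", "pos"))) stop("invalid sign values")
  k <- sum(sgn == "neg")
  n_zero <- sum(sgn == "zero")
  n <- sum(sgn != "zero")
  if (n == 0L) stop("no informative slopes")
  p <- binom_tail(k, n)
  if (alternative == "two.sided") p <- min(1, 2 * min(p, binom_tail(n - k, n)))
  structure(list(k = k, n = n, n_zero = n_zero, p_value = p,
                 alternative = alternative),
            class = "sign_enrichment")
}

#' @export
print.sign_enrichment <- function(x, ...) {
  cat(sprintf(
    "sign enrichment: %d of %d informative slopes negative (%d zero excluded)\n",
    x$k, x$n, x$n_zero))
  cat(sprintf("one-sided exact binomial P = %.4g (alternative: %s)\n",
              x$p_value, x$alternative))
  invisible(x)
}

#' Exact upper binomial tail at p = 1/2
#'
#' P(X >= k) for X ~ Binomial(n, 1/2), computed as
#' sum over i >= k of choose(n, i), divided by 2^n once. For n <= 50 every
#' binomial coefficient and the partial sums are integers below 2^53, so the
#' tail is exact in double precision.
#'
#' @param k number of successes, 0 <= k <= n.
#' @param n number of trials, n >= 1.
#' @return P(X >= k) in (0, 1].
#' @export
binom_tail <- function(k, n) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  if (n <= 50) return(sum(choose(n, k:n)) / 2^n)
  # beyond n = 50 the coefficient sum leaves exact-integer range; accumulate
  # the tail on the log scale instead
  sum(exp(lchoose(n, k:n) - n * log(2)))
}

#' Run the full diversity-shift test on a taxon profile
#'
#' Orders the location classes (by hierarchical clustering unless a forced
#' order is given), fits per-taxon slopes along the ordering, and tests for
#' enrichment in negative slopes with the exact one-sided binomial test.
#'
#' @param profile numeric taxon-by-class matrix.
#' @param forced_order optional character vector: a permutation of the class
#'   columns to use instead of the clustered ordering.
#' @param metric,linkage passed to [order_classes()].
#' @param alternative passed to [sign_enrichment()].
#' @return A `divshift_report`: list with `ordering` (a `class_ordering`),
#'   `slopes` (data frame) and `enrichment` (a `sign_enrichment`).
#' @export
run_divshift <- function(profile, forced_order = NULL,
                         metric = "euclidean", linkage = "average",
                         alternative = "greater") {
  ordering <- if (is.null(forced_order)) {
    order_classes(profile, metric = metric, linkage = linkage)
  } else {
    if (!setequal(forced_order, colnames(profile)) ||
        length(forced_order) != ncol(profile))
      stop("forced_order must be a permutation of the profile's classes")
    forced_ordering(forced_order)
  }
  slopes <- fit_slopes(profile, ordering)
  enrichment <- sign_enrichment(slopes, alternative = alternative)
  structure(list(ordering = ordering, slopes = slopes,
                 enrichment = enrichment),
            class = "divshift_report")
}

#' @export
print.divshift_report <- function(x, ...) {
  print(x$ordering)
  print(x$enrichment)
  invisible(x)
}
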