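# Functional-potential arm: per-site inclusion cutoff, parsimony pathway
# inference (minimal set cover), phylum-by-class pathway profiles, and
# nutrient-cycle comparisons (Fisher exact + AU bootstrap cluster support).

#' Select the most abundant genomes at each site
#'
#' Applies the abundance inclusion cutoff on a -log10 scale. Under the
#' default `"max_scaled"` rule a genome g is included at site s when
#' -log10(a_gs / max_s' a_gs') <= cutoff, i.e. when its abundance at s is
#' within 10^cutoff-fold of its own across-site maximum (for cutoff 0.25,
#' within ~1.78-fold). The alternative `"raw"` rule reads the cutoff against
#' the raw proportion: -log10(a_gs) <= cutoff. Genomes with zero abundance
#' everywhere are excluded with a warning.
#'
#' @param props an [abundance_table()] in proportion mode.
#' @param cutoff non-negative cutoff on the -log10 scale. Default 0.25.
#' @param transform `"max_scaled"` (default) or `"raw"`.
#' @return Named list: for each sample, the character vector of included
#'   genome ids. Attribute `transform` records the rule used.
#' @export
include_genomes_per_site <- function(props, cutoff = 0.25,
                                     transform = c("max_scaled", "raw")) {
  transform <- match.arg(transform)
  if (abundance_units(props) != "proportions")
    stop("include_genomes_per_site expects a proportion-mode table")
  if (cutoff < 0) stop("cutoff must be non-negative")
  m <- abund_matrix(props)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning("genome(s) with zero abundance everywhere excluded: ",
            paste(rownames(m)[zero], collapse = ", "))
    m <- m[!zero, , drop = FALSE]
  }
  score <- if (transform == "max_scaled") {
    -log10(sweep(m, 1L, apply(m, 1L, max), "/"))
  } else {
    -log10(m)
  }
  keep <- score <= cutoff & m > 0
  out <- lapply(seq_len(ncol(m)), function(j) rownames(m)[keep[, j]])
  names(out) <- colnames(m)
  attr(out, "transform") <- transform
  out
}

#' Parsimony pathway inference (minimal set cover)
#'
#' Given the enzymes observed in a genome (or community) and a table of
#' pathway definitions, finds a minimum-cardinality set of pathways whose
#' enzyme union covers every coverable observed enzyme — the parsimony
#' principle of MinPath-style pathway reconstruction. An exact
#' branch-and-bound search is used when at most `exact_limit` candidate
#' pathways contain observed enzymes; otherwise a greedy cover (largest
#' uncovered gain first, ties toward the smallest pathway id) is returned.
#' Pathways supported by a single observed enzyme are flagged, since
#' parsimony calls resting on one gene are weak evidence.
#'
#' @param observed_enzymes character vector of observed enzyme/function ids.
#'   Enzymes absent from every definition are dropped with a warning.
#' @param defs named list: pathway id -> character vector of member enzymes.
#'   Every pathway must be non-empty.
#' @param exact_limit maximum number of candidate pathways for the exact
#'   search. Default 20.
#' @return A `minpath_call`: list with `pathways` (chosen ids, sorted),
#'   `single_hit` (chosen ids supported by exactly one observed enzyme),
#'   `covered` (enzymes covered), `dropped` (observed enzymes in no
#'   definition) and `method` (`"exact"` or `"greedy"`).
#' @examples
#' defs <- list(P1 = "e1", P2 = "e2", P3 = c("e1", "e2"))
#' minpath_infer(c("e1", "e2"), defs)$pathways  # "P3"
#' @export
minpath_infer <- function(observed_enzymes, defs, exact_limit = 20L) {
  if (length(defs) == 0L) stop("empty pathway definitions")
  if (is.null(names(defs)) || any(!nzchar(names(defs))))
    stop("pathway definitions must be named")
  if (any(lengths(defs) == 0L))
    stop("empty pathway definition(s): ",
         paste(names(defs)[lengths(defs) == 0L], collapse = ", "))
  observed <- unique(as.character(observed_enzymes))
  vocab <- unique(unlist(defs, use.names = FALSE))
  dropped <- setdiff(observed, vocab)
  if (length(dropped))
    warning("observed enzyme(s) in no pathway definition dropped: ",
            paste(dropped, collapse = ", "))
  observed <- intersect(observed, vocab)
  if (length(observed) == 0L)
    return(structure(list(pathways = character(), single_hit = character(),
                          covered = character(), dropped = dropped,
                          method = "exact"),
                     class = "minpath_call"))
  hits <- lapply(defs, intersect, observed)
  cand <- names(defs)[lengths(hits) > 0L]
  cand <- cand[order(cand)]
  hits <- hits[cand]
  method <- if (length(cand) <= exact_limit) "exact" else "greedy"
  chosen <- if (method == "exact") {
    cover_exact(hits, observed)
  } else {
    cover_greedy(hits, observed)
  }
  chosen <- sort(chosen)
  single <- chosen[lengths(hits[chosen]) == 1L]
  structure(list(pathways = chosen, single_hit = single, covered = observed,
                 dropped = dropped, method = method),
            class = "minpath_call")
}

#' @export
print.minpath_call <- function(x, ...) {
  cat(sprintf("minimal pathway cover (%s): %d pathway(s) for %d enzyme(s)\n",
              x$method, length(x$pathways), length(x$covered)))
  if (length(x$pathways)) cat("  ", paste(x$pathways, collapse = ", "), "\n")
  if (length(x$single_hit))
    cat("  single-enzyme support (weak): ",
        paste(x$single_hit, collapse = ", "), "\n")
  invisible(x)
}

# greedy set cover; ties toward the lexicographically smallest pathway id
cover_greedy <- function(hits, universe) {
  uncovered <- universe
  chosen <- character()
  ids <- sort(names(hits))
  while (length(uncovered)) {
    gain <- vapply(ids, function(p) length(intersect(hits[[p]], uncovered)),
                   integer(1))
    best <- ids[which.max(gain)]  # which.max takes first -> smallest id
    if (gain[best] == 0L) break   # cannot happen for coverable universes
    chosen <- c(chosen, best)
    uncovered <- setdiff(uncovered, hits[[best]])
    ids <- setdiff(ids, best)
  }
  chosen
}

# exact minimum set cover by branch and bound. Branches on the uncovered
# enzyme contained in the fewest candidate pathways (the standard exact-cover
# heuristic), pruning with a covering-size lower bound; deterministic because
# candidates are visited in sorted-id order and the incumbent only replaced
# on strict improvement (greedy solution seeds the incumbent).
cover_exact <- function(hits, universe) {
  ids <- sort(names(hits))
  sets <- lapply(hits[ids], intersect, universe)
  best <- cover_greedy(hits, universe)
  best_size <- length(best)
  max_set <- max(lengths(sets))
  search <- function(uncovered, chosen) {
    if (length(uncovered) == 0L) {
      if (length(chosen) < best_size) {
        best <<- chosen
        best_size <<- length(chosen)
      }
      return(invisible())
    }
    if (length(chosen) + ceiling(length(uncovered) / max_set) >= best_size)
      return(invisible())
    cover_counts <- vapply(uncovered, function(e) {
      sum(vapply(sets, function(s) e %in% s, logical(1)))
    }, integer(1))
    e <- uncovered[which.min(cover_counts)]
    for (p in ids[vapply(sets, function(s) e %in% s, logical(1))]) {
      if (p %in% chosen) next
      search(setdiff(uncovered, sets[[p]]), c(chosen, p))
    }
    invisible()
  }
  search(universe, character())
  best
}

#' Build a taxon-by-class profile of function and pathway proportions
#'
#' For each location class, counts — over the genomes passing the per-site
#' inclusion cutoff at any site of that class — the presence of each
#' (taxon, item) combination, where items are the genome's annotated
#' functions and (optionally) its parsimony pathway calls, and converts the
#' counts to column proportions. Presence is counted once per genome (set
#' semantics), so duplicated annotations do not change the profile.
#' Proteobacteria are split by taxonomic class by default, mirroring the
#' summary convention of the functional arm.
#'
#' @param included named list from [include_genomes_per_site()].
#' @param annotations named list: genome id -> character vector of function
#'   ids.
#' @param taxonomy data frame with columns `genome`, `phylum`, optional
#'   `class`.
#' @param design data frame with columns `sample`, `class`.
#' @param pathway_calls optional named list: genome id -> character vector of
#'   pathway ids (e.g. from [minpath_infer()] per genome).
#' @param split_proteobacteria_by_class default `TRUE`.
#' @return Numeric matrix, rows labelled `taxon|item`, columns the location
#'   classes, each column summing to 1. Attributes `taxon` and `item` carry
#'   the row factors.
#' @export
build_pathway_profile <- function(included, annotations, taxonomy, design,
                                  pathway_calls = NULL,
                                  split_proteobacteria_by_class = TRUE) {
  design <- validate_design(design, samples = names(included))
  genomes <- unique(unlist(included, use.names = FALSE))
  taxonomy <- validate_taxonomy(taxonomy, required = genomes)
  cls <- design$class[match(names(included), design$sample)]
  classes <- unique(cls)

  items_of <- function(g) {
    it <- unique(as.character(annotations[[g]]))
    if (!is.null(pathway_calls) && !is.null(pathway_calls[[g]]))
      it <- c(it, unique(as.character(pathway_calls[[g]])))
    it
  }
  rows <- list()
  for (cl in classes) {
    inc <- unique(unlist(included[cls == cl], use.names = FALSE))
    if (length(inc) == 0L)
      stop("no genomes pass the inclusion cutoff in class ", cl)
    tax <- taxon_labels(taxonomy, inc, split_proteobacteria_by_class)
    for (i in seq_along(inc)) {
      it <- items_of(inc[i])
      if (length(it))
        rows[[length(rows) + 1L]] <-
          data.frame(class = cl, taxon = tax[i], item = it,
                     stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  if (is.null(long)) stop("no annotations among included genomes")
  key <- paste(long$taxon, long$item, sep = "|")
  tab <- table(key, factor(long$class, levels = classes))
  prof <- matrix(as.integer(tab), nrow = nrow(tab),
                 dimnames = list(rownames(tab), classes))
  cs <- colSums(prof)
  if (any(cs == 0))
    stop("no (taxon, item) presences in class ",
         paste(classes[cs == 0], collapse = ", "))
  prof <- sweep(prof, 2L, cs, "/")
  parts <- strsplit(rownames(prof), "|", fixed = TRUE)
  attr(prof, "taxon") <- vapply(parts, `[`, character(1), 1L)
  attr(prof, "item") <- vapply(parts, `[`, character(1), 2L)
  prof
}

#' Diversity-shift test on a functional profile
#'
#' Delegates to the diversity-shift machinery ([run_divshift()]) with a
#' function/pathway proportion profile in place of the taxon-abundance
#' profile: classes are ordered (clustered or forced), each row's proportion
#' is regressed on the class rank, and enrichment in negative slopes is
#' tested with the exact one-sided binomial test.
#'
#' @param pathway_profile matrix from [build_pathway_profile()] (any
#'   row-by-class proportion matrix works).
#' @param forced_order optional class ordering to force.
#' @param ... passed to [run_divshift()].
#' @return A `divshift_report`.
#' @export
functional_divshift <- function(pathway_profile, forced_order = NULL, ...) {
  run_divshift(pathway_profile, forced_order = forced_order, ...)
}

#' Compare nutrient-cycling processes between runoff transects
#'
#' Groups functions into biogeochemical processes (e.g. carbon, nitrogen,
#' sulfur cycling) and asks, for each process, whether its functions are
#' differentially present between the low- and high-runoff transects, and
#' whether sites cluster by transect on process-level counts.
#'
#' Per process, a 2x2 Fisher exact test (two-sided, minimum-likelihood rule)
#' compares the counts of the process's functions present vs absent in each
#' transect (a function is "present in a transect" when present at any of
#' its sites). Site clustering on the site-by-process count matrix is scored
#' by bootstrap resampling of functions: ordinary bootstrap probabilities
#' (BP) at the original size, and approximately unbiased (AU) support from a
#' multiscale bootstrap over resample sizes r*n for scales r, fitting the
#' normal-quantile model z(r) = v sqrt(r) + c / sqrt(r) by weighted least
#' squares and reporting AU = 1 - pnorm(v - c).
#'
#' @param presence binary function-by-site matrix (1 = function present at
#'   site); row names are function ids, column names site ids.
#' @param process_map data frame with columns `fun` (function id) and
#'   `process`. Functions not mapped are ignored; processes with no observed
#'   function are skipped with a warning.
#' @param design data frame with columns `sample`, `class`; sites of class
#'   `"L"`/`"H"` form the low/high transects for the Fisher tests.
#' @param B bootstrap resamples per scale. Default 1000.
#' @param scales multiscale relative sizes. Default `seq(0.5, 1.4, by = 0.1)`.
#' @param seed integer seed for the bootstrap.
#' @return List with `fisher` (data frame: process, present/absent counts in
#'   L and H, `p_value`), `tree` (hclust of sites), and `support` (data
#'   frame: one row per internal edge, the site split, `bp`, `au`).
#' @export
compare_nutrient_processes <- function(presence, process_map, design,
                                       B = 1000L,
                                       scales = seq(0.5, 1.4, by = 0.1),
                                       seed = 1L) {
  if (!is.matrix(presence) || is.null(rownames(presence)) ||
      is.null(colnames(presence)))
    stop("presence must be a named function-by-site matrix")
  if (!all(c("fun", "process") %in% names(process_map)))
    stop("process_map needs columns: fun, process")
  design <- validate_design(design)
  tested <- intersect(rownames(presence), process_map$fun)
  unmapped <- setdiff(rownames(presence), process_map$fun)
  if (length(tested) == 0L) stop("no presence rows mapped to a process")
  proc <- process_map$process[match(tested, process_map$fun)]

  site_cls <- design$class[match(colnames(presence), design$sample)]
  l_sites <- colnames(presence)[site_cls == "L"]
  h_sites <- colnames(presence)[site_cls == "H"]
  if (length(l_sites) == 0L || length(h_sites) == 0L)
    stop("need at least one L and one H site for transect comparisons")

  fisher <- do.call(rbind, lapply(unique(proc), function(p) {
    funs <- tested[proc == p]
    if (length(funs) == 0L) return(NULL)
    in_l <- rowSums(presence[funs, l_sites, drop = FALSE]) > 0
    in_h <- rowSums(presence[funs, h_sites, drop = FALSE]) > 0
    tab <- matrix(c(sum(in_l), sum(!in_l), sum(in_h), sum(!in_h)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("L", "H"), c("present", "absent")))
    data.frame(process = p, present_L = tab["L", 1], absent_L = tab["L", 2],
               present_H = tab["H", 1], absent_H = tab["H", 2],
               p_value = stats::fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  }))
  skipped <- setdiff(unique(process_map$process), fisher$process)
  if (length(skipped))
    warning("process(es) with no observed functions skipped: ",
            paste(skipped, collapse = ", "))

  # site clustering on process-level counts, with BP and AU support
  counts_mat <- function(rows) {
    pm <- rowsum(presence[rows, , drop = FALSE],
                 group = process_map$process[match(rows, process_map$fun)])
    t(pm)  # sites x processes
  }
  ref <- hclust(dist(counts_mat(tested)), method = "average")
  splits <- tree_splits(ref, colnames(presence))
  set.seed(seed)
  nfun <- length(tested)
  bp_mat <- matrix(0, nrow = length(splits), ncol = length(scales))
  for (j in seq_along(scales)) {
    m <- max(2L, round(scales[j] * nfun))
    hit <- numeric(length(splits))
    for (b in seq_len(B)) {
      rows <- sample(tested, m, replace = TRUE)
      bt <- hclust(dist(counts_mat(rows)), method = "average")
      bs <- tree_splits(bt, colnames(presence))
      hit <- hit + (splits %in% bs)
    }
    bp_mat[, j] <- hit / B
  }
  support <- data.frame(split = splits,
                        bp = bp_mat[, which.min(abs(scales - 1))],
                        au = vapply(seq_along(splits), function(i) {
                          au_from_multiscale(bp_mat[i, ], scales, B)
                        }, numeric(1)),
                        stringsAsFactors = FALSE)
  list(fisher = fisher, tree = ref, support = support,
       unmapped_functions = unmapped)
}

# canonical string encoding of each internal-edge bipartition of an hclust
tree_splits <- function(tree, labels) {
  merge <- tree$merge
  members <- function(node) {
    if (node < 0) return(tree$labels[-node])
    c(members(merge[node, 1]), members(merge[node, 2]))
  }
  out <- character()
  for (i in seq_len(nrow(merge))) {
    side <- sort(members(i))
    other <- sort(setdiff(labels, side))
    if (length(side) < 2L || length(other) < 1L) next  # trivial splits
    canon <- if (paste(side, collapse = ",") < paste(other, collapse = ",")) {
      side
    } else other
    out <- c(out, paste(canon, collapse = ","))
  }
  unique(out)
}

# AU p-value from multiscale bootstrap proportions via the WLS fit of
# qnorm(1 - BP) = v sqrt(r) + c / sqrt(r); AU = 1 - pnorm(v - c).
# Scales where the bootstrap proportion is degenerate (exactly 0 or 1) carry
# no quantile information; they are dropped, and when fewer than three
# informative scales remain the ordinary bootstrap proportion nearest scale 1
# is returned unchanged.
au_from_multiscale <- function(bp, scales, B) {
  ok <- bp > 0 & bp < 1
  if (sum(ok) < 3) return(bp[which.min(abs(scales - 1))])
  bpo <- bp[ok]; sc <- scales[ok]
  z <- qnorm(1 - bpo)
  X <- cbind(sqrt(sc), 1 / sqrt(sc))
  w <- B * dnorm(z)^2 / (bpo * (1 - bpo))
  fit <- tryCatch(solve(t(X) %*% (w * X), t(X) %*% (w * z)),
                  error = function(e) NULL)
  if (is.null(fit)) return(bp[which.min(abs(scales - 1))])
  as.numeric(1 - pnorm(fit[1] - fit[2]))
}
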