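# Community arm: MAG quality filtering, depth normalization, max-abundance
# site assignment, and pooling of proportions by taxon and location class.

#' Filter MAGs on completeness and contamination
#'
#' Applies the MIMAG medium/high-quality screen: keep genomes that are at
#' least `min_completeness` percent complete and have strictly less than
#' `max_contamination` percent contamination. The completeness bound is
#' inclusive and the contamination bound exclusive.
#'
#' @param quality data frame with columns `genome`, `completeness` (percent,
#'   0-100) and `contamination` (percent, >= 0).
#' @param min_completeness inclusive completeness floor, percent. Default 50.
#' @param max_contamination exclusive contamination ceiling, percent.
#'   Default 10.
#' @return Character vector of genome ids passing the filter.
#' @examples
#' q <- data.frame(genome = c("a", "b", "c"),
#'                 completeness = c(50, 49.9, 99),
#'                 contamination = c(9.9, 0, 10))
#' filter_mags(q)  # only "a"
#' @export
filter_mags <- function(quality, min_completeness = 50, max_contamination = 10) {
  quality <- validate_quality(quality)
  if (nrow(quality) == 0L) stop("quality table is empty")
  keep <- quality$completeness >= min_completeness &
    quality$contamination < max_contamination
  quality$genome[keep]
}

# shared quality validation; also used by the io readers
validate_quality <- function(quality) {
  need <- c("genome", "completeness", "contamination")
  if (!is.data.frame(quality) || !all(need %in% names(quality)))
    stop("quality table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(quality$genome))
    stop("duplicated genome ids in quality table")
  if (any(is.na(quality$completeness)) || any(is.na(quality$contamination)))
    stop("quality table contains missing values")
  bad <- quality$completeness < 0 | quality$completeness > 100
  if (any(bad))
    stop("completeness outside [0,100] for: ",
         paste(quality$genome[bad], collapse = ", "))
  if (any(quality$contamination < 0))
    stop("negative contamination for: ",
         paste(quality$genome[quality$contamination < 0], collapse = ", "))
  quality
}

#' Normalize an abundance table by sequencing depth
#'
#' Converts mapped-read counts to relative abundances: each cell is divided
#' by its sample (column) total, i.e. reads mapped to a genome over total
#' reads mapped in that sample, which makes genomes comparable across samples
#' with different sequencing depths.
#'
#' @param counts an [abundance_table()] in count mode with every column sum
#'   positive.
#' @return An [abundance_table()] in proportion mode; every column sums to 1.
#' @examples
#' m <- matrix(c(10, 30, 60), ncol = 1,
#'             dimnames = list(paste0("g", 1:3), "L1"))
#' normalize_abundance(abundance_table(m, "counts"))
#' @export
normalize_abundance <- function(counts) {
  if (abundance_units(counts) != "counts")
    stop("normalize_abundance expects a count-mode table")
  m <- abund_matrix(counts)
  cs <- colSums(m)
  if (any(cs <= 0))
    stop("all-zero sample column(s): ",
         paste(colnames(m)[cs <= 0], collapse = ", "))
  abundance_table(sweep(m, 2L, cs, "/"), "proportions")
}

#' Assign each genome to the sample where it is most abundant
#'
#' @param props an [abundance_table()] in proportion mode.
#' @return Data frame with columns `genome`, `sample` (the argmax sample)
#'   and `tie` (logical: did two or more samples share the maximum?). Ties
#'   are broken toward the lexicographically smallest sample id.
#' @examples
#' m <- matrix(c(0.01, 0.99, 0.5, 0.5, 0.02, 0.98), nrow = 2,
#'             dimnames = list(c("gA", "gB"), c("C", "H1", "L1")))
#' m <- sweep(m, 2, colSums(m), "/")
#' assign_max_site(abundance_table(m, "proportions"))
#' @export
assign_max_site <- function(props) {
  if (abundance_units(props) != "proportions")
    stop("assign_max_site expects a proportion-mode table")
  m <- abund_matrix(props)
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("genome(s) with all-zero abundance: ",
         paste(rownames(m)[zero], collapse = ", "))
  ord <- order(colnames(m))  # lexicographic tie-break
  m_ord <- m[, ord, drop = FALSE]
  idx <- max.col(m_ord, ties.method = "first")
  tie <- vapply(seq_len(nrow(m)), function(i) {
    sum(m[i, ] == max(m[i, ])) > 1L
  }, logical(1))
  data.frame(genome = rownames(m), sample = colnames(m_ord)[idx], tie = tie,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate genome abundances into a taxon-by-location-class profile
#'
#' Pools samples into location classes and genomes into taxa, yielding the
#' taxon-proportion matrix on which the diversity-shift statistic operates.
#' The default pooling sums raw counts over the samples of a class and then
#' renormalizes (depth-aware); `pooling = "mean_props"` instead averages
#' per-sample proportions. Genome proportions are summed within taxa and each
#' class column renormalized to 1; taxa absent from a class keep a zero row
#' so taxon sets stay aligned across classes.
#'
#' @param abund an [abundance_table()]; count mode for
#'   `pooling = "sum_counts"`, either mode for `"mean_props"` (counts are
#'   normalized first).
#' @param taxonomy data frame with columns `genome`, `phylum` and optionally
#'   `class`; must cover every genome in `abund`.
#' @param design data frame with columns `sample`, `class` mapping each
#'   abundance column to exactly one location class (e.g. L, H, C, S).
#' @param split_proteobacteria_by_class if `TRUE`, genomes of phylum
#'   Proteobacteria with a non-missing taxonomic class are labelled by that
#'   class instead of the phylum (the convention of the functional arm).
#' @param pooling `"sum_counts"` (default) or `"mean_props"`.
#' @return A numeric taxon-by-class matrix whose columns each sum to 1, with
#'   attribute `pooling` recording the method.
#' @export
aggregate_profile <- function(abund, taxonomy, design,
                              split_proteobacteria_by_class = FALSE,
                              pooling = c("sum_counts", "mean_props")) {
  pooling <- match.arg(pooling)
  m <- abund_matrix(abund)
  taxonomy <- validate_taxonomy(taxonomy, required = rownames(m))
  design <- validate_design(design, samples = colnames(m))

  if (pooling == "sum_counts") {
    if (abundance_units(abund) != "counts")
      stop("sum_counts pooling needs a count-mode table; ",
           "use pooling = \"mean_props\" for proportions")
  } else if (abundance_units(abund) == "counts") {
    m <- abund_matrix(normalize_abundance(abund))
  }

  cls <- design$class[match(colnames(m), design$sample)]
  classes <- unique(cls)
  pooled <- vapply(classes, function(cl) {
    sub <- m[, cls == cl, drop = FALSE]
    if (pooling == "sum_counts") rowSums(sub) else rowMeans(sub)
  }, numeric(nrow(m)))
  dimnames(pooled) <- list(rownames(m), classes)

  taxon <- taxon_labels(taxonomy, rownames(m), split_proteobacteria_by_class)
  prof <- rowsum(pooled, group = taxon)
  cs <- colSums(prof)
  if (any(cs <= 0))
    stop("location class with zero total abundance: ",
         paste(classes[cs <= 0], collapse = ", "))
  prof <- sweep(prof, 2L, cs, "/")
  attr(prof, "pooling") <- pooling
  prof
}

# map genomes to taxon labels, optionally splitting Proteobacteria by class
taxon_labels <- function(taxonomy, genomes, split) {
  i <- match(genomes, taxonomy$genome)
  lab <- taxonomy$phylum[i]
  if (split && "class" %in% names(taxonomy)) {
    cl <- taxonomy$class[i]
    sub <- !is.na(cl) & cl != "" & lab == "Proteobacteria"
    lab[sub] <- cl[sub]
  }
  lab
}

validate_taxonomy <- function(taxonomy, required = NULL) {
  if (!is.data.frame(taxonomy) ||
      !all(c("genome", "phylum") %in% names(taxonomy)))
    stop("taxonomy needs columns: genome, phylum")
  if (anyDuplicated(taxonomy$genome))
    stop("duplicated genome ids in taxonomy")
  if (!is.null(required)) {
    missing <- setdiff(required, taxonomy$genome)
    if (length(missing))
      stop("genome(s) missing from taxonomy: ",
           paste(missing, collapse = ", "))
  }
  taxonomy
}

validate_design <- function(design, samples = NULL) {
  if (!is.data.frame(design) || !all(c("sample", "class") %in% names(design)))
    stop("design needs columns: sample, class")
  if (anyDuplicated(design$sample))
    stop("duplicated sample ids in design")
  if (!is.null(samples)) {
    missing <- setdiff(samples, design$sample)
    if (length(missing))
      stop("sample(s) missing from design: ", paste(missing, collapse = ", "))
  }
  design
}
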