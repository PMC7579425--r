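#' Construct an abundance table
#'
#' A thin container around a numeric genome-by-sample matrix that records
#' whether its values are raw mapped-read counts or per-sample proportions
#' (relative abundances). All community-arm functions accept and return this
#' class so that count- and proportion-mode inputs cannot be confused.
#'
#' @param x numeric matrix, genomes in rows, samples in columns, with unique
#'   row and column names and no negative values.
#' @param units `"counts"` or `"proportions"`. In proportion mode each column
#'   must sum to 1 within `1e-9`.
#' @return An `abundance_table`: the matrix with a `units` attribute.
#' @examples
#' m <- matrix(c(10, 30, 60), ncol = 1,
#'             dimnames = list(paste0("g", 1:3), "L1"))
#' abundance_table(m, "counts")
#' @export
abundance_table <- function(x, units = c("counts", "proportions")) {
  units <- match.arg(units)
  if (!is.matrix(x) || !is.numeric(x))
    stop("abundance table must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance table must have genome row names and sample column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicated genome ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(is.na(x))) stop("abundance table contains missing values")
  if (any(x < 0)) stop("abundance table contains negative values")
  if (units == "proportions") {
    cs <- colSums(x)
    bad <- abs(cs - 1) > 1e-9
    if (any(bad))
      stop("proportion columns must sum to 1: ",
           paste(colnames(x)[bad], collapse = ", "))
  }
  structure(x, units = units, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table [%s]: %d genomes x %d samples\n",
              abundance_units(x), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more genomes)\n", sep = "")
  invisible(x)
}

#' Units of an abundance table
#'
#' @param x an [abundance_table()].
#' @return `"counts"` or `"proportions"`.
#' @export
abundance_units <- function(x) {
  u <- attr(x, "units")
  if (is.null(u)) stop("not an abundance_table (no units attribute)")
  u
}

#' Subset an abundance table, keeping its units
#'
#' @param x an [abundance_table()].
#' @param i,j row (genome) and column (sample) indices.
#' @param ... unused.
#' @param drop ignored; dimensions are always kept.
#' @export
`[.abundance_table` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)[i, j, drop = FALSE]
  structure(m, units = attr(x, "units"),
            class = c("abundance_table", "matrix", "array"))
}

# internal: plain matrix view
abund_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "units") <- NULL
  m
}
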