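# Readers and writers for the pipeline's TSV interchange formats.
# All tables are tab-separated UTF-8 with a header row; '#' starts a comment.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", comment.char = "#",
               stringsAsFactors = FALSE, check.names = FALSE,
               quote = "", na.strings = "NA"),
    error = function(e) stop("malformed TSV ", path, ": ",
                             conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, " lacks required column(s): ", paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
}

#' Read a genome-by-sample abundance TSV
#'
#' Expects a `genome` column followed by one numeric column per sample.
#' Negative values, missing values and duplicated ids are rejected.
#'
#' @param path TSV path.
#' @param units `"counts"` (default) or `"proportions"`.
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, units = "counts") {
  df <- read_tsv_checked(path, "genome")
  m <- as.matrix(df[, setdiff(names(df), "genome"), drop = FALSE])
  if (!is.numeric(m)) stop(path, ": non-numeric abundance values")
  rownames(m) <- df$genome
  abundance_table(m, units = units)
}

#' Write an abundance table as TSV
#' @param abund an [abundance_table()].
#' @param path output path.
#' @export
write_abundance <- function(abund, path) {
  m <- abund_matrix(abund)
  write_tsv(data.frame(genome = rownames(m), m, check.names = FALSE),
            path)
}

#' Read a genome taxonomy TSV (columns genome, phylum, optional domain/class)
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_taxonomy <- function(path)
  validate_taxonomy(read_tsv_checked(path, c("genome", "phylum")))

#' Read a genome quality TSV (columns genome, completeness, contamination)
#' @param path TSV path.
#' @return Validated data frame; percent bounds enforced.
#' @export
read_quality <- function(path)
  validate_quality(read_tsv_checked(path,
                                    c("genome", "completeness",
                                      "contamination")))

#' Read a sample design TSV (columns sample, class)
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_design <- function(path)
  validate_design(read_tsv_checked(path, c("sample", "class")))

#' Read a long-format annotation TSV (columns genome, fun)
#' @param path TSV path.
#' @return Named list genome -> character vector of function ids.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, c("genome", "fun"))
  lapply(split(df$fun, df$genome), function(x) sort(unique(x)))
}

#' Write annotations as a long-format TSV
#' @param annotations named list genome -> function ids.
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  keep <- lengths(annotations) > 0
  write_tsv(data.frame(
    genome = rep(names(annotations)[keep], lengths(annotations)[keep]),
    fun = unlist(annotations[keep], use.names = FALSE)), path)
}

#' Read a long-format pathway definition TSV (columns pathway, enzyme)
#' @param path TSV path.
#' @return Named list pathway -> character vector of enzymes.
#' @export
read_pathways <- function(path) {
  df <- read_tsv_checked(path, c("pathway", "enzyme"))
  lapply(split(df$enzyme, df$pathway), function(x) sort(unique(x)))
}

#' Write pathway definitions as a long-format TSV
#' @param pathways named list pathway -> enzymes.
#' @param path output path.
#' @export
write_pathways <- function(pathways, path) {
  write_tsv(data.frame(
    pathway = rep(names(pathways), lengths(pathways)),
    enzyme = unlist(pathways, use.names = FALSE)), path)
}

#' Read a sample-by-feature geochemistry TSV (first column sample)
#' @param path TSV path.
#' @return Numeric matrix with sample row names.
#' @export
read_geochem <- function(path) {
  df <- read_tsv_checked(path, "sample")
  m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  if (!is.numeric(m)) stop(path, ": non-numeric geochemistry values")
  if (any(is.na(m))) stop(path, ": missing geochemistry values")
  rownames(m) <- df$sample
  m
}

#' Write a synthetic watershed dataset to a directory of TSVs
#'
#' Writes counts.tsv, taxonomy.tsv, quality.tsv, annotations.tsv,
#' pathways.tsv, geochem.tsv (if present), design.tsv and truth.json.
#'
#' @param ds a `watershed_dataset` from [simulate_watershed()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance(ds$counts, file.path(dir, "counts.tsv"))
  write_tsv(ds$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv(ds$quality, file.path(dir, "quality.tsv"))
  write_annotations(ds$annotations, file.path(dir, "annotations.tsv"))
  write_pathways(ds$pathways, file.path(dir, "pathways.tsv"))
  if (!is.null(ds$geochem))
    write_tsv(data.frame(sample = rownames(ds$geochem), ds$geochem,
                         check.names = FALSE),
              file.path(dir, "geochem.tsv"))
  write_tsv(ds$design, file.path(dir, "design.tsv"))
  jsonlite::write_json(ds$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a watershed dataset back from a directory of TSVs
#'
#' Counterpart of [write_dataset()]; performs cross-file id validation
#' (every counted genome must have exactly one taxonomy and one quality
#' row; every sample must be in the design).
#'
#' @param dir directory holding the TSVs.
#' @return List with `counts`, `taxonomy`, `quality`, `annotations`,
#'   `pathways`, `geochem` (or `NULL`), `design`, `truth` (if truth.json
#'   present).
#' @export
read_dataset <- function(dir) {
  ds <- list(
    counts = read_abundance(file.path(dir, "counts.tsv"), units = "counts"),
    taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
    quality = read_quality(file.path(dir, "quality.tsv")),
    annotations = read_annotations(file.path(dir, "annotations.tsv")),
    pathways = read_pathways(file.path(dir, "pathways.tsv")),
    design = read_design(file.path(dir, "design.tsv")))
  gpath <- file.path(dir, "geochem.tsv")
  ds$geochem <- if (file.exists(gpath)) read_geochem(gpath) else NULL
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) {
    ds$truth <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    if (!is.null(ds$truth$class_props))
      ds$truth$class_props <- lapply(ds$truth$class_props, unlist)
  }
  validate_dataset(ds)
  ds
}

#' Cross-file consistency checks for a dataset
#'
#' @param ds list with at least `counts`, `taxonomy`, `quality`, `design`.
#' @return `ds`, invisibly, or an error listing the offending ids.
#' @export
validate_dataset <- function(ds) {
  genomes <- rownames(ds$counts)
  validate_taxonomy(ds$taxonomy, required = genomes)
  miss_q <- setdiff(genomes, ds$quality$genome)
  if (length(miss_q))
    stop("genome(s) missing from quality: ", paste(miss_q, collapse = ", "))
  validate_design(ds$design, samples = colnames(ds$counts))
  invisible(ds)
}
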