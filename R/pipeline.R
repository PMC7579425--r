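# End-to-end orchestration: filter -> normalize -> profile -> diversity
# shift -> functional arm -> geochemistry arm, with a reproducible report.

#' Run the full diversity-shift pipeline
#'
#' Executes the analysis arms in order on an in-memory dataset (a
#' `watershed_dataset` from [simulate_watershed()] or the list returned by
#' [read_dataset()]): MAG quality filtering, depth normalization, taxon
#' profile aggregation, the taxonomic diversity-shift test, the functional
#' arm (inclusion cutoff, per-genome parsimony pathway calls, pathway
#' profile, functional diversity-shift test) and the geochemistry arm (PCA,
#' PAM/silhouette, Dunn tests, NMDS + envfit). Stages can be restricted;
#' later stages reuse earlier results. When `out_dir` is given every stage's
#' tables plus a JSON run report are written there.
#'
#' @param ds dataset list (`counts`, `taxonomy`, `quality`, `design`, and
#'   for the functional/geochem arms `annotations`, `pathways`, `geochem`).
#' @param stages subset of `c("profile", "stat", "functions", "geochem")`.
#' @param forced_order optional class ordering forced on both diversity-shift
#'   tests.
#' @param min_completeness,max_contamination MAG filter bounds (percent).
#' @param pooling pooling method for [aggregate_profile()].
#' @param metric,linkage clustering choices for [order_classes()].
#' @param cutoff,transform inclusion rule for [include_genomes_per_site()].
#' @param n_perm permutations for the envfit tests.
#' @param seed top-level seed; stage sub-seeds are derived from it.
#' @param out_dir optional output directory.
#' @return A `pipeline_report`: list with `config` (echo of every tunable
#'   actually used), `n_genomes_kept`, `profile`, `taxa` (a
#'   `divshift_report`), `functional` (inclusion, pathway calls, profile,
#'   `divshift_report`), `geochem` (pca, pam, dunn, nmds) and `warnings`.
#' @export
run_pipeline <- function(ds,
                         stages = c("profile", "stat", "functions",
                                    "geochem"),
                         forced_order = NULL,
                         min_completeness = 50, max_contamination = 10,
                         pooling = "sum_counts",
                         metric = "euclidean", linkage = "average",
                         cutoff = 0.25, transform = "max_scaled",
                         n_perm = 999L, seed = 1L, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  warnings <- character()
  note <- function(w) warnings[[length(warnings) + 1L]] <<- w

  config <- list(stages = stages, forced_order = forced_order,
                 min_completeness = min_completeness,
                 max_contamination = max_contamination, pooling = pooling,
                 metric = metric, linkage = linkage, cutoff = cutoff,
                 transform = transform, n_perm = n_perm, seed = seed)
  report <- list(package_version = as.character(packageVersion("divshift")),
                 config = config)

  kept <- filter_mags(ds$quality, min_completeness, max_contamination)
  kept <- intersect(rownames(ds$counts), kept)
  if (length(kept) == 0L) stop("no genomes pass the MIMAG quality filter")
  counts <- ds$counts[kept, ]
  props <- normalize_abundance(counts)
  report$n_genomes_kept <- length(kept)

  if ("profile" %in% stages || "stat" %in% stages) {
    profile <- aggregate_profile(counts, ds$taxonomy, ds$design,
                                 pooling = pooling)
    report$profile <- profile
    detected <- rowSums(abund_matrix(props)) > 0
    report$max_site <- assign_max_site(props[detected, ])
  }
  if ("stat" %in% stages) {
    report$taxa <- run_divshift(report$profile, forced_order = forced_order,
                                metric = metric, linkage = linkage)
  }
  if ("functions" %in% stages) {
    if (is.null(ds$annotations) || is.null(ds$pathways))
      stop("functions stage needs annotations and pathway definitions")
    included <- withCallingHandlers(
      include_genomes_per_site(props, cutoff = cutoff,
                               transform = transform),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    calls <- lapply(ds$annotations[unique(unlist(included))],
                    function(fs) {
                      suppressWarnings(
                        minpath_infer(fs, ds$pathways))$pathways
                    })
    fprofile <- build_pathway_profile(included, ds$annotations, ds$taxonomy,
                                      ds$design, pathway_calls = calls)
    report$functional <- list(
      included = included, pathway_calls = calls, profile = fprofile,
      shift = functional_divshift(fprofile, forced_order = forced_order,
                                  metric = metric, linkage = linkage))
  }
  if ("geochem" %in% stages) {
    if (is.null(ds$geochem)) {
      note("no geochemistry table; geochem stage skipped")
    } else {
      pca <- pca_unit_variance(ds$geochem)
      pam <- pam_silhouette(pca$scores)
      long <- data.frame(
        value = as.vector(ds$geochem),
        feature = rep(colnames(ds$geochem), each = nrow(ds$geochem)),
        sample = rep(rownames(ds$geochem), ncol(ds$geochem)))
      cls <- ds$design$class[match(long$sample, ds$design$sample)]
      dunn <- tryCatch(dunn_bh(long$value, cls),
                       error = function(e) {
                         note(paste("dunn test skipped:",
                                    conditionMessage(e)))
                         NULL
                       })
      comm <- t(abund_matrix(props))[rownames(ds$geochem), , drop = FALSE]
      nmds <- withCallingHandlers(
        nmds_envfit(comm, ds$geochem, n_perm = n_perm, seed = seed + 1L),
        warning = function(w) {
          note(conditionMessage(w)); invokeRestart("muffleWarning")
        })
      report$geochem <- list(pca = pca, pam = pam, dunn = dunn, nmds = nmds)
    }
  }
  report$warnings <- warnings
  report <- structure(report, class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("divshift pipeline report (", x$n_genomes_kept, " genomes kept)\n",
      sep = "")
  if (!is.null(x$taxa)) {
    cat("-- taxonomic arm --\n"); print(x$taxa)
  }
  if (!is.null(x$functional)) {
    cat("-- functional arm --\n"); print(x$functional$shift)
  }
  if (!is.null(x$geochem)) {
    cat("-- geochemistry arm --\n")
    cat("PC1 fraction:",
        round(100 * x$geochem$pca$variance_fraction[1], 1), "%;",
        "PAM k =", x$geochem$pam$k, "\n")
  }
  if (length(x$warnings)) cat("warnings:", length(x$warnings), "\n")
  invisible(x)
}

# serialize the report's tables and a JSON summary into out_dir
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(report$profile))
    write_tsv(data.frame(taxon = rownames(report$profile), report$profile,
                         check.names = FALSE),
              file.path(out_dir, "taxon_profile.tsv"))
  if (!is.null(report$taxa)) {
    write_tsv(report$taxa$slopes, file.path(out_dir, "slopes.tsv"))
    if (!is.na(report$taxa$ordering$newick))
      writeLines(report$taxa$ordering$newick,
                 file.path(out_dir, "class_dendrogram.nwk"))
  }
  if (!is.null(report$functional))
    write_tsv(data.frame(row = rownames(report$functional$profile),
                         report$functional$profile, check.names = FALSE),
              file.path(out_dir, "pathway_profile.tsv"))
  summary <- list(
    package_version = report$package_version,
    config = report$config,
    n_genomes_kept = report$n_genomes_kept,
    taxa = if (!is.null(report$taxa)) list(
      ordering = report$taxa$ordering$order,
      provenance = report$taxa$ordering$provenance,
      k = report$taxa$enrichment$k, n = report$taxa$enrichment$n,
      p_value = report$taxa$enrichment$p_value),
    functional = if (!is.null(report$functional)) list(
      ordering = report$functional$shift$ordering$order,
      k = report$functional$shift$enrichment$k,
      n = report$functional$shift$enrichment$n,
      p_value = report$functional$shift$enrichment$p_value),
    geochem = if (!is.null(report$geochem)) list(
      pc1_fraction = report$geochem$pca$variance_fraction[1],
      pam_k = report$geochem$pam$k,
      nmds_stress = report$geochem$nmds$ordination$stress),
    warnings = report$warnings)
  jsonlite::write_json(summary, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
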