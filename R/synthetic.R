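# Synthetic watershed generator: Dirichlet-multinomial MAG abundances over
# phyla with a tunable runoff-driven loss of evenness in high-runoff
# samples, plus matching taxonomy, quality, annotation, pathway and
# geochemistry tables, so every downstream stage is testable end to end.

PHYLUM_POOL <- c(
  "Proteobacteria", "Actinobacteriota", "Chloroflexota", "Planctomycetota",
  "Acidobacteriota", "Bacteroidota", "Verrucomicrobiota", "Gemmatimonadota",
  "Nitrospirota", "Desulfobacterota", "Myxococcota", "Cyanobacteria",
  "Spirochaetota", "Eisenbacteria", "Patescibacteria", "Omnitrophota",
  "KSB1", "Armatimonadota", "Lindowbacteria", "USBP1", "UBP10",
  "Zixibacteria", "Methylomirabilota", "Crenarchaeota", "Halobacteriota")

GEOCHEM_FEATURES <- c("pH", "O2", "redox", "NO2_NO3", "depth_m", "OC_pct",
                      "CaCO3_pct", "SO4", "NH3", "Cl")

#' Configuration for the synthetic watershed generator
#'
#' Collects and validates the parameters of [simulate_watershed()]. The
#' defaults emulate the study design the package targets: ~300 genomes over
#' 25 phyla, 8 samples in 4 location classes (low-runoff L1/L2, high-runoff
#' H1/H2, negligible-runoff control C, tributary soils S1-S3), around a
#' million mapped reads per sample, and a runoff tilt that depresses phylum
#' evenness in the H-class samples.
#'
#' @param n_genomes number of genomes (MAGs). Default 300.
#' @param n_phyla number of phyla, `<= n_genomes`. Default 25.
#' @param samples data frame with columns `sample`, `class`
#'   (classes among L, H, C, S). Default: L1, L2, H1, H2, C, S1, S2, S3.
#' @param depth_per_sample expected total mapped reads per sample (Poisson
#'   mean). Default 1e6.
#' @param concentration total Dirichlet concentration (> 0) of the base
#'   phylum proportions; each phylum gets shape `concentration / n_phyla`.
#'   Default 25 (shape 1 at 25 phyla: uneven, long-tailed profiles).
#' @param runoff_tilt delta >= 0: strength of the evenness loss in H-class
#'   samples. Phylum p's proportion is multiplied by
#'   `exp(-delta * (rank(p) - 1))` — rank 1 is the most abundant phylum —
#'   and renormalized, so mass concentrates on dominant phyla as delta
#'   grows. Default 0.1.
#' @param function_pool_size size of the function/enzyme vocabulary.
#'   Default 120.
#' @param oxidative_fraction fraction of the vocabulary designated
#'   "oxidative". Default 0.3.
#' @param oxidative_drop fraction of oxidative functions removed from
#'   genomes of H-dominant phyla. Default 0.5.
#' @param n_pathways number of synthetic pathway definitions. Default 30.
#' @param quality_fail_rate fraction of genomes drawn to fail the MIMAG
#'   quality screen. Default 0.1.
#' @param seed integer seed; one global stream governs all draws.
#' @return A validated `watershed_config` list.
#' @export
watershed_config <- function(n_genomes = 300L, n_phyla = 25L,
                             samples = NULL, depth_per_sample = 1e6,
                             concentration = 25, runoff_tilt = 0.1,
                             function_pool_size = 120L,
                             oxidative_fraction = 0.3, oxidative_drop = 0.5,
                             n_pathways = 30L, quality_fail_rate = 0.1,
                             seed = 1L) {
  if (is.null(samples))
    samples <- data.frame(
      sample = c("L1", "L2", "H1", "H2", "C", "S1", "S2", "S3"),
      class = c("L", "L", "H", "H", "C", "S", "S", "S"),
      stringsAsFactors = FALSE)
  samples <- validate_design(samples)
  if (!all(samples$class %in% c("L", "H", "C", "S")))
    stop("location classes must be among L, H, C, S")
  if (n_phyla > n_genomes) stop("n_phyla must not exceed n_genomes")
  if (n_phyla < 1L) stop("n_phyla must be positive")
  if (depth_per_sample <= 0) stop("depth_per_sample must be positive")
  if (concentration <= 0) stop("concentration must be positive")
  if (runoff_tilt < 0) stop("runoff_tilt must be non-negative")
  if (oxidative_drop < 0 || oxidative_drop > 1)
    stop("oxidative_drop must be in [0, 1]")
  structure(list(n_genomes = as.integer(n_genomes),
                 n_phyla = as.integer(n_phyla), samples = samples,
                 depth_per_sample = depth_per_sample,
                 concentration = concentration, runoff_tilt = runoff_tilt,
                 function_pool_size = as.integer(function_pool_size),
                 oxidative_fraction = oxidative_fraction,
                 oxidative_drop = oxidative_drop,
                 n_pathways = as.integer(n_pathways),
                 quality_fail_rate = quality_fail_rate,
                 seed = as.integer(seed)),
            class = "watershed_config")
}

# tilt phylum proportions toward dominant phyla: weight exp(-delta*(rank-1))
tilt_proportions <- function(p, delta) {
  rank_desc <- rank(-p, ties.method = "first")
  w <- p * exp(-delta * (rank_desc - 1))
  w / sum(w)
}

#' Generate a complete synthetic watershed dataset
#'
#' Draws a full set of pipeline inputs from a single seeded stream:
#' \enumerate{
#'   \item Base phylum proportions from a symmetric Dirichlet
#'     (`concentration`); H-class samples use the tilted, renormalized
#'     proportions (see [watershed_config()]), L/C/S the base ones.
#'   \item Genomes assigned to phyla by a stick-breaking split (every phylum
#'     gets at least one genome; some phyla end up singletons, mirroring the
#'     long taxonomic tail of real MAG sets), with stick-breaking
#'     within-phylum genome weights.
#'   \item Per sample, a Poisson total depth and multinomial genome counts
#'     with probabilities (class phylum proportion) x (within-phylum
#'     weight), so counts sum exactly to the drawn depth.
#'   \item Genome quality: ~`quality_fail_rate` of genomes drawn to fail the
#'     MIMAG screen (low completeness or >= 10 percent contamination).
#'   \item Annotations: each phylum gets a function pool; each genome
#'     carries a pool function with probability completeness/100. Genomes
#'     of H-dominant phyla (expected proportion higher in H than in L) lose
#'     a fraction `oxidative_drop` of the designated oxidative functions.
#'   \item Pathway definitions: random enzyme sets over the vocabulary.
#'   \item Geochemistry for the sediment (non-S) samples: Normal draws
#'     around class-and-depth-tier-specific means (H: higher NH3, SO4,
#'     CaCO3; L/C: higher O2, NO2+NO3, redox).
#' }
#'
#' @param config a [watershed_config()].
#' @return A `watershed_dataset`: list with `counts` (an
#'   [abundance_table()]), `taxonomy`, `quality`, `annotations` (named
#'   list), `pathways` (named list), `function_vocab`, `oxidative_functions`,
#'   `geochem` (matrix, sediment samples only), `design`, and `truth`
#'   (generating parameters: per-class phylum proportions, tilt, ranks,
#'   within-phylum weights).
#' @examples
#' ds <- simulate_watershed(watershed_config(n_genomes = 40, n_phyla = 8,
#'                                           depth_per_sample = 1e4))
#' colSums(ds$counts)
#' @export
simulate_watershed <- function(config = watershed_config()) {
  if (!inherits(config, "watershed_config"))
    stop("config must come from watershed_config()")
  set.seed(config$seed)
  P <- config$n_phyla
  G <- config$n_genomes
  samples <- config$samples
  classes <- unique(samples$class)

  # 1. phylum proportions per class
  shape <- config$concentration / P
  base <- rgamma(P, shape = shape, rate = 1)
  base <- pmax(base, 1e-12)
  base <- base / sum(base)
  phyla <- if (P <= length(PHYLUM_POOL)) PHYLUM_POOL[seq_len(P)] else
    c(PHYLUM_POOL, sprintf("Phylum_%02d", seq_len(P - length(PHYLUM_POOL))))
  names(base) <- phyla
  class_props <- list()
  for (cl in classes)
    class_props[[cl]] <- if (cl == "H")
      tilt_proportions(base, config$runoff_tilt) else base

  # 2. genome -> phylum via stick-breaking, one genome per phylum guaranteed
  sb <- function(n, alpha = 4) {
    v <- rbeta(n, 1, alpha)
    w <- v * cumprod(c(1, 1 - v[-n]))
    w / sum(w)
  }
  phylum_w <- sb(P)
  extra <- G - P
  assign_extra <- if (extra > 0)
    sample.int(P, extra, replace = TRUE, prob = phylum_w) else integer()
  genome_phylum <- c(seq_len(P), assign_extra)
  genome_phylum <- genome_phylum[order(genome_phylum)]
  genomes <- sprintf("MAG%03d", seq_len(G))
  # within a phylum, genome weights are symmetric Dirichlet(1): uneven but
  # without the geometric decay of a stick-breaking split, so dominant-phylum
  # members stay detectable at realistic sequencing depths
  within_w <- numeric(G)
  for (ph in seq_len(P)) {
    idx <- which(genome_phylum == ph)
    w <- rgamma(length(idx), shape = 1, rate = 1)
    w <- pmax(w, 1e-9)
    within_w[idx] <- w / sum(w)
  }

  # 3. counts
  counts <- matrix(0L, nrow = G, ncol = nrow(samples),
                   dimnames = list(genomes, samples$sample))
  for (s in seq_len(nrow(samples))) {
    pr <- class_props[[samples$class[s]]][genome_phylum] * within_w
    depth <- rpois(1, config$depth_per_sample)
    counts[, s] <- rmultinom(1, size = depth, prob = pr)[, 1]
  }

  # 4. taxonomy: first phylum pool entry is Proteobacteria -> give classes
  tax_class <- rep(NA_character_, G)
  proteo <- phyla[genome_phylum] == "Proteobacteria"
  if (any(proteo))
    tax_class[proteo] <- sample(c("Alphaproteobacteria",
                                  "Gammaproteobacteria"),
                                sum(proteo), replace = TRUE)
  taxonomy <- data.frame(genome = genomes, domain = "Bacteria",
                         phylum = phyla[genome_phylum], class = tax_class,
                         stringsAsFactors = FALSE)

  # 5. quality
  fail <- runif(G) < config$quality_fail_rate
  completeness <- ifelse(fail, runif(G, 10, 49.9), runif(G, 50, 100))
  contamination <- runif(G, 0, 9.5)
  fail_by_contam <- fail & runif(G) < 0.5
  completeness[fail_by_contam] <- runif(sum(fail_by_contam), 50, 100)
  contamination[fail_by_contam] <- runif(sum(fail_by_contam), 10, 20)
  quality <- data.frame(genome = genomes,
                        completeness = round(completeness, 2),
                        contamination = round(contamination, 2),
                        stringsAsFactors = FALSE)

  # 6. annotations and pathways
  vocab <- sprintf("F%03d", seq_len(config$function_pool_size))
  n_ox <- round(config$oxidative_fraction * length(vocab))
  oxidative <- sample(vocab, n_ox)
  pool_size <- max(5L, round(0.4 * length(vocab)))
  phylum_pool <- lapply(seq_len(P), function(i) sample(vocab, pool_size))
  h_dominant <- phyla[class_props[["H"]] > class_props[[
    if ("L" %in% classes) "L" else classes[1]]]]
  dropped_ox <- lapply(seq_len(P), function(i) {
    ox <- intersect(phylum_pool[[i]], oxidative)
    if (phyla[i] %in% h_dominant && length(ox))
      sample(ox, round(config$oxidative_drop * length(ox)))
    else character()
  })
  annotations <- setNames(vector("list", G), genomes)
  for (g in seq_len(G)) {
    ph <- genome_phylum[g]
    pool <- setdiff(phylum_pool[[ph]], dropped_ox[[ph]])
    keep <- runif(length(pool)) < completeness[g] / 100
    annotations[[g]] <- sort(pool[keep])
  }
  pathways <- setNames(lapply(seq_len(config$n_pathways), function(i) {
    sort(sample(vocab, sample(3:8, 1)))
  }), sprintf("PWY%03d", seq_len(config$n_pathways)))

  # 7. geochemistry, sediment samples only (no soil chemistry measured)
  sed <- samples[samples$class != "S", , drop = FALSE]
  geochem <- NULL
  if (nrow(sed) > 0) {
    class_mean <- list(
      L = c(pH = 7.8, O2 = 9, redox = 250, NO2_NO3 = 6, depth_m = 150,
            OC_pct = 1.2, CaCO3_pct = 18, SO4 = 25, NH3 = 4, Cl = 8),
      C = c(pH = 7.9, O2 = 8.5, redox = 240, NO2_NO3 = 5.5, depth_m = 50,
            OC_pct = 1.1, CaCO3_pct = 19, SO4 = 27, NH3 = 5, Cl = 8.5),
      H = c(pH = 7.5, O2 = 3, redox = 60, NO2_NO3 = 1.5, depth_m = 140,
            OC_pct = 0.7, CaCO3_pct = 32, SO4 = 55, NH3 = 18, Cl = 10))
    sds <- c(pH = 0.08, O2 = 0.5, redox = 15, NO2_NO3 = 0.4, depth_m = 5,
             OC_pct = 0.08, CaCO3_pct = 1.5, SO4 = 3, NH3 = 1.2, Cl = 0.6)
    # deep-tier offset separates the deep sites of each transect
    deep_offset <- c(pH = -0.15, O2 = -1.5, redox = -40, NO2_NO3 = -1,
                     depth_m = 100, OC_pct = 0.3, CaCO3_pct = 3, SO4 = 8,
                     NH3 = 4, Cl = 1.5)
    geochem <- t(vapply(seq_len(nrow(sed)), function(i) {
      cl <- sed$class[i]
      mu <- class_mean[[cl]]
      within <- sum(sed$class[seq_len(i)] == cl)
      if (cl %in% c("L", "H") && within %% 2 == 0) mu <- mu + deep_offset
      rnorm(length(mu), mu, sds)
    }, numeric(length(sds))))
    dimnames(geochem) <- list(sed$sample, GEOCHEM_FEATURES)
  }

  truth <- list(class_props = class_props, base_props = base,
                runoff_tilt = config$runoff_tilt,
                phylum_rank = rank(-base, ties.method = "first"),
                genome_phylum = setNames(phyla[genome_phylum], genomes),
                within_weights = setNames(within_w, genomes),
                h_dominant_phyla = h_dominant,
                oxidative_functions = oxidative)
  structure(list(counts = abundance_table(counts, "counts"),
                 taxonomy = taxonomy, quality = quality,
                 annotations = annotations, pathways = pathways,
                 function_vocab = vocab, oxidative_functions = oxidative,
                 geochem = geochem, design = samples, truth = truth,
                 config = config),
            class = "watershed_dataset")
}

#' @export
print.watershed_dataset <- function(x, ...) {
  cat(sprintf(
    "watershed_dataset: %d genomes, %d phyla, %d samples (classes %s)\n",
    nrow(x$counts), length(unique(x$taxonomy$phylum)), ncol(x$counts),
    paste(unique(x$design$class), collapse = "/")))
  cat(sprintf("runoff tilt delta = %g, seed = %d\n",
              x$config$runoff_tilt, x$config$seed))
  invisible(x)
}

#' Pielou evenness of a class's expected phylum proportions
#'
#' Shannon entropy of the truth-record proportions for a location class,
#' divided by its maximum log(n_phyla): 1 for a uniform profile, 0 when a
#' single phylum carries all mass.
#'
#' @param truth the `truth` element of a [simulate_watershed()] dataset (or
#'   any list with a `class_props` entry), or a bare named list of
#'   proportion vectors.
#' @param location_class class label present in the truth record.
#' @return Evenness in `[0, 1]`.
#' @export
effective_evenness <- function(truth, location_class) {
  props <- if (!is.null(truth$class_props)) truth$class_props else truth
  if (!location_class %in% names(props))
    stop("unknown location class: ", location_class)
  pielou(props[[location_class]])
}

pielou <- function(p) {
  p <- p / sum(p)
  p <- p[p > 0]
  if (length(p) <= 1L) return(0)
  -sum(p * log(p)) / log(length(p))
}

#' Solve for the runoff tilt giving a target evenness ratio
#'
#' Finds delta such that the Pielou evenness of the tilted (H-class) phylum
#' proportions is `target_ratio` times the evenness of the base proportions.
#' Evenness decreases monotonically in delta, so the root is unique.
#'
#' @param base_props named numeric vector of base phylum proportions (e.g.
#'   `truth$base_props`), or a truth record containing `base_props`.
#' @param target_ratio desired evenness(H) / evenness(base), in (0, 1].
#' @param upper upper bracket for the root search. Default 50.
#' @return The tilt delta.
#' @export
calibrate_tilt <- function(base_props, target_ratio, upper = 50) {
  if (is.list(base_props) && !is.null(base_props$base_props))
    base_props <- base_props$base_props
  if (target_ratio <= 0 || target_ratio > 1)
    stop("target_ratio must be in (0, 1]")
  e0 <- pielou(base_props)
  f <- function(d) pielou(tilt_proportions(base_props, d)) / e0 - target_ratio
  if (f(0) <= 0) return(0)
  uniroot(f, c(0, upper), tol = 1e-8)$root
}
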