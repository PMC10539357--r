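#' Generate a complete synthetic dataset
#'
#' Runs the full generative model from a [sim_config()]: a rate-shift
#' birth-death tree, Brownian traits (body size on the log10 scale with
#' regime-linked rate, exported on the raw scale; accessory traits at a
#' constant rate), an elevation-structured landscape with species
#' occupancy, and trait missingness. Truth tables (per-tip regime, true
#' lambda and sigma^2, true trait values) are always included so recovery
#' can be scored.
#'
#' @param config a [sim_config()]; `config$seed` seeds everything.
#' @return list of class `basin_dataset`: `tree`, `painting`, `traits`
#'   (with missingness applied; `body_size` on the raw scale), `truth`
#'   (list: `tip` table, `traits` complete table, `masked` indicator),
#'   `basins`, `incidence`, `n_shifts`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sim <- simulate_shift_tree(config)
  tree <- sim$tree
  painting <- sim$painting

  body_log10 <- simulate_bm_traits(tree, painting,
                                   root_state = config$root_state)
  traits <- data.frame(species = tree$tip.label,
                       body_size = 10^body_log10,
                       stringsAsFactors = FALSE)
  other_names <- c("elongation", "oral_gape_position",
                   "rel_maxillary_length", "rel_eye_size")
  flat <- uniform_painting(tree, sigma2 = config$sigma2_other)
  for (j in seq_len(config$n_other_traits)) {
    nm <- if (j <= length(other_names)) other_names[j] else
      paste0("trait_", j)
    traits[[nm]] <- simulate_bm_traits(tree, flat, root_state = 0)
  }
  land <- simulate_landscape_and_ranges(tree, painting, config)
  miss <- introduce_missingness(traits, config$miss_fraction,
                                mode = config$miss_mode, tree = tree)
  structure(list(tree = tree, painting = painting,
                 traits = miss$traits,
                 truth = list(tip = tip_truth(tree, painting),
                              traits = miss$truth,
                              masked = miss$masked),
                 basins = land$basins, incidence = land$incidence,
                 n_shifts = sim$n_shifts, config = config),
            class = "basin_dataset")
}

#' Analysis options for the assemblage regression pipeline
#'
#' @param stat basin summary statistic for rates (`"mean"`, `"median"`,
#'   `"min"`, `"max"`).
#' @param weight_by_range use inverse range-size weights in basin means.
#' @param min_species drop basins with fewer species.
#' @param drop_taxa,drop_basins exclusion lists.
#' @param z species-area exponent for species density.
#' @param use_density use species density SD = SR/A^z instead of raw
#'   richness as the diversity predictor.
#' @param vif_threshold collinearity screen threshold.
#' @param moran_k,moran_perm k-nearest-neighbour count and permutation
#'   count for the residual Moran's I.
#' @param d_perm permutations for the missingness D test (0 skips it).
#' @param conf_level,alpha CI level and significance level.
#' @return list of class `analysis_options`.
#' @export
analysis_options <- function(stat = "mean", weight_by_range = FALSE,
                             min_species = 5L,
                             drop_taxa = character(),
                             drop_basins = character(),
                             z = 0.25, use_density = FALSE,
                             vif_threshold = 5,
                             moran_k = 8L, moran_perm = 999L,
                             d_perm = 0L,
                             conf_level = 0.95, alpha = 0.05) {
  opts <- as.list(environment())
  class(opts) <- "analysis_options"
  opts
}

#' Run the full assemblage analysis on a dataset
#'
#' The end-to-end statistical surface: per-tip DR and node-density rates;
#' body-size log10 transform, Brownian imputation of missing traits and
#' per-tip trait rates; basin filtering and assemblage summaries
#' (rates, richness/density, Shannon soil diversity); z-scored design with
#' log10 area, iterative VIF screening, standardized OLS of the basin rate
#' summary on the predictors, lmg hierarchical partitioning, commonality
#' analysis over the four predictor groups (morphological evolution,
#' diversity-dependence, climate, habitat), Moran's I on the residuals,
#' and coordinate correlations of the basin rates.
#'
#' Deterministic given `seed`.
#'
#' @param data a `basin_dataset` from [simulate_dataset()] or an
#'   equivalent list built from files (`tree`, `traits`, `basins`,
#'   `incidence`).
#' @param options an [analysis_options()].
#' @param seed seed for the stochastic diagnostics (Moran permutations,
#'   D-statistic nulls).
#' @return list of class `fit_report`; see the elements written by
#'   [write_fit_report()].
#' @export
analyze_dataset <- function(data, options = analysis_options(),
                            seed = 1L) {
  stopifnot(inherits(options, "analysis_options"))
  set.seed(seed)
  tree <- validate_phylo(data$tree)

  rates <- tip_rates(tree)
  dr <- stats::setNames(rates$dr, rates$species)

  traits <- log10_body_size(data$traits)
  miss_d <- NULL
  if (options$d_perm > 0L && anyNA(traits$body_size) &&
      any(!is.na(traits$body_size))) {
    ind <- stats::setNames(as.numeric(is.na(traits$body_size)),
                           traits$species)
    miss_d <- missingness_d(tree, ind, n_perm = options$d_perm)
  }
  imp <- impute_traits_bm(tree, traits)
  trait_rates <- tip_trait_rates_table(tree, imp$traits)

  inc <- filter_and_exclude(data$incidence,
                            min_species = options$min_species,
                            drop_taxa = options$drop_taxa,
                            drop_basins = options$drop_basins)
  prov <- attr(inc, "provenance")
  inc <- inc[rowSums(inc) > 0, , drop = FALSE]  # min_species = 0 corner
  attr(inc, "provenance") <- prov
  basins <- data$basins[match(rownames(inc), data$basins$basin), ]
  weights <- if (options$weight_by_range) inverse_range_weights(inc) else
    NULL
  # the filter may drop species; keep the tree-wide rate vectors as-is and
  # summarize over the surviving incidence columns
  basin_rate <- summarize_rates_by_basin(inc, dr, stat = options$stat,
                                         weights = weights)
  rate_cols <- grep("^rate_", names(trait_rates), value = TRUE)
  basin_trait_rates <- sapply(rate_cols, function(rc) {
    summarize_rates_by_basin(
      inc, stats::setNames(trait_rates[[rc]], trait_rates$species),
      stat = options$stat, weights = weights)
  })
  rd <- richness_and_density(inc,
                             stats::setNames(basins$area, basins$basin),
                             z = options$z)
  soil_cols <- grep("^soil_", names(basins), value = TRUE)
  soil_h <- shannon_soil_diversity(as.matrix(basins[soil_cols]))

  summary_tab <- data.frame(
    basin = rownames(inc),
    rate = unname(basin_rate[rownames(inc)]),
    basin_trait_rates[rownames(inc), , drop = FALSE],
    sr = rd$sr, sd = rd$sd,
    soil_shannon = unname(soil_h),
    basins[c("elevation", "temperature", "runoff", "stream_gradient",
             "area", "x", "y")],
    stringsAsFactors = FALSE, row.names = NULL)

  predictors <- c("rate_body_size", "rate_elongation",
                  if (options$use_density) "sd" else "sr",
                  "temperature", "runoff",
                  "elevation", "area", "stream_gradient", "soil_shannon")
  groups <- c(rate_body_size = "morphological-evolution",
              rate_elongation = "morphological-evolution",
              sr = "diversity-dependence", sd = "diversity-dependence",
              temperature = "climate", runoff = "climate",
              elevation = "habitat", area = "habitat",
              stream_gradient = "habitat", soil_shannon = "habitat")

  design_raw <- summary_tab[predictors]
  design <- standardize(design_raw, log_columns = "area")
  y <- standardize(summary_tab["rate"])$rate

  screen <- vif_screen(design, threshold = options$vif_threshold)
  design <- screen$design
  fit <- fit_standardized_ols(y, design,
                              conf_level = options$conf_level,
                              alpha = options$alpha)
  lmg <- lmg_partition(y, design)
  common <- group_commonality(y, design, groups[names(design)])

  W <- spatial_weights(summary_tab[c("x", "y")], method = "knn",
                       k = min(options$moran_k, nrow(summary_tab) - 1L),
                       row_standardize = TRUE)
  moran <- morans_i(fit$residuals, W, n_perm = options$moran_perm)
  coord <- coordinate_correlation(summary_tab$rate,
                                  summary_tab[c("x", "y")])

  structure(list(tip_rates = rates, trait_rates = trait_rates,
                 imputation = imp$report, imputation_params = imp$params,
                 missingness_d = miss_d,
                 basin_summary = summary_tab,
                 design = design, y = y,
                 vif = screen$vif, vif_removed = screen$removed,
                 ols = fit, lmg = lmg, commonality = common,
                 moran = moran, coordinate_correlation = coord,
                 provenance = attr(inc, "provenance"),
                 groups = groups[names(design)],
                 options = options, seed = seed),
            class = "fit_report")
}

#' Run the whole pipeline from a config and write all outputs
#'
#' Simulates a dataset (or accepts one), analyzes it, and writes every
#' intermediate table plus the machine-readable fit report and a run
#' manifest to `out_dir`.
#'
#' @param config a [sim_config()]; ignored when `data` is supplied.
#' @param options an [analysis_options()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param data optional pre-built `basin_dataset`.
#' @return the `fit_report`, invisibly when writing.
#' @export
run_pipeline <- function(config = sim_config(),
                         options = analysis_options(),
                         out_dir = NULL, data = NULL) {
  if (is.null(data)) data <- simulate_dataset(config)
  seed <- data$config$seed
  if (is.null(seed) || is.na(seed)) seed <- config$seed
  report <- analyze_dataset(data, options, seed = seed)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(data, report, out_dir)
    return(invisible(report))
  }
  report
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Serialize a fit report to JSON
#'
#' @param report a `fit_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fit_report <- function(report, path) {
  out <- list(
    r_squared = report$ols$r_squared,
    coefficients = report$ols$coefficients,
    vif = as.list(report$vif),
    vif_removed = report$vif_removed,
    lmg_shares = as.list(report$lmg$shares),
    lmg_pct_of_r2 = as.list(report$lmg$pct_of_r2),
    commonality = report$commonality$components,
    morans_i = report$moran[c("i", "expectation", "p_value")],
    coordinate_correlation = report$coordinate_correlation,
    missingness_d = report$missingness_d,
    provenance = report$provenance,
    n_basins = nrow(report$basin_summary),
    n_species = nrow(report$tip_rates))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_pipeline_outputs <- function(data, report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(data$tree, file.path(out_dir, "tree.nwk"))
  write_tsv(data$truth$tip, file.path(out_dir, "tip_truth.tsv"))
  write_tsv(data$traits, file.path(out_dir, "traits.tsv"))
  write_tsv(data$basins, file.path(out_dir, "basins.tsv"))
  inc_df <- data.frame(basin = rownames(data$incidence),
                       as.data.frame(data$incidence),
                       check.names = FALSE)
  write_tsv(inc_df, file.path(out_dir, "incidence.tsv"))
  write_tsv(report$tip_rates, file.path(out_dir, "tip_rates.tsv"))
  write_tsv(report$trait_rates, file.path(out_dir, "trait_rates.tsv"))
  if (nrow(report$imputation)) {
    write_tsv(report$imputation,
              file.path(out_dir, "imputation_report.tsv"))
  }
  write_tsv(report$basin_summary, file.path(out_dir, "basin_summary.tsv"))
  write_tsv(data.frame(basin = report$basin_summary$basin,
                       rate_z = report$y, report$design,
                       check.names = FALSE),
            file.path(out_dir, "design_matrix.tsv"))
  write_fit_report(report, file.path(out_dir, "fit_report.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("basinrates")),
    seed = report$seed,
    config = unclass(data$config),
    config_hash = content_hash(jsonlite::toJSON(unclass(data$config),
                                                auto_unbox = TRUE)),
    options = unclass(report$options),
    dropped = report$provenance,
    n_species = nrow(report$tip_rates),
    n_basins = nrow(report$basin_summary),
    status = "OK")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# order-sensitive polynomial checksum of the UTF-8 bytes (hex), used as a
# config fingerprint in the run manifest
content_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 0; p <- 1
  for (b in bytes) {
    p <- (p * 31) %% 2147483647
    h <- (h + b * p) %% 2147483647
  }
  sprintf("%08x", h)
}
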