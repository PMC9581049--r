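#' Build a run configuration
#'
#' Collects every tunable of an end-to-end run, with defaults matching the
#' reference analysis: K = 100 with the shipped CSR basis, a 50-bin grid,
#' k-means with k = 4 for the nine-group scheme, 9999 permutations and a
#' 10 nm co-localisation threshold. A configuration can also be loaded from a
#' YAML file with the same field names via `read_run_config()`.
#'
#' @param inputs Named list of `kna_locs` tables, or character vector of CSV
#'   paths (read with `column_map`).
#' @param column_map Column mapping used when `inputs` are paths.
#' @param K Neighbourhood order.
#' @param basis_path Optional path to a basis JSON; default the shipped basis.
#' @param n_bins Grid bins per axis.
#' @param k_kmeans,split_min_frac,group_seed Nine-group scheme parameters.
#' @param labels Optional condition label per image (enables the permutation
#'   tests).
#' @param n_perm,test_seed Permutation-test parameters.
#' @param channelB Optional second-channel table/path list for enrichment.
#' @param thresholds Co-localisation thresholds.
#' @param out_dir Output directory (created if needed); NULL disables writing.
#' @return A list of class `kna_config`.
#' @export
run_config <- function(inputs, column_map = c(x = "x", y = "y"), K = 100,
                       basis_path = NULL, n_bins = 50, k_kmeans = 4,
                       split_min_frac = 0.10, group_seed = 1,
                       labels = NULL, n_perm = 9999, test_seed = 1,
                       channelB = NULL, thresholds = c(10, 20, 30, 500),
                       out_dir = NULL) {
  structure(list(inputs = inputs, column_map = column_map, K = K,
                 basis_path = basis_path, n_bins = n_bins,
                 k_kmeans = k_kmeans, split_min_frac = split_min_frac,
                 group_seed = group_seed, labels = labels, n_perm = n_perm,
                 test_seed = test_seed, channelB = channelB,
                 thresholds = thresholds, out_dir = out_dir),
            class = "kna_config")
}

#' @rdname run_config
#' @param path YAML file with configuration fields.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

config_basis <- function(config) {
  if (is.null(config$basis_path)) default_basis()
  else read_basis(config$basis_path)
}

resolve_inputs <- function(inputs, column_map) {
  if (inherits(inputs, "kna_locs")) inputs <- list(inputs)
  if (is.character(inputs)) {
    paths <- inputs
    inputs <- lapply(paths, read_localisations, column_map = column_map)
    names(inputs) <- basename(paths)
  }
  if (is.null(names(inputs)) || any(names(inputs) == ""))
    names(inputs) <- vapply(inputs, image_id, "")
  inputs
}

log_stage <- function(log, stage, n) {
  message(sprintf("[kna] %-22s n = %d", stage, n))
  rbind(log, data.frame(stage = stage, n = n))
}

#' Single-image KNA run
#'
#' NNFT, normalisation, SNPCA projection, polar conversion and local density
#' for one image; per-stage localisation counts are logged and the feature
#' table (and optionally a theta-hue render) written to `out_dir`.
#'
#' @param config A `kna_config` with a single input.
#' @return List with `features` (see [kna_features()]), `log` (stage-count
#'   data frame) and, when written, the output paths.
#' @export
run_single_image <- function(config) {
  stopifnot(inherits(config, "kna_config"))
  inputs <- resolve_inputs(config$inputs, config$column_map)
  if (length(inputs) != 1) stop("run_single_image expects exactly one input")
  tab <- inputs[[1]]
  basis <- config_basis(config)
  log <- log_stage(NULL, "localisations", nrow(tab))
  feats <- kna_features(tab, basis = basis, K = config$K)
  log <- log_stage(log, "valid features", sum(feats$valid))
  paths <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$features <- file.path(config$out_dir,
                                paste0(image_id(tab), "_features.csv"))
    write.csv(feats, paths$features, row.names = FALSE)
    off <- auto_hue_offset(feats$theta[feats$valid],
                           feats$log10Den[feats$valid])
    cols <- theta_colours(ifelse(feats$valid, feats$theta, 0), off)
    paths$render <- file.path(config$out_dir,
                              paste0(image_id(tab), "_theta.png"))
    render_points(tab, cols, paths$render)
  }
  list(features = feats, log = log, paths = paths)
}

#' Ensemble KNA run
#'
#' Full pipeline over >= 2 images: per-image features, common grid, frequency
#' table, nine-group scheme, per-localisation groups, log-ratio ordination
#' with BCA and the two permutation tests (when condition labels are given),
#' and per-image enrichment when a second channel is supplied. All stochastic
#' stages are seeded from the configuration, so a rerun is bit-identical.
#'
#' @param config A `kna_config` with >= 2 inputs.
#' @return List with `features`, `grid`, `freq`, `groups`,
#'   `localisation_groups`, `group_freq` (images x groups), and when
#'   applicable `ordination`, `tests`, `enrichment`, plus `provenance`.
#' @export
run_ensemble <- function(config) {
  stopifnot(inherits(config, "kna_config"))
  inputs <- resolve_inputs(config$inputs, config$column_map)
  if (length(inputs) < 2) stop("run_ensemble expects at least two images")
  basis <- config_basis(config)
  if (config$K != basis$K)
    stop("inconsistent K: config K = ", config$K, ", basis K = ", basis$K)

  feats <- lapply(inputs, kna_features, basis = basis, K = config$K)
  grid <- build_grid(feats, n_bins = config$n_bins)
  binned <- lapply(feats, bin_localisations, grid = grid)
  freq <- assemble_frequency_table(binned)
  fc <- filter_common_bins(freq)
  groups <- nine_group_scheme(fc$filtered, fc$leftover, grid,
                              k_kmeans = config$k_kmeans,
                              split_min_frac = config$split_min_frac,
                              seed = config$group_seed)
  loc_groups <- lapply(binned, function(b)
    assign_localisation_groups(b$bin_index, groups))

  group_freq <- t(vapply(loc_groups, function(g) {
    tab <- tabulate(g[!is.na(g)], nbins = groups$n_groups)
    tab / sum(tab)
  }, numeric(groups$n_groups)))
  colnames(group_freq) <- paste0("group", seq_len(groups$n_groups))

  out <- list(features = feats, grid = grid, freq = freq, groups = groups,
              localisation_groups = loc_groups, group_freq = group_freq)

  if (!is.null(config$labels)) {
    labels <- config$labels
    if (nlevels(as.factor(labels)) < 2)
      stop("tests require at least two conditions")
    clr <- logratio_transform(freq$counts[, colSums(freq$counts > 0) ==
                                             nrow(freq$counts), drop = FALSE])
    out$ordination <- ordinate(clr, labels)
    out$tests <- list(
      dispersion = dispersion_test(out$ordination$scores, labels,
                                   n_perm = config$n_perm,
                                   seed = config$test_seed),
      means = mean_difference_test(out$ordination$scores, labels,
                                   n_perm = config$n_perm,
                                   seed = stage_seeds(config$test_seed, 1)))
  } else if (!is.null(config$n_perm)) {
    warning("no condition labels supplied; permutation tests skipped")
  }

  if (!is.null(config$channelB)) {
    chB <- resolve_inputs(config$channelB, config$column_map)
    if (length(chB) != length(inputs))
      stop("channelB must provide one table per image")
    out$enrichment <- lapply(seq_along(inputs), function(i) {
      flags <- colocalise(inputs[[i]], chB[[i]],
                          threshold = min(config$thresholds))
      enrichment_scores(loc_groups[[i]], flags)
    })
    names(out$enrichment) <- names(inputs)
  }

  out$provenance <- list(K = config$K, n_bins = config$n_bins,
                         k_kmeans = config$k_kmeans,
                         split_min_frac = config$split_min_frac,
                         group_seed = config$group_seed,
                         n_perm = config$n_perm, test_seed = config$test_seed,
                         basis = basis$training_params,
                         n_images = length(inputs))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(data.frame(image = rownames(group_freq), group_freq),
              file.path(config$out_dir, "group_frequencies.csv"),
              row.names = FALSE)
    write_groups(groups, file.path(config$out_dir, "groups.json"))
    jsonlite::write_json(out$provenance,
                         file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
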