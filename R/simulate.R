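#' Simulate a clustered SMLM point pattern with ground truth
#'
#' Emulates an SMLM image of spatially random binding sites: parent molecules
#' are drawn from a homogeneous Poisson process over the window; each parent
#' is replaced by a cluster of localisations whose count C is uniform on the
#' integers `[count_min, count_max]` and whose positions are i.i.d. bivariate
#' normal around the parent (per-axis standard deviation `cluster_sd`, zero
#' correlation); spurious background localisations are overlaid as a second
#' Poisson process. Cluster points falling outside the window are kept (edge
#' behaviour belongs to analysis-side filters, not the generator).
#'
#' The defaults are the reference simulation design used throughout the
#' package's validation: parent intensity 5 and noise intensity 50 on a
#' 10 x 10 window, per-axis variance 0.000625 (sd = 0.025) and counts uniform
#' on 10..90, i.e. about 500 clusters of ~50 localisations plus ~5000 noise
#' points.
#'
#' Each stage (parents, counts, cluster offsets, noise) uses its own RNG
#' sub-stream derived from `seed`, so e.g. changing `noise_intensity` does not
#' perturb the signal draw.
#'
#' Ground-truth annotations per point: `is_noise`; `parent_id`; `D_B`, the
#' distance to the own parent (for noise, to the nearest parent — the quantity
#' that dominates a noise point's neighbourhood); `D_BNN`, the own parent's
#' distance to the nearest other parent (NA for noise); `N_clus`, the
#' localisation count of the own parent (NA for noise).
#'
#' @param parent_intensity Poisson intensity of parent molecules.
#' @param win Observation window (default `kna_window(0, 10, 0, 10)`).
#' @param cluster_sd Per-axis standard deviation of the localisation cloud.
#' @param count_min,count_max Inclusive bounds of the uniform localisation
#'   count per parent.
#' @param noise_intensity Poisson intensity of background localisations.
#' @param seed Integer seed.
#' @param image_id Identifier for the generated table.
#' @return Object of class `kna_sim`: list with `table` (`kna_locs`),
#'   `annotations` (data frame, one row per point), `parents` (data frame with
#'   `parent_id`, `x`, `y`, `N_clus`, `D_BNN`) and `params`.
#' @export
simulate_clustered_pattern <- function(parent_intensity = 5,
                                       win = kna_window(0, 10, 0, 10),
                                       cluster_sd = 0.025,
                                       count_min = 10, count_max = 90,
                                       noise_intensity = 50,
                                       seed = NULL,
                                       image_id = "simulated") {
  if (count_min < 1 || count_max < count_min) stop("invalid count interval")
  if (cluster_sd <= 0) stop("cluster_sd must be positive")
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  ss <- stage_seeds(seed, 4)
  area <- window_area(win)

  parents <- with_seed(ss[1], {
    np <- rpois(1, parent_intensity * area)
    tries <- 0
    while (np == 0 && tries < 100) {  # degenerate for D_BNN
      np <- rpois(1, parent_intensity * area)
      tries <- tries + 1
    }
    if (tries > 0) warning("zero parents drawn; re-drew the parent process")
    data.frame(parent_id = seq_len(np),
               x = runif(np, win$xmin, win$xmax),
               y = runif(np, win$ymin, win$ymax))
  })
  np <- nrow(parents)

  counts <- with_seed(ss[2], {
    if (count_min == count_max) rep(as.integer(count_min), np)
    else sample(count_min:count_max, np, replace = TRUE)
  })

  offsets <- with_seed(ss[3], {
    total <- sum(counts)
    cbind(rnorm(total, 0, cluster_sd), rnorm(total, 0, cluster_sd))
  })

  noise <- with_seed(ss[4], {
    nn <- rpois(1, noise_intensity * area)
    cbind(runif(nn, win$xmin, win$xmax), runif(nn, win$ymin, win$ymax))
  })

  pid <- rep.int(parents$parent_id, counts)
  sx <- parents$x[pid] + offsets[, 1]
  sy <- parents$y[pid] + offsets[, 2]

  # parent-to-nearest-other-parent distance
  if (np >= 2) {
    d_bnn <- .knn_self(parents$x, parents$y, 1)[, 1]
  } else d_bnn <- rep(NA_real_, np)
  parents$N_clus <- counts
  parents$D_BNN <- d_bnn

  x <- c(sx, noise[, 1]); y <- c(sy, noise[, 2])
  n_noise <- nrow(noise)
  is_noise <- c(rep(FALSE, length(sx)), rep(TRUE, n_noise))

  d_b_signal <- sqrt((sx - parents$x[pid])^2 + (sy - parents$y[pid])^2)
  d_b_noise <- if (n_noise > 0 && np > 0)
    .nn_cross(noise[, 1], noise[, 2], parents$x, parents$y)
  else numeric(0)

  ann <- data.frame(
    is_noise = is_noise,
    parent_id = c(pid, rep(NA_integer_, n_noise)),
    D_B = c(d_b_signal, d_b_noise),
    D_BNN = c(d_bnn[pid], rep(NA_real_, n_noise)),
    N_clus = c(counts[pid], rep(NA_integer_, n_noise)))

  structure(list(
    table = localisation_table(x, y, image_id = image_id),
    annotations = ann,
    parents = parents,
    params = list(parent_intensity = parent_intensity, window = win,
                  cluster_sd = cluster_sd, count_min = count_min,
                  count_max = count_max, noise_intensity = noise_intensity,
                  seed = seed)),
    class = "kna_sim")
}

#' @export
print.kna_sim <- function(x, ...) {
  cat(sprintf("Simulated pattern '%s': %d localisations (%d signal in %d clusters, %d noise)\n",
              image_id(x$table), nrow(x$table),
              sum(!x$annotations$is_noise), nrow(x$parents),
              sum(x$annotations$is_noise)))
  invisible(x)
}

#' Ground-truth report for a simulated pattern
#'
#' @param pattern A `kna_sim` object.
#' @param point_path,parent_path Optional CSV output paths for the per-point
#'   (coordinates joined to annotations) and per-parent tables.
#' @return List with data frames `points` and `parents` (invisibly written to
#'   the given paths).
#' @export
truth_report <- function(pattern, point_path = NULL, parent_path = NULL) {
  stopifnot(inherits(pattern, "kna_sim"))
  pts <- cbind(as.data.frame(pattern$table)[, c("x", "y")],
               pattern$annotations)
  par <- pattern$parents[, c("parent_id", "x", "y", "N_clus", "D_BNN")]
  if (!is.null(point_path)) write.csv(pts, point_path, row.names = FALSE)
  if (!is.null(parent_path)) write.csv(par, parent_path, row.names = FALSE)
  invisible(list(points = pts, parents = par))
}
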