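#' Compute the nearest-neighbour feature table (NNFT)
#'
#' For each localisation i, the Euclidean distances to its first K nearest
#' neighbours (self excluded) form the nearest-neighbour vector
#' NNV_i = (D_i1, ..., D_iK). Stacked over all N localisations these give an
#' N x K matrix that describes the local topology of every point in the image.
#'
#' The default K = 100 is chosen to exceed the number of localisations that a
#' single blinking molecule typically produces, so the K-neighbourhood reaches
#' beyond one molecule; the analysis is robust over a range of K.
#'
#' Coincident duplicate points are real in SMLM exports; they yield zero
#' distances, which are kept but trigger a warning (downstream normalisation
#' flags such rows rather than failing).
#'
#' @param table A `kna_locs` table with at least K + 1 rows.
#' @param K Neighbourhood order (default 100).
#' @return An object of class `kna_nnft`: list with `distances` (N x K matrix,
#'   rows non-decreasing), `K` and `image_id`.
#' @export
compute_nnft <- function(table, K = 100) {
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  n <- nrow(table)
  if (n <= K)
    stop(sprintf("insufficient points: need at least K + 1 = %d, got %d",
                 K + 1, n))
  d <- .knn_self(table$x, table$y, K)
  if (any(d[, 1] == 0))
    warning(sprintf("%d localisation(s) have coincident duplicates (zero NN distance)",
                    sum(d[, 1] == 0)))
  structure(list(distances = d, K = K, image_id = image_id(table)),
            class = "kna_nnft")
}

#' @export
print.kna_nnft <- function(x, ...) {
  cat(sprintf("NNFT '%s': %d localisations, K = %d\n",
              x$image_id, nrow(x$distances), x$K))
  invisible(x)
}

#' Normalise an NNFT by its K-th nearest-neighbour distance
#'
#' Each row is divided by its own last entry, nNNV_i = NNV_i / D_iK, giving a
#' scale-free description on (0, 1] whose last column is exactly 1. Under
#' complete spatial randomness E(D_ij) is proportional to sqrt(j), so the
#' expected normalised curve is approximately sqrt(j/K); departures from this
#' curve carry the information about local clustering or segregation.
#'
#' Rows whose K-th distance is zero (all K neighbours coincident) cannot be
#' normalised; they are flagged invalid and excluded from downstream
#' statistics, with the count reported via a warning and the `valid` field.
#'
#' @param nnft A `kna_nnft` object.
#' @return An object of class `kna_nnnft`: list with `values` (N x K matrix),
#'   `K`, `image_id` and logical `valid` (per-row flag).
#' @export
normalise_nnft <- function(nnft) {
  stopifnot(inherits(nnft, "kna_nnft"))
  d <- nnft$distances
  last <- d[, ncol(d)]
  valid <- last > 0
  if (!all(valid))
    warning(sprintf("%d row(s) with zero K-th distance flagged invalid",
                    sum(!valid)))
  vals <- d / ifelse(last > 0, last, NA_real_)
  structure(list(values = vals, K = nnft$K, image_id = nnft$image_id,
                 valid = valid),
            class = "kna_nnnft")
}

#' @export
print.kna_nnnft <- function(x, ...) {
  cat(sprintf("Normalised NNFT '%s': %d localisations (%d valid), K = %d\n",
              x$image_id, nrow(x$values), sum(x$valid), x$K))
  invisible(x)
}

#' Per-localisation density from the K-neighbourhood
#'
#' Den_i = (K/2) / (pi * Dbar_i^2), with Dbar_i the mean of the K
#' nearest-neighbour distances of localisation i; units are points per unit
#' area. Local density is examined on a logarithmic scale, so log10(Den) is
#' returned alongside. Rows with zero mean distance are flagged NA.
#'
#' Note the estimator is biased upward by a factor 9/8 under complete spatial
#' randomness (E(Dbar) ~ (2/3) sqrt(K/(pi lambda)) implies
#' (K/2)/(pi E(Dbar)^2) = (9/8) lambda), which is irrelevant for the
#' comparative use made of it.
#'
#' @param nnft A `kna_nnft` object.
#' @return A data frame with columns `Den` and `log10Den`.
#' @export
local_density <- function(nnft) {
  stopifnot(inherits(nnft, "kna_nnft"))
  dbar <- rowMeans(nnft$distances)
  den <- ifelse(dbar > 0, (nnft$K / 2) / (pi * dbar^2), NA_real_)
  data.frame(Den = den, log10Den = log10(den))
}

#' Single k-th nearest-neighbour distance per localisation
#'
#' Long-range structure beyond the K-neighbourhood is profiled with single
#' k-th NN distances at large k (e.g. k = 200, 500), typically partitioned by
#' group label downstream.
#'
#' @param table A `kna_locs` table with at least k + 1 rows.
#' @param k Neighbour order.
#' @return Numeric vector of length N.
#' @export
kth_nn_distances <- function(table, k) {
  nnft <- compute_nnft(table, K = k)
  nnft$distances[, k]
}

#' Per-localisation KNA feature table
#'
#' Convenience wrapper producing the per-localisation feature data frame used
#' throughout the pipeline: local density, SNPC projections and their polar
#' form.
#'
#' @param table A `kna_locs` table.
#' @param basis A `kna_basis` (see [fit_snpca()]); default the shipped one.
#' @param K Neighbourhood order; must match the basis.
#' @return Data frame with columns `index`, `Den`, `log10Den`, `PC1`, `PC2`,
#'   `r`, `theta`, `valid`, plus an `image_id` attribute.
#' @export
kna_features <- function(table, basis = default_basis(), K = basis$K) {
  if (K != basis$K) stop("K must match the basis (basis$K = ", basis$K, ")")
  nnft <- compute_nnft(table, K = K)
  nn <- normalise_nnft(nnft)
  den <- local_density(nnft)
  pc <- project_snpca(nn, basis)
  pol <- polar_coords(pc[, 1], pc[, 2])
  out <- data.frame(index = seq_len(nrow(table)),
                    Den = den$Den, log10Den = den$log10Den,
                    PC1 = pc[, 1], PC2 = pc[, 2],
                    r = pol$r, theta = pol$theta,
                    valid = nn$valid & is.finite(den$Den))
  attr(out, "image_id") <- image_id(table)
  out
}
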