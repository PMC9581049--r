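#' Simulate a completely spatially random (CSR) point pattern
#'
#' Draws a homogeneous planar Poisson process: the point count is
#' Poisson(intensity x window area) and coordinates are i.i.d. uniform over
#' the window.
#'
#' @param intensity Poisson intensity (points per unit area).
#' @param win A `kna_window` (default the unit square).
#' @param seed Optional integer seed for reproducibility.
#' @param image_id Identifier for the generated table.
#' @return A `kna_locs` table.
#' @export
simulate_csr <- function(intensity, win = kna_window(0, 1, 0, 1), seed = NULL,
                         image_id = "csr") {
  if (intensity <= 0) stop("intensity must be positive")
  with_seed(seed, {
    n <- rpois(1, intensity * window_area(win))
    localisation_table(runif(n, win$xmin, win$xmax),
                       runif(n, win$ymin, win$ymax),
                       image_id = image_id)
  })
}

#' Edge filter: keep points whose K-neighbourhood is untruncated
#'
#' A point whose distance to the nearest window boundary is smaller than its
#' own K-th nearest-neighbour distance has a K-neighbourhood disk truncated by
#' the window, which distorts its NNV; such points are discarded when training
#' the CSR basis. The mask is TRUE for points to keep.
#'
#' @param table The `kna_locs` table the NNFT was computed from.
#' @param nnft The corresponding `kna_nnft`.
#' @param win The observation window.
#' @return Logical keep-mask of length N.
#' @export
filter_edge_points <- function(table, nnft, win) {
  stopifnot(inherits(nnft, "kna_nnft"), nrow(table) == nrow(nnft$distances))
  dK <- nnft$distances[, nnft$K]
  boundary <- pmin(table$x - win$xmin, win$xmax - table$x,
                   table$y - win$ymin, win$ymax - table$y)
  boundary >= dK
}

#' Fit the spatial-neighbourhood PCA (SNPCA) basis
#'
#' PCA of the mean-centred normalised NNFT of a CSR point pattern. Fitted on
#' spatially random data, the basis is a universal coordinate system: any
#' image projected on it is directly comparable with any other, which a
#' per-image PCA cannot provide. PCA is computed on the covariance matrix of
#' the mean-centred rows (no variance scaling).
#'
#' The PCA sign indeterminacy is resolved by flipping each loading so that its
#' largest-magnitude entry is positive; serialised bases are therefore
#' reproducible. With this convention SNPC1 is positive for segregated
#' (noise-like) neighbourhood profiles and negative for clustered ones.
#'
#' @param normalised A `kna_nnnft` (typically from edge-filtered CSR data).
#' @param n_components Number of components to retain (default 5; two carry
#'   the structure used by the analysis).
#' @param training_params Optional list recording how the training pattern was
#'   generated (lambda, n_points, seed); stored verbatim.
#' @return An object of class `kna_basis`: list with `K`, `mean_vector`,
#'   `loadings` (K x m, orthonormal columns), `eigenvalues`, `var_explained`
#'   and `training_params`.
#' @export
fit_snpca <- function(normalised, n_components = 5, training_params = list()) {
  stopifnot(inherits(normalised, "kna_nnnft"))
  X <- normalised$values[normalised$valid, , drop = FALSE]
  K <- normalised$K
  if (nrow(X) < K + 1) stop("need at least K + 1 valid rows to fit the basis")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / (nrow(Xc) - 1)
  eig <- eigen(S, symmetric = TRUE)
  if (eig$values[1] <= .Machine$double.eps)
    stop("degenerate covariance: all rows identical")
  m <- min(n_components, K)
  load <- eig$vectors[, seq_len(m), drop = FALSE]
  # sign convention: largest-magnitude entry of each loading is positive
  for (j in seq_len(m)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  total_var <- sum(pmax(eig$values, 0))
  structure(list(K = K, mean_vector = mu, loadings = load,
                 eigenvalues = pmax(eig$values[seq_len(m)], 0),
                 total_variance = total_var,
                 var_explained = pmax(eig$values[seq_len(m)], 0) / total_var,
                 training_params = training_params),
            class = "kna_basis")
}

#' @export
print.kna_basis <- function(x, ...) {
  cat(sprintf("SNPCA basis: K = %d, %d components (%.1f%% + %.1f%% variance)\n",
              x$K, ncol(x$loadings),
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}

#' Train the SNPCA basis from scratch
#'
#' Convenience wrapper reproducing the training recipe: simulate CSR points at
#' the given intensity on the unit square, compute and normalise the NNFT,
#' discard edge points, mean-centre and run the PCA.
#'
#' @param lambda CSR training intensity (default 1e5, i.e. about 100,000
#'   points on the unit square).
#' @param K Neighbourhood order (default 100).
#' @param seed Integer seed.
#' @param n_components Components to retain.
#' @return A `kna_basis`.
#' @export
train_snpca_basis <- function(lambda = 1e5, K = 100, seed = 1,
                              n_components = 5) {
  win <- kna_window(0, 1, 0, 1)
  tab <- simulate_csr(lambda, win, seed = seed, image_id = "csr-training")
  nnft <- compute_nnft(tab, K = K)
  keep <- filter_edge_points(tab, nnft, win)
  nn <- normalise_nnft(nnft)
  nn$values <- nn$values[keep, , drop = FALSE]
  nn$valid <- nn$valid[keep]
  fit_snpca(nn, n_components = n_components,
            training_params = list(lambda = lambda, n_points = nrow(tab),
                                   seed = seed))
}

#' Project a normalised NNFT onto an SNPCA basis
#'
#' Each row, minus the basis mean vector, is dotted with the first two
#' loadings, yielding the per-localisation coordinates (PC1_i, PC2_i).
#' Invalid rows project to NA.
#'
#' @param normalised A `kna_nnnft` with the same K as the basis.
#' @param basis A `kna_basis`.
#' @param n_components Number of components to return (default 2).
#' @return Numeric matrix N x n_components with columns `PC1`, `PC2`, ...
#' @export
project_snpca <- function(normalised, basis, n_components = 2) {
  stopifnot(inherits(normalised, "kna_nnnft"), inherits(basis, "kna_basis"))
  if (normalised$K != basis$K || ncol(normalised$values) != basis$K)
    stop(sprintf("K mismatch: data K = %d (%d columns), basis K = %d",
                 normalised$K, ncol(normalised$values), basis$K))
  m <- min(n_components, ncol(basis$loadings))
  Xc <- sweep(normalised$values, 2, basis$mean_vector)
  sc <- Xc %*% basis$loadings[, seq_len(m), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(m))
  sc
}

#' Polar form of the SNPC coordinates
#'
#' r = sqrt(PC1^2 + PC2^2) and theta = atan2(PC2, PC1) in (-pi, pi]. Points at
#' the origin get theta = 0 and are flagged.
#'
#' @param PC1,PC2 Numeric vectors.
#' @return Data frame with columns `r`, `theta` and logical `at_origin`.
#' @export
polar_coords <- function(PC1, PC2) {
  r <- sqrt(PC1^2 + PC2^2)
  theta <- atan2(PC2, PC1)
  at_origin <- is.finite(r) & r == 0
  theta[at_origin] <- 0
  data.frame(r = r, theta = theta, at_origin = at_origin)
}

#' Serialise / load an SNPCA basis as JSON
#'
#' The on-disk schema is
#' `{version, K, lambda, seed, n_points, mean_vector[K], loadings[m][K],
#' eigenvalues[m]}`; numbers are written at full IEEE precision so that a
#' fit - write - read - project round trip is bit-identical.
#'
#' @param basis A `kna_basis`.
#' @param path Output (input) JSON path.
#' @return `write_basis` returns the path invisibly; `read_basis` a
#'   `kna_basis`.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "kna_basis"))
  tp <- basis$training_params
  obj <- list(version = 1L, K = basis$K,
              lambda = tp$lambda, seed = tp$seed, n_points = tp$n_points,
              mean_vector = basis$mean_vector,
              loadings = lapply(seq_len(ncol(basis$loadings)),
                                function(j) basis$loadings[, j]),
              eigenvalues = basis$eigenvalues,
              total_variance = basis$total_variance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- obj$loadings
  load <- if (is.list(load)) do.call(cbind, lapply(load, as.numeric))
          else t(load)  # simplified to an m x K matrix: components are rows
  eig <- as.numeric(obj$eigenvalues)
  total_var <- if (!is.null(obj$total_variance)) obj$total_variance else sum(eig)
  structure(list(K = as.integer(obj$K),
                 mean_vector = as.numeric(obj$mean_vector),
                 loadings = load,
                 eigenvalues = eig,
                 total_variance = total_var,
                 var_explained = eig / total_var,
                 training_params = list(lambda = obj$lambda, seed = obj$seed,
                                        n_points = obj$n_points)),
            class = "kna_basis")
}

basis_cache <- new.env(parent = emptyenv())

#' The SNPCA basis shipped with the package
#'
#' Trained once on about 100,000 CSR points (Poisson intensity 1e5 on the unit
#' square, K = 100, fixed seed) and distributed as a JSON artefact so that all
#' analyses share one universal coordinate system.
#'
#' @return A `kna_basis` with K = 100.
#' @export
default_basis <- function() {
  if (is.null(basis_cache$default)) {
    path <- system.file("extdata", "snpca_basis_k100.json", package = "kna",
                        mustWork = TRUE)
    basis_cache$default <- read_basis(path)
  }
  basis_cache$default
}
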