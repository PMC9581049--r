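#' Centred log-ratio transform of a compositional frequency matrix
#'
#' The frequency table is compositional (rows sum to one), so ordination works
#' on log ratios: elementwise log, then row centring (the centred log-ratio,
#' which is invariant to row rescaling), then column centring for PCA. Zeros
#' are handled before the log according to `zero_policy`: `"pseudocount"` adds
#' `pseudocount` to every count/frequency cell of a row that contains a zero;
#' `"strict"` raises an error naming the offending cells.
#'
#' @param mat Non-negative matrix (counts or frequencies), images in rows.
#' @param pseudocount Value added under the pseudocount policy (default 0.5,
#'   natural for counts).
#' @param zero_policy `"pseudocount"` or `"strict"`.
#' @param column_centre Apply the final column centring (default TRUE; turn
#'   off to inspect raw CLR rows).
#' @return Transformed numeric matrix of the same shape.
#' @export
logratio_transform <- function(mat, pseudocount = 0.5,
                               zero_policy = c("pseudocount", "strict"),
                               column_centre = TRUE) {
  zero_policy <- match.arg(zero_policy)
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("negative entries are not compositional")
  if (any(mat == 0)) {
    if (zero_policy == "strict") {
      idx <- which(mat == 0, arr.ind = TRUE)
      stop("zero entries at [", paste(apply(head(idx, 5), 1, paste,
                                            collapse = ","), collapse = "; "),
           "] with zero_policy = 'strict'")
    }
    mat <- mat + pseudocount
  }
  mat <- mat / rowSums(mat)
  lx <- log(mat)
  clr <- lx - rowMeans(lx)
  if (column_centre) clr <- sweep(clr, 2, colMeans(clr))
  clr
}

#' Log-ratio ordination with between-component analysis
#'
#' PCA of the column-centred CLR matrix gives per-image scores; the
#' between-component analysis (BCA) then runs a PCA on the condition means
#' (weighted by condition size) and projects every image onto that space,
#' displaying the geometry of the condition separation.
#'
#' @param transformed Column-centred CLR matrix (from
#'   [logratio_transform()]).
#' @param labels Condition label per image (>= 2 conditions, >= 2 images
#'   each).
#' @return Object of class `kna_ordination`: list with `scores` (images x
#'   components PCA scores), `bca_scores`, `bca_group_scores` (condition means
#'   in BCA space), `loadings`, `bca_axes`, `labels`, `var_explained`
#'   (PCA) and `bca_var_explained`.
#' @export
ordinate <- function(transformed, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 conditions")
  if (any(table(labels) < 2)) stop("every condition needs at least 2 images")
  p <- prcomp(transformed, center = TRUE, scale. = FALSE)
  keep <- p$sdev > max(p$sdev) * 1e-10
  scores <- p$x[, keep, drop = FALSE]
  ev <- p$sdev[keep]^2

  # BCA: PCA of the size-weighted condition means, individuals projected
  n_g <- as.vector(table(labels))
  means <- apply(scores, 2, function(col) tapply(col, labels, mean))
  grand <- colSums(means * n_g) / sum(n_g)       # = overall mean = 0
  Mc <- sweep(means, 2, grand)
  B <- crossprod(Mc * sqrt(n_g)) / sum(n_g)      # weighted between-covariance
  be <- eigen(B, symmetric = TRUE)
  nb <- max(1, sum(be$values > max(be$values) * 1e-10))
  axes <- be$vectors[, seq_len(nb), drop = FALSE]
  for (j in seq_len(nb)) {                       # deterministic sign
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  bca_scores <- sweep(scores, 2, grand) %*% axes
  colnames(bca_scores) <- paste0("BCA", seq_len(nb))
  structure(list(scores = scores, bca_scores = bca_scores,
                 bca_group_scores = Mc %*% axes,
                 loadings = p$rotation[, keep, drop = FALSE],
                 bca_axes = axes, labels = labels,
                 var_explained = ev / sum(ev),
                 bca_var_explained = be$values[seq_len(nb)] / sum(pmax(be$values, 0))),
            class = "kna_ordination")
}

#' @export
print.kna_ordination <- function(x, ...) {
  cat(sprintf("Ordination: %d images, %d conditions; BCA axes explain %s of between-condition variance\n",
              nrow(x$scores), nlevels(x$labels),
              paste(sprintf("%.1f%%", 100 * x$bca_var_explained), collapse = " + ")))
  invisible(x)
}

new_perm_result <- function(statistic, null, n_perm, seed, method) {
  p <- (1 + sum(null >= statistic)) / (1 + n_perm)
  structure(list(statistic = statistic, p_value = p, n_perm = n_perm,
                 seed = seed, method = method, null = null),
            class = "kna_permtest")
}

#' @export
print.kna_permtest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%d permutations, seed %s)\n",
              x$method, x$statistic, x$p_value, x$n_perm,
              format(x$seed)))
  invisible(x)
}

disp_stat <- function(scores, labels) {
  # F-type statistic on distances to condition centroids (homogeneity of
  # multivariate dispersions)
  cent <- apply(scores, 2, function(col) tapply(col, labels, mean))
  if (is.null(dim(cent))) cent <- matrix(cent, ncol = 1)
  d <- sqrt(rowSums((scores - cent[as.integer(labels), , drop = FALSE])^2))
  n_g <- tabulate(labels)
  g <- nlevels(labels)
  dbar_g <- tapply(d, labels, mean)
  dbar <- mean(d)
  between <- sum(n_g * (dbar_g - dbar)^2) / (g - 1)
  within <- sum((d - dbar_g[as.integer(labels)])^2) / (length(d) - g)
  between / within
}

mean_stat <- function(scores, labels) {
  # size-weighted sum of squared distances of condition means to grand mean
  cent <- apply(scores, 2, function(col) tapply(col, labels, mean))
  if (is.null(dim(cent))) cent <- matrix(cent, ncol = 1)
  grand <- colMeans(scores)
  n_g <- tabulate(labels)
  sum(n_g * rowSums(sweep(cent, 2, grand)^2))
}

perm_test <- function(scores, labels, n_perm, seed, statistic, method) {
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 conditions")
  if (n_perm < 99) warning("fewer than 99 permutations gives a coarse p-value")
  obs <- statistic(scores, labels)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      statistic(scores, sample(labels)), numeric(1))
  })
  new_perm_result(obs, null, n_perm, seed, method)
}

#' Permutation test for homogeneity of multivariate dispersions
#'
#' Distances of each image's score vector to its condition centroid are
#' compared across conditions with an F-type statistic; the null distribution
#' is obtained by permuting condition labels (Anderson-style dispersion
#' test). p = (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @param scores Numeric matrix of per-image scores (e.g. ordination scores).
#' @param labels Condition label per image.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return A `kna_permtest` with fields `statistic`, `p_value`, `n_perm`,
#'   `seed`.
#' @export
dispersion_test <- function(scores, labels, n_perm = 9999, seed = 1) {
  perm_test(scores, labels, n_perm, seed, disp_stat,
            "Permutation test of multivariate dispersion")
}

#' Permutation test for differences in multivariate means
#'
#' Observed statistic: condition-size-weighted sum of squared distances of the
#' condition mean vectors to the grand mean; null by label permutation.
#'
#' @inheritParams dispersion_test
#' @return A `kna_permtest`.
#' @export
mean_difference_test <- function(scores, labels, n_perm = 9999, seed = 1) {
  perm_test(scores, labels, n_perm, seed, mean_stat,
            "Permutation test of multivariate means")
}
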