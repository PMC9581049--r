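# Brute-force all-pairs kNN oracle: O(N^2), independent of the cell-list
# implementation under test.
brute_force_nnft <- function(x, y, K) {
  D <- as.matrix(dist(cbind(x, y)))
  diag(D) <- Inf
  out <- t(apply(D, 1, function(r) sort(r)[seq_len(K)]))
  dimnames(out) <- NULL
  out
}

# Small clustered ensemble shared by grouping/pipeline tests (three synthetic
# conditions differing in cluster count distribution and noise level).
make_test_ensemble <- function(n_per_cond = 2, side = 6, seed0 = 100) {
  win <- kna_window(0, side, 0, side)
  params <- list(
    A = list(ci = 5, cmin = 10, cmax = 90, noise = 50),
    B = list(ci = 5, cmin = 10, cmax = 40, noise = 100),
    C = list(ci = 8, cmin = 40, cmax = 90, noise = 25))
  sims <- list(); labels <- character(0)
  for (cond in names(params)) {
    p <- params[[cond]]
    for (i in seq_len(n_per_cond)) {
      id <- paste0(cond, i)
      sims[[id]] <- simulate_clustered_pattern(
        parent_intensity = p$ci, win = win, count_min = p$cmin,
        count_max = p$cmax, noise_intensity = p$noise,
        seed = seed0 + 1000 * match(cond, names(params)) + i, image_id = id)
      labels <- c(labels, cond)
    }
  }
  list(sims = sims, labels = labels, win = win)
}

# A frequency-table fixture engineered so that the nine-group scheme finds
# exactly 4 k-means clusters + 2 leftover density categories, of which exactly
# `n_straddle` straddle PC1 = 0 strongly enough to split: 6 -> 6 + n_straddle
# groups. Bins are laid out on a small grid with known centres.
make_nine_group_fixture <- function(n_straddle = 3) {
  n <- 10  # bins per axis; PC1 centres: (i + 0.5) / 10 - 0.5, i = 0..9
  grid <- structure(list(breaks = list(log10Den = c(0, 1), PC1 = c(-0.5, 0.5),
                                       PC2 = c(-0.5, 0.5)),
                         n_bins = n, axes = c("log10Den", "PC1", "PC2")),
                    class = "kna_grid")
  flat <- function(iden, ipc1, ipc2) (iden - 1) * n^2 + (ipc1 - 1) * n + ipc2
  # four k-means clusters of 8 bins each with very distinct frequency
  # profiles across 4 images; clusters 1..n_straddle get bins on both sides
  # of PC1 = 0 (ipc1 4 and 7 -> centres -0.15 and +0.15), the rest one side
  bins <- c(); profile <- c()
  base_profiles <- list(c(40, 5, 5, 5), c(5, 40, 5, 5),
                        c(5, 5, 40, 5), c(5, 5, 5, 40))
  counts <- NULL
  for (cl in 1:4) {
    ipc1 <- if (cl <= n_straddle) rep(c(4, 7), each = 4) else rep(2, 8)
    b <- flat(cl, ipc1, 1:8)
    bins <- c(bins, b)
    counts <- cbind(counts, matrix(rep(base_profiles[[cl]], 8), nrow = 4))
  }
  o <- order(bins)
  counts <- counts[, o, drop = FALSE]
  bins <- bins[o]
  cmat <- matrix(as.integer(counts), nrow = 4,
                 dimnames = list(paste0("img", 1:4), format(bins, trim = TRUE)))
  filtered <- structure(list(counts = cmat, freq = cmat / rowSums(cmat),
                             bins = bins, images = rownames(cmat)),
                        class = "kna_freq")
  # leftover bins: not occupied by all images; spread over two density rows,
  # all on the negative PC1 side so the leftover categories never split
  leftover <- flat(c(6, 6, 9, 9), c(2, 2, 2, 2), c(9, 10, 9, 10))
  attr(leftover, "pooled_counts") <- c(3, 3, 3, 3)
  list(grid = grid, filtered = filtered, leftover = leftover)
}
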