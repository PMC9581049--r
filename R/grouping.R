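#' Build a common 3D binning grid over an ensemble of images
#'
#' The per-localisation triples (log10Den, PC1, PC2) of all images are binned
#' on one fixed grid so that images are directly comparable. For each axis the
#' combined range over all images is split into `n_bins` equal-width bins;
#' bins are half-open `[lo, hi)` except the last, which is closed at the axis
#' maximum. Density enters on the log10 scale, matching the scale on which it
#' is analysed.
#'
#' @param features A `kna_features` data frame, or a list of them (one per
#'   image).
#' @param n_bins Bins per axis (default 50).
#' @return Object of class `kna_grid`: list with `breaks` (per-axis min/max),
#'   `n_bins` and `axes = c("log10Den", "PC1", "PC2")`.
#' @export
build_grid <- function(features, n_bins = 50) {
  if (is.data.frame(features)) features <- list(features)
  axes <- c("log10Den", "PC1", "PC2")
  pooled <- lapply(axes, function(a)
    unlist(lapply(features, function(f) f[[a]][f$valid])))
  rng <- lapply(pooled, range)
  for (i in seq_along(axes)) {
    if (!all(is.finite(rng[[i]]))) stop("non-finite coordinates on axis ", axes[i])
    if (rng[[i]][1] == rng[[i]][2]) stop("degenerate axis ", axes[i],
                                         ": min equals max")
  }
  names(rng) <- axes
  structure(list(breaks = rng, n_bins = as.integer(n_bins), axes = axes),
            class = "kna_grid")
}

#' @export
print.kna_grid <- function(x, ...) {
  cat(sprintf("KNA grid: %d bins per axis\n", x$n_bins))
  for (a in x$axes)
    cat(sprintf("  %-9s [%g, %g]\n", a, x$breaks[[a]][1], x$breaks[[a]][2]))
  invisible(x)
}

# per-axis bin index in 1..n; values beyond the range clamp to boundary bins
axis_bin <- function(v, rng, n) {
  width <- (rng[2] - rng[1]) / n
  i <- floor((v - rng[1]) / width) + 1
  pmin(pmax(i, 1), n)
}

# flattened 1-based index; convention (part of the file format):
# flat = (iDen - 1) * n^2 + (iPC1 - 1) * n + iPC2
flatten_bin <- function(iden, ipc1, ipc2, n) {
  (iden - 1) * n^2 + (ipc1 - 1) * n + ipc2
}

#' Bin the localisations of one image on a grid
#'
#' @param features A `kna_features` data frame.
#' @param grid A `kna_grid`.
#' @return List with `counts` (named integer vector over occupied flat bin
#'   indices), `bin_index` (per-localisation flat index; NA for invalid rows)
#'   and `n_out_of_range` (localisations clamped to boundary bins, which can
#'   only occur when a grid is reused on new data).
#' @export
bin_localisations <- function(features, grid) {
  stopifnot(inherits(grid, "kna_grid"))
  n <- grid$n_bins
  v <- features[features$valid, , drop = FALSE]
  oor <- 0L
  idx <- vector("list", 3)
  for (i in seq_along(grid$axes)) {
    a <- grid$axes[i]
    rng <- grid$breaks[[a]]
    oor <- oor + sum(v[[a]] < rng[1] | v[[a]] > rng[2])
    idx[[i]] <- axis_bin(v[[a]], rng, n)
  }
  if (oor > 0)
    warning(oor, " coordinate(s) outside the grid range assigned to boundary bins")
  flat <- flatten_bin(idx[[1]], idx[[2]], idx[[3]], n)
  bin_index <- rep(NA_real_, nrow(features))
  bin_index[features$valid] <- flat
  counts <- table(flat)
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts, bin_index = bin_index, n_out_of_range = oor)
}

#' Assemble the images x bins frequency table
#'
#' Rows are images, columns the union of occupied 3D bins; the normalised view
#' divides each row by its total, making the table compositional (rows sum to
#' one).
#'
#' @param count_list Named list of per-image count vectors (from
#'   [bin_localisations()]).
#' @return Object of class `kna_freq`: list with integer matrix `counts`,
#'   numeric matrix `freq`, `bins` (flat indices as numeric) and `images`.
#' @export
assemble_frequency_table <- function(count_list) {
  if (is.null(names(count_list)) || any(names(count_list) == ""))
    names(count_list) <- paste0("image", seq_along(count_list))
  counts <- lapply(count_list, function(x) if (is.list(x)) x$counts else x)
  if (any(vapply(counts, sum, 0) == 0)) stop("empty image in ensemble")
  bins <- sort(unique(as.numeric(unlist(lapply(counts, names)))))
  mat <- matrix(0L, nrow = length(counts), ncol = length(bins),
                dimnames = list(names(counts), format(bins, scientific = FALSE,
                                                      trim = TRUE)))
  for (i in seq_along(counts)) {
    b <- as.numeric(names(counts[[i]]))
    mat[i, match(b, bins)] <- counts[[i]]
  }
  structure(list(counts = mat, freq = mat / rowSums(mat), bins = bins,
                 images = names(counts)),
            class = "kna_freq")
}

#' @export
print.kna_freq <- function(x, ...) {
  cat(sprintf("Frequency table: %d images x %d occupied bins\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Split off bins not occupied by every image
#'
#' Bin clustering operates on the bins occupied in all images; the remainder
#' (the leftover set) later forms its own category in the nine-group scheme.
#'
#' @param freq_table A `kna_freq`.
#' @return List with `filtered` (a `kna_freq` restricted to common bins) and
#'   `leftover` (flat indices of the other occupied bins).
#' @export
filter_common_bins <- function(freq_table) {
  stopifnot(inherits(freq_table, "kna_freq"))
  common <- colSums(freq_table$counts > 0) == nrow(freq_table$counts)
  if (!any(common)) stop("no bin is occupied in every image; ",
                         "coarsen the grid or check the ensemble")
  filtered <- structure(list(counts = freq_table$counts[, common, drop = FALSE],
                             freq = freq_table$freq[, common, drop = FALSE],
                             bins = freq_table$bins[common],
                             images = freq_table$images),
                        class = "kna_freq")
  leftover <- freq_table$bins[!common]
  # pooled counts ride along for the nine-group straddle rule
  attr(leftover, "pooled_counts") <-
    unname(colSums(freq_table$counts[, !common, drop = FALSE]))
  list(filtered = filtered, leftover = leftover)
}

#' Average-linkage hierarchical clustering of bins
#'
#' Bins are clustered by the similarity of their normalised-frequency profiles
#' across images (Euclidean distance, average linkage), and the tree is cut
#' into `n_groups` groups. This is the generic path; [nine_group_scheme()] is
#' the k-means-based variant used for the joint nine-group visualisation.
#'
#' @param freq_table A `kna_freq`.
#' @param n_groups Number of groups to cut the tree into.
#' @param metric Distance metric for profiles (default "euclidean").
#' @return Object of class `kna_groups` (see [nine_group_scheme()]).
#' @export
cluster_bins_hierarchical <- function(freq_table, n_groups,
                                      metric = "euclidean") {
  stopifnot(inherits(freq_table, "kna_freq"))
  profiles <- t(freq_table$freq)
  if (n_groups > nrow(profiles))
    stop("n_groups exceeds the number of bins")
  hc <- hclust(dist(profiles, method = metric), method = "average")
  labels <- unname(cutree(hc, k = n_groups))
  new_groups(freq_table$bins, labels,
             provenance = list(method = "hclust-average", metric = metric,
                               n_groups = n_groups))
}

new_groups <- function(bins, labels, provenance = list()) {
  stopifnot(length(bins) == length(labels))
  ng <- max(labels)
  structure(list(bins = bins, group = labels, n_groups = ng,
                 colours = group_palette(ng), provenance = provenance),
            class = "kna_groups")
}

# colour naming follows the joint visualisation's vocabulary
group_palette <- function(n) {
  pal <- c("black", "green3", "cyan", "magenta", "coral", "purple",
           "red", "blue", "violet", "orange", "brown", "grey50")
  rep_len(pal, n)
}

#' @export
print.kna_groups <- function(x, ...) {
  cat(sprintf("Group assignment: %d occupied bins -> %d groups\n",
              length(x$bins), x$n_groups))
  print(table(group = x$group))
  invisible(x)
}

#' The nine-group partition of occupied bins
#'
#' The joint colour scheme for an ensemble: (1) bins occupied in all images
#' are k-means clustered (k = 4, fixed seed, multiple restarts) on their
#' normalised-frequency profiles across images; (2) the leftover bins form a
#' fifth category that is split in two by density, at the median of the
#' leftover bins' log10Den bin centres; (3) every one of the resulting six
#' clusters that straddles SNPC1 = 0 substantially — at least
#' `split_min_frac` of its pooled localisations on each side of PC1 = 0 — is
#' split at the PC1 bin-centre sign. In the reference configuration three of
#' the six clusters split, yielding nine groups. The straddle rule is a
#' deterministic surrogate for a visual-inspection step.
#'
#' @param filtered A `kna_freq` of common bins (from [filter_common_bins()]).
#' @param leftover Flat indices of the non-common occupied bins.
#' @param grid The `kna_grid` the bins live on (for bin centres).
#' @param k_kmeans Number of k-means clusters (default 4).
#' @param split_min_frac Minimum pooled-localisation fraction on each side of
#'   PC1 = 0 for a cluster to be split (default 0.10).
#' @param seed Seed for the k-means restarts.
#' @param n_restarts k-means restarts (default 50; best inertia kept).
#' @return A `kna_groups` covering all occupied bins, with provenance
#'   recording `k_kmeans` and which clusters were split.
#' @export
nine_group_scheme <- function(filtered, leftover, grid, k_kmeans = 4,
                              split_min_frac = 0.10, seed = 1,
                              n_restarts = 50) {
  stopifnot(inherits(filtered, "kna_freq"), inherits(grid, "kna_grid"))
  profiles <- t(filtered$freq)
  if (k_kmeans > nrow(profiles))
    stop("k_kmeans exceeds the number of common bins")
  km <- with_seed(seed, kmeans(profiles, centers = k_kmeans,
                               nstart = n_restarts, iter.max = 100))
  labels <- km$cluster

  all_bins <- c(filtered$bins, as.numeric(leftover))
  cen <- bin_centres(all_bins, grid)

  base <- c(labels, rep(NA_integer_, length(leftover)))
  if (length(leftover) > 0) {
    lo_cen <- bin_centres(leftover, grid)
    med <- median(lo_cen$log10Den)
    base[seq_along(leftover) + length(labels)] <-
      ifelse(lo_cen$log10Den <= med, k_kmeans + 1L, k_kmeans + 2L)
  }
  n_base <- k_kmeans + (if (length(leftover) > 0) 2L else 0L)

  # pooled per-bin localisation counts for the straddle rule; for leftover
  # bins these are the counts of the images that do occupy them
  pooled_counts <- numeric(length(all_bins))
  pooled_counts[seq_len(ncol(filtered$counts))] <- colSums(filtered$counts)
  lo_counts <- attr(leftover, "pooled_counts")
  pooled_counts[seq_along(leftover) + ncol(filtered$counts)] <-
    if (!is.null(lo_counts)) lo_counts else 1

  split_applied <- integer(0)
  final <- base
  next_label <- n_base
  for (g in seq_len(n_base)) {
    memb <- which(base == g)
    neg <- cen$PC1[memb] < 0
    w <- pooled_counts[memb]
    tot <- sum(w)
    if (tot > 0 && sum(w[neg]) / tot >= split_min_frac &&
        sum(w[!neg]) / tot >= split_min_frac) {
      next_label <- next_label + 1L
      final[memb[!neg]] <- next_label
      split_applied <- c(split_applied, g)
    }
  }
  # relabel to consecutive 1..m preserving order of first appearance by base
  final <- match(final, sort(unique(final)))
  new_groups(all_bins, final,
             provenance = list(method = "nine-group", k_kmeans = k_kmeans,
                               split_min_frac = split_min_frac, seed = seed,
                               clusters_split = split_applied,
                               n_before_split = n_base))
}

#' Bin centres on a grid
#'
#' @param bins Flat bin indices.
#' @param grid A `kna_grid`.
#' @return Data frame with `log10Den`, `PC1`, `PC2` centre coordinates.
#' @export
bin_centres <- function(bins, grid) {
  n <- grid$n_bins
  b0 <- as.numeric(bins) - 1
  iden <- b0 %/% (n^2)
  ipc1 <- (b0 %/% n) %% n
  ipc2 <- b0 %% n
  centre <- function(i, rng) rng[1] + (i + 0.5) * (rng[2] - rng[1]) / n
  data.frame(log10Den = centre(iden, grid$breaks$log10Den),
             PC1 = centre(ipc1, grid$breaks$PC1),
             PC2 = centre(ipc2, grid$breaks$PC2))
}

#' Transfer the bin grouping back to localisations
#'
#' @param bin_index Per-localisation flat bin indices (from
#'   [bin_localisations()]; NA allowed for invalid rows).
#' @param groups A `kna_groups` covering every occupied bin.
#' @return Integer group label per localisation (NA for invalid rows).
#' @export
assign_localisation_groups <- function(bin_index, groups) {
  stopifnot(inherits(groups, "kna_groups"))
  pos <- match(bin_index, groups$bins)
  bad <- !is.na(bin_index) & is.na(pos)
  if (any(bad))
    stop(sum(bad), " localisation(s) fall in bins with no group assignment")
  out <- rep(NA_integer_, length(bin_index))
  out[!is.na(pos)] <- groups$group[pos[!is.na(pos)]]
  out
}

#' JSON serialisation of a group assignment
#'
#' Schema: `{version, n_groups, bins[], group[], colours[], provenance}`.
#'
#' @param groups A `kna_groups`.
#' @param path Output (input) path.
#' @export
write_groups <- function(groups, path) {
  jsonlite::write_json(list(version = 1L, n_groups = groups$n_groups,
                            bins = groups$bins, group = groups$group,
                            colours = groups$colours,
                            provenance = groups$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- new_groups(as.numeric(obj$bins), as.integer(obj$group),
                  provenance = as.list(obj$provenance))
  g$colours <- obj$colours
  g
}
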