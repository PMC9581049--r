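fake_features <- function(log10Den, PC1, PC2) {
  data.frame(index = seq_along(log10Den), Den = 10^log10Den,
             log10Den = log10Den, PC1 = PC1, PC2 = PC2,
             r = sqrt(PC1^2 + PC2^2), theta = atan2(PC2, PC1),
             valid = TRUE)
}

test_that("the grid pools ranges over images into equal-width bins", {
  f1 <- fake_features(c(0, 5), c(0, 1), c(0, 1))
  g <- build_grid(f1, n_bins = 50)
  expect_equal(g$breaks$log10Den, c(0, 5))
  w <- diff(g$breaks$log10Den) / g$n_bins
  expect_equal(w, 0.1)
  f2 <- fake_features(c(2, 3), c(2, 3), c(2, 3))
  g2 <- build_grid(list(f1, f2), n_bins = 50)
  expect_equal(g2$breaks$PC1, c(0, 3))
  # adding an image strictly inside the pooled range changes nothing
  f3 <- fake_features(c(1, 2), c(0.5, 1), c(0.5, 1))
  g3 <- build_grid(list(f1, f2, f3), n_bins = 50)
  expect_identical(g2$breaks, g3$breaks)
  expect_error(build_grid(fake_features(c(1, 1), c(0, 1), c(0, 1))),
               "degenerate")
})

test_that("binning conserves counts and closes the last bin", {
  f <- fake_features(c(0, 0.4, 1), c(0, 0, 1), c(0, 1, 1))
  g <- build_grid(f, n_bins = 2)
  b <- bin_localisations(f, g)
  expect_equal(sum(b$counts), 3)
  # hand-placed: (1st bin,1,1), (1st,1,2nd), (2nd,2nd,2nd) on the 2-bin grid
  flat <- function(i, j, k) (i - 1) * 4 + (j - 1) * 2 + k
  expect_setequal(as.numeric(names(b$counts)),
                  c(flat(1, 1, 1), flat(1, 1, 2), flat(2, 2, 2)))
  # values exactly at the axis max land in the last bin (closed)
  expect_equal(b$bin_index[3], flat(2, 2, 2))
  # bin centres invert the flattened index
  cen <- bin_centres(as.numeric(names(b$counts)), g)
  expect_true(all(cen$log10Den %in% c(0.25, 0.75)))
})

test_that("frequency tables are compositional and order-faithful", {
  f1 <- fake_features(runif(50), runif(50), runif(50))
  f2 <- fake_features(runif(40), runif(40), runif(40))
  g <- build_grid(list(f1, f2), n_bins = 3)
  cl <- list(a = bin_localisations(f1, g), b = bin_localisations(f2, g),
             a2 = bin_localisations(f1, g))
  ft <- assemble_frequency_table(cl)
  expect_equal(unname(rowSums(ft$freq)), rep(1, 3))
  expect_equal(unname(rowSums(ft$counts)), c(50, 40, 50))
  # duplicated image gives a duplicated row; permuting images permutes rows
  expect_identical(unname(ft$counts["a", ]), unname(ft$counts["a2", ]))
  ft2 <- assemble_frequency_table(cl[c(2, 1, 3)])
  expect_identical(unname(ft2$counts["a", ]), unname(ft$counts["a", ]))
})

test_that("common-bin filtering separates the leftover set", {
  counts <- rbind(img1 = c(5L, 2L, 1L, 0L), img2 = c(3L, 1L, 0L, 4L))
  colnames(counts) <- format(c(1, 2, 3, 4), trim = TRUE)
  ft <- structure(list(counts = counts, freq = counts / rowSums(counts),
                       bins = c(1, 2, 3, 4), images = rownames(counts)),
                  class = "kna_freq")
  fc <- filter_common_bins(ft)
  expect_equal(fc$filtered$bins, c(1, 2))
  expect_equal(as.numeric(fc$leftover), c(3, 4))
  expect_equal(attr(fc$leftover, "pooled_counts"), c(1, 4))
  # identical images keep everything occupied
  ft2 <- structure(list(counts = counts[c(1, 1), ],
                        freq = counts[c(1, 1), ] / rowSums(counts[c(1, 1), ]),
                        bins = c(1, 2, 3, 4), images = c("a", "b")),
                   class = "kna_freq")
  fc2 <- filter_common_bins(ft2)
  expect_equal(fc2$filtered$bins, c(1, 2, 3))
  # no common bins is an error
  ft3 <- structure(list(counts = rbind(c(1L, 0L), c(0L, 1L)),
                        freq = rbind(c(1, 0), c(0, 1)),
                        bins = c(1, 2), images = c("a", "b")),
                   class = "kna_freq")
  expect_error(filter_common_bins(ft3), "no bin")
})

test_that("average-linkage bin clustering recovers planted structure", {
  # 4 bins: two well-separated profile pairs across 3 images
  counts <- cbind(c(50L, 50L, 50L), c(51L, 49L, 50L),
                  c(5L, 90L, 55L), c(6L, 89L, 54L))
  rownames(counts) <- paste0("img", 1:3)
  colnames(counts) <- format(1:4, trim = TRUE)
  ft <- structure(list(counts = counts, freq = counts / rowSums(counts),
                       bins = 1:4, images = rownames(counts)),
                  class = "kna_freq")
  ga <- cluster_bins_hierarchical(ft, n_groups = 2)
  expect_equal(ga$group[1], ga$group[2])
  expect_equal(ga$group[3], ga$group[4])
  expect_false(ga$group[1] == ga$group[3])
  # identical columns merge first; singleton cut returns all singletons
  expect_equal(cluster_bins_hierarchical(ft, 4)$n_groups, 4)
  expect_error(cluster_bins_hierarchical(ft, 5), "exceeds")
})

test_that("the nine-group scheme splits straddling clusters at SNPC1 = 0", {
  fx <- make_nine_group_fixture(n_straddle = 3)
  ga <- nine_group_scheme(fx$filtered, fx$leftover, fx$grid, seed = 42)
  expect_equal(ga$provenance$n_before_split, 6)
  expect_equal(length(ga$provenance$clusters_split), 3)
  expect_equal(ga$n_groups, 9)
  # a partition: every occupied bin appears exactly once, with one label
  expect_setequal(ga$bins, c(fx$filtered$bins, as.numeric(fx$leftover)))
  expect_equal(length(ga$group), length(ga$bins))
  expect_true(all(ga$group %in% 1:9))
  # with no straddling cluster the scheme stops at 4 + 2 = 6 groups
  fx0 <- make_nine_group_fixture(n_straddle = 0)
  ga0 <- nine_group_scheme(fx0$filtered, fx0$leftover, fx0$grid, seed = 42)
  expect_equal(ga0$n_groups, 6)
  # reproducible under the fixed seed
  ga2 <- nine_group_scheme(fx$filtered, fx$leftover, fx$grid, seed = 42)
  expect_identical(ga$group, ga2$group)
})

test_that("localisations inherit their bin's group label", {
  fx <- make_nine_group_fixture()
  ga <- nine_group_scheme(fx$filtered, fx$leftover, fx$grid, seed = 1)
  bin_index <- c(fx$filtered$bins[c(1, 1, 5)], NA)
  lab <- assign_localisation_groups(bin_index, ga)
  expect_equal(lab[1], lab[2])
  expect_true(is.na(lab[4]))
  expect_error(assign_localisation_groups(999999, ga), "no group")
  # group frequencies aggregate bin frequencies exactly
  all_bins <- ga$bins
  w <- seq_along(all_bins)
  lab_all <- assign_localisation_groups(rep(all_bins, w), ga)
  by_group <- tapply(rep(1, sum(w)), lab_all, sum)
  expect_equal(sum(by_group), sum(w))
  # JSON round trip
  f <- withr::local_tempfile(fileext = ".json")
  write_groups(ga, f)
  ga3 <- read_groups(f)
  expect_equal(ga3$group, ga$group)
  expect_equal(ga3$bins, ga$bins)
})

test_that("noise and large clusters separate into different groups", {
  ens <- make_test_ensemble(n_per_cond = 2, side = 6)
  tabs <- lapply(ens$sims, `[[`, "table")
  res <- run_ensemble(run_config(tabs, n_bins = 12, n_perm = NULL))
  s <- ens$sims[[1]]
  g <- res$localisation_groups[[1]]
  ann <- s$annotations
  big <- !ann$is_noise & ann$N_clus >= 70
  noi <- ann$is_noise
  mg_big <- as.integer(names(which.max(table(g[big]))))
  mg_noi <- as.integer(names(which.max(table(g[noi]))))
  expect_false(mg_big == mg_noi)
  # >= 70% separation by majority group on both sides
  expect_lt(mean(g[big] == mg_noi, na.rm = TRUE), 0.30)
  expect_lt(mean(g[noi] == mg_big, na.rm = TRUE), 0.30)
})
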