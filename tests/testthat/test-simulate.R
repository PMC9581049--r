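test_that("simulator is deterministic with independent sub-streams", {
  s1 <- simulate_clustered_pattern(seed = 5)
  s2 <- simulate_clustered_pattern(seed = 5)
  expect_identical(as.data.frame(s1$table), as.data.frame(s2$table))
  expect_identical(s1$annotations, s2$annotations)
  # raising the noise intensity must not perturb the signal draw
  s3 <- simulate_clustered_pattern(seed = 5, noise_intensity = 200)
  sig1 <- as.data.frame(s1$table)[!s1$annotations$is_noise, ]
  sig3 <- as.data.frame(s3$table)[!s3$annotations$is_noise, ]
  expect_identical(sig1, sig3)
  expect_gt(sum(s3$annotations$is_noise), sum(s1$annotations$is_noise))
})

test_that("annotations conserve counts and encode ground truth", {
  s <- simulate_clustered_pattern(seed = 21)
  ann <- s$annotations
  expect_equal(sum(s$parents$N_clus) + sum(ann$is_noise), nrow(s$table))
  # every signal point has a parent; its N_clus equals the family size
  fam <- table(ann$parent_id[!ann$is_noise])
  expect_equal(unname(fam[as.character(s$parents$parent_id)]),
               s$parents$N_clus, ignore_attr = TRUE)
  expect_true(all(ann$D_B >= 0))
  expect_true(all(s$parents$D_BNN > 0))
  # reference design: ~500 parents, ~5000 noise points, counts mean ~50
  expect_true(abs(nrow(s$parents) - 500) < 4 * sqrt(500))
  expect_true(abs(sum(ann$is_noise) - 5000) < 4 * sqrt(5000))
  expect_equal(mean(s$parents$N_clus), 50,
               tolerance = 3 * sd(10:90) / sqrt(nrow(s$parents)) / 50 + 0.02)
})

test_that("degenerate and two-parent geometries annotate exactly", {
  # two isolated parents: both D_BNN equal their separation
  win <- kna_window(0, 1, 0, 1)
  s <- NULL
  for (seed in 1:50) {
    # a zero-parent draw warns and redraws; irrelevant to this search
    cand <- suppressWarnings(
      simulate_clustered_pattern(parent_intensity = 2, win = win,
                                 cluster_sd = 1e-3, count_min = 3,
                                 count_max = 5, noise_intensity = 0,
                                 seed = seed))
    if (nrow(cand$parents) == 2) { s <- cand; break }
  }
  expect_false(is.null(s))
  d <- sqrt(diff(s$parents$x)^2 + diff(s$parents$y)^2)
  expect_equal(s$parents$D_BNN, rep(d, 2))
  expect_false(any(s$annotations$is_noise))  # noise_intensity = 0
  # cluster_sd -> 0 limit collapses clusters onto parents
  s0 <- simulate_clustered_pattern(cluster_sd = 1e-14, noise_intensity = 0,
                                   seed = 4)
  expect_lt(max(s0$annotations$D_B), 1e-12)
})

test_that("truth report conserves rows and per-parent counts", {
  s <- simulate_clustered_pattern(seed = 13, win = kna_window(0, 5, 0, 5))
  rep <- truth_report(s)
  expect_equal(nrow(rep$points), nrow(s$table))
  expect_equal(sum(rep$parents$N_clus) + sum(rep$points$is_noise),
               nrow(rep$points))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  truth_report(s, f1, f2)
  expect_equal(nrow(read.csv(f1)), nrow(s$table))
  expect_equal(nrow(read.csv(f2)), nrow(s$parents))
})

test_that("parent counts are Poisson and localisation counts uniform", {
  # 200 replicate draws of the parent process (intensity 5 on a 2 x 2 window)
  counts <- vapply(1:200, function(i) {
    s <- simulate_clustered_pattern(parent_intensity = 5,
                                    win = kna_window(0, 2, 0, 2),
                                    count_min = 1, count_max = 1,
                                    cluster_sd = 1e-3, noise_intensity = 0,
                                    seed = 10000 + i)
    nrow(s$parents)
  }, numeric(1))
  mu <- 20
  # chi-square GOF against Poisson(20) on pooled bins with expectation >= 5
  brks <- c(-Inf, 14, 17, 20, 23, 26, Inf)
  obs <- table(cut(counts, brks))
  pr <- diff(c(0, ppois(c(14, 17, 20, 23, 26), mu), 1))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
  # uniform count interval is inclusive with the right mean
  s <- simulate_clustered_pattern(parent_intensity = 60,
                                  win = kna_window(0, 5, 0, 5),
                                  cluster_sd = 1e-3, count_min = 10,
                                  count_max = 90, noise_intensity = 0,
                                  seed = 3)
  expect_gte(min(s$parents$N_clus), 10)
  expect_lte(max(s$parents$N_clus), 90)
  expect_gt(nrow(s$parents), 1000)
  expect_equal(mean(s$parents$N_clus), 50,
               tolerance = 3 * sd(10:90) / sqrt(nrow(s$parents)) / 50)
})
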