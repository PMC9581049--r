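test_that("the centred log-ratio transform honours compositional identities", {
  # equal frequencies give an all-zero CLR row
  m <- rbind(rep(0.25, 4), c(0.1, 0.2, 0.3, 0.4))
  clr <- logratio_transform(m, column_centre = FALSE)
  expect_equal(unname(clr[1, ]), rep(0, 4))
  # invariance to row rescaling (compositional closure)
  clr2 <- logratio_transform(m * c(10, 0.5), column_centre = FALSE)
  expect_equal(clr, clr2)
  # antisymmetric 2 x 2 worked case
  m2 <- rbind(c(1, 3), c(3, 1)) / 4
  clr3 <- logratio_transform(m2, column_centre = FALSE)
  expect_equal(unname(clr3),
               rbind(c(-log(sqrt(3)), log(sqrt(3))),
                     c(log(sqrt(3)), -log(sqrt(3)))))
  # zero handling
  expect_error(logratio_transform(rbind(c(0, 1)), zero_policy = "strict"),
               "zero entries")
  z <- logratio_transform(rbind(c(0, 1), c(1, 1)))
  expect_true(all(is.finite(z)))
  # column centring yields column means zero
  cc <- logratio_transform(m)
  expect_lt(max(abs(colMeans(cc))), 1e-12)
})

test_that("between-component analysis recovers planted mean geometry", {
  set.seed(31)
  true_means <- rbind(c(0, 0), c(4, 0), c(2, 3))
  n_per <- 8; p <- 6
  emb <- matrix(rnorm(2 * p), 2, p)  # embed the 2D geometry in 6 dims
  X <- do.call(rbind, lapply(1:3, function(g)
    matrix(rep(true_means[g, ] %*% emb, n_per), n_per, byrow = TRUE) +
      matrix(rnorm(n_per * p, sd = 0.3), n_per)))
  labels <- rep(c("a", "b", "c"), each = n_per)
  ord <- ordinate(sweep(X, 2, colMeans(X)), labels)
  # PCA scores are column-centred
  expect_lt(max(abs(colMeans(ord$scores))), 1e-10)
  expect_lt(max(abs(colMeans(ord$bca_scores))), 1e-10)
  # with planted noise the group geometry is recovered approximately; the
  # oracle is the geometry of the *embedded* means (the embedding is a
  # general linear map, so it distorts the original 2D distances)
  Mc <- scale(true_means %*% emb, center = TRUE, scale = FALSE)
  pro <- vegan::procrustes(cmdscale(dist(Mc), k = 2),
                           ord$bca_group_scores[, 1:2], symmetric = TRUE)
  expect_gt(sqrt(1 - pro$ss), 0.95)
  # in the zero-noise limit the recovery is exact: BCA group scores are an
  # isometric image of the centred embedded means
  X0n <- do.call(rbind, lapply(1:3, function(g)
    matrix(rep(true_means[g, ] %*% emb, n_per), n_per, byrow = TRUE)))
  ord_ex <- ordinate(sweep(X0n, 2, colMeans(X0n)), labels)
  expect_equal(as.vector(dist(ord_ex$bca_group_scores[, 1:2])),
               as.vector(dist(Mc)), tolerance = 1e-8)
  # identical condition means give (near) zero between-group variance
  X0 <- matrix(rnorm(60), 20, 3)
  lab0 <- rep(c("a", "b"), 10)
  ord0 <- ordinate(X0, lab0)
  expect_lt(sum(ord0$bca_group_scores^2), sum(ord0$scores^2) * 0.2)
  # collinear means give a single non-null BCA component
  expect_equal(ncol(ordinate(rbind(X0, X0 + 5), rep(c("a", "b"),
                                                    each = 20))$bca_scores) >= 1,
               TRUE)
  expect_error(ordinate(X0, rep("a", 20)), "2 conditions")
  expect_error(ordinate(X0, c("b", rep("a", 19))), "at least 2 images")
})

test_that("permutation tests respect the p-value identity and seeding", {
  set.seed(12)
  sc <- matrix(rnorm(30 * 2), 30, 2)
  lab <- rep(c("a", "b", "c"), each = 10)
  t1 <- dispersion_test(sc, lab, n_perm = 199, seed = 7)
  t2 <- dispersion_test(sc, lab, n_perm = 199, seed = 7)
  expect_identical(t1$p_value, t2$p_value)
  expect_equal(t1$p_value,
               (1 + sum(t1$null >= t1$statistic)) / (1 + t1$n_perm))
  expect_gt(t1$p_value, 0); expect_lte(t1$p_value, 1)
  m1 <- mean_difference_test(sc, lab, n_perm = 199, seed = 7)
  expect_equal(m1$p_value,
               (1 + sum(m1$null >= m1$statistic)) / (1 + m1$n_perm))
  expect_warning(dispersion_test(sc, lab, n_perm = 50, seed = 1), "coarse")
})

test_that("the dispersion statistic agrees with the PERMDISP cross-check", {
  set.seed(9)
  sc <- rbind(matrix(rnorm(24, sd = 1), 12, 2),
              matrix(rnorm(24, sd = 2.5), 12, 2))
  lab <- factor(rep(c("a", "b"), each = 12))
  t1 <- dispersion_test(sc, lab, n_perm = 99, seed = 2)
  bd <- vegan::betadisper(dist(sc), lab, type = "centroid")
  f_ref <- anova(bd)$`F value`[1]
  expect_equal(unname(t1$statistic), f_ref, tolerance = 1e-8)
  # a genuine spread difference is detected
  expect_lt(t1$p_value, 0.05)
})

test_that("splitting one condition at random yields high p-values", {
  set.seed(5)
  ps <- vapply(1:40, function(i) {
    sc <- matrix(rnorm(24 * 2), 24, 2)
    lab <- sample(rep(c("a", "b"), each = 12))
    mean_difference_test(sc, lab, n_perm = 99, seed = i)$p_value
  }, numeric(1))
  expect_gt(median(ps), 0.3)
})
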