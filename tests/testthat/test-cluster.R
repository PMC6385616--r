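# t-maps, clustering, and the permutation test: textbook oracles,
# enumeration checks, and symmetry properties.

test_that("t-map values, dfs, and degenerate bins behave", {
  a <- array(c(1, 2, 3), c(3, 1, 1))
  b <- array(c(4, 5, 6), c(3, 1, 1))
  tm <- pointwise_tmap(a, b)
  # oracle: t = (2 - 5) / sqrt(1 * (1/3 + 1/3))
  expect_equal(as.vector(tm$t), -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tm$df, 4L)
  # identical groups give t = 0 where variance is nonzero
  set.seed(1)
  g <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  tm0 <- pointwise_tmap(g, g, design = "paired")
  expect_true(all(is.na(tm0$t)))   # zero-variance differences are masked
  tm0b <- pointwise_tmap(g, g)
  expect_true(all(abs(tm0b$t) < 1e-12))
  # study-sized groups give the expected df
  expect_equal(pointwise_tmap(array(rnorm(12 * 4), c(12, 1, 4)),
                              array(rnorm(16 * 4), c(16, 1, 4)))$df, 26L)
  expect_equal(pointwise_tmap(array(rnorm(12 * 4), c(12, 1, 4)),
                              array(rnorm(12 * 4), c(12, 1, 4)),
                              design = "paired")$df, 11L)
  expect_error(pointwise_tmap(g[1, , , drop = FALSE], g), ">= 2")
})

test_that("clustering uses 4-connectivity and sums masses", {
  tmat <- matrix(0, 3, 3)
  tmat[1, 1] <- 5; tmat[2, 2] <- 5          # touch diagonally only
  fake <- structure(list(t = tmat, df = 20, design = "independent",
                         mask = matrix(TRUE, 3, 3)), class = "tmap")
  cls <- form_clusters(fake)
  expect_length(cls, 2)
  expect_equal(vapply(cls, `[[`, numeric(1), "mass"), c(5, 5))
  # single supra-threshold bin
  tmat2 <- matrix(0, 3, 3); tmat2[2, 2] <- 5
  fake2 <- structure(list(t = tmat2, df = 20, design = "independent",
                          mask = matrix(TRUE, 3, 3)), class = "tmap")
  expect_equal(form_clusters(fake2)[[1]]$mass, 5)
  # all below threshold -> empty
  fake3 <- structure(list(t = matrix(0.5, 3, 3), df = 20,
                          design = "independent",
                          mask = matrix(TRUE, 3, 3)), class = "tmap")
  expect_length(form_clusters(fake3), 0)
  # compiled labeller agrees with the reference labeller
  set.seed(2)
  for (i in 1:25) {
    m <- matrix(runif(15 * 11) < 0.3, 15, 11)
    a <- betarebound:::cpp_label_components(m)
    b <- label_components_ref(m)
    expect_identical(as.integer(factor(a[m])), as.integer(factor(b[m])))
  }
})

test_that("Monte-Carlo p-values track exhaustive enumeration", {
  # opposite-sign whole-grid effects keep every cluster p at an extreme,
  # where the Monte-Carlo estimate of the enumeration probability is stable
  set.seed(7)
  ga <- array(rnorm(4 * 8 * 10), c(4, 8, 10))
  gb <- array(rnorm(4 * 8 * 10), c(4, 8, 10))
  gb[, 1:4, ] <- gb[, 1:4, ] + 6
  gb[, 5:8, ] <- gb[, 5:8, ] - 6
  ex <- permutation_cluster_test(ga, gb, method = "exhaustive")
  mc <- permutation_cluster_test(ga, gb, method = "montecarlo",
                                 n_perm = 1000, seed = 11)
  expect_equal(ex$n_perm, 70)               # choose(8, 4) assignments
  pe <- vapply(ex$clusters, `[[`, numeric(1), "monte_carlo_p")
  pm <- vapply(mc$clusters, `[[`, numeric(1), "monte_carlo_p")
  expect_equal(length(pe), length(pm))
  expect_true(all(abs(pe - pm) <= 0.02))
  # p-value bounds
  expect_true(all(pm >= 1 / 1001 & pm <= 1))
  expect_true(all(pe >= 1 / 70 & pe <= 1))
})

test_that("negating the data swaps cluster signs with identical p-values", {
  set.seed(8)
  ga <- array(rnorm(5 * 6 * 8), c(5, 6, 8))
  gb <- array(rnorm(5 * 6 * 8), c(5, 6, 8))
  gb[, 2:3, 3:5] <- gb[, 2:3, 3:5] + 1.5
  r1 <- permutation_cluster_test(ga, gb, method = "exhaustive")
  r2 <- permutation_cluster_test(-ga, -gb, method = "exhaustive")
  m1 <- vapply(r1$clusters, `[[`, numeric(1), "mass")
  m2 <- vapply(r2$clusters, `[[`, numeric(1), "mass")
  expect_equal(sort(m1), sort(-m2))
  p1 <- vapply(r1$clusters, `[[`, numeric(1), "monte_carlo_p")
  p2 <- vapply(r2$clusters, `[[`, numeric(1), "monte_carlo_p")
  expect_equal(p1[order(m1)], p2[order(-m2)])
})

test_that("the permutation distribution is invariant to subject relabelling", {
  set.seed(9)
  ga <- array(rnorm(4 * 3 * 6), c(4, 3, 6))
  gb <- array(rnorm(4 * 3 * 6), c(4, 3, 6)) + 1
  r1 <- permutation_cluster_test(ga, gb, method = "exhaustive")
  perm <- c(3, 1, 4, 2)
  r2 <- permutation_cluster_test(ga[perm, , ], gb[perm, , ],
                                 method = "exhaustive")
  expect_equal(sort(r1$perm_max_pos), sort(r2$perm_max_pos))
  expect_equal(sort(r1$perm_max_neg), sort(r2$perm_max_neg))
})

test_that("paired sign-flip test is exhaustive for small n and exact", {
  set.seed(10)
  a <- array(rnorm(6 * 2 * 5) + 1.2, c(6, 2, 5))
  b <- array(rnorm(6 * 2 * 5), c(6, 2, 5))
  r <- permutation_cluster_test(a, b, design = "paired")
  expect_equal(r$method, "exhaustive")
  expect_equal(r$n_perm, 2 ^ 6)
  expect_equal(r$tmap$df, 5L)
  ps <- vapply(r$clusters, `[[`, numeric(1), "monte_carlo_p")
  expect_true(all(ps >= 1 / 64))
})

test_that("interaction contrast cancels common session effects", {
  # identical sessions -> all-zero differences, no clusters
  set.seed(11)
  s1 <- array(rnorm(8 * 4 * 10), c(8, 4, 10))
  times <- seq(-0.4, 1.4, by = 0.2)
  groups <- rep(c("pd", "hc"), each = 4)
  r0 <- interaction_contrast(s1, s1, groups, times = times)
  expect_length(r0$clusters, 0)
  # a session effect shared by both groups also cancels exactly
  s2 <- s1; s2[, , 6:10] <- s2[, , 6:10] + 3
  r1 <- interaction_contrast(s1, s2, groups, times = times)
  r2 <- interaction_contrast(s1, s1, groups, times = times)
  expect_equal(r1$tmap$t, r2$tmap$t)
  # a group-specific session change survives
  s3 <- s2; s3[groups == "pd", 2:3, 6:9] <- s3[groups == "pd", 2:3, 6:9] - 4
  r3 <- interaction_contrast(s1, s3, groups, times = times,
                             method = "exhaustive")
  expect_gt(length(r3$clusters), 0)
  expect_true(r3$clusters[[1]]$significant)
})

test_that("EMG contrasts pair the movement window against its baseline", {
  set.seed(12)
  times <- seq(-1.25, 2.5, by = 0.05)
  base <- matrix(rnorm(8 * length(times), mean = 8), 8)
  burst <- base
  burst[, times >= 0.1 & times < 0.4] <- burst[, times >= 0.1 & times < 0.4] + 5
  r <- emg_cluster_tests(burst, times = times,
                         contrast = "movement_vs_baseline")
  expect_equal(r$tmap$df, 7L)
  expect_gt(length(r$clusters), 0)
  cl <- r$clusters[[1]]
  expect_equal(cl$monte_carlo_p, min(vapply(r$clusters, `[[`, numeric(1),
                                            "monte_carlo_p")))
  expect_true(cl$time_range[1] >= 0.05 && cl$time_range[2] <= 0.45)
  # stationary noise: no strong clusters
  r0 <- emg_cluster_tests(base, times = times,
                          contrast = "movement_vs_baseline")
  expect_false(any(vapply(r0$clusters, `[[`, logical(1), "significant")))
  expect_error(emg_cluster_tests(base, times = times,
                                 move_window = c(0, 0.6)), "equal")
})
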