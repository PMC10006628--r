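test_that("k-means finds point masses and the brute-force optimal 2-partition", {
  m <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  km <- kmeans_fit(m, 2, seed = 1)
  expect_equal(km$wcss, 0)
  expect_equal(sort(unique(km$labels)), 1:2)
  expect_true(all(km$labels[1:3] == km$labels[1]))
  expect_error(kmeans_fit(m, 1), "k must be")
  expect_error(kmeans_fit(m, 10), "exceeds")

  # 6 points in 1D: exhaustive search over all 2-partitions for minimal WCSS
  x <- matrix(c(0, 0.3, 1.1, 4.2, 5.0, 5.1), ncol = 1)
  km6 <- kmeans_fit(x, 2, seed = 3)
  wcss_of <- function(assign) {
    sum(sapply(1:2, function(g) {
      pts <- x[assign == g, , drop = FALSE]
      if (!nrow(pts)) return(Inf)
      sum(sweep(pts, 2, colMeans(pts))^2)
    }))
  }
  all_assign <- expand.grid(rep(list(1:2), 6))
  best <- min(apply(all_assign, 1, function(a) {
    if (length(unique(a)) < 2) Inf else wcss_of(a)
  }))
  expect_equal(km6$wcss, best)
})

test_that("average silhouette matches hand-enumerated distances and its bounds", {
  # 4 points, 2 tight pairs on a line at 0, 1 and 10, 11
  m <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(1, 1, 2, 2)
  # point 1: a = 1, b = mean(10, 11) = 10.5 -> s = 9.5/10.5; symmetric others
  s_manual <- mean(c((10.5 - 1) / 10.5, (9.5 - 1) / 9.5,
                     (9.5 - 1) / 9.5, (10.5 - 1) / 10.5))
  expect_equal(average_silhouette(m, lab), s_manual)
  # far-separated tight clouds approach 1
  set.seed(5)
  clouds <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
                  matrix(rnorm(40, 50, 0.05), 20, 2))
  expect_gt(average_silhouette(clouds, rep(1:2, each = 20)), 0.9)
  # bounded and permutation invariant
  set.seed(6)
  mm <- matrix(rnorm(60), 30, 2)
  ll <- sample(1:3, 30, replace = TRUE)
  s <- average_silhouette(mm, ll)
  expect_gte(s, -1)
  expect_lte(s, 1)
  perm <- sample(30)
  expect_equal(average_silhouette(mm[perm, ], ll[perm]), s)
})

test_that("average silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(7)
  m <- matrix(rnorm(80), 40, 2)
  lab <- kmeans_fit(m, 3, seed = 2)$labels
  mine <- average_silhouette(m, lab)
  ref <- mean(cluster::silhouette(lab, dist(m))[, "sil_width"])
  expect_equal(mine, ref)
})

test_that("silhouette-guided selection finds the planted number of groups", {
  tg <- make_two_group_matrix(n = 250, p = 50, frac2 = 0.38, delta = 1.5,
                              seed = 11)
  model <- select_k(tg$X, seed = 4)
  expect_identical(model$k, 2L)
  expect_equal(which.max(model$silhouette_by_k), c(`2` = 1L))
  # deterministic under the seed
  model2 <- select_k(tg$X, seed = 4)
  expect_identical(model$labels, model2$labels)
  expect_equal(model$silhouette_by_k, model2$silhouette_by_k)

  # three well-separated blobs -> k = 3
  set.seed(12)
  blobs <- rbind(matrix(rnorm(100, 0), 50, 2),
                 matrix(rnorm(100, 10), 50, 2),
                 matrix(rnorm(100, c(0, 20)), 50, 2))
  expect_identical(select_k(blobs, seed = 5)$k, 3L)
})

test_that("planted groups are recovered almost perfectly at delta = 1.5", {
  tg <- make_two_group_matrix(n = 1000, p = 50, delta = 1.5, seed = 21)
  model <- select_k(tg$X, seed = 6)
  expect_gt(ari(model$labels, tg$group), 0.9)
})

test_that("nearest-centroid assignment is exact, shift-invariant and tie-stable", {
  cen <- rbind(c(0, 0), c(4, 0))
  expect_identical(assign_groups(cen, cen), c(1L, 2L))
  set.seed(13)
  pts <- matrix(rnorm(40, 1), 20, 2)
  lab <- assign_groups(pts, cen)
  shift <- matrix(3.7, 20, 2)
  expect_identical(assign_groups(pts + shift,
                                 cen + 3.7), lab)
  # exactly equidistant point -> lowest group index
  expect_identical(assign_groups(matrix(c(2, 0), 1), cen), 1L)
  expect_error(assign_groups(matrix(0, 1, 3), cen), "mismatch")
  # assigning the derivation matrix to its own centroids reproduces labels
  tg <- make_two_group_matrix(n = 200, seed = 14)
  km <- kmeans_fit(tg$X, 2, seed = 7)
  expect_identical(assign_groups(tg$X, km$centroids), km$labels)
})

test_that("group comparisons use Welch for quantitative and chi-square for categorical", {
  # identical groups -> t = 0, p = 1
  d <- data.frame(v = rep(c(1, 2, 3), 4))
  lab <- rep(1:2, each = 6)
  res <- compare_groups(data.frame(v = rep(c(1, 2, 3, 4, 5, 9), 2)), lab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # Welch example against a permutation oracle
  set.seed(15)
  x1 <- rnorm(10, 0, 1)
  x2 <- rnorm(10, 1, 1)
  d2 <- data.frame(v = c(x1, x2) )
  p_welch <- compare_groups(d2, rep(1:2, each = 10))$p
  obs <- abs(mean(x1) - mean(x2))
  perm <- replicate(4000, {
    s <- sample(20, 10)
    abs(mean(d2$v[s]) - mean(d2$v[-s]))
  })
  p_perm <- mean(perm >= obs)
  expect_equal(p_welch, p_perm, tolerance = 0.05)

  # 2x2 chi-square (20,10 / 10,20) against the closed-form statistic
  g <- rep(1:2, each = 30)
  v <- c(rep(0, 20), rep(1, 10), rep(0, 10), rep(1, 20))
  res2 <- compare_groups(data.frame(v = v), g)
  expect_identical(res2$test, "chi2")
  expect_equal(res2$statistic, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30))
  expect_error(compare_groups(data.frame(v = 1:4), rep(1, 4)), "2 groups")
})

test_that("group relabelling puts the higher-incidence cluster second", {
  out <- data.frame(time = rep(1, 40),
                    cause = c(rep(1L, 15), rep(0L, 5), rep(1L, 2),
                              rep(0L, 18)))
  model <- list(k = 2L, labels = rep(1:2, each = 20),
                centroids = rbind(c(1, 1), c(2, 2)))
  flipped <- order_groups_by_risk(model, out)
  expect_equal(mean(out$cause[flipped$labels == 2] == 1), 15 / 20)
  expect_equal(flipped$centroids[2, ], c(1, 1))
})

test_that("adding an independent noise covariate barely moves the group coefficient", {
  cfg <- small_cfg(n_patients = 2000, beta1 = log(2), p_asym = 0.25,
                   seed = 91L)
  coh <- simulate_cohort(cfg)
  f0 <- group_risk_model(coh$truth$group, coh$outcomes)
  set.seed(92)
  noise <- data.frame(noise = rnorm(2000))
  f1 <- group_risk_model(coh$truth$group, coh$outcomes, adjust = noise)
  expect_lt(abs(f0$coef[["group2"]] - f1$coef[["group2"]]), 0.05)
})

test_that("dropping proteins: no-op and noise-protein stability", {
  tg <- make_two_group_matrix(n = 300, p = 50, seed = 31)
  base <- select_k(tg$X, seed = 8)
  # dropping nothing cannot change labels
  res0 <- sensitivity_drop(tg$X, character(0), base, seed = 8)
  expect_equal(res0$n_changed_deriv, 0)
  # drop one protein: group structure lives in all 50 equally, so the
  # partition is essentially unchanged
  res1 <- sensitivity_drop(tg$X, colnames(tg$X)[7], base, seed = 8,
                           matrix_valid = tg$X)
  expect_lte(res1$n_changed_deriv / nrow(tg$X), 0.05)
  expect_lte(res1$n_changed_valid / nrow(tg$X), 0.05)
  # the k = 2 label mapping is the overlap-maximizing bijection
  map <- somastrat:::match_labels(3L - base$labels, base$labels, 2L)
  expect_identical(map, c(2L, 1L))
})
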