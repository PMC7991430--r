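test_that("voronoi_partition matches brute-force argmin and tie-break rule", {
  set.seed(21)
  X <- matrix(runif(400), 200, 2)
  C <- matrix(runif(20), 10, 2)
  omega <- c(1.3, 0.6)
  expect_identical(voronoi_partition(X, C, omega),
                   oracle_nearest(X, C, omega))
  # identity: rows equal to centroids map to their own index
  et <- event_table(C, c("a", "b"))
  expect_identical(voronoi_partition(et, C, c(1, 1)), 1:10)
  # equidistant point goes to the lowest centroid index
  Ct <- rbind(c(0, 0), c(0, 0), c(2, 0), c(0, 0), c(2, 0))
  expect_identical(voronoi_partition(matrix(c(1, 0), 1), Ct, c(1, 1)), 1L)
})

test_that("cluster MSE equals hand values and ties to the loss exactly", {
  et <- event_table(matrix(c(0, 2, 0, 0), 2, 2), c("X", "Y"))
  q <- list(centroids = matrix(c(1, 0), 1, 2), labels = c(1L, 1L),
            omega = c(1, 1))
  dg <- cluster_mse(et, q)
  expect_equal(dg$per_cluster_mse, 1)  # (1 + 1)/2
  expect_identical(dg$total_variance, weighted_loss(et, q, c(1, 1)))

  et2 <- make_spiral(500, seed = 3)
  fit <- weighted_kmeans(et2, k = 40, seed = 0)
  dg2 <- cluster_mse(et2, fit)
  expect_identical(dg2$total_variance, weighted_loss(et2, fit, fit$omega))
  expect_identical(dg2$total_variance, fit$loss)
  expect_equal(dg2$average_mse, mean(dg2$per_cluster_mse))
  expect_equal(sum(dg2$weights * dg2$per_cluster_mse), dg2$total_variance)
  # k = N gives all-zero MSE
  sm <- event_table(matrix(rnorm(10), 5, 2))
  f0 <- weighted_kmeans(sm, k = 5, seed = 0, restarts = 3)
  expect_identical(cluster_mse(sm, f0)$per_cluster_mse, rep(0, 5))
})

test_that("per-cluster fidelity improves with k on spiral data", {
  et <- make_spiral(2000, seed = 0)
  f_small <- weighted_kmeans(et, k = 20, seed = 0)
  f_large <- weighted_kmeans(et, k = 100, seed = 0)
  mse_small <- cluster_mse(et, f_small)$per_cluster_mse
  mse_large <- cluster_mse(et, f_large)$per_cluster_mse
  expect_lt(max(mse_large), max(mse_small))
  expect_lt(mean(mse_large), mean(mse_small))
})

test_that("elbow curve decreases in k and bottoms out at zero for k = N", {
  et <- make_spiral(120, seed = 5)
  ec <- elbow_curve(et, c(1, 1), k_list = c(2, 10, 40, 120), seed = 0,
                    restarts = 5)
  expect_identical(ec$k, c(2, 10, 40, 120))
  expect_true(all(diff(ec$total_variance) < 0))
  expect_true(all(diff(ec$average_mse) < 0))
  expect_equal(ec$total_variance[4], 0)
  expect_error(elbow_curve(et, c(1, 1), integer(0)), "non-empty")
  expect_error(elbow_curve(et, c(1, 1), c(10, 2)), "ascending")
})

test_that("the elbow lands at the true blob count in most seeds", {
  centers <- rbind(c(0, 0), c(10, 0), c(5, 9))
  hits <- 0L
  for (s in 1:20) {
    et <- make_blobs(80, centers, sd = 0.6, seed = s)
    ec <- elbow_curve(et, c(1, 1), k_list = 1:6, seed = s, restarts = 3)
    drops <- -diff(ec$total_variance) / ec$total_variance[-nrow(ec)]
    if (which.max(drops) + 1L == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 11L)
})

test_that("weighted density conserves total weight and places point masses", {
  et <- make_bimodal(1000, seed = 8)
  fit <- weighted_kmeans(et, k = 30, seed = 0)
  for (bins in c(2L, 7L, 32L)) {
    g <- weighted_density(fit, "X", "Y", bins = bins)
    expect_identical(dim(g), c(bins, bins))
    expect_equal(sum(g), 1000)
    expect_true(all(g >= 0))
  }
  # two clusters with weights 100/300 land in their own cells
  q <- structure(list(centroids = rbind(c(0, 0), c(10, 10)),
                      weights = c(100L, 300L), k = 2L,
                      channel_names = c("X", "Y")), class = "wkmeans")
  g <- weighted_density(q, "X", "Y", bins = 4)
  expect_identical(sort(g[g > 0]), c(100, 300))
  expect_identical(g[1, 1], 100)
  expect_identical(g[4, 4], 300)
  # single cluster: one cell holds everything
  q1 <- structure(list(centroids = rbind(c(5, 5)), weights = 500L, k = 1L,
                       channel_names = c("X", "Y")), class = "wkmeans")
  g1 <- weighted_density(q1, "X", "Y", bins = 8)
  expect_identical(sum(g1 > 0), 1L)
  expect_identical(sum(g1), 500)
  expect_error(weighted_density(fit, "X", "nope"), "unknown channel")
})

test_that("summary statistics match hand arithmetic and correlation conventions", {
  vals <- cbind(A = c(1, 2, 3, 4, 10), B = c(2, 4, 6, 8, 20))
  et <- event_table(vals)
  ss <- summary_stats(et)
  expect_equal(ss$stats$mean, c(4, 8))
  expect_equal(ss$stats$median, c(3, 6))
  expect_equal(ss$stats$q1, c(2, 4))
  expect_equal(ss$stats$q3, c(4, 8))
  expect_equal(ss$stats$min, c(1, 2))
  expect_equal(ss$stats$max, c(10, 20))
  expect_equal(ss$stats$sd, c(sd(vals[, 1]), sd(vals[, 2])))
  # perfectly linear channels: correlation exactly 1, symmetric, unit diagonal
  expect_equal(ss$correlation, matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))))
  # constant channel: sd 0 and correlations reported as 0
  et2 <- event_table(cbind(A = c(1, 2, 3), C = c(5, 5, 5)))
  ss2 <- summary_stats(et2)
  expect_identical(ss2$stats$sd[2], 0)
  expect_identical(ss2$correlation["A", "C"], 0)
  expect_identical(diag(ss2$correlation), c(A = 1, C = 1))
})
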