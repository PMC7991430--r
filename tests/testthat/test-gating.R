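# a small hand-built quantization for direct gating checks
toy_quant <- function(centroids, weights, labels = NULL,
                      chans = c("X", "Y")) {
  k <- nrow(centroids)
  if (is.null(labels)) labels <- rep(seq_len(k), weights)
  colnames(centroids) <- chans
  structure(list(centroids = centroids, weights = as.integer(weights),
                 labels = as.integer(labels), k = k, n = sum(weights),
                 omega = rep(1, ncol(centroids)),
                 channels_used = chans, channel_names = chans,
                 loss = 0, seed = 0L, restarts = 1L, converged = TRUE),
            class = "wkmeans")
}

test_that("quadrant gate computes weighted percents in the fixed layout", {
  q <- toy_quant(rbind(c(-1, 1), c(1, 1), c(1, -1), c(-1, -1)),
                 weights = c(10, 20, 30, 40))
  g <- quadrant_gate(q, "X", "Y", 0, 0)
  expect_identical(g$quadrant, c("Q1", "Q2", "Q3", "Q4"))
  expect_identical(g$weight, c(10L, 20L, 30L, 40L))
  expect_equal(g$percent, c(10, 20, 30, 40))
  expect_identical(sum(g$weight), 100L)
  expect_equal(sum(g$percent), 100)
  # boundary: coordinate equal to threshold counts positive (upper/right)
  qb <- toy_quant(rbind(c(0, 0)), weights = 7L)
  gb <- quadrant_gate(qb, "X", "Y", 0, 0)
  expect_identical(gb$weight[gb$quadrant == "Q2"], 7L)
  # everything below both thresholds lands in Q4
  qa <- toy_quant(rbind(c(-2, -3), c(-1, -1)), weights = c(3L, 4L))
  ga <- quadrant_gate(qa, "X", "Y", 0, 0)
  expect_equal(ga$percent[ga$quadrant == "Q4"], 100)
  expect_error(quadrant_gate(q, "X", "X", 0, 0), "must differ")
})

test_that("quadrant percents sum to 100 across random weightings", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(3:40, 1)
    q <- toy_quant(matrix(rnorm(2 * k), k, 2),
                   weights = sample.int(500, k, replace = TRUE))
    g <- quadrant_gate(q, "X", "Y", rnorm(1), rnorm(1))
    expect_identical(sum(g$weight), sum(q$weights))
    expect_equal(sum(g$percent), 100)
  }
})

test_that("polygon gate membership matches an independent ray caster", {
  set.seed(17)
  q <- toy_quant(matrix(runif(200, -0.2, 1.2), 100, 2),
                 weights = sample.int(50, 100, replace = TRUE))
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  res <- polygon_gate(q, "X", "Y", square)
  want <- which(oracle_in_polygon(q$centroids[, 1], q$centroids[, 2], square))
  expect_identical(res$selected_clusters, want)
  expect_identical(res$selected_weight, sum(q$weights[want]))
  expect_equal(res$percent_of_parent,
               100 * res$selected_weight / sum(q$weights))
  # non-convex polygon too
  vee <- rbind(c(0, 0), c(0.5, 0.8), c(1, 0), c(1, 1), c(0, 1))
  res2 <- polygon_gate(q, "X", "Y", vee)
  want2 <- which(oracle_in_polygon(q$centroids[, 1], q$centroids[, 2], vee))
  expect_identical(res2$selected_clusters, want2)
})

test_that("polygon gate handles enclosing, empty and degenerate cases", {
  q <- toy_quant(matrix(runif(40), 20, 2), weights = rep(5L, 20))
  big <- rbind(c(-10, -10), c(10, -10), c(10, 10), c(-10, 10))
  expect_equal(polygon_gate(q, "X", "Y", big)$percent_of_parent, 100)
  far <- big + 100
  res <- polygon_gate(q, "X", "Y", far)
  expect_identical(length(res$selected_clusters), 0L)
  expect_equal(res$percent_of_parent, 0)
  expect_error(gate_polygon("X", "Y", rbind(c(0, 0), c(1, 1))), ">= 3")
  expect_error(gate_polygon("X", "Y", rbind(c(0, 0), c(1, 1), c(2, 2))),
               "collinear")
  # boundary point counts inside
  tri <- rbind(c(0, 0), c(2, 0), c(0, 2))
  qb <- toy_quant(rbind(c(1, 0)), weights = 1L)
  expect_identical(polygon_gate(qb, "X", "Y", tri)$selected_weight, 1L)
})

test_that("deep-gating stack composes, commutes and resets", {
  set.seed(12)
  q <- toy_quant(matrix(runif(120), 60, 2),
                 weights = sample.int(100, 60, replace = TRUE))
  rect <- function(x0, x1, y0, y1)
    gate_polygon("X", "Y", rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)))
  A <- rect(0.1, 0.7, 0.0, 1.0)
  B <- rect(0.3, 1.0, 0.2, 0.9)
  AB <- rect(0.3, 0.7, 0.2, 0.9)   # A intersect B

  s <- gate_stack(q)
  expect_identical(current_clusters(s), 1:60)
  expect_identical(population_weight(s), sum(q$weights))

  s2 <- push_gate(push_gate(s, A), B)
  one <- polygon_gate(q, "X", "Y", AB$params$vertices)
  expect_identical(sort(current_clusters(s2)), sort(one$selected_clusters))
  expect_identical(population_weight(s2), one$selected_weight)

  # order independence for commuting gates
  s3 <- push_gate(push_gate(s, B), A)
  expect_identical(sort(current_clusters(s2)), sort(current_clusters(s3)))

  # identity gate leaves the population unchanged
  all_of_it <- rect(-1, 2, -1, 2)
  expect_identical(current_clusters(push_gate(s, all_of_it)), 1:60)

  # reset restores the full dataset
  expect_identical(population_weight(reset_gates(s2)), sum(q$weights))
  expect_identical(length(reset_gates(s2)$gates), 0L)

  expect_error(push_gate(s, gate_quadrant("X", "nope", 0, 0)),
               "unknown channel")
})

test_that("percent_of_parent is invariant under cluster relabeling", {
  set.seed(5)
  C <- matrix(runif(40), 20, 2)
  w <- sample.int(30, 20, replace = TRUE)
  perm <- sample(20)
  q1 <- toy_quant(C, w)
  q2 <- toy_quant(C[perm, ], w[perm])
  tri <- rbind(c(0.2, 0.1), c(0.9, 0.4), c(0.4, 0.95))
  expect_equal(polygon_gate(q1, "X", "Y", tri)$percent_of_parent,
               polygon_gate(q2, "X", "Y", tri)$percent_of_parent)
})

test_that("export writes exactly the surviving raw events", {
  et <- make_bimodal(800, sep = 8, seed = 4)
  fit <- weighted_kmeans(et, k = 16, seed = 0)
  s <- gate_stack(fit)
  f <- withr::local_tempfile(fileext = ".csv")

  # empty stack: all events
  export_gated_events(et, fit, s, f)
  expect_identical(nrow(read_csv_events(f)$values), 800L)

  # right-hand mode only
  g <- gate_quadrant("X", "Y", 0, -100, region = "Q2")
  g$params$ty <- min(et$values[, 2]) - 1
  s2 <- push_gate(s, gate_quadrant("X", "Y", 0, min(et$values[, 2]) - 1, "Q2"))
  export_gated_events(et, fit, s2, f)
  got <- read_csv_events(f)$values
  keep <- fit$labels %in% current_clusters(s2)
  expect_identical(nrow(got), sum(keep))
  expect_identical(nrow(got), population_weight(s2))
  expect_equal(got, et$values[keep, , drop = FALSE], ignore_attr = TRUE)
})

test_that("weighted estimator beats unweighted centroid counting at 75:25", {
  # the reason cluster weights exist: centroid counts are not proportional
  # to population mass, so an unweighted estimate is biased at unequal mixes
  sp <- transform_spec("logicle")
  tx <- flow_transform(sqrt(150 * 15000), sp)
  wins <- 0L
  for (s in 1:10) {
    mx <- make_mixture(mixture_spec(4000, 0.75, seed = s))
    tt <- transform_channels(mx$table, sp, c("FSC-H", "GFP-H"))
    fit <- weighted_kmeans(tt, channels = c("FSC-H", "GFP-H"), k = 80, seed = 0)
    truth <- 100 * mean(mx$truth == "B")
    gi <- match("GFP-H", fit$channel_names)
    pos <- fit$centroids[, gi] >= tx
    weighted_est <- 100 * sum(fit$weights[pos]) / sum(fit$weights)
    unweighted_est <- 100 * mean(pos)
    if (abs(weighted_est - truth) < abs(unweighted_est - truth)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
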