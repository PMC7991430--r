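# Voronoi-partition fidelity diagnostics for a quantization: per-cluster
# mean-squared error (within-cluster variance with the centroid as mean),
# elbow curves over k, weighted density grids, and summary statistics.

#' Nearest-centroid (Voronoi) partition
#'
#' Assigns every event to the centroid with the smallest Omega-weighted
#' squared distance; ties break toward the lowest centroid index. This
#' realizes the Voronoi cell R_i = \{x : d(x, mu_i) <= d(x, mu_j) for all
#' j\} of each centroid.
#'
#' @param table an [event_table] or numeric matrix of events.
#' @param centroids k x d centroid matrix.
#' @param omega per-channel weight vector.
#' @return integer labels of length N, in 1..k.
#' @export
voronoi_partition <- function(table, centroids, omega) {
  X <- if (inherits(table, "event_table")) table$values else as.matrix(table)
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != ncol(X))
    stop("validation error: centroid dimension mismatch")
  omega <- check_omega(omega, ncol(X))
  sw <- sqrt(omega)
  Xs <- sweep(X, 2L, sw, "*")
  Cs <- sweep(centroids, 2L, sw, "*")
  max.col(-dist2_scaled(Xs, Cs), ties.method = "first")
}

#' Per-cluster mean-squared error of a quantization
#'
#' For each cluster, the mean Omega-weighted squared deviation of its
#' member events from the centroid -- the within-cluster variance of the
#' Voronoi cell, with the centroid as the mean. `total_variance` is the
#' unnormalized sum over all clusters and ties exactly to
#' [weighted_loss()]; `average_mse` is the mean of the per-cluster values.
#'
#' @param table the originating [event_table].
#' @param q a `wkmeans` fit (or list with `centroids` and `labels`).
#' @param omega per-channel weight vector; defaults to the fit's.
#' @return An object of class `voronoi_mse`: list with `per_cluster_mse`,
#'   `total_variance`, `average_mse`, `labels`, `weights`, `k`.
#' @export
cluster_mse <- function(table, q, omega = q$omega) {
  stopifnot(inherits(table, "event_table"))
  X <- table$values
  omega <- check_omega(omega, ncol(X))
  C <- as.matrix(q$centroids)
  k <- nrow(C)
  labels <- as.integer(q$labels)
  if (any(labels < 1L) || any(labels > k))
    stop("validation error: label out of range")
  s <- cluster_sq_sums(X, C, labels, omega, k)
  counts <- tabulate(labels, k)
  mse <- ifelse(counts > 0L, s / counts, 0)
  structure(list(per_cluster_mse = mse,
                 total_variance = sum(s),
                 average_mse = mean(mse),
                 labels = labels,
                 weights = counts,
                 k = k),
            class = "voronoi_mse")
}

#' @export
print.voronoi_mse <- function(x, ...) {
  cat(sprintf("Voronoi diagnostics: k=%d, total variance %.6g, average MSE %.6g\n",
              x$k, x$total_variance, x$average_mse))
  cat(sprintf("  per-cluster MSE: min %.4g, median %.4g, max %.4g\n",
              min(x$per_cluster_mse), stats::median(x$per_cluster_mse),
              max(x$per_cluster_mse)))
  invisible(x)
}

#' Elbow curve over candidate cluster counts
#'
#' Runs the quantizer independently for each k and reports the total
#' within-cluster variance (the weighted loss) and the average per-cluster
#' MSE, for locating the elbow at which further clusters buy little
#' variance reduction. Rows are computed independently with matched seeds.
#'
#' @param table an [event_table].
#' @param omega per-channel weight vector.
#' @param k_list ascending candidate cluster counts, all `<= N`.
#' @param seed RNG seed used for every k.
#' @param restarts restarts per k.
#' @param ... further arguments to [weighted_kmeans()].
#' @return data.frame with columns `k`, `total_variance`, `average_mse`.
#' @export
elbow_curve <- function(table, omega, k_list, seed = 0L, restarts = 1L, ...) {
  stopifnot(inherits(table, "event_table"))
  if (length(k_list) == 0L) stop("k_list must be non-empty")
  if (is.unsorted(k_list, strictly = FALSE))
    stop("k_list must be sorted ascending")
  rows <- lapply(k_list, function(k) {
    fit <- weighted_kmeans(table, omega = omega, k = k, seed = seed,
                           restarts = restarts, ...)
    dg <- cluster_mse(table, fit, omega)
    data.frame(k = k, total_variance = dg$total_variance,
               average_mse = dg$average_mse)
  })
  do.call(rbind, rows)
}

#' Weighted density grid of quantized data
#'
#' Bins the centroids of two channels on a regular bins x bins grid, each
#' centroid contributing its full cluster weight, so the grid total equals
#' the number of events in the current population. This is the quantized
#' analogue of an event-level 2-D density plot.
#'
#' @param q a `wkmeans` fit.
#' @param ch_x,ch_y channel names.
#' @param bins grid resolution (>= 2).
#' @param clusters optional cluster index subset (current population);
#'   defaults to all clusters.
#' @param xlim,ylim optional grid limits; default to the centroid range.
#' @return bins x bins numeric matrix (x = rows, y = columns), with
#'   `breaks_x`/`breaks_y` attributes.
#' @export
weighted_density <- function(q, ch_x, ch_y, bins = 32L, clusters = NULL,
                             xlim = NULL, ylim = NULL) {
  if (bins < 2L) stop("bins must be >= 2")
  i <- match(c(ch_x, ch_y), q$channel_names)
  if (anyNA(i)) stop("unknown channel: ",
                     paste(c(ch_x, ch_y)[is.na(i)], collapse = ", "))
  if (is.null(clusters)) clusters <- seq_len(q$k)
  cx <- q$centroids[clusters, i[1L]]
  cy <- q$centroids[clusters, i[2L]]
  w <- q$weights[clusters]
  if (is.null(xlim)) xlim <- range(cx)
  if (is.null(ylim)) ylim <- range(cy)
  bx <- seq(xlim[1L], xlim[2L], length.out = bins + 1L)
  by <- seq(ylim[1L], ylim[2L], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(cx, bx, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(cy, by, rightmost.closed = TRUE), 1L), bins)
  g <- matrix(0, bins, bins)
  for (j in seq_along(w)) g[ix[j], iy[j]] <- g[ix[j], iy[j]] + w[j]
  attr(g, "breaks_x") <- bx
  attr(g, "breaks_y") <- by
  g
}

#' Per-channel summary statistics and correlation table
#'
#' Computes mean, sd, median, quartiles (linear interpolation), min and max
#' for each requested channel, plus the product-moment correlation matrix.
#' Correlations involving a zero-variance channel are reported as 0 by
#' convention (so tables always render); the diagonal is 1.
#'
#' @param table an [event_table].
#' @param channels channel names; `NULL` for all.
#' @return list with `stats` (data.frame, one row per channel) and
#'   `correlation` (symmetric matrix with unit diagonal).
#' @export
summary_stats <- function(table, channels = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (is.null(channels)) channels <- table$channel_names
  idx <- channel_index(table, channels)
  X <- table$values[, idx, drop = FALSE]
  st <- data.frame(
    channel = channels,
    mean = colMeans(X),
    sd = apply(X, 2L, stats::sd),
    median = apply(X, 2L, stats::median),
    q1 = apply(X, 2L, stats::quantile, probs = 0.25, names = FALSE),
    q3 = apply(X, 2L, stats::quantile, probs = 0.75, names = FALSE),
    min = apply(X, 2L, min),
    max = apply(X, 2L, max),
    row.names = NULL)
  cm <- suppressWarnings(stats::cor(X))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  dimnames(cm) <- list(channels, channels)
  list(stats = st, correlation = cm)
}
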