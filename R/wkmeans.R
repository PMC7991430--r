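# Dimension-weighted k-means quantization.
#
# The quantizer minimizes, over a partition S = {S_1..S_k} with centroids
# mu_i, the loss  sum_i sum_{x in S_i} (x - mu_i)' Omega (x - mu_i)  with
# Omega a diagonal matrix of per-channel weights. Assignment uses the
# Omega-weighted distance; the centroid update averages member events over
# ALL channels, so zero-weight channels are carried through the centroids
# and remain available for gating and display.

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

check_omega <- function(omega, d) {
  omega <- as.numeric(omega)
  if (length(omega) != d)
    stop("validation error: channel weights must have length ", d)
  if (any(!is.finite(omega)) || any(omega < 0))
    stop("channel weights must be finite and non-negative")
  if (all(omega == 0))
    stop("channel weights must have at least one positive entry")
  omega
}

#' Build per-channel weights from a channel selection
#'
#' Returns the diagonal of the dimension-weight matrix: 1 for each selected
#' channel, 0 otherwise (the default weighting convention).
#'
#' @param table an [event_table].
#' @param channels names of the selected channels; `NULL` selects all.
#' @return numeric vector of length d.
#' @export
channel_weights <- function(table, channels = NULL) {
  stopifnot(inherits(table, "event_table"))
  d <- ncol(table$values)
  if (is.null(channels)) return(rep(1, d))
  if (length(channels) == 0L) stop("channel selection must be non-empty")
  w <- numeric(d)
  w[channel_index(table, channels)] <- 1
  w
}

# squared weighted distances between pre-scaled rows; clamps the tiny
# negatives produced by the expansion trick
dist2_scaled <- function(Xs, Cs) {
  D <- matrix(rowSums(Xs^2), nrow(Xs), nrow(Cs)) +
    matrix(rowSums(Cs^2), nrow(Xs), nrow(Cs), byrow = TRUE) -
    2 * tcrossprod(Xs, Cs)
  D[D < 0] <- 0
  D
}

# per-cluster weighted squared-deviation sums; the single code path behind
# weighted_loss and cluster_mse so totals agree bit-for-bit
cluster_sq_sums <- function(X, centroids, labels, omega, k) {
  r <- (X - centroids[labels, , drop = FALSE])^2
  per_event <- as.vector(r %*% omega)
  s <- numeric(k)
  agg <- rowsum(per_event, labels)
  s[as.integer(rownames(agg))] <- agg[, 1L]
  s
}

#' Evaluate the dimension-weighted k-means loss
#'
#' Computes `sum_i sum_{x in S_i} (x - mu_i)' Omega (x - mu_i)` for a given
#' assignment and centroid set.
#'
#' @param table an [event_table].
#' @param q a [weighted_kmeans] fit (`wkmeans` object), or any list with
#'   `centroids` (k x d) and `labels` (length N, in 1..k).
#' @param omega per-channel weight vector (diagonal of Omega).
#' @return non-negative scalar loss.
#' @export
weighted_loss <- function(table, q, omega) {
  stopifnot(inherits(table, "event_table"))
  X <- table$values
  omega <- check_omega(omega, ncol(X))
  C <- as.matrix(q$centroids)
  if (ncol(C) != ncol(X)) stop("validation error: centroid dimension mismatch")
  labels <- as.integer(q$labels)
  if (length(labels) != nrow(X) || any(labels < 1L) || any(labels > nrow(C)))
    stop("validation error: labels out of range")
  sum(cluster_sq_sums(X, C, labels, omega, nrow(C)))
}

#' k-means++ initialization under a weighted metric
#'
#' Draws the first centroid uniformly from the events, then each subsequent
#' centroid with probability proportional to the Omega-weighted squared
#' distance to the nearest centroid chosen so far. Deterministic given
#' `seed`.
#'
#' @param table an [event_table].
#' @param omega per-channel weight vector.
#' @param k number of centroids, `1 <= k <= N`.
#' @param seed RNG seed.
#' @return k x d matrix of centroids (rows of the event table).
#' @export
kmeanspp_init <- function(table, omega, k, seed = 0L) {
  stopifnot(inherits(table, "event_table"))
  X <- table$values
  omega <- check_omega(omega, ncol(X))
  n <- nrow(X)
  if (k < 1L || k > n) stop("parameter error: k must be in [1, N]")
  Xs <- sweep(X, 2L, sqrt(omega), "*")
  with_seed(seed, {
    idx <- integer(k)
    idx[1L] <- sample.int(n, 1L)
    if (k > 1L) {
      d2 <- rowSums(sweep(Xs, 2L, Xs[idx[1L], ], "-")^2)
      for (i in 2L:k) {
        idx[i] <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2)
                  else sample.int(n, 1L)
        d2 <- pmin(d2, rowSums(sweep(Xs, 2L, Xs[idx[i], ], "-")^2))
      }
    }
    X[idx, , drop = FALSE]
  })
}

# One Lloyd run from a fixed initialization. Stops at label stability
# (exact fixed point: centroids are the member means and every event sits
# in its nearest cell); once the relative loss change drops below tol it
# allows a bounded number of polish iterations before giving up.
lloyd_run <- function(X, Xs, omega, centroids, tol, max_iter) {
  n <- nrow(X); k <- nrow(centroids)
  sw <- sqrt(omega)
  trace <- numeric(0)
  labels_prev <- NULL
  prev_loss <- Inf
  polish <- 0L
  converged <- FALSE
  it <- 0L
  while (it < max_iter + 50L) {
    it <- it + 1L
    Cs <- sweep(centroids, 2L, sw, "*")
    D <- dist2_scaled(Xs, Cs)
    labels <- max.col(-D, ties.method = "first")
    # empty clusters: reseed to the event farthest (weighted) from its
    # current centroid, so every cluster returns with weight >= 1
    empty <- setdiff(seq_len(k), unique(labels))
    if (length(empty)) {
      cur <- D[cbind(seq_len(n), labels)]
      for (e in empty) {
        far <- which.max(cur)
        centroids[e, ] <- X[far, ]
        labels[far] <- e
        cur[far] <- -Inf
      }
      Cs <- sweep(centroids, 2L, sw, "*")
      D <- dist2_scaled(Xs, Cs)
      labels <- max.col(-D, ties.method = "first")
      # a reseeded centroid can still lose its event to a duplicate at a
      # lower index; force assignment so every cluster keeps weight >= 1
      still <- setdiff(empty, unique(labels))
      taken <- logical(n)
      for (e in still) {
        d2e <- rowSums(sweep(Xs, 2L, Cs[e, ], "-")^2)
        d2e[taken] <- Inf
        nearest <- which.min(d2e)
        labels[nearest] <- e
        taken[nearest] <- TRUE
      }
    }
    loss <- sum(D[cbind(seq_len(n), labels)])
    trace <- c(trace, loss)
    if (identical(labels, labels_prev)) {
      converged <- TRUE
      break
    }
    labels_prev <- labels
    # centroid update: member means over all dimensions
    counts <- tabulate(labels, k)
    present <- sort(unique(labels))
    centroids[present, ] <- rowsum(X, labels) / counts[present]
    rel <- if (is.finite(prev_loss) && prev_loss > 0)
      abs(prev_loss - loss) / prev_loss else Inf
    if (rel < tol) {
      polish <- polish + 1L
      if (polish >= 50L || it >= max_iter) break
    } else if (it >= max_iter) break
    prev_loss <- loss
  }
  list(centroids = centroids, labels = labels, trace = trace,
       iterations = it, converged = converged)
}

#' Automatic cluster-count selection
#'
#' Interpolates the cluster count as `round(n / 200)`, clamped to the
#' automatic range of 250 to 5000 clusters, and never more than `n`.
#' Monotone non-decreasing in `n`.
#'
#' @param n number of events (>= 1).
#' @return integer cluster count.
#' @export
auto_k <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("parameter error: n must be a positive integer")
  as.integer(min(n, max(250, min(5000, round(n / 200)))))
}

#' Quantize an event table by dimension-weighted k-means
#'
#' Fits k weighted centroids to the events by Lloyd's algorithm under the
#' Omega-weighted squared-distance loss, with k-means++ initialization.
#' Assignment uses only channels with positive weight; the centroid update
#' averages member events over all channels, so unweighted channels are
#' carried through. Each cluster's integer weight is its member count; the
#' weights sum to N and every cluster returns non-empty. With multiple
#' restarts the fit with the lowest loss is returned.
#'
#' @param table an [event_table] (typically already display-transformed,
#'   see [transform_channels()]).
#' @param channels channel names to cluster on (sets their weight to 1 and
#'   all others to 0); `NULL` uses all channels. Ignored when `omega` is
#'   given.
#' @param omega explicit per-channel weight vector (diagonal of Omega).
#' @param k number of clusters, or `"auto"` for [auto_k()].
#' @param seed RNG seed (default 0); restart r uses `seed + r - 1`.
#' @param tol relative loss-change convergence tolerance.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param restarts number of k-means++ restarts; best loss wins.
#' @return An object of class `wkmeans` with components `centroids` (k x d),
#'   `weights` (integer member counts), `labels` (1..k per event), `loss`,
#'   `trace` (per-iteration loss), `k`, `seed`, `omega`, `channels_used`,
#'   `iterations`, `converged`, `n`, `channel_names`, `call`.
#' @examples
#' et <- make_bimodal(500, sep = 6, seed = 1)
#' fit <- weighted_kmeans(et, k = 10, seed = 0)
#' fit
#' @export
weighted_kmeans <- function(table, channels = NULL, omega = NULL,
                            k = "auto", seed = 0L, tol = 1e-6,
                            max_iter = 300L, restarts = 1L) {
  stopifnot(inherits(table, "event_table"))
  X <- table$values
  n <- nrow(X); d <- ncol(X)
  if (is.null(omega)) omega <- channel_weights(table, channels)
  omega <- check_omega(omega, d)
  if (identical(k, "auto")) k <- auto_k(n)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n) stop("parameter error: k must be in [1, N]")
  if (!is.numeric(tol) || tol <= 0) stop("parameter error: tol must be > 0")
  if (restarts < 1L) stop("parameter error: restarts must be >= 1")

  Xs <- sweep(X, 2L, sqrt(omega), "*")
  best <- NULL
  for (r in seq_len(restarts)) {
    rseed <- as.integer(seed) + r - 1L
    init <- kmeanspp_init(table, omega, k, seed = rseed)
    run <- lloyd_run(X, Xs, omega, init, tol, max_iter)
    run$loss <- sum(cluster_sq_sums(X, run$centroids, run$labels, omega, k))
    run$restart_seed <- rseed
    if (is.null(best) || run$loss < best$loss) best <- run
  }

  weights <- tabulate(best$labels, k)
  dimnames(best$centroids) <- list(NULL, table$channel_names)
  structure(
    list(centroids = best$centroids,
         weights = as.integer(weights),
         labels = best$labels,
         loss = best$loss,
         trace = best$trace,
         k = k,
         seed = as.integer(seed),
         omega = omega,
         channels_used = table$channel_names[omega > 0],
         iterations = best$iterations,
         converged = best$converged,
         restarts = as.integer(restarts),
         n = n,
         channel_names = table$channel_names,
         call = match.call()),
    class = "wkmeans")
}

#' @export
print.wkmeans <- function(x, ...) {
  cat(sprintf("Weighted k-means quantization: %d events -> %d centroids\n",
              x$n, x$k))
  cat(sprintf("  channels: %s\n", paste(x$channels_used, collapse = ", ")))
  cat(sprintf("  loss: %.6g  (%d iteration%s, %sconverged, seed %d)\n",
              x$loss, x$iterations, if (x$iterations == 1L) "" else "s",
              if (x$converged) "" else "not ", x$seed))
  cat(sprintf("  cluster weights: min %d, median %g, max %d (sum %d)\n",
              min(x$weights), stats::median(x$weights), max(x$weights),
              sum(x$weights)))
  invisible(x)
}

#' @export
coef.wkmeans <- function(object, ...) object$centroids

#' Assign new events to their nearest centroid
#'
#' @param object a `wkmeans` fit.
#' @param newdata an [event_table] or numeric matrix with the fit's
#'   channels; defaults to returning the training labels.
#' @param ... unused.
#' @return integer vector of cluster labels (1..k).
#' @export
predict.wkmeans <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$labels)
  X <- if (inherits(newdata, "event_table")) newdata$values else as.matrix(newdata)
  voronoi_partition(X, object$centroids, object$omega)
}

#' @export
fitted.wkmeans <- function(object, ...) {
  object$centroids[object$labels, , drop = FALSE]
}

#' Event-level quantization residuals
#'
#' @param object a `wkmeans` fit.
#' @param table the [event_table] the fit was computed from.
#' @param ... unused.
#' @return N x d matrix of deviations from the assigned centroid.
#' @export
residuals.wkmeans <- function(object, table, ...) {
  stopifnot(inherits(table, "event_table"), nrow(table$values) == object$n)
  table$values - fitted(object)
}

#' Summarize a quantization fit
#'
#' With the originating event table, computes the full Voronoi fidelity
#' diagnostics (see [cluster_mse()]); without it, reports cluster-weight
#' and loss summaries only.
#'
#' @param object a `wkmeans` fit.
#' @param table optional originating [event_table].
#' @param ... unused.
#' @return A `summary.wkmeans` list.
#' @export
summary.wkmeans <- function(object, table = NULL, ...) {
  out <- list(k = object$k, n = object$n, loss = object$loss,
              weights = object$weights, converged = object$converged,
              channels_used = object$channels_used)
  if (!is.null(table)) out$diagnostics <- cluster_mse(table, object, object$omega)
  structure(out, class = "summary.wkmeans")
}

#' @export
print.summary.wkmeans <- function(x, ...) {
  cat(sprintf("Quantization of %d events into %d clusters (loss %.6g)\n",
              x$n, x$k, x$loss))
  print(summary(x$weights))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("Per-cluster MSE: mean %.6g, max %.6g; total variance %.6g\n",
                x$diagnostics$average_mse, max(x$diagnostics$per_cluster_mse),
                x$diagnostics$total_variance))
  }
  invisible(x)
}

#' Plot a quantization fit
#'
#' Draws the centroids of two channels with point area proportional to
#' cluster weight, optionally colored by per-cluster MSE.
#'
#' @param x a `wkmeans` fit.
#' @param ch_x,ch_y channel names (default: first two clustered channels).
#' @param mse optional per-cluster MSE vector used for coloring.
#' @param ... passed to [graphics::plot()].
#' @export
plot.wkmeans <- function(x, ch_x = NULL, ch_y = NULL, mse = NULL, ...) {
  chs <- if (length(x$channels_used) >= 2L) x$channels_used else x$channel_names
  if (is.null(ch_x)) ch_x <- chs[1L]
  if (is.null(ch_y)) ch_y <- chs[min(2L, length(chs))]
  i <- match(c(ch_x, ch_y), x$channel_names)
  if (anyNA(i)) stop("unknown channel")
  cex <- 0.5 + 2.5 * sqrt(x$weights / max(x$weights))
  col <- if (is.null(mse)) "steelblue" else
    grDevices::hcl.colors(64, "viridis")[cut(mse, 64, labels = FALSE)]
  graphics::plot(x$centroids[, i[1L]], x$centroids[, i[2L]],
                 cex = cex, pch = 19, col = col,
                 xlab = ch_x, ylab = ch_y, ...)
  invisible(x)
}
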