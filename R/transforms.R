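#' Display-transform specification
#'
#' Parameterizes the logicle (Parks--Moore biexponential) and hyperlog
#' (log-linear hybrid) display transforms in their GatingML 2.0 form, or the
#' identity ("none"). Both transforms map raw measurements -- including
#' negative values -- onto a normalized display scale on which the nominal
#' data range occupies [0, 1], with `x = T` mapping exactly to 1.
#'
#' @param kind one of `"logicle"`, `"hyperlog"`, `"none"`.
#' @param T top-of-scale value, in data units (> 0). Default 262144.
#' @param W linearization width in decades (>= 0, <= M/2). Default 0.5.
#' @param M total display decades (> 0). Default 4.5.
#' @param A additional negative decades (0 <= A <= W). Default 0.
#' @return An object of class `transform_spec`.
#' @examples
#' sp <- transform_spec("logicle")
#' flow_transform(c(-100, 0, 1000, 262144), sp)
#' @export
transform_spec <- function(kind = c("logicle", "hyperlog", "none"),
                           T = 262144, W = 0.5, M = 4.5, A = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(T) || T <= 0) stop("parameter error: T must be > 0")
  if (!is.numeric(M) || M <= 0) stop("parameter error: M must be > 0")
  if (!is.numeric(W) || W < 0) stop("parameter error: W must be >= 0")
  if (W > M / 2) stop("parameter error: W must be <= M/2")
  if (!is.numeric(A) || A < 0 || A > W)
    stop("parameter error: A must satisfy 0 <= A <= W")
  if (kind == "hyperlog" && W == 0 && A == 0)
    stop("parameter error: hyperlog requires W > 0 or A > 0")
  structure(list(kind = kind, T = T, W = W, M = M, A = A),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  if (x$kind == "none") cat("transform: none (identity)\n")
  else cat(sprintf("transform: %s (T=%g, W=%g, M=%g, A=%g)\n",
                   x$kind, x$T, x$W, x$M, x$A))
  invisible(x)
}

# Shared scale geometry: b decades in natural log, linearization width w,
# negative range x2, zero point x1, end of linear region x0 -- all on the
# normalized display scale.
scale_geometry <- function(spec) {
  b <- (spec$M + spec$A) * log(10)
  w <- spec$W / (spec$M + spec$A)
  x2 <- spec$A / (spec$M + spec$A)
  list(b = b, w = w, x2 = x2, x1 = x2 + w, x0 = x2 + 2 * w)
}

# Logicle constants. d solves 2*(ln d - ln b) + w*(b + d) = 0 on (0, b];
# w = 0 degenerates to d = b (pure log pair).
logicle_params <- function(spec) {
  g <- scale_geometry(spec)
  d <- if (g$w == 0) g$b else
    stats::uniroot(function(d) 2 * (log(d) - log(g$b)) + g$w * (g$b + d),
                   lower = g$b * 1e-14, upper = g$b, tol = 1e-15)$root
  c_a <- exp(g$x0 * (g$b + d))
  mf_a <- exp(g$b * g$x1) - c_a * exp(-d * g$x1)
  a <- spec$T / (exp(g$b) - mf_a - c_a * exp(-d))
  list(g = g, a = a, b = g$b, c = c_a * a, d = d, f = mf_a * a)
}

# Hyperlog constants: EH is exponential above x0 and linear through zero,
# with slope matched so the linear term continues the exponential at x0.
hyperlog_params <- function(spec) {
  g <- scale_geometry(spec)
  c_a <- exp(g$b * g$x0) / g$x0
  f_a <- exp(g$b * g$x1) + c_a * g$x1
  a <- spec$T / (exp(g$b) + c_a - f_a)
  list(g = g, a = a, b = g$b, c = c_a * a, f = f_a * a)
}

# Analytic display -> data maps (the biexponential and its hyperlog
# analogue), reflected about the zero point x1 for the negative branch.
biexp_value <- function(y, p) {
  x1 <- p$g$x1
  refl <- y < x1
  yy <- ifelse(refl, 2 * x1 - y, y)
  v <- p$a * exp(p$b * yy) - p$c * exp(-p$d * yy) - p$f
  ifelse(refl, -v, v)
}

biexp_deriv <- function(y, p) {
  x1 <- p$g$x1
  yy <- ifelse(y < x1, 2 * x1 - y, y)
  p$a * p$b * exp(p$b * yy) + p$c * p$d * exp(-p$d * yy)
}

hyper_value <- function(y, p) {
  x1 <- p$g$x1
  refl <- y < x1
  yy <- ifelse(refl, 2 * x1 - y, y)
  v <- p$a * exp(p$b * yy) + p$c * yy - p$f
  ifelse(refl, -v, v)
}

hyper_deriv <- function(y, p) {
  x1 <- p$g$x1
  yy <- ifelse(y < x1, 2 * x1 - y, y)
  p$a * p$b * exp(p$b * yy) + p$c
}

# Vectorized safeguarded Newton: monotone increasing value(), brackets
# maintained per element, bisection fallback when a step leaves the bracket.
solve_monotone <- function(x, value, deriv, lo0 = -1, hi0 = 2) {
  n <- length(x)
  lo <- rep(lo0, n); hi <- rep(hi0, n)
  while (any(bad <- value(lo) > x)) lo[bad] <- lo[bad] * 2 - hi0
  while (any(bad <- value(hi) < x)) hi[bad] <- hi[bad] * 2
  y <- (lo + hi) / 2
  for (iter in 1:200) {
    fy <- value(y) - x
    neg <- fy <= 0
    lo[neg] <- y[neg]; hi[!neg] <- y[!neg]
    ynew <- y - fy / deriv(y)
    fallback <- !is.finite(ynew) | ynew <= lo | ynew >= hi
    ynew[fallback] <- (lo[fallback] + hi[fallback]) / 2
    if (max(abs(ynew - y)) <= 1e-15 * max(1, max(abs(ynew)))) {
      y <- ynew
      break
    }
    y <- ynew
  }
  y
}

#' Apply a display transform
#'
#' Maps raw data values onto the normalized display scale. `kind = "none"`
#' returns the input unchanged; logicle and hyperlog are strictly
#' increasing, send `x = T` to 1, keep the nominal data range inside
#' [0, 1], and extrapolate monotonically above 1 for `x > T`.
#'
#' @param x numeric vector of raw (linear) values; must be finite.
#' @param spec a [transform_spec].
#' @return numeric vector of display values, same length as `x`.
#' @export
flow_transform <- function(x, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  if (any(!is.finite(x))) stop("x must be finite")
  if (spec$kind == "none") return(x)
  if (spec$kind == "logicle") {
    p <- logicle_params(spec)
    solve_monotone(x, function(y) biexp_value(y, p),
                   function(y) biexp_deriv(y, p))
  } else {
    p <- hyperlog_params(spec)
    solve_monotone(x, function(y) hyper_value(y, p),
                   function(y) hyper_deriv(y, p))
  }
}

#' Invert a display transform
#'
#' Maps normalized display values back to raw data units; the analytic
#' inverse of [flow_transform()] (closed form for both transforms).
#'
#' @param y numeric vector of display values.
#' @param spec a [transform_spec].
#' @return numeric vector of raw values.
#' @export
flow_inverse <- function(y, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  if (spec$kind == "none") return(y)
  if (spec$kind == "logicle") biexp_value(y, logicle_params(spec))
  else hyper_value(y, hyperlog_params(spec))
}

#' Transform selected channels of an event table
#'
#' Applies a display transform to the named channels (all channels if
#' `channels` is `NULL`), leaving the rest untouched. Channel ranges of
#' transformed channels become 1 (top of display scale).
#'
#' @param table an [event_table].
#' @param spec a [transform_spec].
#' @param channels channel names to transform, or `NULL` for all.
#' @return A new [event_table] on the display scale.
#' @export
transform_channels <- function(table, spec, channels = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (spec$kind == "none") return(table)
  if (is.null(channels)) channels <- table$channel_names
  idx <- channel_index(table, channels)
  vals <- table$values
  rng <- table$channel_ranges
  for (j in idx) {
    vals[, j] <- flow_transform(vals[, j], spec)
    rng[j] <- 1
  }
  event_table(vals, table$channel_names, rng,
              source = paste0(table$source, " | ", spec$kind))
}

#' Parse a transform key=value string
#'
#' Parses the run-config form `"logicle:T=262144,M=4.5,W=0.5,A=0"` (the
#' parameter list is optional) into a [transform_spec].
#'
#' @param s string like `"none"`, `"hyperlog"`, or `"logicle:T=1000,W=1"`.
#' @return A [transform_spec].
#' @export
parse_transform <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
  kind <- parts[1L]
  args <- list(kind = kind)
  if (length(parts) > 1L) {
    for (kv in strsplit(parts[2L], ",", fixed = TRUE)[[1L]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (length(p) != 2L) stop("bad transform parameter: ", kv)
      if (!p[1L] %in% c("T", "W", "M", "A"))
        stop("unknown transform parameter: ", p[1L])
      args[[p[1L]]] <- as.numeric(p[2L])
    }
  }
  do.call(transform_spec, args)
}
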