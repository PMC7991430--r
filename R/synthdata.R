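# Synthetic datasets: the spiral and bimodal toy shapes used to
# demonstrate quantization fidelity, and two-population fluorescence
# mixtures emulating a WT / GFP+ mixing design at desk scale. All
# generators are deterministic given their seed and honor n exactly.

SPIRAL_A <- 1
SPIRAL_B <- 1
SPIRAL_TURNS <- 3 * pi

#' Two-arm spiral toy dataset
#'
#' Two interleaved Archimedean spiral arms (`r = a + b*theta`,
#' `theta in [0, 3*pi]`, second arm rotated by pi) with isotropic Gaussian
#' noise, as a 2-channel event table.
#'
#' @param n number of events (default 5000).
#' @param noise_sd isotropic noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return An [event_table] with channels `X`, `Y`.
#' @export
make_spiral <- function(n = 5000L, noise_sd = 0.25, seed = 0L) {
  if (n < 1L) stop("n must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(seed, {
    theta <- stats::runif(n, 0, SPIRAL_TURNS)
    arm <- sample(c(0, pi), n, replace = TRUE)
    r <- SPIRAL_A + SPIRAL_B * theta
    x <- r * cos(theta + arm) + stats::rnorm(n, sd = noise_sd)
    y <- r * sin(theta + arm) + stats::rnorm(n, sd = noise_sd)
    event_table(cbind(X = x, Y = y),
                source = sprintf("synthetic spiral (n=%d, seed=%d)", n, seed))
  })
}

#' Bimodal toy dataset
#'
#' Two isotropic Gaussian modes of equal size on the first channel,
#' separated by `sep` standard deviations; the second channel is standard
#' normal.
#'
#' @param n number of events (default 10000).
#' @param sep mode separation in units of the mode sd.
#' @param seed RNG seed.
#' @return An [event_table] with channels `X`, `Y`.
#' @export
make_bimodal <- function(n = 10000L, sep = 6, seed = 0L) {
  if (n < 1L) stop("n must be >= 1")
  with_seed(seed, {
    n1 <- n %/% 2L
    mode <- c(rep(-sep / 2, n1), rep(sep / 2, n - n1))
    x <- mode + stats::rnorm(n)
    y <- stats::rnorm(n)
    event_table(cbind(X = x, Y = y),
                source = sprintf("synthetic bimodal (n=%d, sep=%g, seed=%d)",
                                 n, sep, seed))
  })
}

#' Two-population mixture specification
#'
#' Describes a desk-scale emulation of a two-population mixing design: a
#' scatter channel (normal on both populations) and a fluorescence channel
#' (log-normal, right-skewed and strictly positive, as typical of
#' cytometry fluorescence). The default populations are separated 100-fold
#' in fluorescence median (negative ~150 a.u., positive ~15000 a.u.), so a
#' midpoint gate is unambiguous.
#'
#' @param n_total total number of events.
#' @param ratio_a fraction of events from population A (the
#'   fluorescence-negative population) in [0, 1]; allocation is exact:
#'   `count_A = round(ratio_a * n_total)`.
#' @param seed RNG seed.
#' @param channel_params named list of per-channel parameter lists. Each
#'   element is `list(dist, a = c(...), b = c(...))` with `dist` `"normal"`
#'   (`mean`, `sd`) or `"lognormal"` (`meanlog`, `sdlog`).
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(n_total, ratio_a, seed = 0L,
                         channel_params = list(
                           `FSC-H` = list(dist = "normal",
                                          a = c(mean = 50000, sd = 8000),
                                          b = c(mean = 55000, sd = 8000)),
                           `GFP-H` = list(dist = "lognormal",
                                          a = c(meanlog = log(150), sdlog = 0.35),
                                          b = c(meanlog = log(15000), sdlog = 0.35)))) {
  if (!is.numeric(ratio_a) || ratio_a < 0 || ratio_a > 1)
    stop("ratio_a must be in [0, 1]")
  if (n_total < 1L) stop("n_total must be >= 1")
  structure(list(n_total = as.integer(n_total), ratio_a = ratio_a,
                 seed = as.integer(seed), channel_params = channel_params),
            class = "mixture_spec")
}

draw_channel <- function(p, n) {
  if (n == 0L) return(numeric(0))
  switch(p[["dist"]],
         normal = stats::rnorm(n, p$par[["mean"]], p$par[["sd"]]),
         lognormal = stats::rlnorm(n, p$par[["meanlog"]], p$par[["sdlog"]]),
         stop("unknown distribution: ", p[["dist"]]))
}

#' Generate a two-population mixture
#'
#' Draws exactly `round(ratio_a * n_total)` events from population A and
#' the remainder from population B, per the spec's channel distributions,
#' and returns the table together with the ground-truth membership so any
#' gate's true percentage can be computed exactly.
#'
#' @param spec a [mixture_spec].
#' @return list with `table` (an [event_table]) and `truth` (factor of
#'   `"A"`/`"B"` per event).
#' @export
make_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  n <- spec$n_total
  n_a <- as.integer(round(spec$ratio_a * n))
  n_b <- n - n_a
  chans <- names(spec$channel_params)
  with_seed(spec$seed, {
    cols <- lapply(chans, function(ch) {
      p <- spec$channel_params[[ch]]
      c(draw_channel(list(dist = p$dist, par = p$a), n_a),
        draw_channel(list(dist = p$dist, par = p$b), n_b))
    })
    vals <- do.call(cbind, cols)
    colnames(vals) <- chans
    list(table = event_table(vals,
                             source = sprintf("synthetic mixture (n=%d, ratio_a=%g, seed=%d)",
                                              n, spec$ratio_a, spec$seed)),
         truth = factor(rep(c("A", "B"), c(n_a, n_b)), levels = c("A", "B")))
  })
}
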