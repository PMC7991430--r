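# Centroid-level gating. Gates evaluate on cluster centroids, with each
# cluster's integer weight carrying its event count through every
# percentage -- the device that makes interactive gating on quantized data
# faithful to the underlying events. Raw events inherit gate membership
# through their cluster labels only at export time.

#' Gate definitions
#'
#' `gate_quadrant()` defines one region of a two-threshold quadrant
#' partition; `gate_polygon()` a lasso-style polygon gate. Both are applied
#' to centroids via [push_gate()] or evaluated directly with
#' [quadrant_gate()] / [polygon_gate()].
#'
#' Quadrant layout (fixed): Q1 upper-left (`x < tx, y >= ty`), Q2
#' upper-right (`x >= tx, y >= ty`), Q3 lower-right (`x >= tx, y < ty`),
#' Q4 lower-left (`x < tx, y < ty`). A coordinate equal to its threshold
#' counts as positive (upper/right).
#'
#' @param ch_x,ch_y distinct channel names.
#' @param tx,ty finite thresholds in the gated (transformed) units.
#' @param region one of `"Q1".."Q4"`.
#' @param vertices numeric matrix (>= 3 x 2) of ordered polygon vertices,
#'   not all collinear; membership uses the even-odd rule with the boundary
#'   counting as inside.
#' @return An object of class `fc_gate`.
#' @export
gate_quadrant <- function(ch_x, ch_y, tx, ty, region = c("Q1", "Q2", "Q3", "Q4")) {
  region <- match.arg(region)
  if (identical(ch_x, ch_y)) stop("validation error: ch_x and ch_y must differ")
  if (!is.finite(tx) || !is.finite(ty))
    stop("validation error: thresholds must be finite")
  structure(list(kind = "quadrant_region", ch_x = ch_x, ch_y = ch_y,
                 params = list(tx = tx, ty = ty, region = region)),
            class = "fc_gate")
}

#' @rdname gate_quadrant
#' @export
gate_polygon <- function(ch_x, ch_y, vertices) {
  if (identical(ch_x, ch_y)) stop("validation error: ch_x and ch_y must differ")
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L)
    stop("validation error: polygon needs >= 3 two-dimensional vertices")
  if (any(!is.finite(vertices))) stop("validation error: vertices must be finite")
  v1 <- vertices[2L, ] - vertices[1L, ]
  cross <- (vertices[-1L, 1L, drop = TRUE] - vertices[1L, 1L]) * v1[2L] -
           (vertices[-1L, 2L, drop = TRUE] - vertices[1L, 2L]) * v1[1L]
  if (all(abs(cross) < .Machine$double.eps * 100))
    stop("validation error: polygon vertices are collinear")
  structure(list(kind = "polygon", ch_x = ch_x, ch_y = ch_y,
                 params = list(vertices = unname(vertices))),
            class = "fc_gate")
}

#' @export
print.fc_gate <- function(x, ...) {
  if (x$kind == "quadrant_region")
    cat(sprintf("quadrant gate %s on (%s, %s), tx=%g ty=%g\n",
                x$params$region, x$ch_x, x$ch_y, x$params$tx, x$params$ty))
  else
    cat(sprintf("polygon gate on (%s, %s), %d vertices\n",
                x$ch_x, x$ch_y, nrow(x$params$vertices)))
  invisible(x)
}

# even-odd ray casting with inclusive boundary
point_in_polygon <- function(px, py, vertices) {
  vx <- vertices[, 1L]; vy <- vertices[, 2L]
  nv <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary test: zero cross product and within the segment's box
    cr <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    on_seg <- cr == 0 &
      px >= pmin(x1, x2) & px <= pmax(x1, x2) &
      py >= pmin(y1, y2) & py <= pmax(y1, y2)
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | on_edge
}

quadrant_of <- function(x, y, tx, ty) {
  ifelse(y >= ty, ifelse(x < tx, "Q1", "Q2"), ifelse(x < tx, "Q4", "Q3"))
}

gate_members <- function(gate, q, clusters) {
  i <- match(c(gate$ch_x, gate$ch_y), q$channel_names)
  if (anyNA(i)) stop("unknown channel: ",
                     paste(c(gate$ch_x, gate$ch_y)[is.na(i)], collapse = ", "))
  cx <- q$centroids[clusters, i[1L]]
  cy <- q$centroids[clusters, i[2L]]
  if (gate$kind == "quadrant_region") {
    sel <- quadrant_of(cx, cy, gate$params$tx, gate$params$ty) == gate$params$region
  } else {
    sel <- point_in_polygon(cx, cy, gate$params$vertices)
  }
  clusters[sel]
}

gate_result <- function(selected, q, parent_clusters) {
  pw <- sum(q$weights[parent_clusters])
  sw <- sum(q$weights[selected])
  structure(list(selected_clusters = selected,
                 selected_weight = as.integer(sw),
                 parent_weight = as.integer(pw),
                 percent_of_parent = 100 * sw / pw),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("gate: %d cluster(s), %d/%d events (%.2f%% of parent)\n",
              length(x$selected_clusters),
              x$selected_weight, x$parent_weight, x$percent_of_parent))
  invisible(x)
}

#' Quadrant gate with weighted percentages
#'
#' Splits the current population of centroids by one threshold per axis
#' into the four quadrants (layout as in [gate_quadrant()]) and reports,
#' per quadrant, the summed cluster weight and its percentage of the
#' population. Percentages derive from exact integer weights; the four
#' quadrant weights always sum to the population weight.
#'
#' @param q a `wkmeans` fit.
#' @param ch_x,ch_y distinct channel names.
#' @param tx,ty finite thresholds (transformed units).
#' @param clusters optional cluster index subset (current population).
#' @return data.frame with columns `quadrant`, `weight`, `percent`.
#' @export
quadrant_gate <- function(q, ch_x, ch_y, tx, ty, clusters = NULL) {
  if (identical(ch_x, ch_y)) stop("validation error: ch_x and ch_y must differ")
  if (!is.finite(tx) || !is.finite(ty))
    stop("validation error: thresholds must be finite")
  if (is.null(clusters)) clusters <- seq_len(q$k)
  i <- match(c(ch_x, ch_y), q$channel_names)
  if (anyNA(i)) stop("unknown channel: ",
                     paste(c(ch_x, ch_y)[is.na(i)], collapse = ", "))
  qd <- quadrant_of(q$centroids[clusters, i[1L]],
                    q$centroids[clusters, i[2L]], tx, ty)
  w <- vapply(c("Q1", "Q2", "Q3", "Q4"),
              function(z) sum(q$weights[clusters][qd == z]), numeric(1))
  total <- sum(q$weights[clusters])
  data.frame(quadrant = c("Q1", "Q2", "Q3", "Q4"),
             weight = as.integer(w),
             percent = 100 * w / total,
             row.names = NULL)
}

#' Polygon (lasso) gate
#'
#' Selects the clusters whose centroid projection on two channels lies
#' inside the polygon (even-odd rule, boundary inclusive) and reports the
#' weighted sub-population.
#'
#' @inheritParams quadrant_gate
#' @param vertices ordered vertex matrix (>= 3 x 2).
#' @return A `gate_result`: `selected_clusters`, `selected_weight`,
#'   `parent_weight`, `percent_of_parent`.
#' @export
polygon_gate <- function(q, ch_x, ch_y, vertices, clusters = NULL) {
  g <- gate_polygon(ch_x, ch_y, vertices)
  if (is.null(clusters)) clusters <- seq_len(q$k)
  gate_result(gate_members(g, q, clusters), q, clusters)
}

#' Deep-gating stack
#'
#' An ordered list of gates applied successively to a quantization; each
#' [push_gate()] narrows the current population to the clusters surviving
#' all gates (weights unchanged), and [reset_gates()] restores the full,
#' unaltered dataset. An empty stack selects everything.
#'
#' @param q a `wkmeans` fit.
#' @return An object of class `gate_stack`.
#' @export
gate_stack <- function(q) {
  stopifnot(inherits(q, "wkmeans") || !is.null(q$centroids))
  structure(list(q = q, gates = list()), class = "gate_stack")
}

#' @rdname gate_stack
#' @param stack a `gate_stack`.
#' @param gate an `fc_gate` from [gate_quadrant()] or [gate_polygon()].
#' @export
push_gate <- function(stack, gate) {
  stopifnot(inherits(stack, "gate_stack"), inherits(gate, "fc_gate"))
  if (!all(c(gate$ch_x, gate$ch_y) %in% stack$q$channel_names))
    stop("gate on unknown channel")
  stack$gates <- c(stack$gates, list(gate))
  stack
}

#' @rdname gate_stack
#' @export
reset_gates <- function(stack) {
  stopifnot(inherits(stack, "gate_stack"))
  stack$gates <- list()
  stack
}

#' @rdname gate_stack
#' @export
current_clusters <- function(stack) {
  stopifnot(inherits(stack, "gate_stack"))
  clusters <- seq_len(nrow(stack$q$centroids))
  for (g in stack$gates) clusters <- gate_members(g, stack$q, clusters)
  clusters
}

#' @rdname gate_stack
#' @export
population_weight <- function(stack) {
  sum(stack$q$weights[current_clusters(stack)])
}

#' @export
print.gate_stack <- function(x, ...) {
  cat(sprintf("gate stack: %d gate(s), population %d/%d events\n",
              length(x$gates), population_weight(x), sum(x$q$weights)))
  for (g in x$gates) print(g)
  invisible(x)
}

#' Export the raw events surviving a gate stack
#'
#' Writes every original event whose cluster label survives the stack.
#' The row count equals the stack's selected weight.
#'
#' @param table the originating [event_table] (raw or transformed -- the
#'   values written are the values given).
#' @param q the `wkmeans` fit of `table`.
#' @param stack a `gate_stack` on `q`.
#' @param path output path.
#' @param format `"csv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
export_gated_events <- function(table, q, stack, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "event_table"))
  if (nrow(table$values) != length(q$labels))
    stop("validation error: table and quantization sizes differ")
  keep <- q$labels %in% current_clusters(stack)
  if (!any(keep)) {
    if (format == "fcs") stop("empty-data error: no events survive the gate stack")
    writeLines(paste(table$channel_names, collapse = ","), path)
    return(invisible(path))
  }
  sub <- event_table(table$values[keep, , drop = FALSE],
                     table$channel_names, table$channel_ranges,
                     source = paste0(table$source, " | gated"))
  if (format == "csv") write_csv_events(sub, path) else write_fcs(sub, path)
  invisible(path)
}
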