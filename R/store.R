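# SQLite persistence for quantized runs -- the backing store for deep
# gating. Schema (version 1):
#   meta(key TEXT PRIMARY KEY, value TEXT)         -- JSON-encoded metadata
#   clusters(id INTEGER, weight INTEGER, mse REAL, "c_<channel>" REAL ...)
#   events(id INTEGER, cluster_id INTEGER, "v_<channel>" REAL ...)
#   gates(id INTEGER, ordinal INTEGER, kind TEXT, ch_x TEXT, ch_y TEXT,
#         params_json TEXT)
# REAL columns are 8-byte IEEE doubles, so centroids round-trip losslessly.

STORE_SCHEMA_VERSION <- 1L

store_meta_json <- function(x) {
  # I(17) significant digits so doubles survive the text round trip
  as.character(jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE))
}

#' Persist a quantization and its gate stack
#'
#' Writes the fit's centroids, integer weights, event labels, gate
#' definitions and metadata (channel weights, transform, seed, loss) to a
#' single-file SQLite database; optionally also the per-event values, which
#' enables event export and re-diagnosis straight from the store.
#'
#' @param q a `wkmeans` fit.
#' @param stack a `gate_stack` on `q` (or `NULL` for an empty stack).
#' @param path output database path.
#' @param table optional originating [event_table]; when given, per-event
#'   values are stored alongside the labels.
#' @param transform optional [transform_spec] recorded in the metadata.
#' @param mse optional per-cluster MSE vector (see [cluster_mse()]).
#' @return `path`, invisibly.
#' @export
save_store <- function(q, stack = NULL, path, table = NULL,
                       transform = NULL, mse = NULL) {
  stopifnot(inherits(q, "wkmeans"))
  if (is.null(stack)) stack <- gate_stack(q)
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))

  meta <- list(
    schema_version = STORE_SCHEMA_VERSION,
    k = q$k, n = q$n, seed = q$seed, loss = q$loss,
    restarts = q$restarts, converged = q$converged,
    channel_names = q$channel_names, omega = q$omega,
    channels_used = q$channels_used,
    transform = if (is.null(transform)) NULL else unclass(transform),
    has_events = !is.null(table))
  DBI::dbWriteTable(con, "meta",
                    data.frame(key = names(meta),
                               value = vapply(meta, store_meta_json, character(1)),
                               stringsAsFactors = FALSE))

  cl <- data.frame(id = seq_len(q$k), weight = q$weights,
                   mse = if (is.null(mse)) rep(NA_real_, q$k) else mse)
  cent <- as.data.frame(q$centroids)
  cl <- cbind(cl, cent)
  names(cl) <- c("id", "weight", "mse", paste0("c_", q$channel_names))
  DBI::dbWriteTable(con, "clusters", cl)

  ev <- data.frame(id = seq_along(q$labels), cluster_id = q$labels)
  if (!is.null(table)) {
    stopifnot(inherits(table, "event_table"),
              nrow(table$values) == length(q$labels))
    vals <- as.data.frame(table$values)
    ev <- cbind(ev, vals)
    names(ev) <- c("id", "cluster_id", paste0("v_", table$channel_names))
    DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS ranges (channel TEXT, range REAL)")
    DBI::dbWriteTable(con, "ranges",
                      data.frame(channel = table$channel_names,
                                 range = table$channel_ranges),
                      overwrite = TRUE)
  }
  DBI::dbWriteTable(con, "events", ev)

  gates <- stack$gates
  gd <- data.frame(id = seq_along(gates),
                   ordinal = seq_along(gates),
                   kind = vapply(gates, function(g) g$kind, character(1)),
                   ch_x = vapply(gates, function(g) g$ch_x, character(1)),
                   ch_y = vapply(gates, function(g) g$ch_y, character(1)),
                   params_json = vapply(gates, function(g)
                     store_meta_json(g$params), character(1)),
                   stringsAsFactors = FALSE)
  if (nrow(gd) == 0L)
    gd <- gd[0L, , drop = FALSE]
  DBI::dbWriteTable(con, "gates", gd)
  invisible(path)
}

#' Load a quantization and gate stack from a store
#'
#' @param path an SQLite store written by [save_store()].
#' @return list with `quantization` (a `wkmeans` object), `stack`
#'   (a `gate_stack`), `table` (the stored [event_table], or `NULL`),
#'   `transform` (a [transform_spec], or `NULL`) and `meta`.
#' @export
load_store <- function(path) {
  if (!file.exists(path)) stop("store not found: ", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))

  mt <- DBI::dbReadTable(con, "meta")
  meta <- stats::setNames(lapply(mt$value, jsonlite::fromJSON), mt$key)
  ver <- meta$schema_version
  if (is.null(ver) || ver != STORE_SCHEMA_VERSION)
    stop(sprintf("store schema version mismatch: file has %s, expected %d",
                 if (is.null(ver)) "none" else ver, STORE_SCHEMA_VERSION))

  cl <- DBI::dbReadTable(con, "clusters", check.names = FALSE)
  cl <- cl[order(cl$id), , drop = FALSE]
  chans <- as.character(meta$channel_names)
  centroids <- as.matrix(cl[, paste0("c_", chans), drop = FALSE])
  dimnames(centroids) <- list(NULL, chans)

  ev <- DBI::dbReadTable(con, "events", check.names = FALSE)
  ev <- ev[order(ev$id), , drop = FALSE]
  labels <- as.integer(ev$cluster_id)

  q <- structure(
    list(centroids = centroids, weights = as.integer(cl$weight),
         labels = labels, loss = as.numeric(meta$loss), trace = NULL,
         k = as.integer(meta$k), seed = as.integer(meta$seed),
         omega = as.numeric(meta$omega),
         channels_used = as.character(meta$channels_used),
         iterations = NA_integer_, converged = isTRUE(meta$converged),
         restarts = as.integer(meta$restarts), n = as.integer(meta$n),
         channel_names = chans, call = NULL),
    class = "wkmeans")

  stack <- gate_stack(q)
  gd <- DBI::dbReadTable(con, "gates", check.names = FALSE)
  if (nrow(gd)) {
    gd <- gd[order(gd$ordinal), , drop = FALSE]
    for (i in seq_len(nrow(gd))) {
      p <- jsonlite::fromJSON(gd$params_json[i])
      g <- if (gd$kind[i] == "quadrant_region") {
        gate_quadrant(gd$ch_x[i], gd$ch_y[i], p$tx, p$ty, p$region)
      } else {
        vm <- p$vertices
        if (!is.matrix(vm)) vm <- do.call(rbind, vm)
        gate_polygon(gd$ch_x[i], gd$ch_y[i], vm)
      }
      stack <- push_gate(stack, g)
    }
  }

  table <- NULL
  if (isTRUE(meta$has_events)) {
    vals <- as.matrix(ev[, paste0("v_", chans), drop = FALSE])
    rng <- DBI::dbReadTable(con, "ranges", check.names = FALSE)
    table <- event_table(vals, chans,
                         rng$range[match(chans, rng$channel)],
                         source = paste0("store:", path))
  }

  transform <- NULL
  if (!is.null(meta$transform) && length(meta$transform)) {
    tf <- as.list(meta$transform)
    for (nm in c("T", "W", "M", "A")) tf[[nm]] <- as.numeric(tf[[nm]])
    transform <- do.call(transform_spec, tf)
  }

  list(quantization = q, stack = stack, table = table,
       transform = transform, meta = meta)
}

#' Per-cluster MSE values stored in a store
#'
#' @param path an SQLite store.
#' @return numeric vector of per-cluster MSE (NA if never written).
#' @export
store_cluster_mse <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  cl <- DBI::dbReadTable(con, "clusters", check.names = FALSE)
  cl$mse[order(cl$id)]
}
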