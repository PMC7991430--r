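#' Construct an event table
#'
#' The canonical container for flow-cytometry list-mode data: an N x d
#' numeric matrix of events (rows) by channels (columns), plus per-channel
#' display ranges and a free-text provenance string.
#'
#' @param values numeric matrix (or coercible data frame), N x d, finite.
#' @param channel_names character vector of d unique, non-empty names.
#'   Defaults to `colnames(values)`.
#' @param channel_ranges positive numeric vector of d per-channel ranges
#'   (the instrument's top-of-scale, FCS `$PnR`). Defaults to
#'   `pmax(colMax(|values|), 1)`.
#' @param source free-text provenance string.
#' @return An object of class `event_table`: a list with elements
#'   `values`, `channel_names`, `channel_ranges`, `source`.
#' @examples
#' et <- event_table(matrix(rnorm(20), 10, 2), c("FSC-H", "FL1-H"))
#' dim(et)
#' @export
event_table <- function(values, channel_names = colnames(values),
                        channel_ranges = NULL, source = "in-memory") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("event table must have at least one event and one channel")
  if (any(!is.finite(values)))
    stop("event values must be finite (no NA/NaN/Inf)")
  d <- ncol(values)
  if (is.null(channel_names))
    channel_names <- paste0("P", seq_len(d))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != d)
    stop("'channel_names' must have one entry per column")
  if (anyDuplicated(channel_names) || any(!nzchar(channel_names)))
    stop("channel names must be unique and non-empty")
  if (is.null(channel_ranges))
    channel_ranges <- pmax(apply(abs(values), 2L, max), 1)
  channel_ranges <- as.numeric(channel_ranges)
  if (length(channel_ranges) != d || any(!is.finite(channel_ranges)) ||
      any(channel_ranges <= 0))
    stop("'channel_ranges' must be ", d, " positive finite numbers")
  dimnames(values) <- list(NULL, channel_names)
  structure(
    list(values = values, channel_names = channel_names,
         channel_ranges = channel_ranges, source = as.character(source)[1L]),
    class = "event_table")
}

#' @export
dim.event_table <- function(x) dim(x$values)

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d events x %d channels (%s)\n",
              nrow(x$values), ncol(x$values), x$source))
  cat("Channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.event_table <- function(x, ...) x$values

channel_index <- function(table, channel) {
  i <- match(channel, table$channel_names)
  if (anyNA(i))
    stop("unknown channel(s): ",
         paste(channel[is.na(i)], collapse = ", "))
  i
}

#' Read an event table from CSV
#'
#' The first row must hold the channel names; every remaining cell must be
#' numeric. Channel ranges default to `max(value, 1)` per channel.
#'
#' @param path path to a comma-separated file (UTF-8, "." decimal).
#' @return An [event_table].
#' @export
read_csv_events <- function(path) {
  hdr <- utils::read.csv(path, nrows = 1L, header = FALSE,
                         colClasses = "character")
  nm <- as.character(unlist(hdr, use.names = FALSE))
  if (anyDuplicated(nm))
    stop("duplicate channel name in CSV header: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L)
    stop("CSV contains a header but no event rows")
  vals <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value %s at row %d, column %d (%s)",
                   dQuote(df[[j]][bad[1L]]), bad[1L], j, nm[j]))
    vals[, j] <- v
  }
  event_table(vals, channel_names = nm,
              channel_ranges = pmax(apply(vals, 2L, max), 1),
              source = paste0("csv:", path))
}

#' Write an event table to CSV
#'
#' @param table an [event_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_events <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  utils::write.csv(as.data.frame(table$values), path, row.names = FALSE)
  invisible(path)
}
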