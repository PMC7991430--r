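# Minimal FCS 3.0/3.1 list-mode I/O.
#
# Only what cytometry event data needs: HEADER + TEXT + DATA segments,
# $MODE=L, $DATATYPE F/D/I, little/big byte order, $PnE log-amplification
# decoding at read time. Correlated/histogram modes and the ANALYSIS
# segment are rejected/ignored; $SPILLOVER is parsed but not applied.

FCS_HEADER_LEN <- 58L

# TEXT segment: delimiter-separated key/value pairs, delimiter escaped by
# doubling. Returns a named character vector.
parse_fcs_text <- function(txt) {
  if (nchar(txt) < 3L) stop("FCS parse error: TEXT segment too short")
  delim <- substr(txt, 1L, 1L)
  body <- substr(txt, 2L, nchar(txt))
  # strip the final delimiter (required by the standard)
  if (substr(body, nchar(body), nchar(body)) == delim)
    body <- substr(body, 1L, nchar(body) - 1L)
  pieces <- strsplit(body, delim, fixed = TRUE)[[1L]]
  if (length(pieces) == 0L) stop("FCS parse error: empty TEXT segment")
  out <- character(0)
  buf <- pieces[1L]
  i <- 2L
  while (i <= length(pieces)) {
    if (identical(pieces[i], "") && i < length(pieces)) {
      # doubled delimiter: literal delimiter inside the previous token
      buf <- paste0(buf, delim, pieces[i + 1L])
      i <- i + 2L
    } else {
      out <- c(out, buf)
      buf <- pieces[i]
      i <- i + 1L
    }
  }
  out <- c(out, buf)
  if (length(out) %% 2L != 0L)
    stop("FCS parse error: odd number of TEXT tokens (unbalanced key/value)")
  keys <- toupper(out[seq(1L, length(out), by = 2L)])
  vals <- out[seq(2L, length(out), by = 2L)]
  names(vals) <- keys
  vals
}

fcs_kw <- function(kw, key, required = TRUE) {
  v <- unname(kw[toupper(key)])
  if (required && (length(v) != 1L || is.na(v)))
    stop("FCS parse error: missing required TEXT keyword ", key)
  if (length(v) != 1L || is.na(v)) return(NA_character_)
  v
}

#' Read an FCS file
#'
#' Reads list-mode FCS 2.0/3.0/3.1 files with `$DATATYPE` F (float), D
#' (double) or I (uniform-width integer). Channels stored log-amplified
#' (`$PnE = "f1,f2"` with `f1 > 0`) are decoded to linear scale as
#' `f2 * 10^(f1 * raw / $PnR)` (with `f2 = 0` treated as 1, the common
#' convention); `$PnE = "0,0"` channels are returned as stored. Per-channel
#' decode status is recorded in the returned table's `source` field.
#'
#' @param path path to an FCS file.
#' @return An [event_table] with `$TOT` rows and `$PAR` columns.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", FCS_HEADER_LEN))
  version <- trimws(substr(header, 1L, 6L))
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version)
  off <- function(a, b) suppressWarnings(as.numeric(trimws(substr(header, a, b))))
  txt_beg <- off(11L, 18L); txt_end <- off(19L, 26L)
  dat_beg <- off(27L, 34L); dat_end <- off(35L, 42L)
  if (is.na(txt_beg) || is.na(txt_end) || txt_end <= txt_beg)
    stop("FCS parse error: invalid TEXT offsets in HEADER")
  seek(con, txt_beg)
  kw <- parse_fcs_text(rawToChar(readBin(con, "raw", txt_end - txt_beg + 1L)))

  mode <- fcs_kw(kw, "$MODE")
  if (toupper(mode) != "L")
    stop("unsupported-format error: only list mode ($MODE=L) is supported, got ", mode)
  dtype <- toupper(fcs_kw(kw, "$DATATYPE"))
  if (!dtype %in% c("F", "D", "I"))
    stop("unsupported $DATATYPE: ", dtype)
  tot <- as.integer(fcs_kw(kw, "$TOT"))
  par <- as.integer(fcs_kw(kw, "$PAR"))
  if (is.na(tot) || is.na(par))
    stop("FCS parse error: non-numeric $TOT/$PAR")
  if (tot == 0L) stop("empty-data error: $TOT is 0")
  byteord <- fcs_kw(kw, "$BYTEORD")
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stop("unsupported $BYTEORD: ", byteord))
  if (is.na(dat_beg) || dat_beg == 0) dat_beg <- as.numeric(fcs_kw(kw, "$BEGINDATA"))
  if (is.na(dat_end) || dat_end == 0) dat_end <- as.numeric(fcs_kw(kw, "$ENDDATA"))
  if (is.na(dat_beg) || is.na(dat_end) || dat_end < dat_beg)
    stop("FCS parse error: invalid DATA offsets ($BEGINDATA/$ENDDATA)")

  names_ <- character(par); ranges <- numeric(par)
  bits <- integer(par); pne <- character(par)
  for (j in seq_len(par)) {
    names_[j] <- fcs_kw(kw, sprintf("$P%dN", j))
    ranges[j] <- as.numeric(fcs_kw(kw, sprintf("$P%dR", j)))
    bits[j] <- as.integer(fcs_kw(kw, sprintf("$P%dB", j)))
    v <- fcs_kw(kw, sprintf("$P%dE", j), required = FALSE)
    pne[j] <- if (is.na(v)) "0,0" else v
  }

  seek(con, dat_beg)
  nvals <- tot * par
  if (dtype == "F") {
    if (any(bits != 32L)) stop("FCS parse error: $DATATYPE F requires $PnB=32")
    vals <- readBin(con, "numeric", nvals, size = 4L, endian = endian)
  } else if (dtype == "D") {
    if (any(bits != 64L)) stop("FCS parse error: $DATATYPE D requires $PnB=64")
    vals <- readBin(con, "numeric", nvals, size = 8L, endian = endian)
  } else {
    if (length(unique(bits)) != 1L || !bits[1L] %in% c(8L, 16L, 32L))
      stop("unsupported-format error: integer data requires uniform $PnB in {8,16,32}")
    sz <- bits[1L] %/% 8L
    if (sz < 4L) {
      vals <- as.numeric(readBin(con, "integer", nvals, size = sz,
                                 signed = FALSE, endian = endian))
    } else {
      vals <- as.numeric(readBin(con, "integer", nvals, size = 4L, endian = endian))
      vals[vals < 0] <- vals[vals < 0] + 2^32
    }
  }
  if (length(vals) != nvals)
    stop("FCS parse error: DATA segment truncated (expected ", nvals,
         " values, got ", length(vals), ")")
  m <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)

  decoded <- character(0)
  for (j in seq_len(par)) {
    fe <- suppressWarnings(as.numeric(strsplit(pne[j], ",", fixed = TRUE)[[1L]]))
    if (length(fe) == 2L && !anyNA(fe) && fe[1L] > 0) {
      f2 <- if (fe[2L] == 0) 1 else fe[2L]
      m[, j] <- f2 * 10^(fe[1L] * m[, j] / ranges[j])
      decoded <- c(decoded, names_[j])
    }
  }
  src <- paste0("fcs:", path,
                if (length(decoded))
                  paste0(" [log-decoded: ", paste(decoded, collapse = ","), "]")
                else " [linear]")
  event_table(m, channel_names = names_, channel_ranges = ranges, source = src)
}

escape_delim <- function(x, delim) gsub(delim, paste0(delim, delim), x, fixed = TRUE)

#' Write an event table as FCS 3.1
#'
#' Emits a minimal FCS 3.1 file: HEADER with segment offsets, a TEXT segment
#' with `$BEGINDATA`/`$ENDDATA`/`$TOT`/`$PAR`/`$MODE=L`/`$DATATYPE=F`/
#' `$BYTEORD=1,2,3,4`/`$PnN`/`$PnB=32`/`$PnE=0,0`/`$PnR`, and the events as
#' little-endian 32-bit floats. Delimiters inside channel names are escaped
#' by doubling.
#'
#' @param table an [event_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  delim <- "/"
  n <- nrow(table$values); d <- ncol(table$values)
  data_len <- 4L * n * d

  build_text <- function(beg, end) {
    kv <- c("$BEGINDATA", format(beg, scientific = FALSE),
            "$ENDDATA", format(end, scientific = FALSE),
            "$TOT", format(n, scientific = FALSE),
            "$PAR", as.character(d),
            "$MODE", "L", "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
            "$NEXTDATA", "0")
    for (j in seq_len(d)) {
      kv <- c(kv,
              sprintf("$P%dN", j), escape_delim(table$channel_names[j], delim),
              sprintf("$P%dB", j), "32",
              sprintf("$P%dE", j), "0,0",
              sprintf("$P%dR", j), format(table$channel_ranges[j], scientific = FALSE))
    }
    paste0(delim, paste0(kv, delim, collapse = ""))
  }

  # DATA offsets depend on TEXT length; iterate until stable
  beg <- FCS_HEADER_LEN + nchar(build_text(1L, 1L), type = "bytes")
  repeat {
    txt <- build_text(beg, beg + data_len - 1L)
    beg2 <- FCS_HEADER_LEN + nchar(txt, type = "bytes")
    if (beg2 == beg) break
    beg <- beg2
  }
  txt_end <- FCS_HEADER_LEN + nchar(txt, type = "bytes") - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    FCS_HEADER_LEN, txt_end, beg, beg + data_len - 1L, 0L, 0L)
  stopifnot(nchar(header) == FCS_HEADER_LEN)

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write FCS file ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  # events are stored row-major (event by event)
  writeBin(as.vector(t(table$values)), con, size = 4L, endian = "little")
  invisible(path)
}
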