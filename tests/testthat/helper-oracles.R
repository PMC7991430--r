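# Independent oracle implementations used to cross-check the package's
# code paths. Each is deliberately written with a different algorithm or
# a naive formulation than the implementation it checks.

# naive O(N*k) nearest-centroid assignment, scalar loops
oracle_nearest <- function(X, C, omega) {
  n <- nrow(X); k <- nrow(C)
  lab <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf; bj <- 0L
    for (j in seq_len(k)) {
      d <- sum(omega * (X[i, ] - C[j, ])^2)
      if (d < best) { best <- d; bj <- j }
    }
    lab[i] <- bj
  }
  lab
}

# exhaustive global optimum of 2-cluster weighted k-means on tiny n:
# enumerate every nontrivial assignment, score with member-mean centroids
oracle_best_2partition <- function(X, omega) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    lab <- as.integer(intToBits(code)[1:n]) + 1L
    if (length(unique(lab)) < 2L) next
    loss <- 0
    for (g in 1:2) {
      M <- X[lab == g, , drop = FALSE]
      mu <- colMeans(M)
      loss <- loss + sum(t((t(M) - mu)^2) %*% omega)
    }
    best <- min(best, loss)
  }
  best
}

# independent even-odd point-in-polygon: cast the ray upward (+y) instead
# of +x, scalar loop
oracle_in_polygon <- function(px, py, verts) {
  nv <- nrow(verts)
  out <- logical(length(px))
  for (p in seq_along(px)) {
    x <- px[p]; y <- py[p]
    inside <- FALSE
    j <- nv
    for (i in seq_len(nv)) {
      x1 <- verts[j, 1]; y1 <- verts[j, 2]
      x2 <- verts[i, 1]; y2 <- verts[i, 2]
      if ((x1 > x) != (x2 > x)) {
        yc <- y1 + (x - x1) * (y2 - y1) / (x2 - x1)
        if (y < yc) inside <- !inside
      }
      j <- i
    }
    out[p] <- inside
  }
  out
}

# scalar bisection on the analytic display->data map, independent of the
# package's Newton solver
oracle_bisect_transform <- function(x, spec, tol = 1e-12) {
  vapply(x, function(xx) {
    lo <- -5; hi <- 5
    while (fcquant::flow_inverse(lo, spec) > xx) lo <- lo * 2
    while (fcquant::flow_inverse(hi, spec) < xx) hi <- hi * 2
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (fcquant::flow_inverse(mid, spec) < xx) lo <- mid else hi <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

# minimal independent FCS TEXT key/value scanner (state machine over
# characters, unlike the implementation's split-and-merge)
oracle_scan_text <- function(txt) {
  delim <- substr(txt, 1, 1)
  chars <- strsplit(substr(txt, 2, nchar(txt)), "")[[1]]
  tokens <- character(0)
  cur <- ""
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == delim) {
      if (i < length(chars) && chars[i + 1] == delim) {
        cur <- paste0(cur, delim)
        i <- i + 2
        next
      }
      tokens <- c(tokens, cur)
      cur <- ""
    } else {
      cur <- paste0(cur, ch)
    }
    i <- i + 1
  }
  keys <- tokens[seq(1, length(tokens), by = 2)]
  vals <- tokens[seq(2, length(tokens), by = 2)]
  stats::setNames(vals, keys)
}

# hand-build a small FCS file with arbitrary $PnE/$DATATYPE/$BYTEORD --
# independent of the package's writer
build_raw_fcs <- function(path, values, pne = NULL, pnr = NULL,
                          datatype = "F", byteord = "1,2,3,4",
                          extra_kw = character(0), kw_order_rev = FALSE) {
  n <- nrow(values); d <- ncol(values)
  if (is.null(pne)) pne <- rep("0,0", d)
  if (is.null(pnr)) pnr <- rep(1024, d)
  delim <- "\\"
  kv <- c("$MODE", "L", "$DATATYPE", datatype, "$BYTEORD", byteord,
          "$TOT", as.character(n), "$PAR", as.character(d), extra_kw)
  for (j in seq_len(d)) {
    kv <- c(kv, sprintf("$P%dN", j), paste0("CH", j),
            sprintf("$P%dB", j), if (datatype == "D") "64" else "32",
            sprintf("$P%dE", j), pne[j],
            sprintf("$P%dR", j), as.character(pnr[j]))
  }
  if (kw_order_rev) {
    idx <- seq(1, length(kv), by = 2)
    ord <- rev(seq_along(idx))
    kv <- as.vector(rbind(kv[idx][ord], kv[idx + 1][ord]))
  }
  sz <- if (datatype == "D") 8L else 4L
  data_len <- sz * n * d
  build_text <- function(beg)
    paste0(delim, paste0(c(rbind(
      c("$BEGINDATA", "$ENDDATA"),
      c(format(beg, scientific = FALSE),
        format(beg + data_len - 1, scientific = FALSE)))), delim,
      collapse = ""),
      paste0(kv, delim, collapse = ""))
  beg <- 58 + nchar(build_text(1))
  repeat {
    txt <- build_text(beg)
    b2 <- 58 + nchar(txt)
    if (b2 == beg) break
    beg <- b2
  }
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    58L, 58L + nchar(txt) - 1L, beg, beg + data_len - 1L, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  endian <- if (byteord == "4,3,2,1") "big" else "little"
  if (datatype == "I") {
    writeBin(as.integer(t(values)), con, size = 4L, endian = endian)
  } else {
    writeBin(as.vector(t(values)), con, size = sz, endian = endian)
  }
  invisible(path)
}

# small well-separated isotropic blobs for recovery tests
make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  colnames(X) <- c("X", "Y")
  event_table(X)
}
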