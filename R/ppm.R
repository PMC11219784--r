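# Netpbm reader/writer (P2/P3 ASCII, P5/P6 binary, 8- and 16-bit).
# STARE distributes fundus images as .ppm, which none of the raster packages
# used elsewhere in this package read.

readPNM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readToken <- function() {
    tok <- character()
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L)
        stop("unexpected end of PNM file: ", path, call. = FALSE)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("^[[:space:]]$", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- readToken()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path, call. = FALSE)
  W <- as.integer(readToken()); H <- as.integer(readToken())
  maxval <- as.integer(readToken())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- W * H * nch
  if (magic %in% c("P2", "P3")) {
    vals <- numeric(n)
    for (i in seq_len(n)) vals[i] <- as.numeric(readToken())
  } else {
    if (maxval < 256L) {
      vals <- as.numeric(readBin(con, "integer", n = n, size = 1L,
        signed = FALSE))
    } else {
      # 16-bit samples are big-endian per the Netpbm spec
      vals <- as.numeric(readBin(con, "integer", n = n, size = 2L,
        signed = FALSE, endian = "big"))
    }
  }
  if (length(vals) < n)
    stop("truncated PNM payload in ", path, call. = FALSE)
  # samples are row-major, channel-interleaved
  a <- array(vals / maxval, c(nch, W, H))
  a <- aperm(a, c(3, 2, 1))  # -> H x W x C
  if (nch == 1L) a <- array(rep(a, 3L), c(H, W, 3L))
  a
}

writePNM <- function(img, path, maxval = 255L) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  H <- dim(img)[1]; W <- dim(img)[2]
  writeChar(sprintf("P6\n%d %d\n%d\n", W, H, maxval), con, eos = NULL)
  vals <- as.integer(round(aperm(img, c(3, 2, 1)) * maxval))
  writeBin(vals, con, size = 1L)
  invisible(path)
}
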