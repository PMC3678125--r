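## Internal helpers: delimited-text parsing and a minimal ZIP writer.

#' @import methods
#' @importFrom stats rnorm runif var integrate qnorm dnorm sd fft dist
#' @importFrom utils unzip read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Parse a whitespace/tab/comma-delimited numeric matrix from a text file.
## Delimiter is auto-detected; lines starting with '#' are ignored.
.readDelimMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("file '", basename(path), "' contains no data", call. = FALSE)
  sep <- if (any(grepl(",", lines))) "," else ""
  rows <- lapply(lines, function(ln) {
    fields <- if (identical(sep, ",")) strsplit(trimws(ln), "\\s*,\\s*")[[1]]
              else strsplit(trimws(ln), "\\s+")[[1]]
    suppressWarnings(as.numeric(fields))
  })
  ncols <- vapply(rows, length, integer(1))
  if (length(unique(ncols)) != 1L)
    stop("ragged rows in '", basename(path), "'", call. = FALSE)
  m <- do.call(rbind, rows)
  if (anyNA(m))
    stop("non-numeric entries in '", basename(path), "'", call. = FALSE)
  m
}

## ---- CRC-32 and stored-entry ZIP writing --------------------------------
## R integers are signed 32-bit, so the CRC state is carried as a double in
## [0, 2^32) and xor is done on 16-bit halves.

.crcEnv <- new.env(parent = emptyenv())

.bxor32 <- function(a, b) {
  xh <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  xl <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  xh * 65536 + xl
}

.crc32 <- function(raw) {
  if (is.null(.crcEnv$table)) {
    poly <- 3988292384  # 0xEDB88320, reflected IEEE 802.3 polynomial
    t <- numeric(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (c %% 2 == 1) .bxor32(poly, c %/% 2) else c %/% 2
      t[n + 1] <- c
    }
    .crcEnv$table <- t
  }
  t <- .crcEnv$table
  crc <- 4294967295
  for (b in as.integer(raw)) {
    idx <- .bxor32(crc %% 256, b) %% 256
    crc <- .bxor32(t[idx + 1], crc %/% 256)
  }
  .bxor32(crc, 4294967295)
}

## little-endian byte encoding of a non-negative double
.le <- function(x, nbytes) {
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

#' Write files into a ZIP archive without external tools
#'
#' Creates a ZIP archive containing the given files as stored (uncompressed)
#' entries. Used to package connectome archives for [readConnectomeZip()];
#' reading goes through [utils::unzip()].
#'
#' @param zipfile output path.
#' @param files character vector of file paths; entry names are the basenames.
#' @return `zipfile`, invisibly.
#' @export
writeStoredZip <- function(zipfile, files) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  crcs <- numeric(length(files))
  sizes <- numeric(length(files))
  names <- basename(files)
  pos <- 0
  for (i in seq_along(files)) {
    data <- readBin(files[i], "raw", n = file.info(files[i])$size)
    crcs[i] <- .crc32(data)
    sizes[i] <- length(data)
    offsets[i] <- pos
    nm <- charToRaw(names[i])
    hdr <- c(.le(67324752, 4),        # local file header signature
             .le(20, 2), .le(0, 2),   # version needed, flags
             .le(0, 2),               # method 0: stored
             .le(0, 2), .le(0, 2),    # mod time, mod date
             .le(crcs[i], 4),
             .le(sizes[i], 4), .le(sizes[i], 4),
             .le(length(nm), 2), .le(0, 2))
    writeBin(c(hdr, nm, data), con)
    pos <- pos + length(hdr) + length(nm) + length(data)
  }
  cdStart <- pos
  cdSize <- 0
  for (i in seq_along(files)) {
    nm <- charToRaw(names[i])
    cd <- c(.le(33639248, 4),         # central directory signature
            .le(20, 2), .le(20, 2), .le(0, 2), .le(0, 2),
            .le(0, 2), .le(0, 2),
            .le(crcs[i], 4), .le(sizes[i], 4), .le(sizes[i], 4),
            .le(length(nm), 2), .le(0, 2), .le(0, 2),
            .le(0, 2), .le(0, 2), .le(0, 4),
            .le(offsets[i], 4))
    writeBin(c(cd, nm), con)
    cdSize <- cdSize + length(cd) + length(nm)
  }
  eocd <- c(.le(101010256, 4), .le(0, 2), .le(0, 2),
            .le(length(files), 2), .le(length(files), 2),
            .le(cdSize, 4), .le(cdStart, 4), .le(0, 2))
  writeBin(eocd, con)
  invisible(zipfile)
}

.assertScalarNumeric <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be positive", call. = FALSE)
  invisible(x)
}
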