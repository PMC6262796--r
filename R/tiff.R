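# Minimal baseline TIFF 6.0 codec.
#
# Scope: grayscale, uncompressed, 8/16/32-bit unsigned, multi-page; this is
# the dialect confocal exports and ImageJ-style stacks reduce to once
# uncompressed. The writer emits little-endian files with one strip per page
# and a JSON geometry block in the first page's ImageDescription; the reader
# accepts either byte order and arbitrary strip layouts. Anything fancier
# (compression, tiles, palettes, proprietary microscope formats) is out of
# scope and rejected with a clear error.

# unsigned integer vector -> little-endian raw
.le_raw <- function(x, nbytes) {
  x <- as.numeric(x)
  out <- raw(length(x) * nbytes)
  for (b in seq_len(nbytes)) {
    out[seq(b, by = nbytes, length.out = length(x))] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# raw (concatenated uints) -> numeric vector
.raw_uint <- function(r, nbytes, little = TRUE) {
  n <- length(r) %/% nbytes
  m <- matrix(as.numeric(r[seq_len(n * nbytes)]), nrow = nbytes)
  mult <- 256^(0:(nbytes - 1))
  if (!little) mult <- rev(mult)
  as.numeric(crossprod(m, mult))
}

.tiff_type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8)

#' Write a multi-page grayscale TIFF
#'
#' Baseline, uncompressed, little-endian; one strip per page. Used internally
#' by [write_stack()] and [write_label_map()].
#'
#' @param pages list of integer matrices, each dim `(ny, nx)`, all equal size.
#' @param path output file path.
#' @param bits bits per sample: 8, 16 or 32.
#' @param description optional character scalar stored as ImageDescription of
#'   the first page (gutcount stores its geometry JSON here).
#' @return `path`, invisibly.
#' @export
tiff_write <- function(pages, path, bits = 16L, description = NULL) {
  if (!length(pages)) stop("no pages to write")
  if (!bits %in% c(8L, 16L, 32L)) stop("bits must be 8, 16 or 32")
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  maxval <- 2^bits - 1
  bps <- bits %/% 8L
  npage <- length(pages)

  desc_raw <- raw(0)
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(as.character(description)[1L]), as.raw(0L))
    if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))
  }

  page_bytes <- ny * nx * bps
  ntags_first <- 10L + as.integer(length(desc_raw) > 0)
  ntags_rest <- 10L
  ifd_size <- function(ntags) 2L + 12L * ntags + 4L

  # layout: header | desc | [data_i | ifd_i] ...
  desc_off <- 8L
  offs <- vector("list", npage)
  cur <- desc_off + length(desc_raw)
  for (i in seq_len(npage)) {
    ntags <- if (i == 1L) ntags_first else ntags_rest
    offs[[i]] <- list(data = cur, ifd = cur + page_bytes,
                      next_ifd = cur + page_bytes + ifd_size(ntags))
    cur <- offs[[i]]$next_ifd
  }

  tag <- function(id, type, count, value, is_offset = FALSE) {
    # value fits in 4 bytes unless is_offset
    sz <- .tiff_type_size[[as.character(type)]]
    val_raw <- if (is_offset) {
      .le_raw(value, 4)
    } else {
      v <- .le_raw(value, sz)
      c(v, raw(4L - length(v)))
    }
    c(.le_raw(id, 2), .le_raw(type, 2), .le_raw(count, 4), val_raw)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .le_raw(42, 2), .le_raw(offs[[1L]]$ifd, 4)), con)
  if (length(desc_raw)) writeBin(desc_raw, con)

  for (i in seq_len(npage)) {
    pg <- pages[[i]]
    if (nrow(pg) != ny || ncol(pg) != nx) stop("pages differ in size")
    v <- as.vector(t(pg))          # row-major: x fastest
    if (any(v < 0) || any(v > maxval)) {
      stop(sprintf("pixel values outside [0, %d] for %d-bit output",
                   maxval, bits))
    }
    writeBin(.le_raw(v, bps), con)

    tags <- list(
      tag(256, 4, 1, nx),                 # ImageWidth
      tag(257, 4, 1, ny),                 # ImageLength
      tag(258, 3, 1, bits),               # BitsPerSample
      tag(259, 3, 1, 1),                  # Compression = none
      tag(262, 3, 1, 1)                   # Photometric = BlackIsZero
    )
    if (i == 1L && length(desc_raw)) {
      tags <- c(tags, list(tag(270, 2, length(desc_raw), desc_off,
                               is_offset = TRUE)))
    }
    tags <- c(tags, list(
      tag(273, 4, 1, offs[[i]]$data),     # StripOffsets
      tag(277, 3, 1, 1),                  # SamplesPerPixel
      tag(278, 4, 1, ny),                 # RowsPerStrip
      tag(279, 4, 1, page_bytes),         # StripByteCounts
      tag(339, 3, 1, 1)                   # SampleFormat = unsigned
    ))
    nxt <- if (i < npage) offs[[i + 1L]]$ifd else 0L
    writeBin(c(.le_raw(length(tags), 2), do.call(c, tags), .le_raw(nxt, 4)),
             con)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Accepts baseline uncompressed grayscale TIFFs in either byte order.
#'
#' @param path TIFF file path.
#' @return list with `pages` (list of numeric `(ny, nx)` matrices),
#'   `bits`, and `description` (character or `NULL`).
#' @export
tiff_read <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 8L) stop("not a TIFF file (too short)")
  order_tag <- rawToChar(r[1:2])
  little <- order_tag == "II"
  if (!little && order_tag != "MM") stop("not a TIFF file (bad byte order)")
  u <- function(off, nbytes) .raw_uint(r[(off + 1):(off + nbytes)], nbytes,
                                       little)
  if (u(2, 2) != 42) stop("not a TIFF file (bad magic)")

  pages <- list()
  description <- NULL
  ifd_off <- u(4, 4)
  while (ifd_off != 0) {
    ntags <- u(ifd_off, 2)
    tags <- list()
    for (t in seq_len(ntags)) {
      base <- ifd_off + 2 + 12 * (t - 1)
      id <- u(base, 2); type <- u(base + 2, 2); count <- u(base + 4, 4)
      sz <- .tiff_type_size[as.character(type)]
      if (is.na(sz)) next
      total <- sz * count
      voff <- if (total <= 4) base + 8 else u(base + 8, 4)
      vals <- if (type == 2) {
        chr <- r[(voff + 1):(voff + count)]
        rawToChar(chr[chr != as.raw(0)])
      } else if (type == 5) {
        num <- .raw_uint(r[(voff + 1):(voff + total)], 4, little)
        num[c(TRUE, FALSE)] / num[c(FALSE, TRUE)]
      } else {
        .raw_uint(r[(voff + 1):(voff + total)], sz, little)
      }
      tags[[as.character(id)]] <- vals
    }
    need <- function(id) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) stop(sprintf("TIFF missing required tag %d", id))
      v
    }
    nx <- need(256); ny <- need(257)
    bits <- if (is.null(tags[["258"]])) 1 else tags[["258"]][1]
    comp <- if (is.null(tags[["259"]])) 1 else tags[["259"]]
    fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]][1]
    spp <- if (is.null(tags[["277"]])) 1 else tags[["277"]]
    if (comp != 1) stop("only uncompressed TIFF is supported")
    if (spp != 1) stop("only single-sample (grayscale) TIFF is supported")
    if (fmt != 1) stop("only unsigned-integer TIFF samples are supported")
    if (!bits %in% c(8, 16, 32)) {
      stop(sprintf("unsupported bit depth: %s", bits))
    }
    strip_off <- need(273)
    strip_cnt <- need(279)
    data <- do.call(c, lapply(seq_along(strip_off), function(s) {
      r[(strip_off[s] + 1):(strip_off[s] + strip_cnt[s])]
    }))
    v <- .raw_uint(data, bits / 8, little)
    if (length(v) < nx * ny) stop("truncated TIFF page data")
    pages[[length(pages) + 1L]] <- t(matrix(v[seq_len(nx * ny)], nrow = nx))
    if (is.null(description) && !is.null(tags[["270"]])) {
      description <- tags[["270"]]
    }
    ifd_off <- u(ifd_off + 2 + 12 * ntags, 4)
  }
  list(pages = pages, bits = bits, description = description)
}
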