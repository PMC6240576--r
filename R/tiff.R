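# Minimal baseline TIFF support for 8-bit grayscale multi-page stacks.
# Written by hand because no TIFF package is available in the target
# library; covers exactly the subset this package writes (little-endian,
# uncompressed, one strip per page) and reads back any uncompressed 8-bit
# single-sample grayscale TIFF.

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

ifd_entry <- function(tag, type, count, value) {
  c(u16le(tag), u16le(type), u32le(count), u32le(value))
}

#' Write a list of frames as a multi-page 8-bit grayscale TIFF
#'
#' Baseline little-endian TIFF, uncompressed, one strip per page. Values are
#' clamped to 0-255 and rounded.
#'
#' @param frames List of numeric/integer matrices (`height x width`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_tiff_stack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!length(frames) || !all(vapply(frames, is.matrix, logical(1))))
    pc_stop_validation("`frames` must be a non-empty list of matrices")
  sizes <- vapply(frames, length, integer(1))
  data_offsets <- 8 + cumsum(c(0, sizes[-length(sizes)]))
  first_ifd <- 8 + sum(sizes)
  n_entries <- 9L
  ifd_size <- 2 + n_entries * 12 + 4

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16le(42L), u32le(first_ifd)), con)
  for (f in frames) {
    px <- pmin(pmax(round(f), 0), 255)
    writeBin(as.raw(as.integer(t(px))), con)  # row-major strip
  }
  for (p in seq_along(frames)) {
    h <- nrow(frames[[p]]); w <- ncol(frames[[p]])
    nxt <- if (p < length(frames)) first_ifd + p * ifd_size else 0L
    ifd <- c(u16le(n_entries),
             ifd_entry(256L, 4L, 1L, w),                 # ImageWidth
             ifd_entry(257L, 4L, 1L, h),                 # ImageLength
             ifd_entry(258L, 3L, 1L, 8L),                # BitsPerSample
             ifd_entry(259L, 3L, 1L, 1L),                # no compression
             ifd_entry(262L, 3L, 1L, 1L),                # BlackIsZero
             ifd_entry(273L, 4L, 1L, data_offsets[p]),   # StripOffsets
             ifd_entry(277L, 3L, 1L, 1L),                # SamplesPerPixel
             ifd_entry(278L, 4L, 1L, h),                 # RowsPerStrip
             ifd_entry(279L, 4L, 1L, w * h),             # StripByteCounts
             u32le(nxt))
    writeBin(ifd, con)
  }
  invisible(path)
}

rd_u16 <- function(raw, pos, le) {
  b <- as.integer(raw[pos + 0:1])
  if (le) b[1] + 256 * b[2] else b[2] + 256 * b[1]
}
rd_u32 <- function(raw, pos, le) {
  b <- as.integer(raw[pos + 0:3])
  if (!le) b <- rev(b)
  b[1] + 256 * (b[2] + 256 * (b[3] + 256 * b[4]))
}

# Read a tag value array given an IFD entry starting at `pos`.
rd_values <- function(raw, pos, le) {
  type <- rd_u16(raw, pos + 2, le)
  count <- rd_u32(raw, pos + 4, le)
  # only SHORT/LONG tags matter here; others (ASCII, RATIONAL, ...) skipped
  sz <- switch(as.character(type), "3" = 2L, "4" = 4L, return(NULL))
  rd1 <- if (sz == 2L) rd_u16 else rd_u32
  if (count * sz <= 4) {
    vapply(seq_len(count) - 1L, function(i) rd1(raw, pos + 8 + i * sz, le),
           numeric(1))
  } else {
    off <- rd_u32(raw, pos + 8, le)
    vapply(seq_len(count) - 1L, function(i) rd1(raw, off + 1 + i * sz, le),
           numeric(1))
  }
}

#' Read a multi-page 8-bit grayscale TIFF
#'
#' Supports uncompressed baseline grayscale (single sample, 8 bits), either
#' byte order, any strip layout.
#'
#' @param path TIFF file path.
#' @return List of integer matrices (`height x width`).
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  order <- rawToChar(raw[1:2])
  le <- order == "II"
  if (!le && order != "MM") pc_stop_validation("not a TIFF file")
  if (rd_u16(raw, 3, le) != 42L) pc_stop_validation("not a TIFF file")
  ifd_off <- rd_u32(raw, 5, le)
  frames <- list()
  while (ifd_off != 0) {
    pos <- ifd_off + 1
    n <- rd_u16(raw, pos, le)
    tags <- list()
    for (i in seq_len(n)) {
      ep <- pos + 2 + (i - 1) * 12
      v <- rd_values(raw, ep, le)
      if (!is.null(v)) tags[[as.character(rd_u16(raw, ep, le))]] <- v
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    if ((tags[["259"]] %||% 1) != 1)
      pc_stop("compressed TIFF not supported")
    if ((tags[["258"]] %||% 1) != 8 || (tags[["277"]] %||% 1) != 1)
      pc_stop("only 8-bit single-sample grayscale TIFF is supported")
    offs <- tags[["273"]]
    counts <- tags[["279"]]
    bytes <- unlist(lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1):(offs[i] + counts[i])]))
    m <- matrix(as.integer(bytes), nrow = h, ncol = w, byrow = TRUE)
    frames[[length(frames) + 1L]] <- m
    ifd_off <- rd_u32(raw, pos + 2 + n * 12, le)
  }
  frames
}
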