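# Minimal baseline TIFF 6.0 codec: uncompressed grayscale, 8/16-bit unsigned
# or 32-bit float, multi-page, single plane per page.  Written because the
# deployment R stack ships no TIFF package; covers exactly what the pipeline
# needs (ImageJ/tifffile read these files fine).  Little-endian on write;
# both byte orders on read.  Multi-strip files are supported on read.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, ImageDescription = 270L,
               StripOffsets = 273L, SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

# --- writer -----------------------------------------------------------------

# pages: list of numeric matrices (y, x); bits: 8, 16 or 32 (32 = float);
# description: character scalar attached to the first page.
write_tiff_pages <- function(path, pages, bits, description = NULL) {
  stopifnot(bits %in% c(8L, 16L, 32L), length(pages) >= 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  writeChar("II", con, 2, eos = NULL)
  w(42L, 2)
  # compute layout: header(8) + pixel data for all pages + IFDs at the end
  bytespp <- bits / 8L
  sizes <- vapply(pages, function(p) as.numeric(length(p)) * bytespp, 0)
  data_off <- 8 + cumsum(c(0, sizes[-length(sizes)]))
  desc_raw <- NULL
  desc_off <- 0
  pos <- 8 + sum(sizes)
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0L))
    if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0L))
    desc_off <- pos
    pos <- pos + length(desc_raw)
  }
  ifd_off <- pos
  w(as.integer(ifd_off), 4)
  # pixel data (row-major per page)
  for (i in seq_along(pages)) {
    v <- as.vector(t(pages[[i]]))
    if (bits == 32L) {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      v <- as.integer(round(v))
      if (any(v < 0) || any(v >= 2^bits))
        stopf("intensity out of range for %d-bit TIFF output", bits)
      if (bits == 8L) {
        writeBin(as.raw(v), con)
      } else {
        # writeBin size=2 requires signed range; map via two's complement
        v[v >= 32768L] <- v[v >= 32768L] - 65536L
        writeBin(v, con, size = 2, endian = "little")
      }
    }
  }
  if (!is.null(desc_raw)) writeBin(desc_raw, con)
  # IFDs
  n_pages <- length(pages)
  ifd_sizes <- integer(n_pages)
  for (i in seq_len(n_pages)) {
    n_entries <- 10L + (i == 1L && !is.null(desc_raw))
    ifd_sizes[i] <- 2L + n_entries * 12L + 4L
  }
  ifd_offs <- ifd_off + cumsum(c(0L, ifd_sizes[-n_pages]))
  entry <- function(tag, type, count, value) {
    w(as.integer(tag), 2); w(as.integer(type), 2); w(as.integer(count), 4)
    if (type == 3L && count == 1L) { w(as.integer(value), 2); w(0L, 2) }
    else w(as.integer(value), 4)
  }
  fmt <- if (bits == 32L) 3L else 1L
  for (i in seq_len(n_pages)) {
    p <- pages[[i]]
    has_desc <- (i == 1L && !is.null(desc_raw))
    w(as.integer(10L + has_desc), 2)
    entry(256, 3, 1, ncol(p))                     # ImageWidth
    entry(257, 3, 1, nrow(p))                     # ImageLength
    entry(258, 3, 1, bits)                        # BitsPerSample
    entry(259, 3, 1, 1)                           # no compression
    entry(262, 3, 1, 1)                           # BlackIsZero
    if (has_desc) entry(270, 2, length(desc_raw), desc_off)
    entry(273, 4, 1, data_off[i])                 # StripOffsets
    entry(277, 3, 1, 1)                           # SamplesPerPixel
    entry(278, 3, 1, nrow(p))                     # RowsPerStrip (one strip)
    entry(279, 4, 1, sizes[i])                    # StripByteCounts
    entry(339, 3, 1, fmt)                         # SampleFormat
    w(if (i < n_pages) as.integer(ifd_offs[i + 1]) else 0L, 4)
  }
  invisible(path)
}

# --- reader -----------------------------------------------------------------

# Returns list(pages = list of matrices, bits, description or NULL).
read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stopf("not a TIFF file: %s", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stopf("not a TIFF file: %s", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
    if (v < 0) v + 2^32 else v
  }
  if (u16(2) != 42L) stopf("bad TIFF magic in %s", path)
  type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
  read_values <- function(off) {  # off = entry start (0-based)
    type <- u16(off + 2); count <- u32(off + 4)
    nbytes <- type_size[type] * count
    voff <- if (nbytes <= 4) off + 8 else u32(off + 8)
    if (type == 3L) vapply(seq_len(count) - 1L, function(k) u16(voff + 2 * k), 0L)
    else if (type == 4L) vapply(seq_len(count) - 1L, function(k) u32(voff + 4 * k), 0)
    else if (type == 2L) rawToChar(raw[(voff + 1):(voff + count)][
      raw[(voff + 1):(voff + count)] != as.raw(0)])
    else if (type == 1L) as.integer(raw[(voff + 1):(voff + count)])
    else stopf("unsupported TIFF tag type %d", type)
  }
  pages <- list()
  bits <- NULL; fmt <- 1L; descr <- NULL
  ifd <- u32(4)
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2 + (e - 1) * 12
      tags[[as.character(u16(off))]] <- off
    }
    gv <- function(tag, default = NULL) {
      o <- tags[[as.character(TIFF_TAGS[[tag]])]]
      if (is.null(o)) default else read_values(o)
    }
    if (!identical(gv("Compression", 1L)[1], 1L) &&
        !identical(gv("Compression", 1L)[1], 1))
      stopf("compressed TIFF not supported: %s", path)
    wdt <- gv("ImageWidth"); hgt <- gv("ImageLength")
    if (is.null(wdt) || is.null(hgt)) stopf("TIFF page missing dimensions")
    b <- gv("BitsPerSample", 8L)[1]
    if (!b %in% c(8, 16, 32)) stopf("unsupported BitsPerSample %d", b)
    if (is.null(bits)) bits <- b else if (bits != b)
      stopf("mixed bit depths across pages")
    fmt <- gv("SampleFormat", 1L)[1]
    if (!fmt %in% c(1, 3)) stopf("unsupported SampleFormat %d", fmt)
    d <- gv("ImageDescription")
    if (!is.null(d) && is.null(descr)) descr <- d
    offs <- gv("StripOffsets"); cnts <- gv("StripByteCounts")
    if (is.null(offs)) stopf("TIFF page missing strip offsets")
    if (is.null(cnts)) cnts <- rep(wdt * hgt * b / 8 / length(offs), length(offs))
    buf <- unlist(lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1):(offs[i] + cnts[i])]), use.names = FALSE)
    v <- if (b == 8) {
      as.integer(buf)
    } else if (b == 16) {
      x <- readBin(buf, "integer", n = wdt * hgt, size = 2, signed = FALSE,
                   endian = endian)
      x
    } else if (fmt == 3) {
      readBin(buf, "numeric", n = wdt * hgt, size = 4, endian = endian)
    } else {
      x <- readBin(buf, "integer", n = wdt * hgt, size = 4, endian = endian)
      ifelse(x < 0, x + 2^32, x)
    }
    pages[[length(pages) + 1L]] <- matrix(v, nrow = hgt, ncol = wdt, byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12)
  }
  list(pages = pages, bits = as.integer(bits), description = descr)
}

# --- stack-level interface ---------------------------------------------------

#' Write a multi-channel image stack to TIFF
#'
#' Channels are interleaved channel-fastest across pages (page = c + C*z, the
#' ImageJ hyperstack slice order), with voxel sizes, channel names and shape
#' recorded in a JSON ImageDescription so that \code{\link{read_stack}} can
#' restore the stack without external metadata.
#'
#' @param grids a single \code{voxel_grid} or a list of them (equal shapes and
#'   voxel sizes).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_stack <- function(grids, path) {
  if (inherits(grids, "voxel_grid")) grids <- list(grids)
  stopifnot(length(grids) >= 1L, all(vapply(grids, inherits, TRUE, "voxel_grid")))
  d <- dim(grids[[1]]$data)
  for (g in grids) {
    if (!identical(dim(g$data), d)) stopf("channel shapes differ")
    if (!identical(g$voxel_size, grids[[1]]$voxel_size)) stopf("voxel sizes differ")
  }
  bits <- max(vapply(grids, function(g) g$bit_origin, 0L))
  meta <- jsonlite::toJSON(list(
    nucland = TRUE, shape = d, n_channels = length(grids),
    voxel_size_nm = grids[[1]]$voxel_size,
    channels = vapply(grids, function(g) g$channel_name, ""),
    bit_origin = bits, page_order = "channel_fastest"),
    auto_unbox = TRUE, digits = NA)
  pages <- vector("list", d[1] * length(grids))
  k <- 0L
  for (z in seq_len(d[1]))
    for (g in grids) {
      k <- k + 1L
      pages[[k]] <- g$data[z, , , drop = TRUE]
    }
  write_tiff_pages(path, pages, bits = bits, description = as.character(meta))
  invisible(path)
}

#' Read a multi-channel 3D stack from TIFF
#'
#' Reads TIFF volumes written by \code{\link{write_stack}} (self-describing via
#' their JSON ImageDescription) or plain multi-page grayscale TIFFs, in which
#' case \code{voxel_size} must be supplied and \code{channel_layout} determines
#' how pages are de-interleaved (channel-fastest).
#'
#' @param path TIFF file.
#' @param channel_layout named mapping of 0-based channel index to channel
#'   name, e.g. \code{c("0" = "DAPI", "1" = "H3K4me3")}; defaults to embedded
#'   metadata.
#' @param voxel_size (dz, dy, dx) in nm; required if the file has no embedded
#'   voxel metadata.
#' @return named list of \code{voxel_grid}, one per channel.
#' @export
read_stack <- function(path, channel_layout = NULL, voxel_size = NULL) {
  tf <- read_tiff_pages(path)
  meta <- NULL
  if (!is.null(tf$description) && grepl("\"nucland\"", tf$description, fixed = TRUE))
    meta <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e) NULL)
  if (is.null(voxel_size)) {
    if (is.null(meta)) stopf("missing voxel-size metadata: supply voxel_size = c(dz, dy, dx) nm")
    voxel_size <- meta$voxel_size_nm
  }
  n_pages <- length(tf$pages)
  if (!is.null(meta)) {
    n_ch <- meta$n_channels
    ch_names <- meta$channels
  } else if (!is.null(channel_layout)) {
    n_ch <- length(channel_layout)
    ch_names <- as.character(channel_layout)
  } else {
    n_ch <- 1L
    ch_names <- "ch0"
  }
  if (!is.null(channel_layout)) {
    if (!is.null(meta) && length(channel_layout) != meta$n_channels)
      stopf("channel_layout names %d channels but file holds %d",
            length(channel_layout), meta$n_channels)
    ch_names <- as.character(channel_layout)
    n_ch <- length(channel_layout)
  }
  if (n_pages %% n_ch != 0L)
    stopf("channel count mismatch: %d pages not divisible by %d channels",
          n_pages, n_ch)
  nz <- n_pages %/% n_ch
  ny <- nrow(tf$pages[[1]]); nx <- ncol(tf$pages[[1]])
  out <- vector("list", n_ch)
  for (c in seq_len(n_ch)) {
    a <- array(0, c(nz, ny, nx))
    for (z in seq_len(nz)) a[z, , ] <- tf$pages[[(z - 1L) * n_ch + c]]
    out[[c]] <- voxel_grid(a, voxel_size = voxel_size,
                           channel_name = ch_names[c], bit_origin = tf$bits)
  }
  names(out) <- ch_names
  out
}

#' Write a nuclear mask as 8-bit TIFF (0/255) with a JSON sidecar
#'
#' @param mask a \code{nuclear_mask}.
#' @param path output TIFF path; the sidecar is written to \code{<path>.json}.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  g <- voxel_grid(array(ifelse(mask$data, 255, 0), dim(mask$data)),
                  voxel_size = mask$voxel_size, channel_name = "mask",
                  bit_origin = 8L)
  write_stack(g, path)
  idx <- which(mask$data, arr.ind = TRUE)
  sidecar <- list(nucleus_id = mask$nucleus_id,
                  n_voxels = sum(mask$data),
                  voxel_size_nm = mask$voxel_size,
                  bounding_box = list(zmin = min(idx[, 1]), zmax = max(idx[, 1]),
                                      ymin = min(idx[, 2]), ymax = max(idx[, 2]),
                                      xmin = min(idx[, 3]), xmax = max(idx[, 3])))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a nuclear mask written by \code{\link{write_mask}}
#'
#' @param path TIFF path (positive pixels become foreground).
#' @param voxel_size optional override, nm.
#' @return a \code{nuclear_mask}.
#' @export
read_mask <- function(path, voxel_size = NULL) {
  g <- read_stack(path, voxel_size = voxel_size)[[1]]
  id <- 1L
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    side <- tryCatch(jsonlite::fromJSON(sc), error = function(e) NULL)
    if (!is.null(side$nucleus_id)) id <- as.integer(side$nucleus_id)
  }
  nuclear_mask(g$data > 0, voxel_size = g$voxel_size, nucleus_id = id,
               check = FALSE)
}
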