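#' Single-channel 3D image with anisotropic voxel sizes
#'
#' The basic image container: a non-negative 3D intensity array in
#' \code{(z, y, x)} order plus the physical voxel edge lengths
#' \code{(dz, dy, dx)} in nanometres.  The defaults used throughout
#' correspond to 3D-SIM sampling (125 nm axial, 39.5 nm lateral).
#'
#' @param data numeric 3D array, (z, y, x) order, finite and >= 0.
#' @param voxel_size numeric length-3, physical voxel edges (dz, dy, dx) in nm.
#' @param channel_name free-text channel label.
#' @param bit_origin original bit depth of the source data (8, 16 or 32).
#' @return an object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(data, voxel_size = c(125, 39.5, 39.5),
                       channel_name = "DAPI", bit_origin = 16L) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stopf("voxel_grid data must be a 3D array")
  if (anyNA(data) || any(!is.finite(data)) || any(data < 0))
    stopf("voxel_grid intensities must be finite and non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stopf("voxel_size must be 3 strictly positive values (dz, dy, dx) in nm")
  if (!bit_origin %in% c(8L, 16L, 32L)) stopf("bit_origin must be 8, 16 or 32")
  structure(list(data = data, voxel_size = voxel_size,
                 channel_name = as.character(channel_name)[1],
                 bit_origin = as.integer(bit_origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid '%s'> %d x %d x %d (z,y,x), voxel %g x %g x %g nm, %d-bit origin\n",
              x$channel_name, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$bit_origin))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' Binary 3D nuclear mask
#'
#' A logical array sharing shape and voxel size with its source channel.
#' A valid mask has exactly one 26-connected foreground component (lobed
#' nuclei stay connected through their bridges) and does not touch the grid
#' boundary.
#'
#' @param data logical 3D array (z, y, x).
#' @param voxel_size physical voxel edges (dz, dy, dx) in nm.
#' @param nucleus_id integer identifier.
#' @param check validate connectivity and border clearance (default TRUE).
#' @return an object of class \code{nuclear_mask}.
#' @export
nuclear_mask <- function(data, voxel_size = c(125, 39.5, 39.5), nucleus_id = 1L,
                         check = TRUE) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stopf("nuclear_mask data must be a 3D array")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stopf("nuclear_mask must not contain NA")
  m <- structure(list(data = data, voxel_size = as.numeric(voxel_size),
                      nucleus_id = as.integer(nucleus_id)),
                 class = "nuclear_mask")
  if (check) validate_mask(m)
  m
}

validate_mask <- function(mask) {
  d <- dim(mask$data)
  if (!any(mask$data)) stopf("nuclear mask is empty")
  lab <- cpp_label3d(as.logical(mask$data), d, 26L)
  ncomp <- max(lab)
  if (ncomp != 1L)
    stopf("nuclear mask has %d 26-connected components (expected 1)", ncomp)
  if (mask_touches_border(mask$data))
    warnf("nuclear mask touches the volume border")
  invisible(mask)
}

mask_touches_border <- function(a) {
  d <- dim(a)
  any(a[1, , ]) || any(a[d[1], , ]) || any(a[, 1, ]) || any(a[, d[2], ]) ||
    any(a[, , 1]) || any(a[, , d[3]])
}

#' @export
print.nuclear_mask <- function(x, ...) {
  cat(sprintf("<nuclear_mask #%d> %s voxels foreground of %s\n",
              x$nucleus_id, format(sum(x$data), big.mark = ","),
              paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

#' Single 2D section image (TEM or SIM mid-section)
#'
#' @param data numeric 2D matrix of finite intensities.
#' @param pixel_size physical pixel edge in nm.
#' @param modality "TEM" or "SIM-midsection".
#' @return an object of class \code{section_image}.
#' @export
section_image <- function(data, pixel_size, modality = c("TEM", "SIM-midsection")) {
  modality <- match.arg(modality)
  data <- as.matrix(data)
  if (anyNA(data) || any(!is.finite(data))) stopf("section intensities must be finite")
  if (!is_scalar_num(pixel_size) || pixel_size <= 0) stopf("pixel_size must be > 0")
  structure(list(data = data, pixel_size = as.numeric(pixel_size),
                 modality = modality),
            class = "section_image")
}

# Intensities of `grid` restricted to mask voxels (vector, mask order).
masked_values <- function(grid, mask) {
  check_aligned(grid, mask)
  grid$data[mask$data]
}

check_aligned <- function(grid, mask) {
  if (!identical(dim(grid$data), dim(mask$data)))
    stopf("shape mismatch: grid %s vs mask %s",
          paste(dim(grid$data), collapse = "x"),
          paste(dim(mask$data), collapse = "x"))
  invisible(TRUE)
}
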