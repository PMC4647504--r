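# Pixel and spot quantification of punctate marker signals (RNA Pol II style).

#' Count marker-positive pixels inside the nuclear mask
#'
#' Sums the marker-positive voxels over the density classes; by construction
#' this equals the total number of positive voxels inside the mask (tested as
#' a cross-module conservation property).
#'
#' @param marker_positive logical array from \code{\link{threshold_marker}}.
#' @param classmap \code{class_map} of the nucleus.
#' @return integer count, with per-class counts in attribute
#'   \code{per_class}.
#' @export
count_positive_pixels <- function(marker_positive, classmap) {
  stopifnot(inherits(classmap, "class_map"))
  if (!identical(dim(marker_positive), dim(classmap$labels)))
    stopf("marker set and class map shapes differ")
  cls <- classmap$labels[marker_positive]
  if (any(cls == 0L))
    stopf("%d marker-positive voxels fall outside the class map", sum(cls == 0L))
  per_class <- tabulate(cls, nbins = classmap$params$K)
  structure(sum(per_class), per_class = per_class)
}

#' Detect discrete spots as regional intensity maxima
#'
#' A spot is a 26-connected regional maximum of the masked channel whose peak
#' intensity is at least \code{offset}.  A connected plateau of equal-valued
#' maxima contributes one spot at its intensity-weighted centroid.  With
#' \code{min_distance = 0} (the published setting) every regional maximum
#' counts; with \code{min_distance > 0} the lower-intensity member of any
#' pair closer than \code{min_distance} (physical distance, anisotropy-aware)
#' is suppressed.
#'
#' @param marker \code{voxel_grid}.
#' @param mask \code{nuclear_mask}, same shape.
#' @param offset minimum peak intensity (> 0).
#' @param min_distance minimum spot separation in nm (default 0).
#' @return a \code{spot_set}: data.frame of spot positions (nm, voxel-center
#'   coordinates, 0-based origin) and peak intensities, plus the offset used.
#' @export
find_spots <- function(marker, mask, offset, min_distance = 0) {
  stopifnot(inherits(marker, "voxel_grid"), inherits(mask, "nuclear_mask"))
  check_aligned(marker, mask)
  if (!is_scalar_num(offset) || offset <= 0) stopf("offset must be > 0")
  d <- dim(marker$data)
  vs <- marker$voxel_size
  lab <- cpp_regional_maxima(as.numeric(marker$data), as.logical(mask$data),
                             d, offset)
  n <- max(lab)
  if (n == 0L) {
    spots <- data.frame(z_nm = numeric(0), y_nm = numeric(0), x_nm = numeric(0),
                        peak = numeric(0))
  } else {
    idx <- which(lab > 0L)
    li <- lab[idx]
    w <- marker$data[idx]
    ai <- arrayInd(idx, d)
    wsum <- vapply(split(w, li), sum, 0)
    cz <- vapply(split(w * (ai[, 1] - 1) * vs[1], li), sum, 0) / wsum
    cy <- vapply(split(w * (ai[, 2] - 1) * vs[2], li), sum, 0) / wsum
    cx <- vapply(split(w * (ai[, 3] - 1) * vs[3], li), sum, 0) / wsum
    peak <- vapply(split(w, li), max, 0)
    spots <- data.frame(z_nm = cz, y_nm = cy, x_nm = cx, peak = peak)
    spots <- spots[order(-spots$peak, spots$z_nm, spots$y_nm, spots$x_nm), ]
    rownames(spots) <- NULL
    if (min_distance > 0 && nrow(spots) > 1L) {
      keep <- logical(nrow(spots))
      for (i in seq_len(nrow(spots))) {
        if (i == 1L) { keep[1] <- TRUE; next }
        kept <- spots[keep, , drop = FALSE]
        dd <- sqrt((kept$z_nm - spots$z_nm[i])^2 +
                   (kept$y_nm - spots$y_nm[i])^2 +
                   (kept$x_nm - spots$x_nm[i])^2)
        keep[i] <- all(dd >= min_distance)
      }
      spots <- spots[keep, , drop = FALSE]
      rownames(spots) <- NULL
    }
  }
  structure(list(spots = spots, offset_used = offset,
                 min_distance = min_distance, nucleus_id = mask$nucleus_id),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> %d spots (offset %.4g, min distance %g nm)\n",
              nrow(x$spots), x$offset_used, x$min_distance))
  invisible(x)
}
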