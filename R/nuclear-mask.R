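#' Generate a 3D nuclear mask from a DAPI channel
#'
#' Segmentation follows the standard recipe for counterstain masks: global
#' threshold on a Gaussian-smoothed copy (Otsu by default), retention of the
#' largest 26-connected component, morphological closing with a small ball,
#' and filling of enclosed cavities, with care taken that deep surface
#' invaginations that open to the exterior are preserved.  All voxels outside
#' the mask report intensity 0 in \code{\link{masked_view}}.
#'
#' Hole filling closes only cavities with no 3D path to the exterior
#' (6-connected background): interior lacunae become part of the mask, while
#' surface invaginations and tunnels that open to the outside stay open.
#'
#' @param dapi a \code{voxel_grid} containing one nucleus dominating the field.
#' @param threshold \code{"otsu"} (default) or an absolute intensity value.
#' @param smooth_sigma lateral smoothing sigma in voxels; the axial sigma is
#'   scaled by the voxel anisotropy so that smoothing is physically isotropic.
#' @param close_radius_nm radius of the closing ball, nm (0 disables).
#' @param nucleus_id integer id stored in the mask.
#' @return a \code{nuclear_mask}.
#' @export
generate_nuclear_mask <- function(dapi, threshold = "otsu", smooth_sigma = 2,
                                  close_radius_nm = 100, nucleus_id = 1L) {
  stopifnot(inherits(dapi, "voxel_grid"))
  vs <- dapi$voxel_size
  sig <- c(smooth_sigma * vs[3] / vs[1], smooth_sigma * vs[3] / vs[2], smooth_sigma)
  sm <- gaussian_blur3d(dapi$data, sig)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(as.vector(sm))
         else as.numeric(threshold)
  fg <- sm > thr
  if (!any(fg)) stopf("no nucleus found")
  d <- dim(fg)
  lab <- cpp_label3d(as.logical(fg), d, 26L)
  tab <- tabulate(lab[lab > 0L])
  fg <- array(lab == which.max(tab), d)
  if (close_radius_nm > 0) {
    r <- close_radius_nm
    dist_to_fg <- array(cpp_edt3d(as.logical(fg), d, vs), d)
    dil <- dist_to_fg <= r
    dist_to_bg <- array(cpp_edt3d(as.logical(!dil), d, vs), d)
    fg <- fg | (dist_to_bg > r)   # closing is extensive: union keeps original
  }
  fg <- fill_enclosed_cavities(fg)
  # closing/filling cannot split the component, but can merge satellites; keep largest
  lab <- cpp_label3d(as.logical(fg), d, 26L)
  if (max(lab) > 1L) {
    tab <- tabulate(lab[lab > 0L])
    fg <- array(lab == which.max(tab), d)
  }
  if (mask_touches_border(fg)) {
    warnf("nuclear mask touches the volume border; clearing a one-voxel shell")
    fg[c(1, d[1]), , ] <- FALSE
    fg[, c(1, d[2]), ] <- FALSE
    fg[, , c(1, d[3])] <- FALSE
    lab <- cpp_label3d(as.logical(fg), d, 26L)
    if (max(lab) >= 1L) {
      tab <- tabulate(lab[lab > 0L])
      fg <- array(lab == which.max(tab), d)
    }
  }
  if (!any(fg)) stopf("no nucleus found")
  nuclear_mask(fg, voxel_size = vs, nucleus_id = nucleus_id, check = FALSE)
}

# Fill background cavities with no 6-connected 3D path to the volume border;
# tunnels and invaginations open to the exterior are left untouched.
fill_enclosed_cavities <- function(fg) {
  d <- dim(fg)
  bg <- cpp_label3d(as.logical(!fg), d, 6L)
  bg <- array(bg, d)
  if (max(bg) <= 1L) return(fg)
  open_labels <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                          bg[, , 1], bg[, , d[3]]))
  open_labels <- open_labels[open_labels > 0L]
  fg | (bg > 0L & !(bg %in% open_labels))
}

#' Masked view of a channel
#'
#' Returns a copy of the grid with all intensities outside the mask set to 0.
#'
#' @param grid a \code{voxel_grid}.
#' @param mask a \code{nuclear_mask} of the same shape.
#' @return a \code{voxel_grid}.
#' @export
masked_view <- function(grid, mask) {
  check_aligned(grid, mask)
  out <- grid
  out$data[!mask$data] <- 0
  out
}
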