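# Radial topology: shortest 3D distances of signals to the nuclear border
# (eADS-style) and intensity-weighted relative-distance profiles.

#' Anisotropy-aware distance map to the nuclear border
#'
#' Exact Euclidean distance transform with physical voxel spacing: each voxel
#' holds the shortest 3D distance (nm) to the nearest outside-mask voxel
#' center; outside voxels hold 0.  Invagination surfaces count as border —
#' distances respect the mask geometry, not its convex hull.
#'
#' @param mask a \code{nuclear_mask}.
#' @return 3D numeric array of distances in nm.
#' @export
border_distance_map <- function(mask) {
  stopifnot(inherits(mask, "nuclear_mask"))
  if (!any(mask$data)) stopf("empty mask")
  d <- dim(mask$data)
  array(cpp_edt3d(as.logical(!mask$data), d, mask$voxel_size), d)
}

#' Intensity-weighted radial distance profile of a channel
#'
#' Every masked voxel contributes its intensity at relative border distance
#' \eqn{d/d_{max}}, where \eqn{d_{max}} is the per-nucleus maximum interior
#' depth; per-bin intensity sums are normalized to 1.  The abscissa runs from
#' 0 (nuclear border) to 1 (deepest interior point of that nucleus).
#'
#' @param channel \code{voxel_grid}.
#' @param mask \code{nuclear_mask}, same shape.
#' @param distance_map optional precomputed \code{\link{border_distance_map}}.
#' @param n_bins number of equal-width bins on [0, 1] (default 20).
#' @return a \code{distance_profile}: \code{bin_edges} (length n_bins+1),
#'   \code{weights} (sum 1), \code{mean_rel_distance} (intensity-weighted),
#'   \code{channel_name}, \code{n_nuclei = 1}.
#' @export
signal_radial_profile <- function(channel, mask, distance_map = NULL,
                                  n_bins = 20L) {
  stopifnot(inherits(channel, "voxel_grid"), inherits(mask, "nuclear_mask"))
  check_aligned(channel, mask)
  if (is.null(distance_map)) distance_map <- border_distance_map(mask)
  idx <- which(mask$data)
  w <- channel$data[idx]
  tot <- sum(w)
  if (tot <= 0) stopf("zero total intensity inside the mask")
  dmax <- max(distance_map)
  rel <- distance_map[idx] / dmax
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(ceiling(rel * n_bins), 1L), n_bins)
  ws <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), 0)
  structure(list(bin_edges = edges, weights = ws / tot,
                 mean_rel_distance = sum(w * rel) / tot,
                 channel_name = channel$channel_name, n_nuclei = 1L,
                 sem = rep(NA_real_, n_bins)),
            class = "distance_profile")
}

#' Average radial profiles across nuclei
#'
#' Multi-nucleus profiles are the mean of per-nucleus normalized profiles,
#' with across-nuclei standard error of the mean per bin.
#'
#' @param profiles list of single-nucleus \code{distance_profile}s with
#'   identical binning.
#' @return a \code{distance_profile} with \code{n_nuclei} and \code{sem} set.
#' @export
aggregate_radial_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "distance_profile")))
  edges <- profiles[[1]]$bin_edges
  for (p in profiles)
    if (!isTRUE(all.equal(p$bin_edges, edges))) stopf("bin edges differ")
  W <- do.call(rbind, lapply(profiles, `[[`, "weights"))
  n <- nrow(W)
  structure(list(bin_edges = edges, weights = colMeans(W),
                 mean_rel_distance = mean(vapply(profiles, `[[`, 0,
                                                 "mean_rel_distance")),
                 channel_name = profiles[[1]]$channel_name, n_nuclei = n,
                 sem = if (n > 1L) apply(W, 2, sd) / sqrt(n)
                       else rep(NA_real_, ncol(W))),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile '%s'> %d bins, %d nuclei, mean rel. distance %.3f\n",
              x$channel_name, length(x$weights), x$n_nuclei,
              x$mean_rel_distance))
  invisible(x)
}

#' Compare the radial distributions of two channels across nuclei
#'
#' Reduces each nucleus to the intensity-weighted mean relative border
#' distance of each channel, then applies the two-sided Mann-Whitney rank sum
#' test with continuity correction across nuclei.
#'
#' @param profiles_a,profiles_b lists of single-nucleus
#'   \code{distance_profile}s (>= 3 nuclei each).
#' @return list with \code{p.value}, \code{effect} (difference of median mean
#'   relative distances, a - b), per-nucleus values and \code{n_nuclei}.
#' @export
compare_radial_profiles <- function(profiles_a, profiles_b) {
  va <- vapply(profiles_a, `[[`, 0, "mean_rel_distance")
  vb <- vapply(profiles_b, `[[`, 0, "mean_rel_distance")
  if (length(va) < 3L || length(vb) < 3L)
    stopf("need at least 3 nuclei per channel (got %d and %d)",
          length(va), length(vb))
  ts <- rank_sum_test(va, vb)
  list(p.value = ts$p.value, effect = ts$effect,
       values_a = va, values_b = vb,
       n_nuclei = c(length(va), length(vb)))
}

#' Relative border depths of segmented spots
#'
#' FISH-signal mode: instead of weighting every voxel by its intensity,
#' summarize a channel by its segmented spot centroids
#' (\code{\link{find_spots}}) and report each spot's relative border
#' distance.
#'
#' @param spotset a \code{spot_set}.
#' @param mask the \code{nuclear_mask} the spots live in.
#' @param distance_map optional precomputed distance map.
#' @return numeric vector of relative distances in [0, 1], one per spot.
#' @export
spot_relative_depths <- function(spotset, mask, distance_map = NULL) {
  stopifnot(inherits(spotset, "spot_set"), inherits(mask, "nuclear_mask"))
  if (is.null(distance_map)) distance_map <- border_distance_map(mask)
  if (nrow(spotset$spots) == 0L) return(numeric(0))
  vs <- mask$voxel_size
  d <- dim(mask$data)
  iz <- pmin(pmax(round(spotset$spots$z_nm / vs[1]) + 1L, 1L), d[1])
  iy <- pmin(pmax(round(spotset$spots$y_nm / vs[2]) + 1L, 1L), d[2])
  ix <- pmin(pmax(round(spotset$spots$x_nm / vs[3]) + 1L, 1L), d[3])
  distance_map[cbind(iz, iy, ix)] / max(distance_map)
}
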