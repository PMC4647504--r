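# Marker topology over density classes: threshold a marker channel, correlate
# positive voxels with the DAPI class map, and express over/underrepresentation
# per class as E_c = (M_c - D_c) / D_c.

#' Threshold a marker channel within the nuclear mask
#'
#' @param marker \code{voxel_grid} of the marker channel.
#' @param mask \code{nuclear_mask}, same shape.
#' @param method \code{"otsu"} (within-mask histogram) or an absolute
#'   intensity value; voxels strictly above the threshold are positive.
#' @return logical 3D array of marker-positive voxels (TRUE only inside the
#'   mask), with the threshold used stored in attribute \code{threshold}.
#'   An empty positive set raises a warning, not an error.
#' @export
threshold_marker <- function(marker, mask, method = "otsu") {
  stopifnot(inherits(marker, "voxel_grid"), inherits(mask, "nuclear_mask"))
  check_aligned(marker, mask)
  vals <- marker$data[mask$data]
  thr <- if (identical(method, "otsu")) otsu_threshold(vals)
         else as.numeric(method)
  pos <- marker$data > thr & mask$data
  if (!any(pos)) warnf("no marker-positive voxels above threshold %.4g", thr)
  attr(pos, "threshold") <- thr
  pos
}

#' Enrichment/depletion profile of a marker over density classes
#'
#' Computes the relative signal distribution of marker-positive voxels over
#' the K density classes (\eqn{M_c}), the reference DAPI class distribution
#' (\eqn{D_c}), and the relative enrichment
#' \eqn{E_c = (M_c - D_c) / D_c}: the difference between the relative amount
#' of marker signal and DAPI signal in class c, in relation to the DAPI
#' amount.  Positive values mean overrepresentation, negative depletion;
#' \eqn{E_c \ge -1} always, and \eqn{\sum_c D_c E_c = 0} identically.
#' Classes with \eqn{D_c = 0} get \code{NA} and are flagged.
#'
#' @param marker_positive logical 3D array from \code{\link{threshold_marker}}
#'   (or any voxel set inside the class map).
#' @param classmap \code{class_map} of the corresponding DAPI channel.
#' @param marker_name label stored in the profile.
#' @return an \code{enrichment_profile} with fields \code{M}, \code{D},
#'   \code{E}, \code{n_marker_voxels}, \code{empty}.
#' @export
enrichment_profile <- function(marker_positive, classmap, marker_name = "marker") {
  stopifnot(inherits(classmap, "class_map"))
  if (!identical(dim(marker_positive), dim(classmap$labels)))
    stopf("marker set and class map shapes differ")
  K <- classmap$params$K
  dd <- class_distribution(classmap)
  cls <- classmap$labels[marker_positive]
  if (any(cls == 0L))
    stopf("%d marker-positive voxels fall outside the class map", sum(cls == 0L))
  n <- length(cls)
  if (n == 0L) {
    return(structure(list(marker_name = marker_name, K = K,
                          M = rep(NA_real_, K), D = dd$fractions,
                          E = rep(NA_real_, K), n_marker_voxels = 0L,
                          empty = TRUE),
                     class = "enrichment_profile"))
  }
  M <- tabulate(cls, nbins = K) / n
  D <- dd$fractions
  E <- ifelse(D > 0, (M - D) / D, NA_real_)
  structure(list(marker_name = marker_name, K = K, M = M, D = D, E = E,
                 n_marker_voxels = n, empty = FALSE),
            class = "enrichment_profile")
}

#' @export
print.enrichment_profile <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<enrichment_profile '%s'> empty (no positive voxels)\n",
                x$marker_name))
    return(invisible(x))
  }
  cat(sprintf("<enrichment_profile '%s'> %d positive voxels\n",
              x$marker_name, x$n_marker_voxels))
  print(data.frame(class = seq_len(x$K), D = round(x$D, 4),
                   M = round(x$M, 4), E = round(x$E, 3)), row.names = FALSE)
  invisible(x)
}

# Intensity-class-weighted mean class of a fraction vector: sum(c * f_c).
weighted_mean_class <- function(fractions) {
  f <- fractions[!is.na(fractions)]
  sum(seq_along(fractions)[!is.na(fractions)] * f) / sum(f)
}

#' Wilcoxon rank-sum test (normal approximation, continuity correction)
#'
#' Thin wrapper over the two-sided Mann-Whitney/Wilcoxon rank-sum test with
#' tie-corrected normal approximation and continuity correction, the variant
#' used for all group comparisons here.  Completely tied samples (zero rank
#' variance) return p = 1.
#'
#' @param x,y numeric samples.
#' @return list with \code{p.value}, \code{statistic} (Mann-Whitney U of x),
#'   \code{median_x}, \code{median_y}, \code{effect} (median_x - median_y).
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stopf("both samples must be nonempty")
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1        # degenerate: zero variance under H0 (all tied)
  list(p.value = p, statistic = unname(wt$statistic),
       median_x = median(x), median_y = median(y),
       effect = median(x) - median(y))
}

#' Compare marker and DAPI class distributions across nuclei
#'
#' Each nucleus' marker and DAPI channel distributions are reduced to their
#' intensity-class-weighted mean class \eqn{\sum_c c\,f_c} (one exchangeable
#' value per nucleus), and the two per-nucleus samples are compared with the
#' two-sided Wilcoxon rank-sum test with continuity correction.
#'
#' @param profiles list of per-nucleus \code{enrichment_profile}s (>= 3
#'   non-empty profiles required).
#' @return list with \code{p.value}, \code{effect} (difference of median
#'   weighted mean classes, marker - DAPI), per-nucleus values
#'   \code{marker_values}, \code{dapi_values}, and \code{n_nuclei}.
#' @export
compare_marker_to_dapi <- function(profiles) {
  stopifnot(is.list(profiles),
            all(vapply(profiles, inherits, TRUE, "enrichment_profile")))
  profiles <- Filter(function(p) !p$empty, profiles)
  if (length(profiles) < 3L) stopf("need at least 3 nuclei, got %d", length(profiles))
  mv <- vapply(profiles, function(p) weighted_mean_class(p$M), 0)
  dv <- vapply(profiles, function(p) weighted_mean_class(p$D), 0)
  ts <- rank_sum_test(mv, dv)
  list(p.value = ts$p.value, effect = ts$effect,
       marker_values = mv, dapi_values = dv, n_nuclei = length(profiles))
}
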