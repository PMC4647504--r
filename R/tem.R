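# Chromatin/IC interface length on 2D sections: (chromatin perimeter -
# nuclear perimeter), normalized by nuclear area.

#' Crofton perimeter of a binary 2D mask
#'
#' 4-direction Crofton approximation: boundary intercepts are counted in the
#' horizontal, vertical and both diagonal directions via 2x2 pixel
#' configurations and combined with Cauchy-Crofton weights.  Low bias on
#' smooth boundaries (< 0.1 percent on large digital disks); axis-aligned
#' straight edges carry the estimator's known bias factor of
#' \eqn{\pi(1+\sqrt 2)/8 \approx 0.948}.  A single pixel measures
#' \eqn{\approx 2.6815} pixel units.
#'
#' @param mask2d logical/0-1 matrix (nonempty).
#' @param pixel_size physical pixel edge, nm (default 1 = pixel units).
#' @return perimeter length in nm.
#' @export
perimeter_crofton <- function(mask2d, pixel_size = 1) {
  m <- (as.matrix(mask2d) > 0) * 1L
  if (!any(m == 1L)) stopf("mask is empty")
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  # 2x2 configuration code at (i, j): m(i,j) + 4 m(i,j-1) + 2 m(i-1,j) + 8 m(i-1,j-1)
  xf <- p +
    4L * cbind(0L, p[, -ncol(p)]) +
    2L * rbind(0L, p[-nrow(p), ]) +
    8L * rbind(0L, cbind(0L, p[, -ncol(p)])[-nrow(p), ])
  h <- tabulate(xf + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  sum(coefs * h) * pixel_size
}

#' Chromatin/IC interface length of a 2D section
#'
#' Thresholds chromatin inside the nuclear mask (Otsu within the mask by
#' default) and measures the interface between chromatin and the
#' interchromatin compartment as the chromatin perimeter minus the nuclear
#' perimeter; chromatin touching the nuclear boundary shares that boundary,
#' so the shared edge cancels in the subtraction.  The result is normalized
#' by nuclear area.
#'
#' @param section a \code{section_image}.
#' @param nuclear_mask2d logical matrix enclosing the chromatin.
#' @param chromatin_threshold \code{"otsu"} or absolute intensity; values
#'   strictly above are chromatin (use \code{polarity = "dark"} for stains
#'   where chromatin is the low-intensity phase).
#' @param polarity \code{"bright"} (chromatin above threshold) or
#'   \code{"dark"}.
#' @return an \code{interface_measure}: perimeters and area in nm / nm^2,
#'   \code{interface_length} (nm), \code{normalized_interface} (1/nm) and
#'   \code{normalized_interface_px} (dimensionless, pixel units).
#' @export
interface_length <- function(section, nuclear_mask2d,
                             chromatin_threshold = "otsu",
                             polarity = c("bright", "dark")) {
  stopifnot(inherits(section, "section_image"))
  polarity <- match.arg(polarity)
  msk <- as.matrix(nuclear_mask2d) > 0
  if (!identical(dim(msk), dim(section$data)))
    stopf("section and mask shapes differ")
  if (!any(msk)) stopf("nuclear mask is empty")
  img <- section$data
  if (polarity == "dark") img <- max(img) - img
  vals <- img[msk]
  thr <- if (identical(chromatin_threshold, "otsu")) otsu_threshold(vals)
         else as.numeric(chromatin_threshold)
  chrom <- (img > thr) & msk
  if (!any(chrom)) stopf("no chromatin above threshold")
  px <- section$pixel_size
  p_nuc <- perimeter_crofton(msk, px)
  p_chr <- perimeter_crofton(chrom, px)
  a_nuc <- sum(msk) * px^2
  il <- p_chr - p_nuc
  structure(list(P_nucleus = p_nuc, P_chromatin = p_chr, A_nucleus = a_nuc,
                 interface_length = il,
                 normalized_interface = il / a_nuc,
                 normalized_interface_px = (il / px) / sum(msk),
                 threshold = thr, pixel_size = px),
            class = "interface_measure")
}

#' @export
print.interface_measure <- function(x, ...) {
  cat(sprintf(paste0("<interface_measure> P_nucleus=%.4g nm, P_chromatin=%.4g nm,\n",
                     "  interface=%.4g nm, area=%.4g nm^2, normalized=%.4g /nm\n"),
              x$P_nucleus, x$P_chromatin, x$interface_length, x$A_nucleus,
              x$normalized_interface))
  invisible(x)
}
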