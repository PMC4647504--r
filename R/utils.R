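# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Separable Gaussian blur of a 3D array (z, y, x).  `sigma` is in voxels per
# axis (dz, dy, dx); sigma 0 along an axis skips that axis.  Reflective
# boundary via kernel renormalisation (no intensity bleed out of the volume).
gaussian_blur3d <- function(a, sigma) {
  stopifnot(length(dim(a)) == 3L, length(sigma) == 3L, all(sigma >= 0))
  blur_mat <- function(n, s) {
    if (s <= 0 || n == 1L) return(NULL)
    r <- max(1L, ceiling(3 * s))
    idx <- seq_len(n)
    m <- outer(idx, idx, function(i, j) {
      d <- abs(i - j)
      ifelse(d <= r, dnorm(d, sd = s), 0)
    })
    sweep(m, 1, rowSums(m), "/")
  }
  d <- dim(a)
  gz <- blur_mat(d[1], sigma[1])
  gy <- blur_mat(d[2], sigma[2])
  gx <- blur_mat(d[3], sigma[3])
  if (!is.null(gz)) a <- array(gz %*% matrix(a, d[1]), d)
  if (!is.null(gy)) {
    a <- aperm(a, c(2, 1, 3))
    a <- array(gy %*% matrix(a, d[2]), dim(a))
    a <- aperm(a, c(2, 1, 3))
  }
  if (!is.null(gx)) {
    a <- aperm(a, c(3, 2, 1))
    a <- array(gx %*% matrix(a, d[3]), dim(a))
    a <- aperm(a, c(3, 2, 1))
  }
  a
}

# Otsu's threshold on a numeric vector (256-bin histogram over the data
# range).  Returns the threshold value; voxels strictly above are foreground.
#' Otsu threshold of an intensity sample
#'
#' Maximises between-class variance on a 256-bin histogram.  Values strictly
#' greater than the returned threshold are considered positive.
#'
#' @param x numeric vector of intensities.
#' @param n_bins number of histogram bins.
#' @return scalar threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stopf("degenerate histogram: no finite values")
  rng <- range(x)
  if (rng[1] == rng[2]) stopf("degenerate histogram: all values equal")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- h / sum(h)
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mt <- cm[n_bins]
  valid <- cw > 0 & cw < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mt * cw[valid] - cm[valid])^2 / (cw[valid] * (1 - cw[valid]))
  k <- which.max(bcv)
  breaks[k + 1L]
}
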