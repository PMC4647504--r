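# Chromatin density classification: equal-variance Gaussian mixture fitted by
# EM on the masked DAPI intensities, with an optional Potts spatial prior
# (hidden Markov random field) applied at the labelling stage.  The analysis
# default follows the published usage: K = 7 classes, neighbour influence
# (beta) = 0, so labels reduce to the per-voxel MAP rule of the mixture.

#' Mixture parameters for density classification
#'
#' Container for an equal-variance Gaussian mixture plus Potts coupling.
#' "Equal intensity variance" means one shared standard deviation across all
#' K components; means are kept sorted ascending so that class 1 is always
#' the lowest-intensity (near-background) class.
#'
#' @param means strictly increasing component means (intensity units).
#' @param sd shared component standard deviation (> 0).
#' @param weights component probabilities (sum 1).
#' @param beta Potts coupling >= 0 (0 = pure mixture MAP).
#' @param neighborhood 6, 18 or 26 (3D neighbourhood for the Potts term).
#' @return an object of class \code{mixture_params}.
#' @export
mixture_params <- function(means, sd, weights = NULL, beta = 0, neighborhood = 26L) {
  means <- as.numeric(means)
  K <- length(means)
  if (is.null(weights)) weights <- rep(1 / K, K)
  if (length(weights) != K || any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stopf("weights must be K probabilities summing to 1")
  if (!is_scalar_num(sd) || sd <= 0) stopf("shared sd must be > 0")
  if (is.unsorted(means, strictly = TRUE)) {
    o <- order(means)
    means <- means[o]; weights <- weights[o]
    if (any(duplicated(means))) stopf("component means must be distinct")
  }
  if (beta < 0) stopf("beta must be >= 0")
  if (!neighborhood %in% c(6L, 18L, 26L)) stopf("neighborhood must be 6, 18 or 26")
  structure(list(K = K, means = means, sd = as.numeric(sd),
                 weights = as.numeric(weights), beta = as.numeric(beta),
                 neighborhood = as.integer(neighborhood)),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("<mixture_params> K=%d, shared sd=%.4g, beta=%g (%d-neighbourhood)\n",
              x$K, x$sd, x$beta, x$neighborhood))
  cat("  means:  ", paste(signif(x$means, 5), collapse = " "), "\n")
  cat("  weights:", paste(signif(x$weights, 4), collapse = " "), "\n")
  invisible(x)
}

#' Fit an equal-variance Gaussian mixture by EM
#'
#' Maximum-likelihood fit of a K-component Gaussian mixture constrained to a
#' single shared variance, the model behind DAPI intensity classes.
#' Initialisation is deterministic (K quantile midpoints of the intensity
#' distribution); the log-likelihood is non-decreasing across iterations.
#' For large samples the EM runs on a fine histogram (weighted EM over
#' \code{n_bins} equal-width bins), which is numerically indistinguishable at
#' 16-bit intensity resolution and keeps runtime linear in the bin count.
#'
#' @param intensities numeric vector of masked voxel intensities.
#' @param K number of classes (paper analysis: 7).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap; non-convergence returns the best estimate
#'   with a warning and \code{converged = FALSE}.
#' @param seed RNG seed reserved for optional random restarts
#'   (\code{n_restarts > 0}); the default path is fully deterministic.
#' @param n_restarts optional random restarts keeping the best likelihood.
#' @param bin_threshold sample size above which the histogram approximation
#'   is used.
#' @param n_bins histogram resolution for the binned path.
#' @return a \code{mixture_params} with attributes \code{loglik} (trace),
#'   \code{converged}, \code{n}.
#' @export
fit_mixture <- function(intensities, K = 7L, tol = 1e-6, max_iter = 500L,
                        seed = 0L, n_restarts = 0L,
                        bin_threshold = 20000L, n_bins = 4096L) {
  x <- as.numeric(intensities)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10L * K) stopf("need at least 10*K = %d voxels, got %d", 10L * K, n)
  if (diff(range(x)) == 0) stopf("degenerate histogram: all intensities equal")

  if (n > bin_threshold) {
    breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
    cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = n_bins)
    keep <- cnt > 0L
    xe <- ((breaks[-1] + breaks[-length(breaks)]) / 2)[keep]
    wts <- cnt[keep]
  } else {
    xe <- x
    wts <- rep(1, n)
  }

  run_em <- function(mu0, sd0, pi0) {
    mu <- mu0; sg <- sd0; pw <- pi0
    ll_trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      lg <- vapply(seq_len(K), function(c)
        log(pw[c]) + dnorm(xe, mu[c], sg, log = TRUE), numeric(length(xe)))
      m <- apply(lg, 1, max)
      lse <- m + log(rowSums(exp(lg - m)))
      ll <- sum(wts * lse)
      ll_trace <- c(ll_trace, ll)
      g <- exp(lg - lse) * wts       # responsibilities scaled by bin counts
      nk <- colSums(g)
      pw <- nk / sum(wts)
      mu <- colSums(g * xe) / nk
      sg <- sqrt(sum(g * (xe - rep(mu, each = length(xe)))^2) / sum(wts))
      if (sg <= 0 || !is.finite(sg)) sg <- max(1e-8, sd0 * 1e-6)
      if (is.finite(ll_prev) && (ll - ll_prev) <= tol * abs(ll_prev)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
    list(mu = mu, sg = sg, pw = pw, ll = ll_trace, converged = converged)
  }

  probs <- (seq_len(K) - 0.5) / K
  rngx <- diff(range(x))
  sd0 <- max(sd(x) / K, 1e-8 * rngx)
  # two deterministic starts: quantile midpoints (adapts to skew) and
  # equal-width midpoints (robust when several quantiles crowd one mode);
  # keep the higher-likelihood fit
  inits <- list(as.numeric(quantile(x, probs, names = FALSE, type = 7)),
                min(x) + probs * rngx)
  inits <- lapply(inits, function(m) {
    if (any(duplicated(m))) m + (seq_len(K) - 1) * 1e-6 * max(rngx, 1) else m
  })
  best <- NULL
  for (mu0 in inits) {
    cand <- run_em(mu0, sd0, rep(1 / K, K))
    if (is.null(best) || max(cand$ll) > max(best$ll)) best <- cand
  }
  if (n_restarts > 0L) {
    with_seed(seed, {
      for (r in seq_len(n_restarts)) {
        mu_r <- sort(runif(K, min(x), max(x)))
        cand <- run_em(mu_r, sd0, rep(1 / K, K))
        if (max(cand$ll) > max(best$ll)) best <- cand
      }
    })
  }
  if (!best$converged)
    warnf("EM did not converge in %d iterations; returning best estimate", max_iter)
  o <- order(best$mu)
  mu <- best$mu[o]
  collapsed <- which(diff(mu) <= 0)
  if (length(collapsed)) {   # components collapsed onto one mode; keep valid
    warnf("EM collapsed %d component pair(s) to identical means", length(collapsed))
    for (k in collapsed + 1L) mu[k] <- mu[k - 1L] + 1e-8 * max(abs(mu[k - 1L]), 1)
  }
  p <- mixture_params(means = mu, sd = best$sg, weights = best$pw[o])
  attr(p, "loglik") <- best$ll
  attr(p, "converged") <- best$converged
  attr(p, "n") <- n
  p
}

# log posterior (up to constant) matrix for a vector of intensities: n x K
log_posterior_matrix <- function(x, params) {
  vapply(seq_len(params$K), function(c)
    log(params$weights[c]) + dnorm(x, params$means[c], params$sd, log = TRUE),
    numeric(length(x)))
}

#' Classify masked voxels into density classes
#'
#' With \code{beta = 0} (the published analysis setting) each masked voxel
#' receives the class maximising \eqn{\pi_c N(x | \mu_c, \sigma)}.  With
#' \code{beta > 0} labels are the ICM (iterated conditional modes) fixed
#' point of the HMRF posterior with Potts energy \eqn{\beta\cdot}(number of
#' differently-labelled neighbours), initialised from the beta-0 map and
#' swept until label stability (at most \code{max_sweeps}).  Ties break
#' toward the lower class index.
#'
#' @param dapi \code{voxel_grid} of the classified channel.
#' @param mask \code{nuclear_mask}, same shape.
#' @param params \code{mixture_params} fitted on the same channel's masked
#'   intensities.
#' @param max_sweeps ICM sweep cap (beta > 0 only).
#' @return a \code{class_map}: integer labels, 0 outside the mask, 1..K inside.
#' @export
classify_voxels <- function(dapi, mask, params, max_sweeps = 50L) {
  stopifnot(inherits(dapi, "voxel_grid"), inherits(mask, "nuclear_mask"),
            inherits(params, "mixture_params"))
  check_aligned(dapi, mask)
  d <- dim(dapi$data)
  idx <- which(mask$data)
  x <- dapi$data[idx]
  lp <- matrix(log_posterior_matrix(x, params), ncol = params$K)
  lab0 <- max.col(lp, ties.method = "first")
  labels <- array(0L, d)
  labels[idx] <- lab0
  sweeps <- 0L
  if (params$beta > 0) {
    r <- cpp_icm(as.numeric(dapi$data), as.logical(mask$data), as.integer(labels),
                 d, params$means, params$sd, log(params$weights), params$beta,
                 params$neighborhood, as.integer(max_sweeps))
    labels <- array(r$labels, d)
    sweeps <- r$sweeps
    if (!r$converged)
      warnf("ICM did not stabilise within %d sweeps", max_sweeps)
  }
  structure(list(labels = labels, params = params,
                 source_channel = dapi$channel_name,
                 voxel_size = dapi$voxel_size, icm_sweeps = sweeps),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  n <- sum(x$labels > 0L)
  cat(sprintf("<class_map> %s voxels in %d classes (channel '%s', beta=%g)\n",
              format(n, big.mark = ","), x$params$K, x$source_channel,
              x$params$beta))
  invisible(x)
}

#' Relative class-volume distribution of a class map
#'
#' @param classmap a \code{class_map}.
#' @return a \code{class_distribution}: fractions \eqn{D_c} summing to 1,
#'   voxel counts, and class count K.
#' @export
class_distribution <- function(classmap) {
  stopifnot(inherits(classmap, "class_map"))
  K <- classmap$params$K
  counts <- tabulate(classmap$labels[classmap$labels > 0L], nbins = K)
  n <- sum(counts)
  if (n == 0L) stopf("class map is empty")
  structure(list(fractions = counts / n, counts = counts, n_voxels = n, K = K),
            class = "class_distribution")
}

#' @export
print.class_distribution <- function(x, ...) {
  cat("<class_distribution>", paste(sprintf("%d:%.3f", seq_len(x$K), x$fractions),
                                    collapse = " "), "\n")
  invisible(x)
}

#' One-call chromatin density classification of a nucleus
#'
#' Convenience wrapper: fit the K-class equal-variance mixture on the masked
#' intensities, label the voxels, and return map, parameters and class
#' distribution together.
#'
#' @inheritParams classify_voxels
#' @inheritParams fit_mixture
#' @param beta Potts coupling for the labelling stage.
#' @return list with elements \code{params}, \code{classmap}, \code{distribution}.
#' @export
classify_nucleus <- function(dapi, mask, K = 7L, beta = 0, seed = 0L, ...) {
  params <- fit_mixture(masked_values(dapi, mask), K = K, seed = seed, ...)
  params$beta <- beta
  cm <- classify_voxels(dapi, mask, params)
  list(params = params, classmap = cm, distribution = class_distribution(cm))
}
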