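# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (loops, exhaustive enumeration, closed forms)
# and never call the code paths they check.

SIM_VS <- c(125, 39.5, 39.5)   # 3D-SIM voxel size (dz, dy, dx) nm

ellipsoid_arr <- function(shape, center, semi) {
  z <- seq_len(shape[1]); y <- seq_len(shape[2]); x <- seq_len(shape[3])
  az <- ((z - center[1]) / semi[1])^2
  ay <- ((y - center[2]) / semi[2])^2
  ax <- ((x - center[3]) / semi[3])^2
  array(outer(outer(az, ay, `+`), ax, `+`), shape) <= 1
}

ball_mask <- function(r_vox = 8, voxel_size = c(50, 50, 50)) {
  n <- 2L * r_vox + 5L
  c0 <- (n + 1) / 2
  nuclear_mask(ellipsoid_arr(c(n, n, n), rep(c0, 3), rep(r_vox, 3)),
               voxel_size = voxel_size, check = FALSE)
}

# exhaustive all-pairs minimum distance from every inside voxel to the nearest
# outside voxel (physical coordinates)
brute_edt <- function(mask_arr, voxel_size) {
  d <- dim(mask_arr)
  ins <- which(mask_arr)
  outs <- which(!mask_arr)
  co_i <- (arrayInd(ins, d) - 1) %*% diag(voxel_size)
  co_o <- t((arrayInd(outs, d) - 1) %*% diag(voxel_size))
  vapply(seq_along(ins), function(k)
    sqrt(min(colSums((co_o - co_i[k, ])^2))), 0)
}

# per-voxel posterior argmax of the equal-variance mixture, one voxel at a
# time (ties toward lower class); log scale so small sigmas cannot underflow
gmm_map_oracle <- function(x, params) {
  vapply(x, function(xi) {
    post <- log(params$weights) + dnorm(xi, params$means, params$sd, log = TRUE)
    which(post >= max(post))[1]
  }, 0L)
}

# exact two-sided permutation p-value of the rank-sum test for tie-free
# samples, by enumerating every rank split
exact_rank_p <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  cmb <- utils::combn(N, m)
  us <- apply(cmb, 2, function(ix) sum(ix) - m * (m + 1) / 2)
  mean(abs(us - m * n / 2) >= abs(u_obs - m * n / 2))
}

# wrap a label array into a class_map without running the classifier
fake_classmap <- function(labels, K, voxel_size = SIM_VS) {
  structure(list(labels = labels,
                 params = mixture_params(means = seq_len(K) * 100, sd = 10,
                                         weights = rep(1 / K, K)),
                 source_channel = "DAPI", voxel_size = voxel_size,
                 icm_sweeps = 0L),
            class = "class_map")
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# one small noisy nucleus image around a known ellipsoid, for mask tests
noisy_ellipsoid_grid <- function(seed = 1, shape = c(32, 64, 64),
                                 semi = c(11, 24, 24), fg = 500, bg = 80) {
  set.seed(seed)
  tru <- ellipsoid_arr(shape, (shape + 1) / 2, semi)
  img <- array(rnorm(prod(shape), bg, 15), shape)
  img[tru] <- rnorm(sum(tru), fg, 40)
  list(grid = voxel_grid(pmax(img, 0), SIM_VS), truth = tru)
}
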