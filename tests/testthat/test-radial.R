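# Border distance transform and radial distance profiles.

test_that("distance map matches the brute-force oracle on random masks", {
  set.seed(51)
  for (rep in 1:10) {
    sh <- c(sample(10:20, 1), sample(10:20, 1), sample(10:20, 1))
    vs <- sample(c(50, 100, 125, 200), 3, replace = TRUE)
    m <- array(runif(prod(sh)) > 0.55, sh)
    m[1, , ] <- m[sh[1], , ] <- FALSE
    if (!any(m)) next
    mk <- nuclear_mask(m, vs, check = FALSE)
    dm <- border_distance_map(mk)
    expect_equal(dm[m], brute_edt(m, vs), tolerance = 1e-9)
    expect_true(all(dm[!m] == 0))
  }
})

test_that("ball center depth and anisotropic slab depth are exact", {
  mk <- ball_mask(8, c(50, 50, 50))
  dm <- border_distance_map(mk)
  c0 <- (dim(mk$data)[1] + 1) / 2
  expect_lt(abs(dm[c0, c0, c0] - 8 * 50), 50)
  slab <- array(FALSE, c(20, 7, 7)); slab[6:15, , ] <- TRUE
  dm2 <- border_distance_map(nuclear_mask(slab, c(200, 50, 50), check = FALSE))
  expect_equal(dm2[10, 4, 4], 5 * 200)
  expect_error(border_distance_map(
    nuclear_mask(array(FALSE, c(3, 3, 3)), check = FALSE)), "empty")
})

test_that("uniform intensity in a ball reproduces the shell-volume law", {
  sh <- c(65, 65, 65)
  mk <- nuclear_mask(ellipsoid_arr(sh, c(33, 33, 33), c(30, 30, 30)),
                     c(50, 50, 50), check = FALSE)
  rp <- signal_radial_profile(voxel_grid(array(1, sh), c(50, 50, 50)), mk,
                              n_bins = 20)
  e <- rp$bin_edges
  analytic <- (1 - e[-21])^3 - (1 - e[-1])^3
  expect_lt(max(abs(rp$weights - analytic)), 0.03)
  expect_equal(sum(rp$weights), 1, tolerance = 1e-9)
})

test_that("a point source at the deepest voxel puts all mass in the last bin", {
  mk <- ball_mask(7)
  dm <- border_distance_map(mk)
  a <- array(0, dim(mk$data))
  a[which.max(dm)] <- 1000
  rp <- signal_radial_profile(voxel_grid(a, mk$voxel_size), mk, dm, n_bins = 20)
  expect_equal(rp$weights[20], 1)
  expect_error(signal_radial_profile(
    voxel_grid(array(0, dim(mk$data)), mk$voxel_size), mk, dm), "zero total")
})

test_that("profiles are invariant to intensity scaling and mirror reflection", {
  set.seed(52)
  sh <- c(18, 22, 26)
  m <- ellipsoid_arr(sh, (sh + 1) / 2, c(6, 8, 10))
  a <- array(runif(prod(sh), 0, 100), sh)
  mk <- nuclear_mask(m, SIM_VS, check = FALSE)
  rp1 <- signal_radial_profile(voxel_grid(a, SIM_VS), mk)
  rp2 <- signal_radial_profile(voxel_grid(a * 17, SIM_VS), mk)
  expect_equal(rp1$weights, rp2$weights, tolerance = 1e-12)
  flip <- function(x) x[, , dim(x)[3]:1]
  mkf <- nuclear_mask(flip(m), SIM_VS, check = FALSE)
  rp3 <- signal_radial_profile(voxel_grid(flip(a), SIM_VS), mkf)
  expect_equal(rp1$weights, rp3$weights, tolerance = 1e-12)
})

test_that("designed radial placements are recovered within 0.05", {
  fx <- generate_radial_fixture(c(deep = 0.7, shallow = 0.3),
                                photon_scale = 1, seed = 53)
  for (ch in names(fx$channels)) {
    rp <- signal_radial_profile(fx$channels[[ch]], fx$mask, fx$distance_map)
    expect_lt(abs(rp$mean_rel_distance - fx$truth$design_means[[ch]]), 0.05)
  }
})

test_that("aggregation averages profiles and reports SEM across nuclei", {
  profs <- lapply(1:4, function(s) {
    fx <- generate_radial_fixture(c(ch = 0.5), photon_scale = 0.5, seed = s)
    signal_radial_profile(fx$channels$ch, fx$mask, fx$distance_map)
  })
  agg <- aggregate_radial_profiles(profs)
  expect_identical(agg$n_nuclei, 4L)
  expect_equal(sum(agg$weights), 1, tolerance = 1e-9)
  expect_true(all(is.finite(agg$sem)))
})

test_that("compare_radial_profiles separates designed depths and guards n < 3", {
  mkprof <- function(mean_rel) structure(
    list(bin_edges = seq(0, 1, 0.05), weights = rep(0.05, 20),
         mean_rel_distance = mean_rel, channel_name = "c", n_nuclei = 1L,
         sem = rep(NA_real_, 20)), class = "distance_profile")
  expect_error(compare_radial_profiles(list(mkprof(0.4), mkprof(0.4)),
                                       list(mkprof(0.6), mkprof(0.6))),
               "at least 3")
  identical_p <- compare_radial_profiles(lapply(rep(0.5, 5), mkprof),
                                         lapply(rep(0.5, 5), mkprof))$p.value
  expect_gte(identical_p, 0.9)
  # scaled-down power check (10 replicates here; 100 in the acceptance suite)
  set.seed(54)
  hits <- 0L
  for (r in 1:10) {
    a <- lapply(rnorm(20, 0.4, 0.03), mkprof)
    b <- lapply(rnorm(20, 0.6, 0.03), mkprof)
    if (compare_radial_profiles(a, b)$p.value < 0.005) hits <- hits + 1L
  }
  expect_identical(hits, 10L)
})

test_that("spot mode reports sensible relative depths", {
  mk <- nuclear_mask(ellipsoid_arr(c(30, 72, 72), c(15.5, 36, 36), c(12, 30, 30)),
                     SIM_VS, check = FALSE)
  sp <- generate_spot_channel(mk, n_spots = 20, min_separation_nm = 500,
                              seed = 55)
  ss <- find_spots(sp$channel, mk, offset = 250)
  depths <- spot_relative_depths(ss, mk)
  expect_identical(length(depths), nrow(ss$spots))
  expect_true(all(depths > 0 & depths <= 1))
})
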