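# Marker thresholding, enrichment/depletion profiles, rank-sum comparisons.

test_that("hand-computed enrichment example: D=(0.2,0.8), M=(0.3,0.7)", {
  lab <- array(0L, c(5, 5, 4))
  lab[1:20] <- 1L; lab[21:100] <- 2L      # D = (0.2, 0.8)
  cm <- fake_classmap(lab, 2)
  pos <- array(FALSE, dim(lab))
  pos[c(1:3, 21:27)] <- TRUE              # M = (0.3, 0.7)
  prof <- enrichment_profile(pos, cm)
  expect_equal(prof$E, c(0.5, -0.125), tolerance = 1e-12)
})

test_that("marker equal to DAPI gives E identically 0", {
  sim <- generate_nucleus(phenotype_spec("precursor"), seed = 21)
  cm <- sim$truth$classmap
  pos <- sim$truth$mask$data              # every masked voxel positive
  prof <- enrichment_profile(pos, cm)
  expect_equal(prof$M, prof$D, tolerance = 1e-12)
  expect_true(all(abs(prof$E) < 1e-12))
})

test_that("sum_c D_c E_c = 0 and E_c >= -1 on every profile (property)", {
  set.seed(22)
  for (rep in 1:20) {
    K <- sample(2:7, 1)
    n <- 500
    lab <- array(0L, c(10, 10, 5))
    lab[seq_len(n)] <- sample.int(K, n, replace = TRUE,
                                  prob = {w <- runif(K); w / sum(w)})
    cm <- fake_classmap(lab, K)
    pos <- array(FALSE, dim(lab))
    pos[sample(which(lab > 0L), sample(50:300, 1))] <- TRUE
    prof <- enrichment_profile(pos, cm)
    ok <- !is.na(prof$E)
    expect_lt(abs(sum(prof$D[ok] * prof$E[ok])
                  + sum(prof$M[!ok])), 1e-12)  # identity, NA classes carry M=0 here
    expect_true(all(prof$E[ok] >= -1))
  }
})

test_that("classes with D_c = 0 are flagged NA, not infinite", {
  lab <- array(0L, c(4, 4, 4))
  lab[1:30] <- 2L                          # class 1 absent
  cm <- fake_classmap(lab, 2)
  pos <- array(FALSE, dim(lab)); pos[1:5] <- TRUE
  prof <- enrichment_profile(pos, cm)
  expect_true(is.na(prof$E[1]))
  expect_false(is.infinite(prof$E[1]))
})

test_that("empty marker sets yield an explicit empty profile", {
  lab <- array(0L, c(4, 4, 4)); lab[1:30] <- 1L
  cm <- fake_classmap(lab, 1)
  prof <- enrichment_profile(array(FALSE, dim(lab)), cm)
  expect_true(prof$empty)
  expect_true(all(is.na(prof$E)))
})

test_that("threshold_marker recovers generator-placed voxels (Dice >= 0.9)", {
  sim <- generate_nucleus(phenotype_spec("progenitor"),
                          markers = list(mk = c(2, 1, 0, -0.5, -1, -1, -1)),
                          seed = 23)
  pos <- threshold_marker(sim$channels$mk, sim$truth$mask)
  tp <- sim$truth$markers$mk$positive_idx
  det <- which(pos)
  dice <- 2 * length(intersect(tp, det)) / (length(tp) + length(det))
  expect_gte(dice, 0.9)
})

test_that("threshold_marker handles degenerate channels per contract", {
  mk <- ball_mask(5)
  zero <- voxel_grid(array(0, dim(mk$data)), mk$voxel_size)
  expect_warning(pos <- threshold_marker(zero, mk, method = 1), "no marker")
  expect_false(any(pos))
  const <- voxel_grid(array(7, dim(mk$data)), mk$voxel_size)
  expect_error(threshold_marker(const, mk), "degenerate histogram")
  pos2 <- threshold_marker(const, mk, method = 5)
  expect_identical(which(pos2), which(mk$data))
})

test_that("enrichment is invariant to marker intensity rescaling", {
  sim <- generate_nucleus(phenotype_spec("monocyte"),
                          markers = list(mk = c(1, 1, 0, 0, -1, -1, -1)),
                          seed = 24)
  cm <- sim$truth$classmap
  m1 <- sim$channels$mk
  pos1 <- threshold_marker(m1, sim$truth$mask, method = 300)
  m2 <- voxel_grid(m1$data * 4, m1$voxel_size)
  pos2 <- threshold_marker(m2, sim$truth$mask, method = 1200)
  expect_equal(enrichment_profile(pos1, cm)$E, enrichment_profile(pos2, cm)$E)
})

test_that("designed enrichment is recovered with MAE <= 0.1 per class", {
  # recovery is judged against the generator's realizable design (the
  # projection of the requested vector onto the identity sum(D*E) = 0)
  designs <- list(flat = rep(0, 7),
                  anc = c(2.5, 1.5, 0.5, -0.5, -1, -1, -1),
                  inc = c(-1, -1, -0.5, 0, 0.8, 1.5, 2))
  for (nm in names(designs)) {
    sim <- generate_nucleus(phenotype_spec("precursor"),
                            markers = setNames(designs[nm], "mk"), seed = 25)
    truthE <- sim$truth$markers$mk$E_design
    pos <- threshold_marker(sim$channels$mk, sim$truth$mask)
    prof <- enrichment_profile(pos, sim$truth$classmap)
    expect_lt(mean(abs(prof$E - truthE)), 0.1)
    if (nm == "flat") expect_lt(max(abs(truthE)), 1e-9)
  }
})

test_that("rank_sum_test matches the published variant and handles ties", {
  expect_gte(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p.value, 0.9)
  expect_equal(rank_sum_test(rep(2, 4), rep(2, 4))$p.value, 1)
  # spec example: agrees with exhaustive rank-split enumeration
  p_norm <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p.value
  p_exact <- exact_rank_p(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p_exact, 2 / choose(6, 3))
  expect_lt(abs(p_norm - p_exact), 0.06)
})

test_that("compare_marker_to_dapi needs >= 3 nuclei and detects a class shift", {
  mkprof <- function(M, D) structure(list(marker_name = "m", K = 7, M = M,
                                          D = D, E = (M - D) / D,
                                          n_marker_voxels = 1000L,
                                          empty = FALSE),
                                     class = "enrichment_profile")
  rand_frac <- function(center) {
    w <- dnorm(1:7, center, 1.2) * exp(rnorm(7, 0, 0.25))
    w / sum(w)
  }
  expect_error(compare_marker_to_dapi(list(mkprof(rep(1/7, 7), rep(1/7, 7)))),
               "at least 3")
  # Monte-Carlo power, scaled down from the spec's image-level experiment:
  # per-nucleus class distributions are simulated directly (the reduction to
  # the weighted mean class is what the test exercises), 20 nuclei per group,
  # marker shifted +1 mean class, 50 replicates
  set.seed(26)
  hits <- 0L
  for (r in 1:50) {
    profs <- lapply(1:20, function(i) mkprof(rand_frac(4.5), rand_frac(3.5)))
    if (compare_marker_to_dapi(profs)$p.value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 48L)
})
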