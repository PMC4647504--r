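# Image containers, TIFF round trips, nuclear mask generation.

test_that("voxel_grid and section_image validate their invariants", {
  expect_error(voxel_grid(array(-1, c(2, 2, 2))), "non-negative")
  expect_error(voxel_grid(array(1, c(2, 2))), "3D")
  expect_error(voxel_grid(array(1, c(2, 2, 2)), voxel_size = c(0, 1, 1)),
               "positive")
  expect_error(section_image(matrix(Inf, 2, 2), 10), "finite")
  expect_error(section_image(matrix(1, 2, 2), -1), "pixel_size")
  g <- voxel_grid(array(0:7, c(2, 2, 2)), c(125, 39.5, 39.5), "DAPI", 16L)
  expect_identical(dim(g), c(2L, 2L, 2L))
})

test_that("write_stack/read_stack round-trips 8- and 16-bit data bit-exactly", {
  withr::with_tempdir({
    set.seed(1)
    for (bits in c(8L, 16L)) {
      a <- array(sample.int(2^bits, 6 * 10 * 12, replace = TRUE) - 1L,
                 c(6, 10, 12))
      b <- array(sample.int(2^bits, 6 * 10 * 12, replace = TRUE) - 1L,
                 c(6, 10, 12))
      grids <- list(voxel_grid(a, SIM_VS, "DAPI", bits),
                    voxel_grid(b, SIM_VS, "H3K4me3", bits))
      write_stack(grids, "s.tif")
      back <- read_stack("s.tif")
      expect_named(back, c("DAPI", "H3K4me3"))
      expect_equal(back$DAPI$data, a, ignore_attr = TRUE)
      expect_equal(back$H3K4me3$data, b, ignore_attr = TRUE)
      expect_equal(back$DAPI$voxel_size, SIM_VS)
    }
  })
})

test_that("read_stack enforces the channel layout and metadata contract", {
  withr::with_tempdir({
    g <- voxel_grid(array(1, c(4, 6, 6)), SIM_VS)
    write_stack(list(g, g, g), "three.tif")
    expect_error(read_stack("three.tif", channel_layout = c("0" = "a", "1" = "b")),
                 "channel")
    # plain TIFF without embedded metadata requires an explicit voxel size
    nucland:::write_tiff_pages("plain.tif",
                               list(matrix(1:20, 4, 5), matrix(1:20, 4, 5)), 16L)
    expect_error(read_stack("plain.tif"), "voxel")
    got <- read_stack("plain.tif", voxel_size = c(200, 50, 50))
    expect_equal(dim(got[[1]]$data), c(2L, 4L, 5L))
  })
})

test_that("mask TIFF + JSON sidecar round-trips", {
  withr::with_tempdir({
    mk <- ball_mask(6, SIM_VS)
    mk$nucleus_id <- 7L
    write_mask(mk, "m.tif")
    expect_true(file.exists("m.tif.json"))
    back <- read_mask("m.tif")
    expect_identical(back$data, mk$data)
    expect_identical(back$nucleus_id, 7L)
    side <- jsonlite::fromJSON("m.tif.json")
    expect_equal(side$n_voxels, sum(mk$data))
  })
})

test_that("generate_nuclear_mask recovers a noisy ellipsoid (Jaccard >= 0.95)", {
  fx <- noisy_ellipsoid_grid(seed = 11)
  mk <- generate_nuclear_mask(fx$grid)
  expect_gte(jaccard(mk$data, fx$truth), 0.95)
  lab <- nucland:::cpp_label3d(as.logical(mk$data), dim(mk$data), 26L)
  expect_identical(max(lab), 1L)
})

test_that("generate_nuclear_mask errors on an empty field", {
  g <- voxel_grid(array(0, c(8, 8, 8)), SIM_VS)
  expect_error(generate_nuclear_mask(g, threshold = 10), "no nucleus found")
})

test_that("two-lobed nuclei stay one 26-connected component", {
  sim <- generate_nucleus(phenotype_spec("granulocyte"), seed = 2)
  dapi <- sim$channels$DAPI
  mk <- generate_nuclear_mask(dapi)
  lab <- nucland:::cpp_label3d(as.logical(mk$data), dim(mk$data), 26L)
  expect_identical(max(lab), 1L)
  expect_gte(jaccard(mk$data, sim$truth$mask$data), 0.9)
})

test_that("mask generation is stable on its own masked image", {
  # exact voxel idempotence is unattainable for a smoothing-based threshold
  # (the blurred hard edge moves the level crossing by up to half a voxel);
  # assert near-identity with differences confined to the boundary shell
  fx <- noisy_ellipsoid_grid(seed = 5)
  mk <- generate_nuclear_mask(fx$grid)
  mk2 <- generate_nuclear_mask(masked_view(fx$grid, mk))
  expect_gte(jaccard(mk$data, mk2$data), 0.99)
  dm <- border_distance_map(mk)
  diff_idx <- which(mk$data != mk2$data)
  if (length(diff_idx))
    expect_lte(max(dm[diff_idx]), sqrt(sum(SIM_VS^2)) + 1e-9)
})

test_that("open tunnels and invaginations survive hole filling; cavities do not", {
  sh <- c(24, 48, 48)
  tru <- ellipsoid_arr(sh, (sh + 1) / 2, c(9, 20, 20))
  tunnel <- array(FALSE, sh)
  tunnel[, 21:28, 21:28] <- TRUE       # open tunnel along z, ~316 nm wide
  cavity <- ellipsoid_arr(sh, c(12.5, 16, 16), c(3, 4, 4))  # enclosed cavity
  img <- array(60, sh)
  img[tru & !tunnel & !cavity] <- 500
  mk <- generate_nuclear_mask(voxel_grid(img, SIM_VS), close_radius_nm = 0)
  mid <- mk$data[12, 24, 24]
  expect_false(mid)                     # tunnel stays open
  expect_true(mk$data[12, 16, 16])      # cavity filled
})

test_that("masked_view zeroes everything outside the mask", {
  fx <- noisy_ellipsoid_grid(seed = 3)
  mk <- generate_nuclear_mask(fx$grid)
  mv <- masked_view(fx$grid, mk)
  expect_true(all(mv$data[!mk$data] == 0))
  expect_identical(mv$data[mk$data], fx$grid$data[mk$data])
})
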