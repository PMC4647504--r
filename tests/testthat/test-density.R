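# Equal-variance mixture EM, MAP/ICM classification, class distributions.

test_that("EM recovers a 3-component mixture within stated tolerances", {
  set.seed(42)
  x <- c(rnorm(5e4, 100, 40), rnorm(3e4, 300, 40), rnorm(2e4, 500, 40))
  p <- fit_mixture(x, K = 3)
  expect_true(attr(p, "converged"))
  expect_lt(max(abs(p$weights - c(0.5, 0.3, 0.2))), 0.01)
  expect_lt(max(abs(p$means / c(100, 300, 500) - 1)), 0.02)
  expect_lt(abs(p$sd / 40 - 1), 0.05)
  # fitted likelihood must reach at least the brute-force likelihood at truth
  ll_at <- function(mu, sg, pw) {
    lg <- vapply(seq_along(mu), function(c)
      log(pw[c]) + dnorm(x, mu[c], sg, log = TRUE), numeric(length(x)))
    m <- apply(lg, 1, max)
    sum(m + log(rowSums(exp(lg - m))))
  }
  expect_gte(ll_at(p$means, p$sd, p$weights) + 1e-6 * abs(ll_at(p$means, p$sd, p$weights)),
             ll_at(c(100, 300, 500), 40, c(0.5, 0.3, 0.2)))
})

test_that("K = 1 reduces to the closed-form single-Gaussian MLE", {
  set.seed(1)
  x <- rnorm(500, 37, 5)
  p <- fit_mixture(x, K = 1)
  expect_equal(p$means, mean(x), tolerance = 1e-6)
  expect_equal(p$sd, sqrt(mean((x - mean(x))^2)), tolerance = 1e-4)
  expect_equal(p$weights, 1)
})

test_that("EM log-likelihood is non-decreasing and errors on degenerate input", {
  set.seed(2)
  x <- c(rnorm(3000, 50, 10), rnorm(3000, 150, 10))
  p <- fit_mixture(x, K = 2)
  ll <- attr(p, "loglik")
  expect_true(all(diff(ll) >= -1e-7 * abs(ll[-length(ll)])))
  expect_error(fit_mixture(rep(5, 1000), K = 3), "degenerate histogram")
  expect_error(fit_mixture(rnorm(10), K = 3), "at least")
})

test_that("beta = 0 classification equals the per-voxel posterior argmax oracle", {
  set.seed(3)
  for (rep in 1:5) {
    K <- sample(2:7, 1)
    params <- mixture_params(means = sort(runif(K, 0, 1000)),
                             sd = runif(1, 10, 80),
                             weights = {w <- runif(K); w / sum(w)})
    sh <- c(8, 8, 8)
    m <- array(runif(prod(sh)) > 0.3, sh)
    g <- voxel_grid(array(runif(prod(sh), 0, 1000), sh), SIM_VS)
    mk <- nuclear_mask(m, SIM_VS, check = FALSE)
    cm <- classify_voxels(g, mk, params)
    expect_identical(cm$labels[m], gmm_map_oracle(g$data[m], params))
    expect_true(all(cm$labels[!m] == 0L))
  }
})

test_that("exact posterior ties break toward the lower class", {
  params <- mixture_params(means = c(100, 300), sd = 50,
                           weights = c(0.5, 0.5))
  sh <- c(4, 4, 4)
  g <- voxel_grid(array(200, sh), SIM_VS)  # equidistant from both means
  mk <- nuclear_mask(array(TRUE, sh), SIM_VS, check = FALSE)
  cm <- suppressWarnings(classify_voxels(g, mk, params))
  expect_true(all(cm$labels == 1L))
})

test_that("ICM with beta > 0 absorbs salt noise that beta = 0 keeps", {
  K <- 3
  params0 <- mixture_params(means = c(100, 300, 500), sd = 40,
                            weights = rep(1 / 3, 3))
  sh <- c(7, 7, 7)
  a <- array(500, sh)
  a[4, 4, 4] <- 100                      # lone low-intensity voxel
  g <- voxel_grid(a, SIM_VS)
  mk <- nuclear_mask(array(TRUE, sh), SIM_VS, check = FALSE)
  cm0 <- suppressWarnings(classify_voxels(g, mk, params0))
  expect_identical(cm0$labels[4, 4, 4], 1L)
  params2 <- params0; params2$beta <- 2
  cm2 <- suppressWarnings(classify_voxels(g, mk, params2))
  expect_identical(cm2$labels[4, 4, 4], 3L)
  # hand check: with 26 neighbours of class 3, class 3 wins iff
  # logN(100|500) - logN(100|100) > -beta*26, i.e. beta*26 > (400/40)^2/2 = 50
  expect_gt(2 * 26, (400 / 40)^2 / 2)
})

test_that("ICM is stable when restarted from its own output", {
  set.seed(4)
  sh <- c(10, 10, 10)
  g <- voxel_grid(array(runif(prod(sh), 0, 600), sh), SIM_VS)
  mk <- nuclear_mask(ellipsoid_arr(sh, c(5.5, 5.5, 5.5), c(4, 4, 4)),
                     SIM_VS, check = FALSE)
  params <- mixture_params(means = c(100, 300, 500), sd = 60,
                           weights = rep(1 / 3, 3), beta = 1.5)
  cm <- classify_voxels(g, mk, params)
  again <- nucland:::cpp_icm(as.numeric(g$data), as.logical(mk$data),
                             as.integer(cm$labels), dim(g$data),
                             params$means, params$sd, log(params$weights),
                             params$beta, params$neighborhood, 50L)
  expect_identical(array(again$labels, sh), cm$labels)
})

test_that("classification is invariant under affine intensity rescaling", {
  set.seed(5)
  sh <- c(9, 9, 9)
  g <- voxel_grid(array(runif(prod(sh), 0, 800), sh), SIM_VS)
  mk <- nuclear_mask(array(TRUE, sh), SIM_VS, check = FALSE)
  params <- mixture_params(means = c(120, 380, 640), sd = 55,
                           weights = c(0.3, 0.4, 0.3))
  cm1 <- suppressWarnings(classify_voxels(g, mk, params))
  a <- 3.7; b <- 55
  g2 <- voxel_grid(a * g$data + b, SIM_VS)
  params2 <- mixture_params(means = a * params$means + b, sd = a * params$sd,
                            weights = params$weights)
  cm2 <- suppressWarnings(classify_voxels(g2, mk, params2))
  expect_identical(cm1$labels, cm2$labels)
})

test_that("class_distribution counts and normalizes", {
  lab <- array(0L, c(4, 4, 4))
  lab[1:10] <- 1L; lab[11:40] <- 2L
  cd <- class_distribution(fake_classmap(lab, 2))
  expect_equal(cd$fractions, c(0.25, 0.75))
  expect_equal(sum(cd$fractions), 1, tolerance = 1e-12)
  expect_identical(cd$n_voxels, 40L)
})

test_that("full classification recovers generator class volumes within 0.03", {
  sim <- generate_nucleus(phenotype_spec("monocyte"), seed = 9)
  res <- classify_nucleus(sim$channels$DAPI, sim$truth$mask, K = 7)
  expect_lt(max(abs(res$distribution$fractions - sim$truth$class_volumes)),
            0.03)
  # class 1 mean sits in the generator's background-intensity band
  bg <- sim$truth$background_level
  expect_gt(res$params$means[1], 0.5 * bg)
  expect_lt(res$params$means[1], 2.5 * bg)
  expect_false(is.unsorted(res$params$means, strictly = TRUE))
})

test_that("granulocyte-like nuclei carry more class 5-7 mass than progenitor-like", {
  mass <- vapply(c("progenitor", "granulocyte"), function(ph) {
    sim <- generate_nucleus(phenotype_spec(ph), seed = 12)
    res <- classify_nucleus(sim$channels$DAPI, sim$truth$mask, K = 7)
    sum(res$distribution$fractions[5:7])
  }, 0)
  expect_gt(mass[["granulocyte"]], mass[["progenitor"]])
})
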