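# Synthetic nucleus generator: multi-channel 3D nuclei, TEM-like 2D sections
# and radial-signal fixtures with exact ground truth, emulating the imaged
# phenotypes at desk scale.  The DAPI landscape is built from a structured
# scalar field (chromatin-domain-cluster cores + peripheral shell - central
# lacunae + smooth texture); class volumes are made exact pre-noise by rank
# remapping of that field onto the target class-volume vector.

#' Phenotype specification for the synthetic nucleus generator
#'
#' Encodes the morphological regimes seen across myelopoietic differentiation:
#' a progenitor-like network of many small chromatin domain clusters (CDCs)
#' permeated by interchromatin channels, through intermediates, to a
#' granulocyte-like lobed nucleus with a compact peripheral chromatin shell
#' around a central IC lacuna.  Target class-volume vectors keep the class-1
#' (IC) fraction near-constant across phenotypes while shifting mass toward
#' higher classes with differentiation.
#'
#' @param phenotype one of "progenitor", "precursor", "monocyte",
#'   "granulocyte".
#' @param ... overrides for any field (n_lobes, cdc_count, cdc_radius_nm,
#'   cdc_clustering, peripheral_shell_fraction, ic_lacuna_fraction,
#'   target_class_volumes).
#' @return a \code{phenotype_spec}.
#' @export
phenotype_spec <- function(phenotype = c("progenitor", "precursor", "monocyte",
                                         "granulocyte"), ...) {
  phenotype <- match.arg(phenotype)
  defaults <- switch(phenotype,
    progenitor = list(n_lobes = 1L, cdc_count = 40L, cdc_radius_nm = 300,
                      cdc_clustering = 0.3, peripheral_shell_fraction = 0.10,
                      ic_lacuna_fraction = 0.05,
                      target_class_volumes = c(0.17, 0.20, 0.18, 0.15, 0.12, 0.10, 0.08)),
    precursor  = list(n_lobes = 1L, cdc_count = 30L, cdc_radius_nm = 350,
                      cdc_clustering = 0.5, peripheral_shell_fraction = 0.25,
                      ic_lacuna_fraction = 0.08,
                      target_class_volumes = c(0.17, 0.17, 0.16, 0.15, 0.13, 0.12, 0.10)),
    monocyte   = list(n_lobes = 1L, cdc_count = 20L, cdc_radius_nm = 400,
                      cdc_clustering = 0.6, peripheral_shell_fraction = 0.40,
                      ic_lacuna_fraction = 0.12,
                      target_class_volumes = c(0.17, 0.14, 0.14, 0.15, 0.14, 0.13, 0.13)),
    granulocyte = list(n_lobes = 2L, cdc_count = 8L, cdc_radius_nm = 450,
                       cdc_clustering = 0.8, peripheral_shell_fraction = 0.80,
                       ic_lacuna_fraction = 0.20,
                       target_class_volumes = c(0.17, 0.10, 0.11, 0.13, 0.15, 0.16, 0.18)))
  spec <- modifyList(defaults, list(...))
  v <- spec$target_class_volumes
  if (any(v < 0) || abs(sum(v) - 1) > 1e-8)
    stopf("inconsistent spec: target_class_volumes must be non-negative and sum to 1")
  if (spec$ic_lacuna_fraction > v[1] + v[2])
    stopf("inconsistent spec: ic_lacuna_fraction %.2f exceeds low-class volume %.2f",
          spec$ic_lacuna_fraction, v[1] + v[2])
  spec$phenotype <- phenotype
  structure(spec, class = "phenotype_spec")
}

# Ellipsoid foreground in voxel units; center and semi-axes in (z, y, x) voxels.
ellipsoid_mask <- function(shape, center, semi) {
  z <- seq_len(shape[1]); y <- seq_len(shape[2]); x <- seq_len(shape[3])
  az <- ((z - center[1]) / semi[1])^2
  ay <- ((y - center[2]) / semi[2])^2
  ax <- ((x - center[3]) / semi[3])^2
  array(outer(outer(az, ay, `+`), ax, `+`), shape) <= 1
}

# Lobed nuclear mask in a given grid; returns logical array + lobe centers.
build_lobed_mask <- function(shape, n_lobes, voxel_size) {
  cz <- (shape[1] + 1) / 2; cy <- (shape[2] + 1) / 2; cx <- (shape[3] + 1) / 2
  rz <- 0.38 * shape[1]
  if (n_lobes <= 1L) {
    r <- 0.40 * min(shape[2], shape[3])
    m <- ellipsoid_mask(shape, c(cz, cy, cx), c(rz, r, r))
    return(list(mask = m, centers = list(c(cz, cy, cx)),
                lobe_radius_vox = r))
  }
  r <- 0.26 * min(shape[2], shape[3])
  sep <- 1.35 * r
  centers <- lapply(seq_len(n_lobes), function(i)
    c(cz, cy, cx + (i - (n_lobes + 1) / 2) * sep))
  m <- array(FALSE, shape)
  for (ce in centers) m <- m | ellipsoid_mask(shape, ce, c(rz, r, r))
  # bridge between consecutive lobes so the mask stays 26-connected
  for (i in seq_len(n_lobes - 1L)) {
    a <- centers[[i]]; b <- centers[[i + 1L]]
    bridge <- ellipsoid_mask(shape, (a + b) / 2, c(0.35 * rz, 0.30 * r,
                                                   0.80 * sep))
    m <- m | bridge
  }
  list(mask = m, centers = centers, lobe_radius_vox = r)
}

# Additive Gaussian blob field at physical-coordinate centers.
add_blobs <- function(field, centers, sigma_nm, voxel_size, amplitude = 1) {
  d <- dim(field)
  sig_vox <- sigma_nm / voxel_size
  for (ce in centers) {
    lo <- pmax(1, floor(ce - 3 * sig_vox))
    hi <- pmin(d, ceiling(ce + 3 * sig_vox))
    if (any(hi < lo)) next
    rg <- lapply(1:3, function(k) lo[k]:hi[k])
    az <- ((rg[[1]] - ce[1]) / sig_vox[1])^2
    ay <- ((rg[[2]] - ce[2]) / sig_vox[2])^2
    ax <- ((rg[[3]] - ce[3]) / sig_vox[3])^2
    blob <- exp(-outer(outer(az, ay, `+`), ax, `+`) / 2)
    dims <- c(length(rg[[1]]), length(rg[[2]]), length(rg[[3]]))
    field[rg[[1]], rg[[2]], rg[[3]]] <-
      array(field[rg[[1]], rg[[2]], rg[[3]]], dims) +
      amplitude * array(blob, dims)
  }
  field
}

#' Generate a synthetic multi-channel nucleus with ground truth
#'
#' Builds a DAPI landscape whose noiseless class-volume vector matches the
#' phenotype's target exactly: a structured chromatin field (CDC cores +
#' peripheral shell - lacunae + texture) is smoothed at the PSF scale and
#' then rank-remapped onto the target class-volume vector, so the noiseless
#' image realizes the designed classes exactly (generator writes truth
#' before noise).  Marker channels are laid down as diffraction-sized voxel
#' patches sampled with per-class probabilities proportional to the designed
#' enrichment.  Poisson photon noise, Gaussian read noise and 16-bit
#' quantization are applied last.  Deterministic for a given seed.
#'
#' @param spec a \code{\link{phenotype_spec}}.
#' @param markers named list of designed per-class enrichment vectors
#'   \eqn{E_c} (length K, each >= -1); may be NULL.
#' @param shape grid shape (z, y, x) in voxels.
#' @param voxel_size physical voxel edges (dz, dy, dx) nm.
#' @param noise list: \code{photon_scale} (photons per intensity unit),
#'   \code{read_sd}, \code{psf_sigma_nm} (z, y, x; smooths the structured
#'   field, i.e. sets the morphological grain of the landscape).
#' @param n_marker_voxels positive voxels laid down per marker channel.
#' @param seed integer RNG seed.
#' @return list with \code{channels} (named list of \code{voxel_grid}, DAPI
#'   first) and \code{truth} (mask, exact noiseless \code{class_map}, realized
#'   class volumes, per-marker design and positive-voxel indices, intensity
#'   levels, seed).
#' @export
generate_nucleus <- function(spec, markers = NULL, shape = c(42L, 100L, 100L),
                             voxel_size = c(125, 39.5, 39.5),
                             noise = list(photon_scale = 2, read_sd = 20,
                                          psf_sigma_nm = c(125, 50, 50)),
                             n_marker_voxels = 4000L, seed = 1L) {
  stopifnot(inherits(spec, "phenotype_spec"))
  noise <- modifyList(list(photon_scale = 2, read_sd = 20,
                           psf_sigma_nm = c(125, 50, 50)), noise)
  K <- length(spec$target_class_volumes)
  with_seed(seed, {
    lob <- build_lobed_mask(shape, spec$n_lobes, voxel_size)
    msk <- lob$mask
    d <- shape
    idx <- which(msk)
    n <- length(idx)
    depth <- array(cpp_edt3d(as.logical(!msk), d, voxel_size), d)

    # CDC centers: clustered around a few parents (Matern-like)
    n_parents <- max(1L, round(spec$cdc_count * (1 - spec$cdc_clustering)))
    cand <- which(depth > 0.2 * max(depth))
    parents <- arrayInd(sample(cand, n_parents, replace = TRUE), d)
    assign_p <- sample(n_parents, spec$cdc_count, replace = TRUE)
    spread_vox <- (2 - spec$cdc_clustering) * spec$cdc_radius_nm / voxel_size
    centers <- lapply(seq_len(spec$cdc_count), function(i) {
      p <- parents[assign_p[i], ]
      p + rnorm(3) * spread_vox
    })
    S <- array(0, d)
    S <- add_blobs(S, centers, spec$cdc_radius_nm, voxel_size, amplitude = 1)
    # peripheral compacted shell: high density near the border
    S <- S + 2.5 * spec$peripheral_shell_fraction * exp(-depth / 300)
    # central IC lacuna per lobe: density sink
    lac_sigma <- 0.45 * lob$lobe_radius_vox * voxel_size[3]
    S <- add_blobs(S, lob$centers, lac_sigma, voxel_size,
                   amplitude = -6 * spec$ic_lacuna_fraction)
    # smooth texture for within-class variety and deterministic tie-breaks
    tex <- gaussian_blur3d(array(rnorm(prod(d)), d), c(1, 1.5, 1.5))
    S <- S + 0.15 * tex / max(sd(tex), 1e-12)
    # PSF-scale smoothing of the structured field (morphological grain)
    S <- gaussian_blur3d(S, noise$psf_sigma_nm / voxel_size)

    # rank remap: exact class volumes on the noiseless image
    v <- spec$target_class_volumes
    counts <- diff(round(c(0, cumsum(v)) * n))
    cls <- integer(n)
    cls[order(S[idx])] <- rep.int(seq_len(K), counts)
    labels <- array(0L, d)
    labels[idx] <- cls

    background_level <- 100
    class_levels <- 120 + 120 * (seq_len(K) - 1)
    dapi0 <- array(background_level, d)
    dapi0[idx] <- class_levels[cls]

    # marker channels: voxel placement follows the designed enrichment
    D_real <- counts / n
    marker_truth <- list()
    marker0 <- list()
    if (!is.null(markers)) {
      stopifnot(is.list(markers), !is.null(names(markers)))
      for (mn in names(markers)) {
        E <- markers[[mn]]
        if (length(E) != K || any(E < -1))
          stopf("designed enrichment for '%s' must have length %d and E >= -1", mn, K)
        M <- D_real * (1 + E)
        if (sum(M) <= 0) stopf("designed enrichment for '%s' leaves no signal", mn)
        M <- M / sum(M)
        n_per <- round(M * n_marker_voxels)
        # place diffraction-sized patches (seed voxel + in-class 26-neighbours)
        # so signals survive noise the way real immunostain puncta do
        cls_grid <- labels
        used <- array(FALSE, d)
        pos <- integer(0)
        for (c in seq_len(K)) {
          pool <- idx[cls == c]
          quota <- min(n_per[c], length(pool))
          placed <- 0L
          guard <- 0L
          while (placed < quota && guard < 20L * quota + 100L) {
            guard <- guard + 1L
            s <- pool[sample.int(length(pool), 1L)]
            ai <- arrayInd(s, d)
            zr <- max(1L, ai[1] - 1L):min(d[1], ai[1] + 1L)
            yr <- max(1L, ai[2] - 1L):min(d[2], ai[2] + 1L)
            xr <- max(1L, ai[3] - 1L):min(d[3], ai[3] + 1L)
            nb <- as.vector(outer(outer(zr, (yr - 1L) * d[1], `+`),
                                  (xr - 1L) * d[1] * d[2], `+`))
            nb <- nb[cls_grid[nb] == c & !used[nb]]
            if (length(nb) == 0L) next
            take <- nb[seq_len(min(length(nb), quota - placed))]
            used[take] <- TRUE
            pos <- c(pos, take)
            placed <- placed + length(take)
          }
        }
        ch0 <- array(50, d)
        ch0[pos] <- 600
        marker0[[mn]] <- ch0
        realized <- tabulate(cls_grid[pos], nbins = K)
        # a requested E violating the identity sum(D*E) = 0 is unrealizable;
        # the achievable design is its projection E' = M/D - 1 with M
        # proportional to D*(1+E) renormalized
        marker_truth[[mn]] <- list(E_requested = E,
                                   E_design = ifelse(D_real > 0,
                                                     M / D_real - 1, NA_real_),
                                   M_design = M,
                                   M_realized = realized / length(pos),
                                   positive_idx = sort(pos),
                                   n_positive = length(pos))
      }
    }

    add_noise <- function(a) {
      ph <- noise$photon_scale
      a <- rpois(length(a), lambda = as.vector(a) * ph) / ph +
        rnorm(length(a), sd = noise$read_sd)
      array(pmin(pmax(round(a), 0), 65535), d)
    }
    channels <- list(DAPI = voxel_grid(add_noise(dapi0), voxel_size,
                                       channel_name = "DAPI", bit_origin = 16L))
    for (mn in names(marker0))
      channels[[mn]] <- voxel_grid(add_noise(marker0[[mn]]), voxel_size,
                                   channel_name = mn, bit_origin = 16L)

    truth_params <- mixture_params(means = class_levels,
                                   sd = max(10, noise$read_sd),
                                   weights = D_real)
    truth <- list(
      mask = nuclear_mask(msk, voxel_size, nucleus_id = 1L, check = FALSE),
      classmap = structure(list(labels = labels, params = truth_params,
                                source_channel = "DAPI",
                                voxel_size = voxel_size, icm_sweeps = 0L),
                           class = "class_map"),
      class_volumes = D_real,
      target_class_volumes = v,
      markers = marker_truth,
      background_level = background_level,
      class_levels = class_levels,
      phenotype = spec$phenotype,
      seed = seed)
    list(channels = channels, truth = truth)
  })
}

#' Generate a TEM-like binary chromatin section with analytic interface length
#'
#' A disk nucleus whose chromatin is the disk minus a set of non-overlapping
#' circular IC holes; the exact analytic interface length is the summed hole
#' circumference.  "many-small-holes" emulates a progenitor-like section,
#' "single-lacuna" a granulocyte-like one.
#'
#' @param layout "many-small-holes" or "single-lacuna".
#' @param n_holes number of holes (forced to 1 for "single-lacuna").
#' @param hole_radius_px hole radius in pixels.
#' @param nucleus_radius_px disk radius in pixels.
#' @param pixel_size nm per pixel.
#' @param noise_sd Gaussian intensity noise (intensity units; chromatin 200,
#'   IC 50).
#' @param seed RNG seed.
#' @return list: \code{section} (a \code{section_image}), \code{nuclear_mask}
#'   and \code{chromatin_mask} (logical matrices), and \code{truth} with the
#'   analytic \code{interface_length} (nm), \code{P_nucleus},
#'   \code{A_nucleus} and normalized interface.
#' @export
generate_tem_section <- function(layout = c("many-small-holes", "single-lacuna"),
                                 n_holes = 20L, hole_radius_px = 10,
                                 nucleus_radius_px = 200, pixel_size = 10,
                                 noise_sd = 8, seed = 1L) {
  layout <- match.arg(layout)
  if (layout == "single-lacuna") n_holes <- 1L
  R <- nucleus_radius_px
  sz <- 2L * ceiling(R) + 21L
  c0 <- (sz + 1) / 2
  xg <- matrix(rep(seq_len(sz), each = sz), sz)
  yg <- matrix(rep(seq_len(sz), times = sz), sz)
  nuc <- (xg - c0)^2 + (yg - c0)^2 <= R^2
  with_seed(seed, {
    centers <- matrix(0, 0, 2)
    margin <- 4
    if (n_holes == 1L) {
      centers <- matrix(c(c0, c0), 1)
    } else {
      tries <- 0L
      while (nrow(centers) < n_holes && tries < 20000L) {
        tries <- tries + 1L
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * (R - hole_radius_px - margin)
        p <- c(c0 + rad * cos(ang), c0 + rad * sin(ang))
        if (nrow(centers) == 0L ||
            all(sqrt(rowSums(sweep(centers, 2, p)^2)) >
                2 * hole_radius_px + 3))
          centers <- rbind(centers, p)
      }
      if (nrow(centers) < n_holes)
        stopf("could not place %d non-overlapping holes of radius %g in radius %g",
              n_holes, hole_radius_px, R)
    }
    holes <- matrix(FALSE, sz, sz)
    for (i in seq_len(nrow(centers)))
      holes <- holes | ((xg - centers[i, 1])^2 + (yg - centers[i, 2])^2 <=
                          hole_radius_px^2)
    chrom <- nuc & !holes
    img <- matrix(50, sz, sz)
    img[chrom] <- 200
    img <- img + rnorm(length(img), sd = noise_sd)
    img <- pmax(img, 0)
    n_placed <- nrow(centers)
    truth <- list(
      interface_length = n_placed * 2 * pi * hole_radius_px * pixel_size,
      P_nucleus = 2 * pi * R * pixel_size,
      A_nucleus = pi * R^2 * pixel_size^2,
      normalized_interface = (n_placed * 2 * pi * hole_radius_px) /
        (pi * R^2) / pixel_size,
      n_holes = n_placed, hole_radius_px = hole_radius_px, layout = layout)
    list(section = section_image(img, pixel_size, modality = "TEM"),
         nuclear_mask = nuc, chromatin_mask = chrom, truth = truth)
  })
}

#' Generate a radial-signal fixture with designed mean relative depths
#'
#' Channels whose intensity mass concentrates at designed relative border
#' distances of an ellipsoidal mask: intensity
#' \eqn{\exp(-(d_{rel}-m)^2 / 2s^2)} per masked voxel, optionally Poisson
#' sampled.  \code{spread = 0} places all mass on the voxel(s) whose relative
#' depth is nearest the design mean.
#'
#' @param channel_means named vector of designed mean relative distances in
#'   (0, 1]; names become channel names.
#' @param spread Gaussian spread of the radial placement (relative units).
#' @param shape grid shape (z, y, x).
#' @param voxel_size physical voxel edges, nm.
#' @param photon_scale Poisson photon scale (0 = noise-free).
#' @param seed RNG seed.
#' @return list: \code{channels} (named \code{voxel_grid} list), \code{mask},
#'   \code{distance_map}, \code{truth} (designed means and realized
#'   intensity-weighted mean relative depths).
#' @export
generate_radial_fixture <- function(channel_means, spread = 0.12,
                                    shape = c(24L, 40L, 40L),
                                    voxel_size = c(125, 39.5, 39.5),
                                    photon_scale = 0, seed = 1L) {
  stopifnot(all(channel_means > 0), all(channel_means <= 1))
  if (is.null(names(channel_means)))
    names(channel_means) <- paste0("ch", seq_along(channel_means))
  cz <- (shape[1] + 1) / 2; cy <- (shape[2] + 1) / 2; cx <- (shape[3] + 1) / 2
  msk <- ellipsoid_mask(shape, c(cz, cy, cx),
                        c(0.4 * shape[1], 0.42 * shape[2], 0.42 * shape[3]))
  mask <- nuclear_mask(msk, voxel_size, check = FALSE)
  dm <- border_distance_map(mask)
  rel <- dm / max(dm)
  idx <- which(msk)
  with_seed(seed, {
    channels <- list()
    realized <- numeric(0)
    for (mn in names(channel_means)) {
      m <- channel_means[[mn]]
      a <- array(0, shape)
      if (spread <= 0) {
        dev <- abs(rel[idx] - m)
        a[idx[dev <= min(dev) + 1e-12]] <- 1000
      } else {
        # calibrate the placement center so the noiseless intensity-weighted
        # mean relative depth hits the design (border truncation and shell
        # geometry bias a naive Gaussian placement by up to ~0.05)
        ctr <- m
        for (it in 1:30) {
          w <- exp(-(rel[idx] - ctr)^2 / (2 * spread^2))
          got <- sum(w * rel[idx]) / sum(w)
          if (abs(got - m) < 5e-4) break
          ctr <- min(max(ctr + (m - got), -1), 2)
        }
        a[idx] <- 1000 * exp(-(rel[idx] - ctr)^2 / (2 * spread^2))
      }
      if (photon_scale > 0)
        a <- array(rpois(length(a), as.vector(a) * photon_scale) / photon_scale,
                   shape)
      realized[mn] <- sum(a[idx] * rel[idx]) / sum(a[idx])
      channels[[mn]] <- voxel_grid(a, voxel_size, channel_name = mn,
                                   bit_origin = 16L)
    }
    list(channels = channels, mask = mask, distance_map = dm,
         truth = list(design_means = channel_means, realized_means = realized,
                      seed = seed))
  })
}

#' Generate a channel of well-separated Gaussian spots
#'
#' Point-signal fixture for spot counting: \code{n_spots} Gaussian spots
#' (sigma in nm, peak amplitude over a flat background) at mask voxels with
#' pairwise physical separation >= \code{min_separation_nm}.
#'
#' @param mask a \code{nuclear_mask}.
#' @param n_spots number of spots.
#' @param spot_sigma_nm isotropic physical sigma of each spot.
#' @param peak peak amplitude added on top of \code{background}.
#' @param background flat background level.
#' @param min_separation_nm minimum pairwise center distance.
#' @param noise_sd Gaussian read noise (0 = noise-free).
#' @param seed RNG seed.
#' @return list: \code{channel} (\code{voxel_grid}), \code{positions_nm}
#'   (matrix, one row per spot, z/y/x nm).
#' @export
generate_spot_channel <- function(mask, n_spots = 50L, spot_sigma_nm = 80,
                                  peak = 500, background = 50,
                                  min_separation_nm = 500, noise_sd = 0,
                                  seed = 1L) {
  stopifnot(inherits(mask, "nuclear_mask"))
  d <- dim(mask$data)
  vs <- mask$voxel_size
  dm <- border_distance_map(mask)
  pool <- which(dm > max(2 * spot_sigma_nm, 1.5 * max(vs)))
  if (length(pool) < n_spots) stopf("mask too small for %d spots", n_spots)
  with_seed(seed, {
    coords <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(coords) < n_spots && tries < 50000L) {
      tries <- tries + 1L
      i <- sample(pool, 1L)
      p <- (arrayInd(i, d) - 1) * vs
      if (nrow(coords) == 0L ||
          all(sqrt(rowSums(sweep(coords, 2, as.numeric(p))^2)) >=
              min_separation_nm))
        coords <- rbind(coords, as.numeric(p))
    }
    if (nrow(coords) < n_spots)
      stopf("could not place %d spots with separation %g nm", n_spots,
            min_separation_nm)
    a <- array(background, d)
    centers_vox <- lapply(seq_len(nrow(coords)), function(i)
      coords[i, ] / vs + 1)
    a <- add_blobs(a, centers_vox, spot_sigma_nm, vs, amplitude = peak)
    if (noise_sd > 0) a <- a + array(rnorm(length(a), sd = noise_sd), d)
    a <- pmax(a, 0)
    list(channel = voxel_grid(a, vs, channel_name = "spots", bit_origin = 16L),
         positions_nm = coords)
  })
}
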