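# nucland

Quantitative analysis of nuclear architecture in 3D fluorescence microscopy
and 2D TEM images of cell nuclei.

## The scientific problem

During myelopoietic differentiation (progenitor → precursor → monocyte /
granulocyte), the higher-order chromatin landscape of the nucleus is
remodelled: the network of chromatin domain clusters (CDCs) permeated by
finely branched interchromatin (IC) channels seen in progenitors gives way to
a compact peripheral chromatin shell around large central IC lacunae in
granulocytes.  `nucland` provides the measurement machinery to make such
statements quantitative:

- **Chromatin density classification.** Masked DAPI voxel intensities are
  modelled as a K-component Gaussian mixture with a *single shared variance*
  ("equal intensity variance"), fitted by EM:

  p(x) = Σ_c π_c · N(x | μ_c, σ²),  μ_1 < … < μ_K

  Voxels are labelled by the MAP rule argmax_c π_c N(x | μ_c, σ²); with a
  Potts spatial prior (coupling β ≥ 0, hidden Markov random field), labels
  minimise the posterior energy by ICM.  The reference analysis uses K = 7
  and β = 0 (neighbour influence switched off), so class 1 is the
  near-background IC compartment and class 7 the densest chromatin.
- **Marker enrichment/depletion.** A thresholded marker channel is
  correlated voxel-by-voxel with the class map; with D_c the DAPI class
  fractions and M_c the marker fractions, enrichment is
  E_c = (M_c − D_c) / D_c (positive = overrepresentation; Σ_c D_c E_c = 0
  identically).  Group comparisons use the two-sided Wilcoxon rank-sum test
  with continuity correction.
- **Pixel/spot quantification** of punctate signals (e.g. RNA Pol II):
  marker-positive voxels summed over the density classes, plus discrete spot
  counting as 26-connected regional maxima above an intensity offset
  (minimum spot distance 0 by default).
- **Chromatin/IC interface length** on 2D sections (osmium-ammine TEM or SIM
  mid-sections): interface = P(chromatin) − P(nucleus), normalized by nuclear
  area, with perimeters estimated by the 4-direction Crofton approximation.
- **Radial distance profiling** (eADS-style): an exact anisotropic Euclidean
  distance transform to the nuclear border; each voxel contributes its
  intensity at relative depth d/d_max; two-channel comparisons use the
  Mann-Whitney rank-sum test on per-nucleus mean relative depths.
- **Synthetic nucleus generator**: multi-channel 3D nuclei (phenotype-
  dependent morphology, exact class-volume ground truth, designed marker
  enrichment), TEM-like sections with analytic interface length, and radial
  fixtures with designed signal depths — so every stage is testable without
  microscope data.

## Worked example

Simulate a granulocyte-like nucleus with an H3K4me3-like marker designed to
be enriched in the low-density classes, then run the analysis:

```r
library(nucland)
spec <- phenotype_spec("granulocyte")
sim  <- generate_nucleus(spec,
          markers = list(H3K4me3 = c(1.5, 1, 0.5, 0, -0.5, -1, -1)),
          seed = 7)

res <- classify_nucleus(sim$channels$DAPI, sim$truth$mask, K = 7)
res$params
#> <mixture_params> K=7, shared sd=25.44, beta=0 (26-neighbourhood)
#>   means:   120.41 240.56 360.53 480.54 599.87 720.48 840.47
#>   weights: 0.1705 0.09992 0.1101 0.13 0.1501 0.1604 0.179
res$distribution
#> <class_distribution> 1:0.170 2:0.100 3:0.110 4:0.130 5:0.150 6:0.160 7:0.179
```

The seven fitted means are the class centres (class 1 ≈ the background level
of 100 intensity units, the IC); the class distribution shows the
granulocyte-typical weight in the dense classes 5–7 (0.49 of the nuclear
volume here, vs ≈ 0.30 for the progenitor phenotype).

```r
pos  <- threshold_marker(sim$channels$H3K4me3, sim$truth$mask)
enrichment_profile(pos, res$classmap, "H3K4me3")
#> <enrichment_profile 'H3K4me3'> 4001 positive voxels
#>  class      D      M      E
#>      1 0.1704 0.4276  1.510
#>      2 0.1000 0.2009  1.009
#>      3 0.1098 0.1660  0.511
#>      4 0.1302 0.1282 -0.015
#>      5 0.1500 0.0757 -0.495
#>      6 0.1603 0.0015 -0.991
#>      7 0.1793 0.0000 -1.000
```

E > 0 means the marker is overrepresented in that density class relative to
chromatin itself (here: strong enrichment in the decondensed classes 1–3,
near-complete depletion from compact chromatin — the designed pattern).

```r
dm <- border_distance_map(sim$truth$mask)
signal_radial_profile(sim$channels$DAPI, sim$truth$mask, dm)
#> <distance_profile 'DAPI'> 20 bins, 1 nuclei, mean rel. distance 0.243
```

A mean relative border distance of 0.24 reflects the peripheral chromatin
shell of the lobed granulocyte nucleus.

## Command line

```sh
Rscript inst/cli/nucland.R simulate --phenotype granulocyte --seed 7 --out sim/
Rscript inst/cli/nucland.R classify --dapi sim/channels.tif --mask sim/mask.tif \
    --K 7 --beta 0 --summary classes.csv
Rscript inst/cli/nucland.R run --config study.yaml
```

`run_study()` / `nucland run` execute the full comparative study over a
manifest of nuclei (per-nucleus class distributions, enrichment profiles,
spot counts, radial profiles; per-cell-type summaries and pairwise rank-sum
comparisons) and write CSV tables plus a JSON provenance record.

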