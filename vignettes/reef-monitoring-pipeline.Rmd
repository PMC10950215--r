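---
title: "Simulated hyperspectral reef surveys: models, parameters and design choices"
author: "reefscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated hyperspectral reef surveys: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefscan)
```

## The monitoring problem

Benthic reef monitoring traditionally scores photoquadrats: 0.25 m²
photographs taken at every meter mark of fixed 50 m transects, each
overlaid with 50 sample points whose underlying organism or substrate
is identified by an expert (point-intercept cover estimation). A
diver-operated push-broom hyperspectral imager surveying the same
transects promises the same community-composition estimates at a
fraction of the annotation effort: every recorded pixel carries a full
visible/near-infrared spectrum, a classifier predicts a benthic label
per pixel, and percent cover falls out of the label map.

`reefscan` implements both estimation routes end to end and — because
no public scan archive accompanies the survey programme it models —
pairs them with a fully seeded scene simulator, so that every stage can
be tested against known ground truth. The reference conditions are the
Lafac Bay (Guam) forereef surveys of 2015, 2017 and 2019:
ten benthic groups (with the habitat-defining staghorn coral *Acropora
abrotanoides* kept separate from other Scleractinia), five permanent
50 m × 1 m transects, and the published per-survey group mean covers
and between-transect SDs bundled as `lafac_cover_means()` /
`lafac_cover_sd()`.

## The scene simulator

### Label maps

`sample_label_map()` discretizes a transect at `pixel_size_m` (default
1 cm, configurable coarser for fast tests) and realizes a patchy mosaic
of the 10 groups. Each group receives an independent Gaussian-smoothed
random field with correlation length `patchiness_scale_m` (default
0.5 m). Groups claim pixels in order of increasing target cover, each
taking its apportioned pixel count from the highest values of its field
among unclaimed pixels; the dominant group fills the remainder. Two
properties follow by construction:

* **Exact cover matching.** Pixel counts are largest-remainder
  apportionments of the target fractions, so realized group cover
  deviates from the target by at most one pixel per group
  (`10 / n_pixels` in cover units) — every map conserves 100% cover.
* **Compact patches for rare groups.** Because each group thresholds
  *its own* field at a quantile, a 0.5%-cover group forms a few compact
  blobs around its field peaks. (An earlier design thresholded a single
  shared field into ordered quantile bins; that gives mid-bin groups
  thin shell-shaped regions — unrealistic, and pathological for
  patch-based classification. The per-group-field design replaced it.)

Within a group, member fine categories (58 in the bundled scheme) are
laid out along a second, finer field with Dirichlet-distributed
proportions, emulating the within-group taxonomic mixture that the
photoquadrat protocol identifies at species/genus level.

### Spectra and the imaging model

`make_endmembers()` builds one reflectance spectrum per fine category
on the sensor's wavelength grid (400–750 nm at ~2.9 nm): a smooth
random baseline per group, chlorophyll-like absorption troughs near 440
and 675 nm for photosynthetic groups, a flat bright baseline for bare
substrate, plus a group-specific trough placed along the grid. These
are synthetic stand-ins with the qualitative structure of benthic
reflectances, not measured optical properties — conclusions about real
spectra do not transfer. Separability is controlled, not assumed: the
library is redrawn (escalating spectral contrast) until all 45 pairwise
group-mean spectral angles exceed `min_separation` (default 0.05 rad);
tests that need an easy regime request 0.15–0.2 rad explicitly.

`render_scan()` emulates the push-broom camera:

```
radiance(px, λ) = illumination(λ) · exp(−2 k(λ) d) ·
                  reflectance(px, λ) · (1 + intra-class perturbation)
                  + N(0, noise_sd)
```

with a piecewise-linear diffuse attenuation coefficient `k(λ)` rising
steeply above 700 nm (two-way path at the survey altitude d = 1 m —
this reproduces the near-infrared signal collapse that motivates band
trimming), a 10 × 10 cm matte grey reference plate (albedo 0.35)
rendered flat at the same altitude, a fixed cross-track width of 680
sensor pixels (nearest-neighbour resampling of the scene; tests render
on the native grid for speed), and a smooth multiplicative intra-class
perturbation (two fixed low-frequency modes, per-category SD) that
provides the easy/hard dial for classification experiments. Radiance is
clipped at zero. Not modelled: Raman scattering, surface glint, depth
variation, sensor georeferencing.

`simulate_survey_set()` draws per-transect target covers around the
survey means with configurable between-transect SD (the published SDs
by default; truncated at zero and renormalized to 100), then realizes
maps and optionally scans. The true between-transect spatial variance
of the original surveys is unknown, so it stays an explicit parameter
rather than an asserted constant.

## Preprocessing

The scan-processing chain is `smooth → trim → normalize →
standardize` (`preprocess()`); it is deterministic, never changes the
spatial dimensions, and only shrinks the band axis.

* **Smoothing.** Savitzky–Golay (window 7 bands, order 2), the
  spectroscopy standard that preserves absorption-feature shape better
  than a moving average. The filter matrix reproduces
  `signal::sgolayfilt` exactly, including the polynomial edge fits.
* **Band trimming.** The survey protocol removes wavelengths without
  sufficient signal. The band statistic is plate-pixel mean divided by
  plate-pixel SD — the plate is the only calibrated region — with a
  zero-SD convention of infinite SNR so noiseless cubes keep all bands.
  The default threshold of 10 removes the water-absorbed bands above
  ~700 nm under the default water model. `preprocess_set()` applies the
  intersection of per-scan retained bands so one model fingerprint
  serves all transects.
* **Plate normalization.** Reflectance = radiance / mean plate radiance
  × `plate_albedo`. Because plate and reef share the illumination and
  water path, both cancel; with the true plate albedo the simulator's
  endmember reflectances are recovered exactly (to sensor noise). The
  default `plate_albedo = 1` reports reflectance *relative to the
  plate*, sufficient for classification.
* **Standardization.** Per-spectrum z-scoring across bands (constant
  spectra map to zero). Classification then depends on spectral shape,
  not brightness — consistent with the goal of plate normalization.
  The ordering (smoothing before normalization) is a design choice; the
  operations nearly commute and the package fixes one order for
  reproducibility.

## Annotation

Regions of interest are polygons (pixel-center, even-odd containment;
boundary pixels resolved by strict interiority) each containing a
single fine category. `split_library()` stratifies the 90/10
train/validation split by group — whether the original protocol
stratified is unknown; stratification is the safer default — with an
ROI-level split option (`unit = "roi"`) to control spatial
autocorrelation leakage; pixel-level is the default because the
protocol splits labelled *pixels*.

For simulated scenes, `auto_rois()` stands in for the expert: square
single-label ROIs per fine category, half of them deliberately placed
*adjacent to category boundaries*. This mirrors how annotators
delineate polygons up to organism edges, and it matters: with
interior-only ROIs a patch-based classifier never sees boundary
context, and in development the dominant turf matrix systematically
lost its blob-boundary pixels to neighbouring classes (a 3–4
percentage-point cover bias); with boundary-adjacent ROIs the bias
drops below ~0.6 points in the easy regime.

## The spectral-spatial residual network

`ssrn()` fits the package's classifier: for each labelled pixel a
`patch_size × patch_size` patch (default 7, reflect-padded at scan
edges so *every* recorded pixel is classifiable) is processed by

1. a 1×1 convolution projecting the bands to `reduced_channels`
   (default 32),
2. `n_spectral_units` (2) pre-activation residual units acting along
   the feature axis,
3. a linear feature-adjustment layer (output width equal to
   `reduced_channels` — the resize layer's dimension is otherwise
   unspecified in the architecture family, so the simplest choice),
4. `n_spatial_units` (2) residual units acting across the patch
   positions (shared across channels),
5. average pooling over the window and a softmax layer.

The architecture sizes are package defaults (the published study names
the architecture family but no sizes); all are overridable in
`ssrn_config()`. Training minimizes class-weighted cross-entropy
(inverse-frequency weights by default — rare-class failure, as for red
macroalgae in the reference study, is attributed to under-representation,
and weighting is the minimal, ablatable mitigation) with Adam
(`learning_rate = 2e-3`), early-stopping on validation accuracy with
patience 8 of at most 40 epochs; shorter patience proved to stop on
transient plateaus. The softmax layer starts at zero, so the first
recorded loss is exactly `log(n_classes)` — a cheap sanity invariant.
Backpropagation is hand-derived and verified against finite differences
in the test suite. Fixing the seed (and BLAS thread count) makes
training bit-reproducible.

`predict.ssrn()` labels every non-plate pixel (plate pixels carry a
reserved code 0 and are excluded from cover), stores the full softmax
probability raster, breaks argmax ties toward the lowest class index,
and refuses cubes whose band fingerprint differs from training.
`validation_report()` reports the confusion matrix and per-class match
proportions as row-normalized recall (the natural reading of
"proportion of predicted labels that matched the true labels in each
category"); classes with no validation entries are `NA`, not zero.

## Cover estimation

`place_quadrats()` puts one 0.5 × 0.5 m quadrat at every meter mark
(centered on the transect line — the side is unspecified in the
protocol), giving the design identity 5 × 50 × 50 = 12,500 points per
survey. "Nonaligned, systematically sampled" points are implemented as
stratified random sampling: one uniform point per cell of a 10 × 5
lattice over the quadrat. Point-intercept cover pools all points of a
transect (pooling versus averaging quadrat-level covers is identical
with equal point counts per quadrat, as here). Map cover is the pixel
histogram over non-plate pixels. Half-open pixel and quadrat intervals
prevent double counting at boundaries.

## Community statistics

* `shannon()`: H = −Σ p log p (nats), E = H / log S with S fixed at the
  full category count (10), including zero-cover groups. This is the
  convention that reproduces the published 2017 evenness (0.55); with
  S = number of observed groups, 2017 would be unchanged but 2015 would
  not round to the printed value, indicating the published E values
  were computed with the full denominator (the 2015/2019 second
  decimals suggest per-transect inputs).
* `anova_tukey()`: classical one-way ANOVA on square-root transformed
  covers plus Tukey HSD, with a hand-rolled insert-and-absorb compact
  letter display (the box-plot coloring semantics). The sqrt transform
  carries a flag so it cannot be applied twice.
* `bray_curtis()`, `anosim()`, `nmds()`: computed via vegan (`vegdist`,
  `anosim`, `metaMDS` with `autotransform = FALSE`), wrapped behind the
  package API with seeded RNG so permutation p-values are
  bit-reproducible; the test suite checks them against independent
  brute-force implementations (double-loop Bray-Curtis, direct
  rank-algebra R, exhaustive relabeling for small n). Following the
  published analysis, ANOSIM runs on untransformed covers (rank-based),
  nMDS on sqrt-transformed ones; permutation count defaults to 9999
  with the +1-corrected p. ANOSIM uses the 10-group matrices (the
  58-category alternative is unstated in the source protocol).

## Problem sizes and numerical choices

The test suite and the acceptance analyses run on reduced scenes chosen
to exercise every code path at interactive cost: unit fixtures use
40 × 40 to 100 × 100-pixel maps; the end-to-end classifier check uses
five 200 × 100-pixel transects (2 m × 1 m at 1 cm), ~5,000 labelled
pixels, and the full published cover structure of the 2019 survey.
Scaling to full 5,000 × 100-pixel transects changes runtime, not code
paths — the map sampler and cover estimators are tested at full size.
Tolerances: probability rasters sum to 1 ± 1e-5; plate recovery to
1e-6; nMDS uses 20 restarts plus a metric start, tolerance 1e-7.
Degenerate inputs have defined conventions throughout (constant spectra
→ zero vectors, zero-SD bands → infinite SNR, all-zero cover vectors →
error, single-class training libraries → error).

## What passing tests do and do not show

The simulator demonstrates that the pipeline is *correct*: cover
estimates converge to ground truth, the classifier recovers composition
within two percentage points per group under high spectral separation
and low noise, and photoquadrat and map-based covers of the same scenes
are statistically indistinguishable (ANOSIM p > 0.05), mirroring the
method-equivalence claim for the real surveys. On reduced scenes the
method comparison is made over *matched sampling support* — the
classified-map cover is evaluated over the same quadrat footprints the
point survey samples. A miniature transect holds only a handful of
patches, so the quadrat subsample and the full swath differ by
patch-scale spatial sampling error alone; at full survey scale that
error averages out over 50 quadrats, but on a 2 m scene it would
dominate the comparison and ANOSIM would detect the dispersion
mismatch between an exact whole-map estimate and a spatially
subsampled one — a property of the miniature geometry, not of either
method. It does not demonstrate
that the published per-class accuracies (0.88–1.0) transfer: those
depend on real sensor optics, water variability and annotation quality
that the simulator deliberately idealizes. Likewise the published
ANOSIM statistics that depend on per-transect data (R = 0.564 for
2015 vs 2017; R = 0.284 for the 2019 method comparison) cannot be
recomputed from the bundled summary tables; the package reproduces the
comparisons that the summary statistics determine — complete separation
(R = 1, p ≈ 0.009) of 2017 vs 2019 at the published effect sizes — and
exposes `read_cover_csv()` for running the identical analysis on the
original per-transect file where available.
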