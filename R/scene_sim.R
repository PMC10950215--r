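#' Scene configuration for a simulated reef transect
#'
#' A transect scene is a `transect_length_m` x `swath_width_m` strip of
#' reef discretized at `pixel_size_m`, with patchy cover of the 10
#' benthic groups.  Target covers are percent per group and must sum to
#' ~100; `patchiness_scale_m` is the spatial correlation length of the
#' patch mosaic.
#'
#' @param transect_length_m along-track length in metres (default 50).
#' @param swath_width_m cross-track swath width in metres (default 1).
#' @param pixel_size_m ground pixel size in metres (default 0.01).
#' @param target_cover named numeric vector, percent cover per group,
#'   names matching `scheme$groups`; entries >= 0, sum in \[99.5, 100.5\].
#' @param patchiness_scale_m correlation length of patches in metres.
#' @param seed integer RNG seed.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(transect_length_m = 50, swath_width_m = 1,
                         pixel_size_m = 0.01,
                         target_cover = lafac_cover_means()[, "2019-PQ"],
                         patchiness_scale_m = 0.5, seed = 1L) {
  stop_if_not_scalar_pos(transect_length_m, "transect_length_m")
  stop_if_not_scalar_pos(swath_width_m, "swath_width_m")
  stop_if_not_scalar_pos(pixel_size_m, "pixel_size_m")
  stop_if_not_scalar_pos(patchiness_scale_m, "patchiness_scale_m")
  if (any(target_cover < 0))
    stop("target covers must be nonnegative", call. = FALSE)
  s <- sum(target_cover)
  if (s < 99.5 || s > 100.5)
    stop(sprintf("target covers must sum to ~100 (got %.2f)", s),
         call. = FALSE)
  if (is.null(names(target_cover)))
    stop("'target_cover' must be named by group", call. = FALSE)
  structure(list(transect_length_m = transect_length_m,
                 swath_width_m = swath_width_m,
                 pixel_size_m = pixel_size_m,
                 target_cover = target_cover,
                 patchiness_scale_m = patchiness_scale_m,
                 seed = as.integer(seed)),
            class = "scene_config")
}

## Gaussian-smoothed standard-normal random field via circular FFT
## convolution.  `scale_px` is the kernel standard deviation in pixels.
smooth_field <- function(nr, nc, scale_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (scale_px <= 0) return(z)
  kr <- stats::dnorm(pmin(0:(nr - 1), nr - (0:(nr - 1))), sd = scale_px)
  kc <- stats::dnorm(pmin(0:(nc - 1), nc - (0:(nc - 1))), sd = scale_px)
  k <- outer(kr, kc)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

#' Sample a ground-truth label map for a scene
#'
#' Generates a patchy per-pixel map of fine benthic categories whose
#' realized group covers match the configured targets up to pixel
#' discretization.  Each group receives its own Gaussian-smoothed random
#' field; groups claim pixels in order of increasing target cover, each
#' taking its apportioned pixel count from the highest values of its
#' field among still-unclaimed pixels (threshold-at-quantile on smoothed
#' noise).  Rare groups therefore form compact patches around their
#' field peaks instead of thin level-set shells, and the absolute
#' per-group cover error is at most `length(groups) / n_pixels`
#' percentage points (largest-remainder rounding of the target
#' fractions).  Within a group, member fine categories are laid out
#' along a second, finer field with Dirichlet-distributed proportions.
#'
#' @param cfg a [scene_config()].
#' @param scheme a [build_category_scheme()] scheme.
#' @return Object of class `label_map`: list with `grid` (integer
#'   matrix, rows = along-track lines from the transect start, values =
#'   fine-category indices into `scheme$fine`), `resolution_m`,
#'   `level = "fine"` and `scheme`.
#' @export
sample_label_map <- function(cfg, scheme = build_category_scheme()) {
  stopifnot(inherits(cfg, "scene_config"), inherits(scheme, "category_scheme"))
  nr <- max(1L, round(cfg$transect_length_m / cfg$pixel_size_m))
  nc <- max(1L, round(cfg$swath_width_m / cfg$pixel_size_m))
  tc <- cfg$target_cover
  miss <- setdiff(names(tc)[tc > 0], scheme$groups)
  if (length(miss))
    stop("target cover names unknown to scheme: ",
         paste(miss, collapse = ", "), call. = FALSE)
  with_seed(cfg$seed, {
    scale_px <- cfg$patchiness_scale_m / cfg$pixel_size_m
    ## exact pixel counts per group; rare groups claim their field
    ## peaks first, the dominant group fills the remainder
    counts <- apportion(tc, nr * nc)
    gidx <- integer(nr * nc)
    claim_order <- order(counts, seq_along(counts))
    claim_order <- claim_order[counts[claim_order] > 0L]
    unclaimed <- rep(TRUE, nr * nc)
    for (k in seq_along(claim_order)) {
      g <- claim_order[k]
      gcode <- match(names(tc)[g], scheme$groups)
      if (k == length(claim_order)) {
        gidx[unclaimed] <- gcode
        break
      }
      fg <- smooth_field(nr, nc, scale_px)
      cand <- which(unclaimed)
      take <- cand[order(fg[cand], decreasing = TRUE)[seq_len(counts[g])]]
      gidx[take] <- gcode
      unclaimed[take] <- FALSE
    }
    ## fine categories within each group along a finer field
    f2 <- smooth_field(nr, nc, max(1, scale_px / 4))
    fine_idx <- integer(nr * nc)
    gi_all <- group_index(scheme)
    for (g in unique(gidx)) {
      members <- which(gi_all == g)
      cells <- which(gidx == g)
      if (length(members) == 1L) { fine_idx[cells] <- members; next }
      w <- stats::rgamma(length(members), shape = 1.5)
      cnt <- apportion(w, length(cells))
      co <- cells[order(f2[cells])]
      at2 <- 0L
      for (m in seq_along(members)) {
        if (cnt[m] == 0L) next
        fine_idx[co[(at2 + 1L):(at2 + cnt[m])]] <- members[m]
        at2 <- at2 + cnt[m]
      }
    }
    structure(list(grid = matrix(fine_idx, nr, nc),
                   resolution_m = cfg$pixel_size_m,
                   level = "fine", scheme = scheme),
              class = "label_map")
  })
}

#' Realized percent cover of a label map
#'
#' @param map a `label_map` (fine- or group-level).
#' @param level `"group"` (default) or `"fine"`.
#' @param exclude optional logical matrix of pixels to leave out (e.g. a
#'   reference-plate mask).
#' @return named numeric vector of percent covers summing to 100.
#' @export
realized_cover <- function(map, level = c("group", "fine"), exclude = NULL) {
  stopifnot(inherits(map, "label_map"))
  level <- match.arg(level)
  v <- as.integer(map$grid)
  if (!is.null(exclude)) v <- v[!as.logical(exclude)]
  v <- v[v > 0L]                      # drop reserved codes (plate = 0)
  if (!length(v)) stop("no labelled pixels", call. = FALSE)
  if (map$level == "fine") {
    names_all <- map$scheme$fine
    if (level == "group") {
      v <- group_index(map$scheme)[v]
      names_all <- map$scheme$groups
    }
  } else {
    if (level == "fine")
      stop("map holds group-level labels; fine cover unavailable",
           call. = FALSE)
    names_all <- map$scheme$groups
  }
  cnt <- tabulate(v, nbins = length(names_all))
  stats::setNames(100 * cnt / sum(cnt), names_all)
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d x %d pixels at %.3g m (%s-level labels)\n",
              nrow(x$grid), ncol(x$grid), x$resolution_m, x$level))
  cv <- realized_cover(x, "group")
  cv <- sort(cv[cv > 0], decreasing = TRUE)
  for (g in names(cv)) cat(sprintf("  %-42s %5.1f%%\n", g, cv[[g]]))
  invisible(x)
}

#' Synthetic endmember spectra for the benthic categories
#'
#' Builds one reflectance spectrum per fine category: a smooth random
#' baseline per group plus category-specific Gaussian absorption
#' troughs.  Photosynthetic groups receive chlorophyll-like dips near
#' 440 and 675 nm; the bare-substrate group keeps a flat bright
#' baseline.  Spectra are synthetic stand-ins with the qualitative
#' structure of real benthic reflectances ("species-specific absorption
#' signatures"), not measured optical properties.  The library is
#' redrawn (up to `max_retries` seeds) until every pair of group-mean
#' spectra is separated by at least `min_separation` radians of spectral
#' angle.
#'
#' @param scheme category scheme.
#' @param wavelength_nm ascending wavelength grid (default 400-750 nm at
#'   the sensor's ~2.9 nm spacing).
#' @param seed integer seed.
#' @param min_separation minimum pairwise spectral angle (radians)
#'   between group means (default 0.05).
#' @param intra_sd per-category intra-class spectral variability used
#'   later by [render_scan()] (default 0.02, multiplicative SD).
#' @param max_retries redraws allowed to achieve separation.  Across
#'   retries the spectral contrast (trough depth and baseline spread) is
#'   escalated, so large separations remain attainable.
#' @param contrast multiplier on absorption-trough depth and baseline
#'   spread (1 = default; larger values make groups easier to
#'   distinguish).
#' @return Object of class `endmember_library`: `wavelength_nm`,
#'   `spectra` (fine categories x bands, in \[0,1\]), `intra_sd`, `scheme`.
#' @export
make_endmembers <- function(scheme = build_category_scheme(),
                            wavelength_nm = seq(400, 750, by = 2.9),
                            seed = 1L, min_separation = 0.05,
                            intra_sd = 0.02, max_retries = 20L,
                            contrast = 1) {
  stopifnot(inherits(scheme, "category_scheme"))
  if (length(wavelength_nm) < 3L || any(diff(wavelength_nm) <= 0))
    stop("'wavelength_nm' must be strictly ascending", call. = FALSE)
  for (try in seq_len(max_retries)) {
    ctr <- contrast * (1 + 0.3 * (try - 1))
    lib <- with_seed(derive_seed(seed, try - 1L),
                     build_endmembers_once(scheme, wavelength_nm, intra_sd,
                                           ctr))
    gm <- group_mean_spectra(lib)
    ang <- min_pairwise_angle(gm)
    if (ang >= min_separation) {
      lib$min_group_angle <- ang
      return(lib)
    }
  }
  stop(sprintf(
    "could not achieve group separation >= %.3g rad in %d retries",
    min_separation, max_retries), call. = FALSE)
}

build_endmembers_once <- function(scheme, wl, intra_sd, contrast = 1) {
  B <- length(wl)
  x <- (wl - min(wl)) / diff(range(wl))       # 0..1
  ngrp <- length(scheme$groups)
  photosyn <- grepl(
    "Acropora|Scleractinia|macroalgae|Turf|Corallinophycidae|Peyssonneliales|Octocorals",
    scheme$groups)
  bare <- grepl("Bare substrate", scheme$groups)
  dip <- function(center, width, depth)
    depth * exp(-0.5 * ((wl - center) / width)^2)
  dep <- function(lo, hi) pmin(0.45, contrast * stats::runif(1, lo, hi))
  base <- matrix(0, ngrp, B)
  for (g in seq_len(ngrp)) {
    lev <- stats::runif(1, 0.25, 0.65)
    if (bare[g]) lev <- stats::runif(1, 0.55, 0.75)
    slope <- stats::runif(1, -0.1, 0.25) * min(2, contrast)
    wig <- stats::rnorm(2, 0, 0.05 * min(2, contrast))
    s <- lev + slope * x + wig[1] * sin(pi * x) + wig[2] * cos(2 * pi * x)
    if (photosyn[g]) {
      s <- s - dip(440, 18, dep(0.10, 0.25)) - dip(675, 12, dep(0.10, 0.25))
    }
    ## group-specific trough spread across the grid for separability
    c1 <- 430 + (g - 1) * (280 / ngrp) + stats::runif(1, -8, 8)
    s <- s - dip(c1, stats::runif(1, 10, 25), dep(0.08, 0.2))
    if (!bare[g] && stats::runif(1) < 0.5)
      s <- s - dip(stats::runif(1, 480, 640), stats::runif(1, 8, 20),
                   dep(0.03, 0.1))
    base[g, ] <- pmin(0.97, pmax(0.03, s))
  }
  gi <- group_index(scheme)
  spectra <- matrix(0, length(scheme$fine), B,
                    dimnames = list(scheme$fine, NULL))
  for (i in seq_along(scheme$fine)) {
    pert <- 1 + 0.04 * stats::rnorm(1) * sin(pi * x + stats::runif(1, 0, pi)) +
      0.02 * stats::rnorm(1)
    spectra[i, ] <- pmin(0.99, pmax(0.01, base[gi[i], ] * pert))
  }
  structure(list(wavelength_nm = wl, spectra = spectra,
                 intra_sd = stats::setNames(rep(intra_sd,
                                                length(scheme$fine)),
                                            scheme$fine),
                 scheme = scheme),
            class = "endmember_library")
}

#' @rdname make_endmembers
#' @param lib an `endmember_library`.
#' @export
group_mean_spectra <- function(lib) {
  stopifnot(inherits(lib, "endmember_library"))
  gi <- group_index(lib$scheme)
  t(vapply(seq_along(lib$scheme$groups),
           function(g) colMeans(lib$spectra[gi == g, , drop = FALSE]),
           numeric(length(lib$wavelength_nm))))
}

min_pairwise_angle <- function(m) {
  n <- nrow(m)
  best <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    best <- min(best, spectral_angle(m[i, ], m[j, ]))
  best
}

#' Diffuse attenuation model of the water column
#'
#' Piecewise-linear diffuse attenuation coefficient k(lambda) (per
#' metre), steeply increasing above ~700 nm where water absorbs most of
#' the signal, applied two-way over a sensor altitude of about one metre
#' above the reef.
#'
#' @param altitude_m sensor altitude above the bottom (default 1).
#' @param scale multiplier on the attenuation curve (0 disables
#'   attenuation).
#' @return list of class `water_model` with a function `k(wavelength)`.
#' @export
water_model <- function(altitude_m = 1, scale = 1) {
  stopifnot(altitude_m >= 0, scale >= 0)
  wl0 <- c(380, 450, 550, 600, 650, 680, 700, 720, 750, 800)
  k0 <- c(0.03, 0.02, 0.06, 0.12, 0.25, 0.40, 0.70, 1.60, 3.00, 4.00)
  structure(list(altitude_m = altitude_m, scale = scale,
                 k = function(wl) scale * stats::approx(wl0, k0, wl,
                                                        rule = 2)$y),
            class = "water_model")
}

#' Render a push-broom hyperspectral scan of a scene
#'
#' Simulates the at-sensor radiance cube for a labelled scene:
#' `radiance = illumination * exp(-2 k(lambda) d) * reflectance *
#' (1 + intra-class perturbation) + noise`, with a matte grey reference
#' plate of flat spectral albedo embedded in the scene and marked in
#' `plate_mask`.  The cross-track axis is resampled to the sensor's
#' `samples` pixels (680 by default, the line-camera width).
#'
#' @param map fine-level `label_map`.
#' @param lib `endmember_library` sharing the map's category scheme.
#' @param water a [water_model()].
#' @param plate list with `row_m`, `col_m` (top-left corner in metres),
#'   `size_m` (default 0.1, the 10 x 10 cm plate) and `albedo`
#'   (default 0.35).
#' @param noise_sd additive sensor noise SD in radiance units.
#' @param seed integer seed.
#' @param samples cross-track sensor pixels (default 680); use
#'   `ncol(map$grid)` to render on the native scene grid.
#' @param illumination scalar or per-band vector of source irradiance.
#' @return Object of class `spectral_cube`: `data` (lines x samples x
#'   bands, nonnegative), `wavelength_nm`, `plate_mask`, `units`
#'   (`"radiance"`), `noise_sd`, and `retained_bands` (all bands).
#' @export
render_scan <- function(map, lib, water = water_model(),
                        plate = list(row_m = 0.2, col_m = 0.2,
                                     size_m = 0.1, albedo = 0.35),
                        noise_sd = 0.005, seed = 1L, samples = 680L,
                        illumination = 1) {
  stopifnot(inherits(map, "label_map"), inherits(lib, "endmember_library"),
            inherits(water, "water_model"))
  if (!identical(map$scheme$fine, lib$scheme$fine))
    stop("map and endmember library use different category schemes",
         call. = FALSE)
  if (map$level != "fine")
    stop("render_scan() needs a fine-level label map", call. = FALSE)
  wl <- lib$wavelength_nm
  B <- length(wl)
  nr <- nrow(map$grid); nc_map <- ncol(map$grid)
  samples <- as.integer(samples)
  stop_if_not_scalar_pos(samples, "samples")
  ## cross-track resampling of the scene onto the sensor grid
  col_of_sample <- pmin(nc_map, pmax(1L, ceiling(seq_len(samples) *
                                                   nc_map / samples)))
  att <- exp(-2 * water$k(wl) * water$altitude_m)
  illum <- rep_len(illumination, B)
  cross_res <- map$resolution_m * nc_map / samples
  pr <- plate_pixels(plate, nr, samples, map$resolution_m, cross_res)
  with_seed(seed, {
    labs <- map$grid[, col_of_sample, drop = FALSE]   # nr x samples
    spec_att <- sweep(lib$spectra, 2, illum * att, `*`) # cat x B
    X <- spec_att[as.integer(labs), , drop = FALSE]    # (nr*samples) x B
    ## multiplicative smooth intra-class perturbation (two fixed modes)
    x01 <- (wl - min(wl)) / diff(range(wl))
    m1 <- sin(pi * x01); m2 <- cos(pi * x01)
    sds <- lib$intra_sd[as.integer(labs)]
    a1 <- stats::rnorm(length(labs), 0, sds)
    a2 <- stats::rnorm(length(labs), 0, sds)
    X <- X * (1 + outer(a1, m1) + outer(a2, m2))
    ## reference plate: flat albedo, same illumination and water path
    plate_rad <- plate$albedo * illum * att
    X[pr$idx, ] <- matrix(plate_rad, length(pr$idx), B, byrow = TRUE)
    if (noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X), B)
    X <- pmax(X, 0)
    structure(list(data = array(X, c(nr, samples, B)),
                   wavelength_nm = wl,
                   plate_mask = pr$mask,
                   units = "radiance",
                   noise_sd = noise_sd,
                   retained_bands = seq_len(B)),
              class = "spectral_cube")
  })
}

plate_pixels <- function(plate, nr, ns, res_row, res_col) {
  r0 <- floor(plate$row_m / res_row) + 1L
  c0 <- floor(plate$col_m / res_col) + 1L
  r1 <- ceiling((plate$row_m + plate$size_m) / res_row)
  c1 <- ceiling((plate$col_m + plate$size_m) / res_col)
  if (r0 < 1L || c0 < 1L || r1 > nr || c1 > ns)
    stop("reference plate region falls outside the scan", call. = FALSE)
  mask <- matrix(FALSE, nr, ns)
  mask[r0:r1, c0:c1] <- TRUE
  list(mask = mask, idx = which(mask))
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "spectral_cube: %d lines x %d samples x %d bands (%.0f-%.0f nm), %s\n",
    d[1], d[2], d[3], min(x$wavelength_nm), max(x$wavelength_nm), x$units))
  cat(sprintf("  plate pixels: %d\n", sum(x$plate_mask)))
  invisible(x)
}

#' Per-band mean signal-to-noise ratio of a simulated cube
#'
#' Mean radiance per band divided by the additive sensor noise SD used
#' at render time; a simulator diagnostic for band-quality checks.
#' @param cube a rendered `spectral_cube`.
#' @return named numeric vector (by wavelength).
#' @export
band_snr <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (is.null(cube$noise_sd) || cube$noise_sd <= 0)
    stop("cube was rendered without noise; SNR undefined", call. = FALSE)
  s <- apply(cube$data, 3, mean) / cube$noise_sd
  stats::setNames(s, cube$wavelength_nm)
}

#' Simulate a multi-year survey set of transect scenes
#'
#' Emulates the monitoring design (five permanent 50 m transects
#' surveyed repeatedly): for each survey, per-transect target covers are
#' drawn around the survey means with a configurable between-transect
#' SD, a label map is realized per transect, and (optionally) a
#' hyperspectral scan is rendered.  Ground-truth realized covers are
#' returned as a [cover_table()] with method `"truth"`.
#'
#' @param targets numeric matrix, groups x surveys, percent cover means
#'   (default the bundled Lafac Bay survey means for 2015/2017/2019).
#' @param n_transects transects per survey (>= 2; ANOSIM is undefined
#'   below that).
#' @param between_sd between-transect SD in percentage points: scalar or
#'   a matrix shaped like `targets`.
#' @param cfg_template `scene_config` whose geometry/patchiness every
#'   transect inherits.
#' @param scheme category scheme.
#' @param lib endmember library (only needed when `render = TRUE`).
#' @param seed master seed; per-transect seeds are derived from it.
#' @param render render radiance cubes (slow) or maps only.
#' @param ... passed on to [render_scan()].
#' @return list with `maps` (named list survey.transect), `cubes` (or
#'   NULL), `targets` (named list of the per-transect target covers
#'   actually drawn), and `truth` (a `cover_table`).
#' @export
simulate_survey_set <- function(targets = lafac_cover_means()[, 1:3],
                                n_transects = 5L,
                                between_sd = lafac_cover_sd()[, 1:3],
                                cfg_template = scene_config(),
                                scheme = build_category_scheme(),
                                lib = NULL, seed = 1L, render = FALSE,
                                ...) {
  stopifnot(is.matrix(targets))
  if (n_transects < 2L)
    stop("'n_transects' must be >= 2", call. = FALSE)
  if (is.null(colnames(targets)))
    stop("'targets' must have survey column names", call. = FALSE)
  sdm <- if (is.matrix(between_sd)) between_sd else
    matrix(between_sd, nrow(targets), ncol(targets),
           dimnames = dimnames(targets))
  maps <- list(); cubes <- if (render) list() else NULL
  rows <- list(); targets_out <- list()
  if (render && is.null(lib))
    lib <- make_endmembers(scheme, seed = derive_seed(seed, 999L))
  off <- 0L
  for (s in colnames(targets)) {
    for (t in seq_len(n_transects)) {
      off <- off + 1L
      tseed <- derive_seed(seed, off)
      tc <- with_seed(derive_seed(tseed, 1L), {
        v <- pmax(0, stats::rnorm(nrow(targets), targets[, s], sdm[, s]))
        v[targets[, s] == 0 & sdm[, s] == 0] <- 0
        if (sum(v) == 0) v <- targets[, s]
        100 * v / sum(v)
      })
      names(tc) <- rownames(targets)
      cfg <- cfg_template
      cfg$target_cover <- tc
      cfg$seed <- derive_seed(tseed, 2L)
      m <- sample_label_map(cfg, scheme)
      key <- sprintf("%s.T%d", s, t)
      maps[[key]] <- m
      targets_out[[key]] <- tc
      if (render)
        cubes[[key]] <- render_scan(m, lib, seed = derive_seed(tseed, 3L),
                                    ...)
      cv <- realized_cover(m, "group")
      rows[[key]] <- data.frame(survey = s, transect = sprintf("T%d", t),
                                method = "truth",
                                category = names(cv), cover_pct = unname(cv),
                                stringsAsFactors = FALSE)
    }
  }
  truth <- cover_table(do.call(rbind, rows))
  list(maps = maps, cubes = cubes, targets = targets_out, truth = truth)
}
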