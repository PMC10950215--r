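#' Preprocessing configuration for hyperspectral scans
#'
#' The scan-processing chain is: Savitzky-Golay smoothing along the band
#' axis, removal of bands without sufficient signal (estimated from the
#' reference-plate pixels), normalization to the grey reference plate to
#' make scans comparable between transects, and per-spectrum
#' standardization so classification depends on spectral shape rather
#' than brightness.
#'
#' @param smooth_window odd filter window in bands (default 7, >= 3).
#' @param smooth_order polynomial order (default 2, < window).
#' @param min_band_snr bands whose plate-pixel mean/SD falls below this
#'   are dropped (default 10; 0 retains everything).
#' @param standardize apply per-spectrum z-scoring as the final step.
#' @param plate_albedo assumed albedo of the reference plate; the
#'   default 1 yields reflectance relative to the plate.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(smooth_window = 7L, smooth_order = 2L,
                              min_band_snr = 10, standardize = TRUE,
                              plate_albedo = 1) {
  smooth_window <- as.integer(smooth_window)
  smooth_order <- as.integer(smooth_order)
  if (smooth_window < 3L || smooth_window %% 2L == 0L)
    stop("'smooth_window' must be an odd integer >= 3", call. = FALSE)
  if (smooth_order < 0L || smooth_order >= smooth_window)
    stop("'smooth_order' must be nonnegative and < smooth_window",
         call. = FALSE)
  if (min_band_snr < 0) stop("'min_band_snr' must be >= 0", call. = FALSE)
  if (plate_albedo <= 0 || plate_albedo > 1)
    stop("'plate_albedo' must be in (0, 1]", call. = FALSE)
  structure(list(smooth_window = smooth_window, smooth_order = smooth_order,
                 min_band_snr = min_band_snr,
                 standardize = isTRUE(standardize),
                 plate_albedo = plate_albedo),
            class = "preprocess_config")
}

## Pixel-major matrix view of the cube data and its inverse.
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  list(m = matrix(cube$data, d[1] * d[2], d[3]), dim = d)
}

set_cube_data <- function(cube, m, dim) {
  cube$data <- array(m, dim)
  cube
}

## Dense Savitzky-Golay smoothing operator (B x B) with polynomial-fit
## edge handling, matching signal::sgolayfilt.
sgolay_operator <- function(n_bands, window, order) {
  F <- signal::sgolay(p = order, n = window)
  h <- (window - 1L) %/% 2L
  op <- matrix(0, n_bands, n_bands)
  mid <- F[h + 1L, ]
  for (i in seq_len(n_bands)) {
    if (i <= h) op[i, 1:window] <- F[i, ]
    else if (i > n_bands - h)
      op[i, (n_bands - window + 1L):n_bands] <- F[window - (n_bands - i), ]
    else op[i, (i - h):(i + h)] <- mid
  }
  op
}

#' Smooth every pixel spectrum with a Savitzky-Golay filter
#'
#' @param cube a `spectral_cube`.
#' @param cfg a [preprocess_config()].
#' @return the cube with smoothed spectra; spatial dimensions unchanged.
#' @export
smooth_spectra <- function(cube, cfg = preprocess_config()) {
  stopifnot(inherits(cube, "spectral_cube"),
            inherits(cfg, "preprocess_config"))
  B <- dim(cube$data)[3]
  if (cfg$smooth_window >= B)
    stop("smoothing window must be smaller than the band count",
         call. = FALSE)
  cm <- cube_matrix(cube)
  op <- sgolay_operator(B, cfg$smooth_window, cfg$smooth_order)
  set_cube_data(cube, cm$m %*% t(op), cm$dim)
}

#' Drop bands without sufficient signal
#'
#' Band quality is estimated from the reference-plate pixels (the only
#' calibrated region of the scan): a band is retained when its
#' plate-pixel mean divided by plate-pixel SD is at least
#' `cfg$min_band_snr`.  A zero SD counts as infinite SNR, so a noiseless
#' cube keeps every band at any finite threshold.  Under the default
#' water model this removes the long wavelengths (above ~700 nm) where
#' water absorbs most of the signal.
#'
#' @inheritParams smooth_spectra
#' @return cube restricted to the retained bands; `retained_bands` holds
#'   the surviving indices of the *original* band grid and
#'   `band_log` a data frame (band_index, wavelength_nm, snr, kept).
#' @export
trim_bands <- function(cube, cfg = preprocess_config()) {
  stopifnot(inherits(cube, "spectral_cube"),
            inherits(cfg, "preprocess_config"))
  if (is.null(cube$plate_mask) || !any(cube$plate_mask))
    stop("cube has no reference-plate pixels to estimate signal from",
         call. = FALSE)
  d <- dim(cube$data)
  idx <- which(cube$plate_mask)
  pm <- matrix(cube$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
  mu <- colMeans(pm)
  sdv <- apply(pm, 2, stats::sd)
  snr <- ifelse(sdv == 0, Inf, mu / sdv)
  keep <- snr >= cfg$min_band_snr
  if (!any(keep)) stop("all bands fall below the SNR threshold",
                       call. = FALSE)
  prev <- cube$retained_bands %||% seq_len(d[3])
  cube$band_log <- data.frame(band_index = prev,
                              wavelength_nm = cube$wavelength_nm,
                              snr = snr, kept = keep)
  cube$data <- cube$data[, , keep, drop = FALSE]
  cube$wavelength_nm <- cube$wavelength_nm[keep]
  cube$retained_bands <- prev[keep]
  cube
}

#' Normalize a radiance cube to the grey reference plate
#'
#' `reflectance(pixel, band) = radiance(pixel, band) /
#' mean-plate-radiance(band) * plate_albedo`.  Because the plate sits at
#' the same altitude as the reef, illumination and the two-way water
#' path cancel, making scans comparable between transects.
#'
#' @inheritParams smooth_spectra
#' @return cube in reflectance units; plate pixels map to ~`plate_albedo`
#'   at every band.
#' @export
normalize_to_plate <- function(cube, cfg = preprocess_config()) {
  stopifnot(inherits(cube, "spectral_cube"),
            inherits(cfg, "preprocess_config"))
  if (!identical(cube$units, "radiance"))
    stop("cube must be in radiance units", call. = FALSE)
  n_plate <- sum(cube$plate_mask)
  if (n_plate < 25L)
    stop(sprintf("reference plate covers only %d pixels (>= 25 required)",
                 n_plate), call. = FALSE)
  cm <- cube_matrix(cube)
  mu <- colMeans(cm$m[which(cube$plate_mask), , drop = FALSE])
  if (any(mu <= 0))
    stop("plate mean radiance is zero at a retained band", call. = FALSE)
  cube <- set_cube_data(cube, sweep(cm$m, 2, mu / cfg$plate_albedo, `/`),
                        cm$dim)
  cube$units <- "reflectance"
  cube
}

#' Standardize each pixel spectrum to zero mean and unit SD
#'
#' Constant spectra map to all zeros (defined convention).  Standardized
#' spectra are invariant to per-pixel affine brightness changes, so
#' classification depends only on spectral shape.
#'
#' @param cube a `spectral_cube` with >= 2 retained bands.
#' @return the standardized cube; `units` becomes `"standardized"`.
#' @export
standardize_spectra <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  cm <- cube_matrix(cube)
  if (ncol(cm$m) < 2L)
    stop("need >= 2 retained bands to standardize", call. = FALSE)
  mu <- rowMeans(cm$m)
  sdv <- sqrt(rowMeans((cm$m - mu)^2))
  sdv[sdv == 0] <- Inf                 # constant spectra -> all zeros
  cube <- set_cube_data(cube, (cm$m - mu) / sdv, cm$dim)
  cube$units <- "standardized"
  cube
}

#' Full preprocessing chain: smooth, trim, normalize, standardize
#'
#' @inheritParams smooth_spectra
#' @return preprocessed cube carrying `retained_bands` and `band_log`.
#' @export
preprocess <- function(cube, cfg = preprocess_config()) {
  cube <- smooth_spectra(cube, cfg)
  cube <- trim_bands(cube, cfg)
  cube <- normalize_to_plate(cube, cfg)
  if (cfg$standardize) cube <- standardize_spectra(cube)
  cube
}

#' @describeIn preprocess Preprocess several scans onto one common band
#'   set: each cube is smoothed and its band quality assessed, then the
#'   intersection of the per-scan retained bands is applied everywhere,
#'   so all transects share a single band fingerprint for training and
#'   prediction.
#' @param cubes named list of `spectral_cube`s.
#' @export
preprocess_set <- function(cubes, cfg = preprocess_config()) {
  stopifnot(is.list(cubes), length(cubes) > 0L)
  smoothed <- lapply(cubes, smooth_spectra, cfg = cfg)
  trimmed <- lapply(smoothed, trim_bands, cfg = cfg)
  keep <- Reduce(intersect, lapply(trimmed, `[[`, "retained_bands"))
  if (!length(keep))
    stop("no band survives the SNR threshold in every scan", call. = FALSE)
  out <- lapply(smoothed, function(cb) {
    cb$band_log <- data.frame(band_index = cb$retained_bands %||%
                                seq_along(cb$wavelength_nm),
                              wavelength_nm = cb$wavelength_nm,
                              kept = seq_along(cb$wavelength_nm) %in% keep)
    cb$data <- cb$data[, , keep, drop = FALSE]
    cb$wavelength_nm <- cb$wavelength_nm[keep]
    cb$retained_bands <- keep
    cb <- normalize_to_plate(cb, cfg)
    if (cfg$standardize) cb <- standardize_spectra(cb)
    cb
  })
  names(out) <- names(cubes)
  out
}
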