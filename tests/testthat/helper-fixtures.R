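# Shared fixtures, built lazily and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixtures)) assign(name, build(), .fixtures)
  get(name, .fixtures)
}

scheme10 <- function() fixture("scheme10", build_category_scheme)

## Small two-group scene (40 x 40 px at 5 cm) with an easy spectral
## regime, used by classifier unit tests.
two_class_scene <- function(noise_sd = 0.002) {
  key <- sprintf("two_class_%g", noise_sd)
  fixture(key, function() {
    sch <- scheme10()
    tc <- stats::setNames(rep(0, 10), sch$groups)
    tc["Turf algae/Cyanobacteria/Bare substrate"] <- 55
    tc["Scleractinia"] <- 45
    cfg <- scene_config(transect_length_m = 2, swath_width_m = 2,
                        pixel_size_m = 0.05, target_cover = tc,
                        patchiness_scale_m = 0.4, seed = 5L)
    map <- sample_label_map(cfg, sch)
    lib <- make_endmembers(sch, seed = 2L, min_separation = 0.15,
                           contrast = 2, intra_sd = 0.005)
    cube <- render_scan(map, lib, samples = ncol(map$grid),
                        plate = list(row_m = 0.1, col_m = 0.1,
                                     size_m = 0.4, albedo = 0.35),
                        noise_sd = noise_sd, seed = 7L)
    ## keep the full band set: these fixtures are reused across noise
    ## levels, where SNR-based trimming would change the band grid
    pp <- preprocess(cube, preprocess_config(min_band_snr = 0))
    list(scheme = sch, map = map, lib = lib, cube = cube, proc = pp)
  })
}

## Annotation library + stratified split on the two-class scene.
two_class_library <- function(noise_sd = 0.002) {
  key <- sprintf("two_class_lib_%g", noise_sd)
  fixture(key, function() {
    sc <- two_class_scene(noise_sd)
    rois <- auto_rois(sc$map, n_per_category = 6, size = 5, seed = 3L,
                      transect_id = "T1")
    lib <- rasterize_rois(rois, dim(sc$map$grid), sc$scheme)
    sp <- split_library(lib, 0.9, seed = 4L)
    c(sc, list(rois = rois, library = lib, train = sp$train,
               validation = sp$validation))
  })
}

## Trained small model on the easy two-class scene.
two_class_model <- function() {
  fixture("two_class_model", function() {
    fx <- two_class_library()
    cfg <- ssrn_config(patch_size = 5, reduced_channels = 8,
                       n_spectral_units = 1, n_spatial_units = 1,
                       max_epochs = 20, early_stop_patience = 6,
                       seed = 11L)
    model <- ssrn(fx$train, list(T1 = fx$proc), cfg,
                  validation = fx$validation)
    c(fx, list(model = model))
  })
}

## Plain double-loop Bray-Curtis, independent of vegan.
brute_bray_curtis <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  d
}

## ANOSIM R computed directly from its definition (average ranks,
## between-vs-within mean rank difference over n(n-1)/4).
brute_anosim_R <- function(d, grouping) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  rk <- rank(dm[upper.tri(dm)])
  within <- grouping[pairs[, 1]] == grouping[pairs[, 2]]
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}
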