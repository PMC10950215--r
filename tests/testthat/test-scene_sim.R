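test_that("degenerate target cover gives a uniform map of that group", {
  sch <- scheme10()
  tc <- stats::setNames(rep(0, 10), sch$groups)
  tc["Corallinophycidae"] <- 100
  cfg <- scene_config(transect_length_m = 1, pixel_size_m = 0.05,
                      target_cover = tc, seed = 1)
  map <- sample_label_map(cfg, sch)
  expect_setequal(unique(group_of(sch, sch$fine[unique(as.integer(map$grid))])),
                  "Corallinophycidae")
  cv <- realized_cover(map)
  expect_equal(unname(cv["Corallinophycidae"]), 100)
})

test_that("realized group covers match targets within one percentage
          point on a full-size transect map", {
  sch <- scheme10()
  cfg <- scene_config(transect_length_m = 50, pixel_size_m = 0.01,
                      target_cover = lafac_cover_means()[, "2019-PQ"],
                      seed = 42)
  map <- sample_label_map(cfg, sch)      # 5000 x 100 pixels
  expect_equal(dim(map$grid), c(5000L, 100L))
  cv <- realized_cover(map)
  tc <- lafac_cover_means()[, "2019-PQ"]
  tc <- 100 * tc / sum(tc)
  expect_true(all(abs(cv[names(tc)] - tc) <= 1.0))
  ## cover conservation: every pixel labelled, covers sum to 100
  expect_equal(sum(cv), 100)
  ## discretization bound: largest-remainder apportionment is exact up
  ## to one pixel per group
  expect_true(all(abs(cv[names(tc)] - tc) <= 100 * 10 / length(map$grid) +
                    1e-9))
})

test_that("label maps are bit-identical for identical configs and seeds", {
  sch <- scheme10()
  cfg <- scene_config(transect_length_m = 1, pixel_size_m = 0.02, seed = 9)
  expect_identical(sample_label_map(cfg, sch)$grid,
                   sample_label_map(cfg, sch)$grid)
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(sample_label_map(cfg, sch)$grid,
                         sample_label_map(cfg2, sch)$grid))
})

test_that("scene configuration is validated", {
  expect_error(scene_config(target_cover = c(a = 50, b = 30)), "sum")
  expect_error(scene_config(transect_length_m = -1), "positive")
  expect_error(scene_config(pixel_size_m = 0), "positive")
  tc <- lafac_cover_means()[, "2015"]
  expect_error(scene_config(target_cover = unname(tc)), "named")
})

test_that("endmember libraries are valid, separated and seeded", {
  sch <- scheme10()
  lib <- make_endmembers(sch, seed = 1)
  expect_true(all(lib$spectra >= 0 & lib$spectra <= 1))
  expect_equal(nrow(lib$spectra), 58)
  ## all 45 pairwise group-mean angles at least the default separation
  gm <- group_mean_spectra(lib)
  angs <- combn(10, 2, function(ij)
    acos(sum(gm[ij[1], ] * gm[ij[2], ]) /
           sqrt(sum(gm[ij[1], ]^2) * sum(gm[ij[2], ]^2))))
  expect_length(angs, 45)
  expect_gte(min(angs), 0.05)
  expect_equal(lib$min_group_angle, min(angs), tolerance = 1e-12)
  ## determinism
  lib2 <- make_endmembers(sch, seed = 1)
  expect_identical(lib$spectra, lib2$spectra)
  expect_error(make_endmembers(sch, min_separation = 10, max_retries = 2),
               "separation")
})

test_that("rendered scans follow the attenuation physics and sensor
          geometry", {
  fx <- two_class_scene()
  ## water absorbs the long wavelengths: SNR at 740 nm below 550 nm
  snr <- band_snr(fx$cube)
  wl <- fx$cube$wavelength_nm
  expect_lt(snr[which.min(abs(wl - 740))], snr[which.min(abs(wl - 550))])
  ## default cross-track sensor width is 680 samples
  cube680 <- render_scan(fx$map, fx$lib, noise_sd = 0, seed = 1,
                         plate = list(row_m = 0.1, col_m = 0.1,
                                      size_m = 0.4, albedo = 0.35))
  expect_equal(dim(cube680$data)[2], 680L)
  expect_true(all(cube680$data >= 0))
  ## identity physics: no noise, no attenuation, flat illumination
  ## makes plate pixels exactly the flat plate albedo
  lib0 <- fx$lib; lib0$intra_sd[] <- 0
  cube0 <- render_scan(fx$map, lib0, water = water_model(scale = 0),
                       samples = ncol(fx$map$grid),
                       plate = list(row_m = 0.1, col_m = 0.1,
                                    size_m = 0.4, albedo = 0.35),
                       noise_sd = 0, seed = 1)
  pm <- matrix(cube0$data, prod(dim(cube0$data)[1:2]))[which(cube0$plate_mask), ]
  expect_equal(max(abs(pm - 0.35)), 0, tolerance = 1e-12)
  ## plate outside the scan errors
  expect_error(render_scan(fx$map, fx$lib, samples = ncol(fx$map$grid),
                           plate = list(row_m = 10, col_m = 0, size_m = 0.1,
                                        albedo = 0.35)),
               "outside")
})

test_that("survey sets have the monitoring-design shape and respect the
          between-transect spread", {
  sch <- scheme10()
  cfgt <- scene_config(transect_length_m = 1, pixel_size_m = 0.02, seed = 1)
  sim <- simulate_survey_set(lafac_cover_means()[, c("2015", "2017")],
                             n_transects = 3, between_sd = 1,
                             cfg_template = cfgt, scheme = sch, seed = 2)
  expect_length(sim$maps, 6)
  expect_equal(nrow(sim$truth), 6 * 10)
  expect_s3_class(sim$truth, "cover_table")
  expect_true(all(sim$truth$method == "truth"))
  ## degenerate: zero between-transect SD means identical targets
  sim0 <- simulate_survey_set(lafac_cover_means()[, "2015", drop = FALSE],
                              n_transects = 3, between_sd = 0,
                              cfg_template = cfgt, scheme = sch, seed = 2)
  tg <- do.call(cbind, sim0$targets)
  expect_true(all(apply(tg, 1, function(r) diff(range(r))) < 1e-9))
  expect_error(simulate_survey_set(lafac_cover_means()[, 1:2],
                                   n_transects = 1, cfg_template = cfgt),
               ">= 2")
})

test_that("survey means of realized covers track the configured means", {
  ## Monte-Carlo across seeds: the grand mean over several survey
  ## draws (5 transects each) stays within 2 percentage points of the
  ## configured survey means
  sch <- scheme10()
  cfgt <- scene_config(transect_length_m = 2, pixel_size_m = 0.02, seed = 1)
  mu_all <- sapply(c(3, 17, 29, 41), function(sd0) {
    sim <- simulate_survey_set(lafac_cover_means()[, "2017", drop = FALSE],
                               n_transects = 5,
                               between_sd = lafac_cover_sd()[, "2017",
                                                             drop = FALSE],
                               cfg_template = cfgt, scheme = sch,
                               seed = sd0)
    colMeans(community_matrix(sim$truth))
  })
  tc <- lafac_cover_means()[, "2017"]
  err <- rowMeans(mu_all)[names(tc)] - 100 * tc / sum(tc)
  expect_lte(max(abs(err)), 2)
})
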