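test_that("backpropagation matches numerical gradients on a tiny
          network", {
  ns <- asNamespace("reefscan")
  set.seed(42)
  cfg <- ssrn_config(patch_size = 3, reduced_channels = 4,
                     n_spectral_units = 1, n_spatial_units = 1,
                     n_classes = 3, seed = 5)
  w <- ssrn_build(cfg, n_bands = 6)$weights
  for (nm in names(w)) w[[nm]] <- w[[nm]] + rnorm(length(w[[nm]]), 0, 0.3)
  n <- 5L; P <- 9L
  X <- matrix(rnorm(n * P * 6), n * P, 6)
  y <- sample(1:3, n, replace = TRUE)
  sw <- runif(n, 0.5, 2)
  cache <- ns$ssrn_forward(w, X, n, P, cfg)
  g <- ns$ssrn_backward(w, cache, y, sw, cfg)
  eps <- 1e-6
  worst <- 0
  for (nm in names(w)) {
    for (k in sample(length(w[[nm]]), min(3, length(w[[nm]])))) {
      wp <- w; wp[[nm]][k] <- wp[[nm]][k] + eps
      wm <- w; wm[[nm]][k] <- wm[[nm]][k] - eps
      num <- (ns$weighted_ce(ns$ssrn_forward(wp, X, n, P, cfg)$probs, y, sw) -
                ns$weighted_ce(ns$ssrn_forward(wm, X, n, P, cfg)$probs,
                               y, sw)) / (2 * eps)
      worst <- max(worst, abs(num - g[[nm]][k]) /
                     max(1e-8, abs(num) + abs(g[[nm]][k])))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("network construction is seeded, softmax-normalized and grows
          with channel width", {
  ns <- asNamespace("reefscan")
  cfg <- ssrn_config(n_classes = 10, seed = 3)
  m1 <- ssrn_build(cfg, 50)
  m2 <- ssrn_build(cfg, 50)
  expect_identical(m1$weights, m2$weights)
  ## softmax output is a probability distribution for any input
  P <- cfg$patch_size^2
  X <- matrix(rnorm(4 * P * 50), 4 * P, 50)
  probs <- ns$ssrn_forward(m1$weights, X, 4L, P, cfg)$probs
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-9)
  expect_true(all(probs >= 0))
  ## parameter count strictly increases with reduced_channels
  p16 <- n_params(ssrn_build(ssrn_config(reduced_channels = 16,
                                         n_classes = 10), 50))
  p32 <- n_params(ssrn_build(ssrn_config(reduced_channels = 32,
                                         n_classes = 10), 50))
  expect_lt(p16, p32)
  expect_error(ssrn_config(patch_size = 4), "odd")
  expect_error(ssrn_config(n_classes = 1), ">= 2")
  expect_error(ssrn_build(ssrn_config(), 50), "n_classes")
})

test_that("initial loss is log(K) and training is deterministic and
          rejects degenerate libraries", {
  fx <- two_class_library()
  cfg <- ssrn_config(patch_size = 3, reduced_channels = 4,
                     n_spectral_units = 1, n_spatial_units = 1,
                     max_epochs = 1, batch_size = 10000,
                     class_weights = "none", seed = 2)
  m <- ssrn(fx$train, list(T1 = fx$proc), cfg, validation = fx$validation)
  ## zero-initialized softmax layer: first recorded loss is exactly the
  ## uniform cross-entropy log(n_classes)
  expect_equal(m$history$train_loss[1], log(2), tolerance = 1e-9)
  m2 <- ssrn(fx$train, list(T1 = fx$proc), cfg,
             validation = fx$validation)
  expect_identical(m$weights, m2$weights)
  single <- fx$train[fx$train$group == fx$train$group[1], ]
  class(single) <- class(fx$train)
  expect_error(ssrn(single, list(T1 = fx$proc), cfg), "single class")
})

test_that("the easy regime trains to high validation accuracy", {
  fx <- two_class_model()
  h <- fx$model$history
  expect_gte(max(h$val_acc, na.rm = TRUE), 0.95)
  rep <- validation_report(fx$model, fx$validation, list(T1 = fx$proc))
  expect_gte(rep$overall, 0.95)
  ## confusion bookkeeping: rows sum to per-class validation counts
  expect_equal(as.numeric(rowSums(rep$confusion)),
               as.numeric(table(factor(fx$validation$group,
                                       levels = fx$model$classes))))
  expect_true(all(rep$per_class_match >= 0 & rep$per_class_match <= 1,
                  na.rm = TRUE))
})

test_that("per-pixel prediction fills the map, stores valid
          probabilities and breaks ties deterministically", {
  fx <- two_class_model()
  pred <- predict(fx$model, fx$proc)
  d <- dim(fx$proc$data)
  expect_equal(dim(pred$map$grid), d[1:2])
  expect_equal(dim(pred$prob), c(d[1:2], 2L))
  ## plate pixels carry the reserved code 0 and are excluded from cover
  expect_true(all(pred$map$grid[fx$proc$plate_mask] == 0L))
  expect_true(all(pred$map$grid[!fx$proc$plate_mask] > 0L))
  cv <- cover_from_map(pred$map)
  expect_equal(sum(cv), 100)
  ## probabilities are distributions and argmax reproduces the map
  pm <- matrix(pred$prob, d[1] * d[2], 2)
  expect_equal(rowSums(pm), rep(1, nrow(pm)), tolerance = 1e-5)
  relab <- matrix(max.col(pm, ties.method = "first"), d[1], d[2])
  relab[fx$proc$plate_mask] <- 0L
  expect_identical(relab, pred$map$grid)
  ## band fingerprint guard
  wrong <- fx$proc
  wrong$data <- wrong$data[, , -1, drop = FALSE]
  wrong$wavelength_nm <- wrong$wavelength_nm[-1]
  expect_error(predict(fx$model, wrong), "fingerprint")
})

test_that("a uniform scene is predicted as a uniform map after easy
          training", {
  fx <- two_class_model()
  sch <- fx$scheme
  tc <- stats::setNames(rep(0, 10), sch$groups)
  tc["Scleractinia"] <- 100
  cfg <- scene_config(transect_length_m = 1, swath_width_m = 1,
                      pixel_size_m = 0.05, target_cover = tc, seed = 21)
  umap <- sample_label_map(cfg, sch)
  ## restrict to fine categories the model saw in training
  seen <- unique(fx$library$fine[fx$library$group == "Scleractinia"])
  umap$grid[] <- match(seen[1], sch$fine)
  ucube <- render_scan(umap, fx$lib, samples = ncol(umap$grid),
                       plate = list(row_m = 0.1, col_m = 0.1,
                                    size_m = 0.4, albedo = 0.35),
                       noise_sd = 0.002, seed = 3)
  uproc <- preprocess(ucube, preprocess_config(min_band_snr = 0))
  uproc$data <- uproc$data[, , match(fx$proc$wavelength_nm,
                                     uproc$wavelength_nm), drop = FALSE]
  uproc$wavelength_nm <- fx$proc$wavelength_nm
  upred <- predict(fx$model, uproc)
  lab <- upred$map$grid[!uproc$plate_mask]
  expect_gte(mean(fx$model$classes[lab] == "Scleractinia"), 0.99)
})

test_that("validation accuracy does not increase with scene noise", {
  accs <- sapply(c(0.002, 1.5, 3), function(nsd) {
    fx <- two_class_library(noise_sd = nsd)
    cfg <- ssrn_config(patch_size = 5, reduced_channels = 8,
                       n_spectral_units = 1, n_spatial_units = 1,
                       max_epochs = 12, early_stop_patience = 4,
                       seed = 11)
    m <- ssrn(fx$train, list(T1 = fx$proc), cfg,
              validation = fx$validation)
    max(m$history$val_acc, na.rm = TRUE)
  })
  expect_gte(accs[1], accs[2] - 0.02)
  expect_gte(accs[2], accs[3] - 0.02)
  expect_gt(accs[1], accs[3])
})

test_that("under-represented classes are recognized less reliably than
          abundant ones at matched noise", {
  ## rare-class regime: the red-macroalgae class keeps a normal
  ## validation set but its training representation is cut to ~0.5% of
  ## the library (scant annotation of an infrequent taxon); without
  ## class weighting its match proportion falls behind the abundant
  ## classes
  sch <- scheme10()
  tc <- stats::setNames(rep(0, 10), sch$groups)
  tc["Turf algae/Cyanobacteria/Bare substrate"] <- 50
  tc["Scleractinia"] <- 40
  tc["Red macroalgae"] <- 10
  cfg <- scene_config(transect_length_m = 2, swath_width_m = 2,
                      pixel_size_m = 0.02, target_cover = tc,
                      patchiness_scale_m = 0.4, seed = 31)
  map <- sample_label_map(cfg, sch)
  lib <- make_endmembers(sch, seed = 2, min_separation = 0.1,
                         intra_sd = 0.03)
  cube <- render_scan(map, lib, samples = ncol(map$grid),
                      plate = list(row_m = 0.1, col_m = 0.1, size_m = 0.4,
                                   albedo = 0.35),
                      noise_sd = 0.3, seed = 8)
  proc <- preprocess(cube, preprocess_config(min_band_snr = 0))
  rois <- auto_rois(map, n_per_category = 8, size = 4, seed = 3)
  alib <- rasterize_rois(rois, dim(map$grid), sch)
  sp <- split_library(alib, 0.7, seed = 4)
  rare_tr <- which(sp$train$group == "Red macroalgae")
  keep_n <- max(3L, round(0.005 * nrow(sp$train)))
  train <- sp$train[-setdiff(rare_tr, rare_tr[seq_len(keep_n)]), ]
  class(train) <- class(sp$train)
  mcfg <- ssrn_config(patch_size = 3, reduced_channels = 8,
                      n_spectral_units = 1, n_spatial_units = 1,
                      max_epochs = 15, early_stop_patience = 5,
                      class_weights = "none", seed = 11)
  m <- ssrn(train, list(T1 = proc), mcfg, validation = sp$validation)
  rep <- validation_report(m, sp$validation, list(T1 = proc))
  rare <- rep$per_class_match["Red macroalgae"]
  abundant <- rep$per_class_match[c("Scleractinia",
                                    "Turf algae/Cyanobacteria/Bare substrate")]
  expect_lt(unname(rare), min(abundant))
})
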