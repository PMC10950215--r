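#' Configuration of the spectral-spatial residual network
#'
#' The classifier follows the spectral-spatial residual architecture
#' used for per-pixel classification of hyperspectral imagery: the
#' spectra in a small patch around the target pixel are first projected
#' to a reduced channel dimension with a 1x1 convolution, residual units
#' then act along the spectral/feature axis, a feature-adjustment layer
#' resizes the representation, further residual units act across the
#' patch (spatial features), and average pooling over the window feeds a
#' softmax classifier.  Architecture sizes are tunable; the defaults are
#' a 7-pixel patch, 32 reduced channels and two residual units per
#' stage.
#'
#' @param patch_size odd patch side length in pixels (>= 3, default 7).
#' @param reduced_channels channel dimension after the 1x1 projection.
#' @param n_spectral_units,n_spatial_units residual units per stage.
#' @param n_classes number of classes, or `NULL` to infer from the
#'   training library.
#' @param label_level train on `"group"` (default, 10 classes) or
#'   `"fine"` labels.
#' @param learning_rate Adam step size.
#' @param max_epochs,batch_size,early_stop_patience training schedule;
#'   early stopping monitors validation accuracy.
#' @param class_weights `"inverse"` (inverse-frequency weights in the
#'   cross-entropy, mitigating rare-class failure modes) or `"none"`.
#' @param seed integer seed for initialization and batch shuffling.
#' @return list of class `ssrn_config`.
#' @export
ssrn_config <- function(patch_size = 7L, reduced_channels = 32L,
                        n_spectral_units = 2L, n_spatial_units = 2L,
                        n_classes = NULL, label_level = c("group", "fine"),
                        learning_rate = 2e-3, max_epochs = 40L,
                        batch_size = 64L, early_stop_patience = 8L,
                        class_weights = c("inverse", "none"), seed = 1L) {
  patch_size <- as.integer(patch_size)
  if (patch_size < 3L || patch_size %% 2L == 0L)
    stop("'patch_size' must be an odd integer >= 3", call. = FALSE)
  for (nm in c("reduced_channels", "n_spectral_units", "n_spatial_units",
               "max_epochs", "batch_size", "early_stop_patience"))
    stop_if_not_scalar_pos(get(nm), nm)
  if (!is.null(n_classes) && n_classes < 2L)
    stop("'n_classes' must be >= 2", call. = FALSE)
  stop_if_not_scalar_pos(learning_rate, "learning_rate")
  structure(list(patch_size = patch_size,
                 reduced_channels = as.integer(reduced_channels),
                 n_spectral_units = as.integer(n_spectral_units),
                 n_spatial_units = as.integer(n_spatial_units),
                 n_classes = if (is.null(n_classes)) NULL
                             else as.integer(n_classes),
                 label_level = match.arg(label_level),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 class_weights = match.arg(class_weights),
                 seed = as.integer(seed)),
            class = "ssrn_config")
}

## ---- weight initialization ------------------------------------------------

he_mat <- function(nin, nout, gain = 1)
  matrix(stats::rnorm(nin * nout, 0, gain * sqrt(2 / nin)), nin, nout)

#' Build an untrained spectral-spatial residual network
#'
#' @param config an [ssrn_config()] with `n_classes` set.
#' @param n_bands number of spectral bands of the preprocessed input.
#' @return object of class `ssrn` with seeded initial weights (two
#'   builds with the same config and seed are identical).  The final
#'   softmax layer starts at zero, so the initial cross-entropy equals
#'   `log(n_classes)` for balanced classes.
#' @export
ssrn_build <- function(config, n_bands) {
  stopifnot(inherits(config, "ssrn_config"))
  if (is.null(config$n_classes))
    stop("'config$n_classes' must be set to build a model", call. = FALSE)
  B <- as.integer(n_bands); C <- config$reduced_channels
  P <- config$patch_size^2L; K <- config$n_classes
  w <- with_seed(config$seed, {
    w <- list(W0 = he_mat(B, C), b0 = numeric(C))
    for (i in seq_len(config$n_spectral_units)) {
      w[[sprintf("spec%d_U", i)]] <- he_mat(C, C)
      w[[sprintf("spec%d_bu", i)]] <- numeric(C)
      w[[sprintf("spec%d_V", i)]] <- he_mat(C, C, gain = 0.1)
      w[[sprintf("spec%d_bv", i)]] <- numeric(C)
    }
    w$Wa <- he_mat(C, C); w$ba <- numeric(C)
    for (i in seq_len(config$n_spatial_units)) {
      w[[sprintf("spat%d_U", i)]] <- he_mat(P, P)
      w[[sprintf("spat%d_bu", i)]] <- numeric(P)
      w[[sprintf("spat%d_V", i)]] <- he_mat(P, P, gain = 0.1)
      w[[sprintf("spat%d_bv", i)]] <- numeric(P)
    }
    w$Wc <- matrix(0, C, K); w$bc <- numeric(K)
    w
  })
  structure(list(config = config, n_bands = B, weights = w,
                 classes = NULL, history = NULL, fingerprint = NULL),
            class = "ssrn")
}

#' @rdname ssrn_build
#' @param model an `ssrn` object.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "ssrn"))
  sum(vapply(model$weights, length, integer(1)))
}

## ---- forward / backward ---------------------------------------------------

addb <- function(M, b) sweep(M, 2, b, `+`)

res_unit_fwd <- function(H, U, bu, V, bv) {
  A1 <- pmax(H, 0)
  Z1 <- addb(A1 %*% U, bu)
  A2 <- pmax(Z1, 0)
  out <- H + addb(A2 %*% V, bv)
  list(out = out, A1 = A1, M1 = H > 0, M2 = Z1 > 0, A2 = A2)
}

res_unit_bwd <- function(dOut, cache, U, V) {
  dV <- crossprod(cache$A2, dOut)
  dbv <- colSums(dOut)
  dZ1 <- (dOut %*% t(V)) * cache$M2
  dU <- crossprod(cache$A1, dZ1)
  dbu <- colSums(dZ1)
  dH <- dOut + (dZ1 %*% t(U)) * cache$M1
  list(dH = dH, dU = dU, dbu = dbu, dV = dV, dbv = dbv)
}

## X: (n*P) x B matrix, patch positions fastest within a sample.
ssrn_forward <- function(w, X, n, P, config) {
  C <- config$reduced_channels
  cache <- list(X = X, n = n, P = P)
  H <- addb(X %*% w$W0, w$b0)
  cache$spec <- vector("list", config$n_spectral_units)
  for (i in seq_len(config$n_spectral_units)) {
    u <- res_unit_fwd(H, w[[sprintf("spec%d_U", i)]],
                      w[[sprintf("spec%d_bu", i)]],
                      w[[sprintf("spec%d_V", i)]],
                      w[[sprintf("spec%d_bv", i)]])
    cache$spec[[i]] <- u
    H <- u$out
  }
  cache$Hpre_adj <- H
  Ha <- addb(H %*% w$Wa, w$ba)
  ## reshape (sample, position, channel) -> rows (sample fastest within
  ## channel), columns = patch positions
  G <- matrix(aperm(array(Ha, c(P, n, C)), c(2, 3, 1)), n * C, P)
  cache$spat <- vector("list", config$n_spatial_units)
  for (i in seq_len(config$n_spatial_units)) {
    u <- res_unit_fwd(G, w[[sprintf("spat%d_U", i)]],
                      w[[sprintf("spat%d_bu", i)]],
                      w[[sprintf("spat%d_V", i)]],
                      w[[sprintf("spat%d_bv", i)]])
    cache$spat[[i]] <- u
    G <- u$out
  }
  pool <- matrix(rowMeans(G), n, C)          # average over the window
  cache$pool <- pool
  logits <- addb(pool %*% w$Wc, w$bc)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  cache$probs <- probs
  cache
}

## y: integer class labels (1..K); sw: per-sample loss weights.
ssrn_backward <- function(w, cache, y, sw, config) {
  n <- cache$n; P <- cache$P; C <- config$reduced_channels
  probs <- cache$probs
  dLogits <- probs
  dLogits[cbind(seq_len(n), y)] <- dLogits[cbind(seq_len(n), y)] - 1
  dLogits <- dLogits * (sw / sum(sw))
  g <- list()
  g$Wc <- crossprod(cache$pool, dLogits)
  g$bc <- colSums(dLogits)
  dPool <- dLogits %*% t(w$Wc)               # n x C
  dG <- matrix(as.vector(dPool) / P, n * C, P)
  for (i in rev(seq_len(config$n_spatial_units))) {
    bb <- res_unit_bwd(dG, cache$spat[[i]],
                       w[[sprintf("spat%d_U", i)]],
                       w[[sprintf("spat%d_V", i)]])
    g[[sprintf("spat%d_U", i)]] <- bb$dU
    g[[sprintf("spat%d_bu", i)]] <- bb$dbu
    g[[sprintf("spat%d_V", i)]] <- bb$dV
    g[[sprintf("spat%d_bv", i)]] <- bb$dbv
    dG <- bb$dH
  }
  dHa <- matrix(aperm(array(dG, c(n, C, P)), c(3, 1, 2)), n * P, C)
  g$Wa <- crossprod(cache$Hpre_adj, dHa)
  g$ba <- colSums(dHa)
  dH <- dHa %*% t(w$Wa)
  for (i in rev(seq_len(config$n_spectral_units))) {
    bb <- res_unit_bwd(dH, cache$spec[[i]],
                       w[[sprintf("spec%d_U", i)]],
                       w[[sprintf("spec%d_V", i)]])
    g[[sprintf("spec%d_U", i)]] <- bb$dU
    g[[sprintf("spec%d_bu", i)]] <- bb$dbu
    g[[sprintf("spec%d_V", i)]] <- bb$dV
    g[[sprintf("spec%d_bv", i)]] <- bb$dbv
    dH <- bb$dH
  }
  g$W0 <- crossprod(cache$X, dH)
  g$b0 <- colSums(dH)
  g
}

weighted_ce <- function(probs, y, sw) {
  p <- pmax(probs[cbind(seq_along(y), y)], 1e-12)
  sum(-sw * log(p)) / sum(sw)
}

## ---- patch extraction -----------------------------------------------------

## Returns an (n*P) x B matrix of reflect-padded patches, positions
## fastest within each sample.
extract_patches <- function(cube, rows, cols, patch_size) {
  d <- dim(cube$data)
  L <- d[1]; S <- d[2]; B <- d[3]
  h <- (patch_size - 1L) %/% 2L
  P <- patch_size^2L
  n <- length(rows)
  dm <- matrix(cube$data, L * S, B)
  X <- matrix(0, n * P, B)
  for (k in seq_len(P)) {
    dr <- (k - 1L) %% patch_size - h
    dc <- (k - 1L) %/% patch_size - h
    rk <- reflect_index(rows + dr, L)
    ck <- reflect_index(cols + dc, S)
    X[(seq_len(n) - 1L) * P + k, ] <- dm[rk + (ck - 1L) * L, , drop = FALSE]
  }
  X
}

## ---- fitting --------------------------------------------------------------

#' Fit a spectral-spatial residual network to labelled pixels
#'
#' `ssrn()` is the package's model-fitting entry point.  Patches are
#' extracted around every labelled pixel of the (preprocessed) cubes,
#' and the network is trained with Adam on class-weighted cross-entropy,
#' early-stopping on validation accuracy.  Training is deterministic for
#' a fixed seed and thread count.
#'
#' @param train training `annotation_library`
#'   (see [split_library()]).
#' @param cubes named list of preprocessed `spectral_cube`s keyed by
#'   transect id (a single cube is accepted when all entries share one
#'   transect).  All cubes must share the same retained-band grid.
#' @param config an [ssrn_config()].
#' @param validation optional validation `annotation_library`.
#' @return object of class `ssrn`: the trained weights, `classes`
#'   (class-name vector), per-epoch `history` (train loss/accuracy and
#'   validation accuracy), and the retained-band `fingerprint` used to
#'   reject incompatible cubes at prediction time.
#' @seealso [predict.ssrn()], [validation_report()]
#' @export
ssrn <- function(train, cubes, config = ssrn_config(), validation = NULL) {
  stopifnot(inherits(train, "annotation_library"),
            inherits(config, "ssrn_config"))
  cubes <- as_cube_list(cubes, train, validation)
  fingerprint <- cubes[[1]]$wavelength_nm
  for (cb in cubes)
    if (!isTRUE(all.equal(cb$wavelength_nm, fingerprint)))
      stop("cubes disagree on the retained band grid", call. = FALSE)
  lvl <- config$label_level
  y_tr_lab <- train[[lvl]]
  classes <- sort(unique(c(y_tr_lab,
                           if (!is.null(validation)) validation[[lvl]])))
  if (length(unique(y_tr_lab)) < 2L)
    stop("training library holds a single class", call. = FALSE)
  if (!is.null(config$n_classes) && config$n_classes != length(classes))
    stop(sprintf("config$n_classes = %d but %d classes present",
                 config$n_classes, length(classes)), call. = FALSE)
  config$n_classes <- length(classes)
  missing_tr <- setdiff(classes, y_tr_lab)
  if (length(missing_tr))
    warning("classes absent from training (validation will score them ",
            "as misses): ", paste(missing_tr, collapse = ", "))
  K <- length(classes)
  y_tr <- match(y_tr_lab, classes)
  B <- length(fingerprint)
  P <- config$patch_size^2L
  Xtr <- patches_for_library(train, cubes, config$patch_size)
  n_tr <- nrow(train)
  has_val <- !is.null(validation) && nrow(validation) > 0L
  if (has_val) {
    Xval <- patches_for_library(validation, cubes, config$patch_size)
    y_val <- match(validation[[lvl]], classes)
  }
  cw <- if (config$class_weights == "inverse") {
    cnt <- tabulate(y_tr, K)
    w <- ifelse(cnt > 0, n_tr / (sum(cnt > 0) * pmax(cnt, 1)), 0)
    w
  } else rep(1, K)
  model <- ssrn_build(config, B)
  w <- model$weights
  adam_m <- lapply(w, function(x) x * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
  best <- list(metric = -Inf, weights = w, epoch = 0L)
  hist <- NULL
  with_seed(derive_seed(config$seed, 17L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; ep_n <- 0; ep_correct <- 0
      for (b0 in seq(1L, n_tr, by = config$batch_size)) {
        bi <- ord[b0:min(n_tr, b0 + config$batch_size - 1L)]
        nb <- length(bi)
        rowsel <- rep((bi - 1L) * P, each = P) + seq_len(P)
        Xb <- Xtr[rowsel, , drop = FALSE]
        yb <- y_tr[bi]
        sw <- cw[yb]
        cache <- ssrn_forward(w, Xb, nb, P, config)
        loss <- weighted_ce(cache$probs, yb, sw)
        g <- ssrn_backward(w, cache, yb, sw, config)
        step <- step + 1L
        for (nm in names(w)) {
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g[[nm]]
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          w[[nm]] <- w[[nm]] - config$learning_rate *
            mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + loss * nb
        ep_n <- ep_n + nb
        ep_correct <- ep_correct +
          sum(max.col(cache$probs, ties.method = "first") == yb)
      }
      val_acc <- NA_real_
      if (has_val) {
        pv <- predict_probs(w, Xval, nrow(validation), P, config)
        val_acc <- mean(max.col(pv, ties.method = "first") == y_val)
      }
      hist <- rbind(hist, data.frame(
        epoch = epoch, train_loss = ep_loss / ep_n,
        train_acc = ep_correct / ep_n, val_acc = val_acc))
      metric <- if (has_val) val_acc else -ep_loss / ep_n
      if (metric > best$metric + 1e-12) {
        best$metric <- metric; best$weights <- w; best$epoch <- epoch
      } else if (epoch - best$epoch >= config$early_stop_patience) {
        break
      }
      if (has_val && val_acc >= 1) break     # cannot improve further
    }
  })
  model$weights <- best$weights
  model$classes <- classes
  model$history <- hist
  model$fingerprint <- fingerprint
  model$class_weights <- stats::setNames(cw, classes)
  model$call <- match.call()
  model
}

as_cube_list <- function(cubes, train, validation = NULL) {
  if (inherits(cubes, "spectral_cube")) {
    tid <- unique(c(train$transect, validation$transect))
    if (length(tid) > 1L)
      stop("multiple transects in the library but a single cube given",
           call. = FALSE)
    cubes <- stats::setNames(list(cubes), tid)
  }
  stopifnot(is.list(cubes), !is.null(names(cubes)))
  need <- unique(c(train$transect, validation$transect))
  miss <- setdiff(need, names(cubes))
  if (length(miss))
    stop("no cube supplied for transect(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  cubes
}

patches_for_library <- function(lib, cubes, patch_size) {
  P <- patch_size^2L
  parts <- vector("list", length(unique(lib$transect)))
  X <- NULL
  for (tid in unique(lib$transect)) {
    sel <- lib$transect == tid
    Xi <- extract_patches(cubes[[tid]], lib$row[sel], lib$col[sel],
                          patch_size)
    if (is.null(X)) {
      X <- matrix(0, nrow(lib) * P, ncol(Xi))
    }
    rowsel <- rep((which(sel) - 1L) * P, each = P) + seq_len(P)
    X[rowsel, ] <- Xi
  }
  X
}

predict_probs <- function(w, X, n, P, config, batch = 2048L) {
  K <- config$n_classes
  out <- matrix(0, n, K)
  for (b0 in seq(1L, n, by = batch)) {
    bi <- b0:min(n, b0 + batch - 1L)
    rowsel <- rep((bi - 1L) * P, each = P) + seq_len(P)
    cache <- ssrn_forward(w, X[rowsel, , drop = FALSE], length(bi), P,
                          config)
    out[bi, ] <- cache$probs
  }
  out
}

## ---- methods --------------------------------------------------------------

#' Predict a label for every recorded pixel of a scan
#'
#' Applies the trained network to each non-plate pixel of a preprocessed
#' cube, producing a per-pixel label map (the basis of hyperspectral
#' cover estimates) and the full softmax probability raster.  Ties in
#' the argmax are broken towards the lowest class index; reference-plate
#' pixels receive the reserved code 0 and are excluded from cover
#' estimation.
#'
#' @param object a trained `ssrn`.
#' @param cube preprocessed `spectral_cube` on the same retained-band
#'   grid as training (checked via the band fingerprint).
#' @param ... unused.
#' @return list of class `ssrn_prediction` with `map` (a group- or
#'   fine-level `label_map` whose grid holds indices into
#'   `object$classes`, 0 = plate) and `prob` (lines x samples x classes
#'   array).
#' @export
predict.ssrn <- function(object, cube, ...) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (is.null(object$classes))
    stop("model has not been trained", call. = FALSE)
  if (!isTRUE(all.equal(cube$wavelength_nm, object$fingerprint)))
    stop("band fingerprint mismatch: cube was not preprocessed like the ",
         "training data", call. = FALSE)
  d <- dim(cube$data)
  coords <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  P <- object$config$patch_size^2L
  n <- nrow(coords)
  probs <- matrix(0, n, object$config$n_classes)
  chunk <- 4096L                     # extract + classify in chunks
  for (b0 in seq(1L, n, by = chunk)) {
    bi <- b0:min(n, b0 + chunk - 1L)
    X <- extract_patches(cube, coords$row[bi], coords$col[bi],
                         object$config$patch_size)
    probs[bi, ] <- predict_probs(object$weights, X, length(bi), P,
                                 object$config)
  }
  lab <- max.col(probs, ties.method = "first")
  grid <- matrix(lab, d[1], d[2])
  if (!is.null(cube$plate_mask)) grid[cube$plate_mask] <- 0L
  scheme <- ssrn_scheme(object)
  map <- structure(list(grid = grid, resolution_m = NA_real_,
                        level = object$config$label_level,
                        classes = object$classes, scheme = scheme),
                   class = "label_map")
  structure(list(map = map,
                 prob = array(probs, c(d[1], d[2], ncol(probs))),
                 classes = object$classes),
            class = "ssrn_prediction")
}

## A minimal scheme view whose groups are the model's classes (group
## level) so cover helpers work on prediction maps.
ssrn_scheme <- function(object) {
  if (object$config$label_level == "group")
    structure(list(fine = object$classes, group = object$classes,
                   groups = object$classes), class = "category_scheme")
  else structure(list(fine = object$classes, group = object$classes,
                      groups = unique(object$classes)),
                 class = "category_scheme")
}

#' Validation report of a trained classifier
#'
#' Confusion matrix and per-class match proportions (the proportion of
#' validation entries whose predicted label equals the true label, i.e.
#' row-normalized recall) on a held-out annotation library.
#'
#' @param model trained `ssrn`.
#' @param val validation `annotation_library`.
#' @param cubes named list of preprocessed cubes (as in [ssrn()]).
#' @return list of class `ssrn_validation`: `confusion` (true x
#'   predicted counts), `per_class_match` (NA for classes with no
#'   validation entries, not 0), `overall` accuracy.
#' @export
validation_report <- function(model, val, cubes) {
  stopifnot(inherits(model, "ssrn"), inherits(val, "annotation_library"))
  if (nrow(val) == 0L) stop("validation library is empty", call. = FALSE)
  cubes <- as_cube_list(cubes, val)
  X <- patches_for_library(val, cubes, model$config$patch_size)
  P <- model$config$patch_size^2L
  probs <- predict_probs(model$weights, X, nrow(val), P, model$config)
  pred <- model$classes[max.col(probs, ties.method = "first")]
  truth <- val[[model$config$label_level]]
  lev <- model$classes
  confusion <- table(factor(truth, lev), factor(pred, lev))
  names(dimnames(confusion)) <- c("true", "predicted")
  rowtot <- rowSums(confusion)
  per_class <- ifelse(rowtot > 0, diag(confusion) / rowtot, NA_real_)
  structure(list(confusion = confusion,
                 per_class_match = stats::setNames(per_class, lev),
                 overall = mean(pred == truth)),
            class = "ssrn_validation")
}

#' @export
print.ssrn_validation <- function(x, ...) {
  cat(sprintf("Validation: overall accuracy %.3f\n", x$overall))
  pc <- x$per_class_match
  for (k in names(pc))
    cat(sprintf("  %-42s %s\n", k,
                if (is.na(pc[[k]])) "(no validation entries)"
                else sprintf("%.2f", pc[[k]])))
  invisible(x)
}

#' @export
print.ssrn <- function(x, ...) {
  cfg <- x$config
  cat("Spectral-spatial residual network\n")
  cat(sprintf("  patch %dx%d, %d channels, %d+%d residual units, %s\n",
              cfg$patch_size, cfg$patch_size, cfg$reduced_channels,
              cfg$n_spectral_units, cfg$n_spatial_units,
              if (is.null(x$classes)) "untrained"
              else sprintf("%d classes", length(x$classes))))
  cat(sprintf("  parameters: %d, input bands: %d\n", n_params(x),
              x$n_bands))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; train acc %.3f, val acc %s\n",
                nrow(x$history), last$train_acc,
                if (is.na(last$val_acc)) "-" else
                  sprintf("%.3f", max(x$history$val_acc, na.rm = TRUE))))
  }
  invisible(x)
}

#' @export
summary.ssrn <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  if (!is.null(object$class_weights)) {
    cat("\nClass weights:\n")
    print(round(object$class_weights, 3))
  }
  invisible(object)
}

#' @export
plot.ssrn <- function(x, ...) {
  if (is.null(x$history)) stop("no training history to plot", call. = FALSE)
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  if (!all(is.na(h$val_acc))) {
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    graphics::plot(h$epoch, h$val_acc, type = "l", lty = 2, col = 2,
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("validation accuracy", side = 4, line = 2)
  }
  invisible(x)
}

#' Save and load a trained model checkpoint
#'
#' The checkpoint is a single RDS archive holding config, class list,
#' band fingerprint and weights.
#' @param model trained `ssrn`.
#' @param path file path.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ssrn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ssrn")) stop("not an ssrn checkpoint", call. = FALSE)
  m
}
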