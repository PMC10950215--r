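#' Regions of interest and the labelled-pixel library
#'
#' Expert annotation of hyperspectral scans is modelled as polygon
#' regions of interest (ROIs), each containing a single fine benthic
#' category.  Rasterizing the ROIs yields the labelled-pixel library
#' used to train and validate the classifier.
#'
#' Coordinates: pixel `(i, j)` of a scan covers the half-open square
#' `[i-1, i) x [j-1, j)` in (row, col) units, so its center sits at
#' `(i - 0.5, j - 0.5)`.  A pixel belongs to an ROI when its center lies
#' strictly inside the polygon (even-odd rule).
#'
#' @param vertices numeric matrix (>= 3 rows) of polygon vertices,
#'   columns (row, col) in pixel units.
#' @param label fine-category name.
#' @param transect_id transect identifier.
#' @return list of class `roi`.
#' @export
roi <- function(vertices, label, transect_id = "T1") {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L)
    stop("an ROI polygon needs >= 3 (row, col) vertices", call. = FALSE)
  structure(list(vertices = vertices, label = as.character(label),
                 transect_id = as.character(transect_id)),
            class = "roi")
}

## Even-odd (crossing number) point-in-polygon, vectorized over points.
points_in_polygon <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize ROIs into an annotation library
#'
#' @param rois list of [roi()] objects.
#' @param cube a `spectral_cube` (or a `label_map`) giving scan
#'   dimensions; alternatively an integer vector `c(rows, cols)`.
#' @param scheme category scheme used to validate labels and attach
#'   group labels.
#' @return Object of class `annotation_library`: a data frame with
#'   columns `transect`, `row`, `col`, `fine`, `group`, `roi_id`.
#'   Overlapping ROIs within a transect are an error.
#' @export
rasterize_rois <- function(rois, cube, scheme = build_category_scheme()) {
  stopifnot(is.list(rois), length(rois) > 0L)
  dims <- scan_dims(cube)
  out <- vector("list", length(rois))
  for (k in seq_along(rois)) {
    r <- rois[[k]]
    stopifnot(inherits(r, "roi"))
    v <- r$vertices
    if (any(v[, 1] < 0) || any(v[, 2] < 0) ||
        any(v[, 1] > dims[1]) || any(v[, 2] > dims[2]))
      stop(sprintf("ROI %d extends outside the %d x %d scan",
                   k, dims[1], dims[2]), call. = FALSE)
    group <- group_of(scheme, r$label)   # errors on unknown label
    ri <- max(1L, ceiling(min(v[, 1]))):min(dims[1], ceiling(max(v[, 1])))
    ci <- max(1L, ceiling(min(v[, 2]))):min(dims[2], ceiling(max(v[, 2])))
    gr <- expand.grid(row = ri, col = ci)
    hit <- points_in_polygon(gr$row - 0.5, gr$col - 0.5, v[, 1], v[, 2])
    if (!any(hit)) next
    out[[k]] <- data.frame(transect = r$transect_id,
                           row = gr$row[hit], col = gr$col[hit],
                           fine = r$label, group = group, roi_id = k,
                           stringsAsFactors = FALSE)
  }
  lib <- do.call(rbind, out)
  if (is.null(lib) || nrow(lib) == 0L)
    stop("no pixels fell inside any ROI", call. = FALSE)
  dup <- duplicated(lib[c("transect", "row", "col")])
  if (any(dup)) {
    bad <- unique(lib$roi_id[dup | duplicated(lib[c("transect", "row",
                                                    "col")],
                                              fromLast = TRUE)])
    stop("overlapping ROIs within a transect: ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  }
  rownames(lib) <- NULL
  class(lib) <- c("annotation_library", "data.frame")
  lib
}

scan_dims <- function(x) {
  if (inherits(x, "spectral_cube")) dim(x$data)[1:2]
  else if (inherits(x, "label_map")) dim(x$grid)
  else if (is.numeric(x) && length(x) == 2L) as.integer(x)
  else stop("cannot determine scan dimensions from ", class(x)[1L],
            call. = FALSE)
}

#' @export
print.annotation_library <- function(x, ...) {
  cat(sprintf("annotation_library: %d labelled pixels, %d ROIs, %d groups\n",
              nrow(x), length(unique(x$roi_id)),
              length(unique(x$group))))
  print(table(x$group))
  invisible(x)
}

#' Split an annotation library into training and validation sets
#'
#' Stratified split: within every group label the training share is
#' within one entry of `train_fraction` (the survey protocol trains on
#' 90% of labelled pixels and validates on the remaining 10%).  With
#' `unit = "roi"` whole ROIs are assigned to one side, which controls
#' spatial-autocorrelation leakage between training and validation.
#'
#' @param lib an `annotation_library`.
#' @param train_fraction fraction in (0, 1]; 1 leaves the validation set
#'   empty (with a warning).
#' @param seed integer seed; the partition is deterministic per seed.
#' @param unit `"pixel"` (default) or `"roi"`.
#' @return list with elements `train` and `validation` (both
#'   `annotation_library`), disjoint and exhaustive.
#' @export
split_library <- function(lib, train_fraction = 0.9, seed = 1L,
                          unit = c("pixel", "roi")) {
  stopifnot(inherits(lib, "annotation_library"))
  unit <- match.arg(unit)
  if (train_fraction <= 0 || train_fraction > 1)
    stop("'train_fraction' must be in (0, 1]", call. = FALSE)
  cnt <- table(lib$group)
  if (any(cnt < 2L))
    stop("every group needs >= 2 entries; too few: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "), call. = FALSE)
  if (train_fraction == 1) {
    warning("train_fraction = 1: validation set is empty")
    val <- lib[integer(0L), ]
    class(val) <- class(lib)
    return(list(train = lib, validation = val))
  }
  take <- with_seed(seed, {
    sel <- logical(nrow(lib))
    if (unit == "pixel") {
      for (g in names(cnt)) {
        idx <- which(lib$group == g)
        n_tr <- max(1L, min(length(idx) - 1L,
                            round(train_fraction * length(idx))))
        sel[sample(idx, n_tr)] <- TRUE
      }
    } else {
      key <- paste(lib$transect, lib$roi_id)
      for (g in unique(lib$group)) {
        rois_g <- unique(key[lib$group == g])
        n_tr <- max(1L, min(length(rois_g) - 1L,
                            round(train_fraction * length(rois_g))))
        if (length(rois_g) == 1L) n_tr <- 1L
        tr <- sample(rois_g, n_tr)
        sel[key %in% tr & lib$group == g] <- TRUE
      }
    }
    sel
  })
  train <- lib[take, ]; val <- lib[!take, ]
  rownames(train) <- rownames(val) <- NULL
  class(train) <- class(val) <- class(lib)
  list(train = train, validation = val)
}

#' Automatically place rectangular ROIs on a simulated scene
#'
#' Convenience for simulated surveys, standing in for expert annotation:
#' for each category present in the ground-truth map, up to
#' `n_per_category` square ROIs of side `size` pixels are placed at
#' locations whose full footprint carries a single label.  A fraction of
#' the ROIs (default half) is placed *adjacent to category boundaries*
#' (still single-label, but with mixed surroundings), the way an expert
#' delineates polygons right up to the edge of an organism; this exposes
#' patch-based classifiers to boundary context during training.
#'
#' @param map fine-level `label_map` (ground truth).
#' @param n_per_category ROIs per fine category (default 3).
#' @param size ROI side length in pixels (default 5).
#' @param seed integer seed.
#' @param transect_id transect identifier stamped on the ROIs.
#' @param edge_fraction fraction of ROIs targeted at boundary-adjacent
#'   blocks of side `edge_size` (default 0.5; 0 disables).
#' @param edge_size side length of boundary-adjacent ROIs (default 3).
#' @return list of [roi()] objects (categories with no pure block of the
#'   requested size are skipped); ROIs never overlap.
#' @export
auto_rois <- function(map, n_per_category = 3L, size = 5L, seed = 1L,
                      transect_id = "T1", edge_fraction = 0.5,
                      edge_size = 3L) {
  stopifnot(inherits(map, "label_map"), map$level == "fine")
  g <- map$grid
  nr <- nrow(g); nc <- ncol(g)
  if (size >= nr || size >= nc)
    stop("'size' exceeds the map dimensions", call. = FALSE)
  pure <- function(s) {
    ## corner (i, j) is TRUE when the s x s block starting there is
    ## single-label; value matrix gives that label
    rr <- seq_len(nr - s + 1L); cc <- seq_len(nc - s + 1L)
    ok <- matrix(TRUE, length(rr), length(cc))
    ref <- g[rr, cc, drop = FALSE]
    for (dr in seq_len(s) - 1L) for (dc in seq_len(s) - 1L) {
      if (dr == 0L && dc == 0L) next
      ok <- ok & (g[rr + dr, cc + dc, drop = FALSE] == ref)
    }
    list(ok = ok, ref = ref, rr = rr, cc = cc)
  }
  interior <- pure(size)
  edge <- NULL
  n_edge_want <- 0L
  if (edge_fraction > 0 && edge_size < size) {
    edge <- pure(edge_size)
    ## boundary-adjacent: pure small block not contained in any pure
    ## big block
    ir <- seq_len(nrow(interior$ok)); ic <- seq_len(ncol(interior$ok))
    ins <- matrix(FALSE, nrow(edge$ok), ncol(edge$ok))
    for (dr in 0:(size - edge_size)) for (dc in 0:(size - edge_size)) {
      sub <- matrix(FALSE, nrow(edge$ok), ncol(edge$ok))
      sub[ir + dr, ic + dc] <- interior$ok
      ins <- ins | sub
    }
    edge$ok <- edge$ok & !ins
    n_edge_want <- ceiling(n_per_category * edge_fraction)
  }
  place <- function(cat_idx, cand_pool, s, n_want, taken, rois) {
    cand <- cand_pool$rr_cc
    if (!length(cand)) return(list(taken = taken, rois = rois))
    cand <- cand[sample.int(length(cand))]
    accepted <- 0L
    nrr <- cand_pool$nrr
    for (p in cand) {
      if (accepted >= n_want) break
      r0 <- (p - 1L) %% nrr
      c0 <- (p - 1L) %/% nrr
      rs <- (r0 + 1L):(r0 + s); cs <- (c0 + 1L):(c0 + s)
      if (any(taken[rs, cs])) next
      taken[rs, cs] <- TRUE
      accepted <- accepted + 1L
      rois[[length(rois) + 1L]] <-
        roi(rbind(c(r0, c0), c(r0, c0 + s), c(r0 + s, c0 + s),
                  c(r0 + s, c0)),
            label = map$scheme$fine[cat_idx], transect_id = transect_id)
    }
    list(taken = taken, rois = rois)
  }
  with_seed(seed, {
    rois <- list()
    taken <- matrix(FALSE, nr, nc)
    for (cat_idx in sort(unique(as.integer(g)))) {
      if (!is.null(edge)) {
        pool <- list(rr_cc = which(edge$ok & edge$ref == cat_idx),
                     nrr = nrow(edge$ok))
        st <- place(cat_idx, pool, edge_size, n_edge_want, taken, rois)
        taken <- st$taken; rois <- st$rois
      }
      pool <- list(rr_cc = which(interior$ok & interior$ref == cat_idx),
                   nrr = nrow(interior$ok))
      st <- place(cat_idx, pool, size, n_per_category, taken, rois)
      taken <- st$taken; rois <- st$rois
    }
    rois
  })
}

#' Read and write ROI files
#'
#' ROIs are stored as a JSON array of
#' `{transect_id, label, vertices: [[row, col], ...]}`.
#' @param path file path.
#' @export
read_rois <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  lapply(js, function(e)
    roi(do.call(rbind, lapply(e$vertices, unlist)),
        label = e$label, transect_id = e$transect_id))
}

#' @rdname read_rois
#' @param rois list of `roi` objects.
#' @export
write_rois <- function(rois, path) {
  js <- lapply(rois, function(r)
    list(transect_id = r$transect_id, label = r$label,
         vertices = lapply(seq_len(nrow(r$vertices)),
                           function(i) as.numeric(r$vertices[i, ]))))
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
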