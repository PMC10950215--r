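#' Photoquadrat survey design
#'
#' The monitoring design places one 0.25 m^2 (0.5 m x 0.5 m) quadrat at
#' every meter mark along each 50 m transect and scores 50 nonaligned,
#' systematically sampled points per quadrat photo: 50 quadrats per
#' transect, 250 per survey of five transects, 12,500 identification
#' points per survey.
#'
#' @param transect_length_m positive integer transect length (default
#'   50); one quadrat per meter mark.
#' @param quadrat_size_m quadrat side length (default 0.5).
#' @param swath_width_m transect swath width (default 1); quadrats are
#'   centered on the transect line.
#' @return data frame of class `quadrat_frame` with one row per
#'   quadrat: `position_m` (meter mark), and footprint bounds
#'   `along0`, `along1`, `cross0`, `cross1` in metres (half-open
#'   intervals, so adjacent footprints never overlap).
#' @export
place_quadrats <- function(transect_length_m = 50, quadrat_size_m = 0.5,
                           swath_width_m = 1) {
  stop_if_not_scalar_pos(transect_length_m, "transect_length_m")
  stopifnot(quadrat_size_m <= 1, quadrat_size_m <= swath_width_m)
  marks <- seq_len(floor(transect_length_m)) - 1L
  c0 <- (swath_width_m - quadrat_size_m) / 2
  q <- data.frame(position_m = marks,
                  along0 = marks, along1 = marks + quadrat_size_m,
                  cross0 = c0, cross1 = c0 + quadrat_size_m)
  class(q) <- c("quadrat_frame", "data.frame")
  q
}

#' Sample nonaligned systematic points within a quadrat
#'
#' "Nonaligned, systematically sampled" is implemented as stratified
#' random sampling: the quadrat footprint is partitioned into a
#' `grid[1] x grid[2]` cell lattice (default 10 x 5 = 50 cells) and one
#' uniform random point is drawn per cell, guaranteeing even spatial
#' spread without grid alignment.
#'
#' @param quadrat single row of a [place_quadrats()] frame.
#' @param n number of points; must equal `prod(grid)` (default 50).
#' @param grid cells along x across the footprint.
#' @param seed integer seed; points are deterministic per seed.
#' @return data frame with columns `along_m`, `cross_m`, `cell`.
#' @export
sample_points <- function(quadrat, n = 50L, grid = c(10L, 5L), seed = 1L) {
  stopifnot(is.data.frame(quadrat), nrow(quadrat) == 1L)
  if (n != prod(grid))
    stop("'n' must equal prod(grid) (one point per cell)", call. = FALSE)
  da <- (quadrat$along1 - quadrat$along0) / grid[1]
  dc <- (quadrat$cross1 - quadrat$cross0) / grid[2]
  with_seed(seed, {
    cells <- expand.grid(ia = seq_len(grid[1]), ic = seq_len(grid[2]))
    data.frame(
      along_m = quadrat$along0 + (cells$ia - 1 + stats::runif(n)) * da,
      cross_m = quadrat$cross0 + (cells$ic - 1 + stats::runif(n)) * dc,
      cell = seq_len(n))
  })
}

#' Identify the benthic category under each sample point
#'
#' Each point is labelled by the fine category of the ground-truth map
#' pixel containing it (pixel `(i, j)` covers the half-open square
#' `[(i-1), i) x [(j-1), j)` times the map resolution).
#'
#' @param points data frame with `along_m`, `cross_m` (metres).
#' @param map fine-level `label_map`.
#' @return the `points` data frame with added `fine` and `group`
#'   columns plus a `tally` attribute (named fine-category counts).
#' @export
identify_points <- function(points, map) {
  stopifnot(inherits(map, "label_map"), map$level == "fine")
  res <- map$resolution_m
  r <- floor(points$along_m / res) + 1L
  c <- floor(points$cross_m / res) + 1L
  if (any(r < 1L) || any(r > nrow(map$grid)) ||
      any(c < 1L) || any(c > ncol(map$grid)))
    stop("sample point outside the map", call. = FALSE)
  idx <- map$grid[cbind(r, c)]
  points$fine <- map$scheme$fine[idx]
  points$group <- map$scheme$group[idx]
  attr(points, "tally") <- table(factor(points$fine,
                                        levels = map$scheme$fine))
  points
}

#' Percent cover from point-intercept counts
#'
#' `cover = 100 * points on category / total points`, pooling all
#' quadrat points of a transect (the point-intercept estimator).
#'
#' @param labels character vector of per-point labels (fine or group)
#'   for one transect.
#' @param categories full category vector (levels), so zero-cover
#'   categories appear explicitly.
#' @return named numeric vector of percent covers summing to 100.
#' @export
cover_from_points <- function(labels, categories = sort(unique(labels))) {
  if (!length(labels)) stop("zero identification points", call. = FALSE)
  cnt <- table(factor(labels, levels = categories))
  stats::setNames(100 * as.numeric(cnt) / length(labels), categories)
}

#' Percent cover from a classified (or ground-truth) label map
#'
#' Pixel-fraction cover over all non-plate pixels; equals a brute-force
#' histogram of the map.
#'
#' @param map a `label_map`; reserved code 0 (reference plate) is
#'   excluded.
#' @param level `"group"` or `"fine"` (for fine-level maps).
#' @param exclude optional logical matrix of additional pixels to drop.
#' @return named percent-cover vector summing to 100.
#' @export
cover_from_map <- function(map, level = c("group", "fine"),
                           exclude = NULL) {
  realized_cover(map, match.arg(level), exclude = exclude)
}

#' Aggregate fine-category covers into broader groups
#'
#' Group cover is the sum of its member categories' covers, so row sums
#' are preserved.  `mapping` defaults to the scheme's fine-to-group
#' mapping; any named character vector (from -> to) works, e.g. merging
#' *Acropora abrotanoides* with Scleractinia into combined hard-coral
#' cover.  Categories absent from `mapping` are an error; aggregating an
#' already-grouped vector with an identity mapping returns it unchanged.
#'
#' @param cover named numeric vector of percent covers.
#' @param mapping named character vector mapping category -> group, or a
#'   `category_scheme`.
#' @return named numeric vector of group covers.
#' @export
aggregate_cover <- function(cover, mapping) {
  if (inherits(mapping, "category_scheme"))
    mapping <- stats::setNames(mapping$group, mapping$fine)
  stopifnot(!is.null(names(cover)), !is.null(names(mapping)))
  miss <- setdiff(names(cover), names(mapping))
  if (length(miss))
    stop("unmapped categories: ", paste(miss, collapse = ", "),
         call. = FALSE)
  to <- mapping[names(cover)]
  out <- tapply(cover, factor(to, levels = unique(mapping)), sum)
  out <- out[!is.na(out)]
  stats::setNames(as.numeric(out), names(out))
}

#' Tally a per-point attribute within a category filter
#'
#' Used e.g. to report the share of points on a coral category that were
#' flagged as juvenile colonies.
#'
#' @param points data frame with label and attribute columns.
#' @param category category value(s) to filter on.
#' @param attribute name of a logical attribute column.
#' @param label_col which label column to filter (default `"fine"`).
#' @return list with `count`, `total` and `percent` (rounded to one
#'   decimal, e.g. 47 of 135 -> 34.8).
#' @export
tally_attribute <- function(points, category, attribute,
                            label_col = "fine") {
  stopifnot(attribute %in% names(points), label_col %in% names(points))
  sel <- points[[label_col]] %in% category
  total <- sum(sel)
  count <- sum(sel & as.logical(points[[attribute]]))
  list(count = count, total = total,
       percent = if (total == 0) 0 else round(100 * count / total, 1))
}

#' Survey design arithmetic
#'
#' @param n_transects,transect_length_m,points_per_quadrat design
#'   parameters (defaults: 5 transects x 50 m x 50 points).
#' @return list with `n_quadrats` (per survey) and `n_points`; asserts
#'   the 5 x 50 x 50 = 12,500-point design identity.
#' @export
survey_plan <- function(n_transects = 5L, transect_length_m = 50L,
                        points_per_quadrat = 50L) {
  nq <- n_transects * floor(transect_length_m)
  np <- nq * points_per_quadrat
  stopifnot(nq == n_transects * floor(transect_length_m),
            np == nq * points_per_quadrat)
  list(n_transects = n_transects, quadrats_per_transect =
         floor(transect_length_m), n_quadrats = nq,
       points_per_quadrat = points_per_quadrat, n_points = np)
}

#' Simulate a photoquadrat point-intercept survey of a scene
#'
#' Places quadrats along the ground-truth map, draws the stratified
#' points of each quadrat, identifies them against the map, and returns
#' per-point records plus the pooled transect cover estimate.
#'
#' @param map fine-level `label_map` of one transect.
#' @param seed integer seed.
#' @param points_per_quadrat default 50.
#' @param juvenile_prob optional named per-fine-category probability
#'   that a point is flagged `juvenile` (simulation of demography
#'   attributes; defaults to none).
#' @return list with `points` (per-point data frame), `cover_fine`,
#'   `cover_group` (percent, method PQ).
#' @export
simulate_point_survey <- function(map, seed = 1L, points_per_quadrat = 50L,
                                  juvenile_prob = NULL) {
  stopifnot(inherits(map, "label_map"), map$level == "fine")
  len_m <- nrow(map$grid) * map$resolution_m
  wid_m <- ncol(map$grid) * map$resolution_m
  quads <- place_quadrats(len_m, quadrat_size_m = min(0.5, wid_m),
                          swath_width_m = wid_m)
  pts <- vector("list", nrow(quads))
  for (i in seq_len(nrow(quads))) {
    p <- sample_points(quads[i, ], n = points_per_quadrat,
                       grid = best_grid(points_per_quadrat),
                       seed = derive_seed(seed, i))
    p$quadrat_m <- quads$position_m[i]
    pts[[i]] <- p
  }
  pts <- do.call(rbind, pts)
  pts <- identify_points(pts, map)
  if (!is.null(juvenile_prob)) {
    pr <- juvenile_prob[pts$fine]
    pr[is.na(pr)] <- 0
    pts$juvenile <- with_seed(derive_seed(seed, 0L),
                              stats::runif(nrow(pts)) < pr)
  }
  list(points = pts,
       cover_fine = cover_from_points(pts$fine, map$scheme$fine),
       cover_group = cover_from_points(pts$group, map$scheme$groups))
}

## 10 x 5 for 50 points; otherwise the most square factorization.
best_grid <- function(n) {
  if (n == 50L) return(c(10L, 5L))
  f <- which(n %% seq_len(floor(sqrt(n))) == 0)
  a <- max(f)
  c(as.integer(n / a), as.integer(a))
}
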