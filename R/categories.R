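#' Benthic category schemes
#'
#' Benthic organisms and substrates are identified at fine taxonomic
#' resolution (typically genus or species, 58 categories in the bundled
#' default) and aggregated into 10 broad taxonomic or functional groups
#' for community-level analysis.  The staghorn coral *Acropora
#' abrotanoides* is kept in its own group, separate from other
#' Scleractinia, because it is the habitat-defining coral at exposed
#' forereef sites such as Lafac Bay (Guam).
#'
#' @param table data frame with character columns `fine` and `group`,
#'   one row per fine category.  Defaults to the table bundled with the
#'   package (a synthetic stand-in list of 58 plausible reef categories;
#'   see `inst/extdata/synthetic_s1_categories.csv`).
#' @return An object of class `category_scheme`: a list with elements
#'   `fine` (character vector of fine-category names), `group`
#'   (group of each fine category, parallel to `fine`), and `groups`
#'   (the 10 group names, in first-appearance order).
#' @examples
#' sch <- build_category_scheme()
#' length(sch$fine)    # 58
#' length(sch$groups)  # 10
#' group_of(sch, "Acropora abrotanoides")
#' @export
build_category_scheme <- function(table = default_category_table()) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("'table' must be a nonempty data frame", call. = FALSE)
  if (!all(c("fine", "group") %in% names(table)))
    stop("'table' needs columns 'fine' and 'group'", call. = FALSE)
  fine <- as.character(table$fine)
  group <- as.character(table$group)
  if (anyDuplicated(fine))
    stop("duplicate fine category names: ",
         paste(unique(fine[duplicated(fine)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(fine)) || any(!nzchar(group)))
    stop("empty category names are not allowed", call. = FALSE)
  groups <- unique(group)
  if (length(groups) != 10L)
    stop(sprintf("expected exactly 10 groups, got %d", length(groups)),
         call. = FALSE)
  structure(list(fine = fine, group = group, groups = groups),
            class = "category_scheme")
}

#' @rdname build_category_scheme
#' @export
default_category_table <- function() {
  path <- system.file("extdata", "synthetic_s1_categories.csv",
                      package = "reefscan", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname build_category_scheme
#' @param scheme a `category_scheme`.
#' @param fine character vector of fine-category names to look up.
#' @export
group_of <- function(scheme, fine) {
  stopifnot(inherits(scheme, "category_scheme"))
  idx <- match(fine, scheme$fine)
  if (anyNA(idx))
    stop("unmapped fine categories: ",
         paste(fine[is.na(idx)], collapse = ", "), call. = FALSE)
  scheme$group[idx]
}

## Integer group index (1..10) for each fine-category index.
group_index <- function(scheme) {
  match(scheme$group, scheme$groups)
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("Benthic category scheme:", length(x$fine), "fine categories in",
      length(x$groups), "groups\n")
  tab <- table(factor(x$group, levels = x$groups))
  for (g in x$groups) cat(sprintf("  %-42s %d\n", g, tab[[g]]))
  invisible(x)
}

#' Mean percent covers of the Lafac Bay (Guam) monitoring surveys
#'
#' Group-level mean percent cover (and, from [lafac_cover_sd()], the
#' between-transect standard deviations) of the 10 benthic groups for
#' the 2015, 2017 and 2019 photoquadrat surveys and the 2019
#' hyperspectral (DiveRay) survey of five permanent 50 m transects at
#' Lafac Bay.  These summary tables are the reference conditions used by
#' the scene simulator and by the worked examples.
#'
#' @return A 10 x 4 numeric matrix (groups x surveys `2015`, `2017`,
#'   `2019-PQ`, `2019-DR`), values in percent.
#' @examples
#' shannon(lafac_cover_means()[, "2015"])
#' @export
lafac_cover_means <- function() {
  m <- cbind(
    `2015`    = c(7.5, 24.3, 0.4, 60.9, 2.9, 1.1, 2.2, 0.0, 0.6, 0.2),
    `2017`    = c(10.1, 28.7, 1.0, 52.1, 4.0, 0.1, 2.9, 0.1, 0.4, 0.4),
    `2019-PQ` = c(0.2, 6.9, 2.9, 81.1, 2.8, 1.9, 2.6, 0.9, 0.4, 0.2),
    `2019-DR` = c(0.6, 7.0, 1.1, 84.6, 2.3, 0.1, 1.0, 3.4, 0.1, 0.0))
  rownames(m) <- lafac_group_names()
  m
}

#' @rdname lafac_cover_means
#' @export
lafac_cover_sd <- function() {
  m <- cbind(
    `2015`    = c(1.2, 2.5, 0.2, 1.1, 0.5, 0.6, 0.6, 0.0, 0.7, 0.1),
    `2017`    = c(3.7, 6.5, 0.4, 3.8, 0.8, 0.1, 1.5, 0.2, 0.4, 0.2),
    `2019-PQ` = c(0.3, 2.6, 1.1, 2.4, 0.9, 0.9, 0.6, 1.6, 0.6, 0.2),
    `2019-DR` = c(0.3, 2.7, 0.8, 4.5, 1.1, 0.0, 0.5, 4.0, 0.1, 0.0))
  rownames(m) <- lafac_group_names()
  m
}

lafac_group_names <- function() {
  c("Acropora abrotanoides", "Scleractinia", "Green macroalgae",
    "Turf algae/Cyanobacteria/Bare substrate", "Corallinophycidae",
    "Porifera", "Peyssonneliales", "Red macroalgae",
    "Octocorals/Hydrozoans", "Brown macroalgae")
}
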