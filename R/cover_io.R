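#' Cover tables
#'
#' Long-format percent-cover records: one row per (survey, transect,
#' method, category).  `method` is `"PQ"` (photoquadrat point counts),
#' `"DR"` (classified hyperspectral map) or `"truth"` (simulator ground
#' truth).  Per (survey, transect, method) the covers must sum to 100
#' (tolerance 0.01; a looser tolerance applies to rounded external
#' files).
#'
#' @param df data frame with columns `survey`, `transect`, `method`,
#'   `category`, `cover_pct`.
#' @param tol allowed deviation of the per-sample cover sum from 100.
#' @return `df` with class `cover_table`.
#' @export
cover_table <- function(df, tol = 0.01) {
  need <- c("survey", "transect", "method", "category", "cover_pct")
  if (!all(need %in% names(df)))
    stop("cover table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$cover_pct < 0))
    stop("negative cover values", call. = FALSE)
  key <- paste(df$survey, df$transect, df$method)
  sums <- tapply(df$cover_pct, key, sum)
  bad <- abs(sums - 100) > tol
  if (any(bad))
    stop("cover does not sum to 100 for: ",
         paste(names(sums)[bad], collapse = "; "),
         sprintf(" (sums %s)", paste(round(sums[bad], 2), collapse = ", ")),
         call. = FALSE)
  df <- df[need]
  rownames(df) <- NULL
  class(df) <- c("cover_table", "data.frame")
  df
}

#' Read and write cover tables as CSV
#'
#' The on-disk dialect mirrors the supplementary-table convention: when
#' every record's method is `PQ` or `DR`, the method is carried as a
#' `-PQ` / `-DR` suffix on the `survey` label and no method column is
#' written; the suffix is parsed back into the `method` field on read.
#' Tables holding other methods (e.g. simulator ground truth) keep an
#' explicit `method` column, and survey labels are then taken verbatim.
#'
#' @param path CSV file path.
#' @param tol cover-sum tolerance passed to [cover_table()]; the default
#'   0.5 accommodates values rounded to the nearest tenth of a percent.
#' @return a `cover_table`.
#' @export
read_cover_csv <- function(path, tol = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!"method" %in% names(df)) {
    has <- grepl("-(PQ|DR)$", df$survey)
    df$method <- ifelse(has, sub("^.*-(PQ|DR)$", "\\1", df$survey), "PQ")
    df$survey[has] <- sub("-(PQ|DR)$", "", df$survey[has])
  }
  if (!"transect" %in% names(df)) df$transect <- "T1"
  cover_table(df, tol = tol)
}

#' @rdname read_cover_csv
#' @param tab a `cover_table`.
#' @export
write_cover_csv <- function(tab, path) {
  stopifnot(inherits(tab, "cover_table"))
  out <- as.data.frame(tab)
  if (all(out$method %in% c("PQ", "DR"))) {
    out$survey <- paste0(out$survey, "-", out$method)
    out$method <- NULL
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cover_table <- function(x, ...) {
  cat(sprintf("cover_table: %d records, %d surveys x %d transects, %s\n",
              nrow(x), length(unique(x$survey)),
              length(unique(x$transect)),
              paste(unique(x$method), collapse = "/")))
  NextMethod()
}
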