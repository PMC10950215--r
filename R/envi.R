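#' Read and write ENVI rasters
#'
#' Spectral cubes are exchanged in the ENVI format standard for
#' hyperspectral imagery: a flat binary file plus a text `.hdr` with
#' `samples`, `lines`, `bands`, `interleave`, `data type`, `byte order`
#' and a `wavelength` block.  Cubes are written as 32-bit little-endian
#' float, BIL interleave; BIL, BIP and BSQ are all read.  Label maps are
#' written as a single-band integer raster with a category legend CSV
#' (`index,name,group`).
#'
#' @param cube a `spectral_cube`.
#' @param path output path of the binary file; the header is written to
#'   `<path>.hdr`.
#' @param interleave `"bil"` (default), `"bip"` or `"bsq"`.
#' @return `write_envi` returns `path` invisibly; `read_envi` returns a
#'   `spectral_cube`.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bip", "bsq")) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)                 # lines, samples, bands
  a <- switch(interleave,
              bsq = aperm(cube$data, c(2, 1, 3)),   # sample, line, band
              bil = aperm(cube$data, c(2, 3, 1)),   # sample, band, line
              bip = aperm(cube$data, c(3, 2, 1)))   # band, sample, line
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(a), con, size = 4L, endian = "little")
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("units = %s", cube$units %||% "radiance"),
           if (!is.null(cube$noise_sd))
             sprintf("; noise sd = %g", cube$noise_sd),
           sprintf("wavelength = { %s }",
                   paste(format(cube$wavelength_nm, trim = TRUE,
                                digits = 15),
                         collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  if (!is.null(cube$plate_mask) && any(cube$plate_mask)) {
    idx <- which(cube$plate_mask, arr.ind = TRUE)
    utils::write.csv(data.frame(row = idx[, 1], col = idx[, 2]),
                     paste0(path, ".plate.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_envi
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) hdr_path <- sub("\\.[^.]+$", ".hdr", path)
  if (!file.exists(hdr_path))
    stop("missing ENVI header for ", path, call. = FALSE)
  h <- parse_envi_header(hdr_path)
  for (k in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(h[[k]]))
      stop("ENVI header missing key: ", k, call. = FALSE)
  ns <- as.integer(h$samples); nl <- as.integer(h$lines)
  nb <- as.integer(h$bands)
  dt <- as.integer(h[["data type"]])
  size <- switch(as.character(dt), `1` = 1L, `2` = 2L, `3` = 4L,
                 `4` = 4L, `5` = 8L, `12` = 2L,
                 stop("unsupported ENVI data type ", dt, call. = FALSE))
  what <- if (dt %in% c(4, 5)) numeric() else integer()
  endian <- if (identical(h[["byte order"]], "1")) "big" else "little"
  n_expect <- ns * nl * nb
  if (file.info(path)$size != n_expect * size)
    stop(sprintf("ENVI file size mismatch: %d bytes, expected %d",
                 file.info(path)$size, n_expect * size), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_v <- readBin(con, what, n = n_expect, size = size, endian = endian,
                   signed = dt != 1L)
  a <- switch(tolower(h$interleave),
              bsq = aperm(array(raw_v, c(ns, nl, nb)), c(2, 1, 3)),
              bil = aperm(array(raw_v, c(ns, nb, nl)), c(3, 1, 2)),
              bip = aperm(array(raw_v, c(nb, ns, nl)), c(3, 2, 1)),
              stop("unknown interleave ", h$interleave, call. = FALSE))
  wl <- h$wavelength
  if (!is.null(wl)) {
    wl <- as.numeric(strsplit(gsub("[{}]", "", wl), ",")[[1]])
    if (length(wl) != nb)
      stop(sprintf("header lists %d wavelengths for %d bands",
                   length(wl), nb), call. = FALSE)
  }
  plate_path <- paste0(path, ".plate.csv")
  pm <- NULL
  if (file.exists(plate_path)) {
    pp <- utils::read.csv(plate_path)
    pm <- matrix(FALSE, nl, ns)
    pm[cbind(pp$row, pp$col)] <- TRUE
  }
  structure(list(data = a, wavelength_nm = wl, plate_mask = pm,
                 units = h$units %||% "radiance",
                 retained_bands = seq_len(nb)),
            class = "spectral_cube")
}

parse_envi_header <- function(path) {
  lines_raw <- readLines(path, warn = FALSE)
  h <- list()
  buf <- NULL
  for (ln in lines_raw) {
    if (is.null(buf)) {
      if (grepl("^\\s*;", ln) || !grepl("=", ln)) next
      buf <- ln
    } else {
      buf <- paste(buf, ln)
    }
    ## keep accumulating while a { } block is open
    nopen <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    nclose <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    if (nopen > nclose) next
    kv <- strsplit(buf, "=", fixed = TRUE)[[1]]
    h[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = "="))
    buf <- NULL
  }
  h
}

#' @rdname write_envi
#' @param map a `label_map`.
#' @export
write_label_envi <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  g <- map$grid
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(g)), con, size = 4L, endian = "little")
  writeLines(c("ENVI",
               sprintf("samples = %d", ncol(g)),
               sprintf("lines = %d", nrow(g)),
               "bands = 1", "header offset = 0",
               "file type = ENVI Classification",
               "data type = 3", "interleave = bsq", "byte order = 0",
               sprintf("; resolution_m = %g", map$resolution_m),
               sprintf("; level = %s", map$level)),
             paste0(path, ".hdr"))
  if (map$level == "fine")
    legend <- data.frame(index = seq_along(map$scheme$fine),
                         name = map$scheme$fine,
                         group = map$scheme$group)
  else
    legend <- data.frame(index = seq_along(map$scheme$groups),
                         name = map$scheme$groups,
                         group = map$scheme$groups)
  utils::write.csv(legend, paste0(path, ".legend.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_envi
#' @param scheme category scheme used to rebuild the map labels.
#' @export
read_label_envi <- function(path, scheme = build_category_scheme()) {
  h <- parse_envi_header(paste0(path, ".hdr"))
  ns <- as.integer(h$samples); nl <- as.integer(h$lines)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, integer(), n = ns * nl, size = 4L, endian = "little")
  g <- t(matrix(v, ns, nl))
  cmt <- readLines(paste0(path, ".hdr"), warn = FALSE)
  res <- sub(".*resolution_m = ", "",
             grep("resolution_m", cmt, value = TRUE)[1])
  lvl <- sub(".*level = ", "", grep("; level", cmt, value = TRUE)[1])
  if (is.na(lvl) || !nzchar(lvl)) lvl <- "fine"
  structure(list(grid = g, resolution_m = as.numeric(res),
                 level = lvl, scheme = scheme),
            class = "label_map")
}
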