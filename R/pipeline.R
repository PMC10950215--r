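#' Pipeline configuration
#'
#' A flat, diffable key-value config with one section per pipeline
#' stage (`scene`, `preprocess`, `annotate`, `model`, `survey`,
#' `stats`), plus a `master_seed` and output directory.  Every stage
#' derives its own seed deterministically from `master_seed` and the
#' stage name, so a run is fully reproducible from the config alone.
#'
#' @param master_seed integer master seed.
#' @param out_dir output directory for stage artifacts.
#' @param ... named lists overriding stage sections, e.g.
#'   `scene = list(transect_length_m = 10)`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(master_seed = 1L, out_dir = "reefscan_out",
                            ...) {
  cfg <- list(
    version = as.character(utils::packageVersion("reefscan")),
    master_seed = as.integer(master_seed),
    out_dir = out_dir,
    scene = list(transect_length_m = 50, swath_width_m = 1,
                 pixel_size_m = 0.01, patchiness_scale_m = 0.5,
                 n_transects = 5, surveys = "2015,2017,2019-PQ",
                 samples = 680, noise_sd = 0.005, plate_size_m = 0.1,
                 render = 1),
    preprocess = list(smooth_window = 7, smooth_order = 2,
                      min_band_snr = 10, standardize = 1,
                      plate_albedo = 1),
    annotate = list(n_per_category = 3, roi_size = 5,
                    train_fraction = 0.9, unit = "pixel"),
    model = list(patch_size = 7, reduced_channels = 32,
                 n_spectral_units = 2, n_spatial_units = 2,
                 learning_rate = 2e-3, max_epochs = 40, batch_size = 64,
                 early_stop_patience = 8),
    survey = list(points_per_quadrat = 50),
    stats = list(n_perm = 9999))
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec,
                                   call. = FALSE)
    if (is.list(cfg[[sec]])) cfg[[sec]][names(over[[sec]])] <- over[[sec]]
    else cfg[[sec]] <- over[[sec]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param stage stage name.
#' @param cfg a `pipeline_config`.
#' @export
stage_seed <- function(cfg, stage) {
  derive_seed(cfg$master_seed, sum(utf8ToInt(stage)))
}

#' Read and write pipeline configs
#'
#' On-disk format: `[section]` headers over flat `key = value` lines.
#' Configs round-trip through serialization unchanged.
#'
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- c(sprintf("version = %s", cfg$version),
           sprintf("master_seed = %d", cfg$master_seed),
           sprintf("out_dir = %s", cfg$out_dir))
  for (sec in setdiff(names(cfg), c("version", "master_seed", "out_dir"))) {
    out <- c(out, "", sprintf("[%s]", sec))
    for (k in names(cfg[[sec]]))
      out <- c(out, sprintf("%s = %s", k,
                            as.character(cfg[[sec]][[k]])))
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines_raw <- readLines(path, warn = FALSE)
  cfg <- pipeline_config()
  sec <- NULL
  for (ln in lines_raw) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (grepl("^\\[.*\\]$", ln)) { sec <- gsub("[][]", "", ln); next }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    val <- if (!is.na(num)) num else val
    if (is.null(sec)) {
      if (key == "master_seed") cfg$master_seed <- as.integer(val)
      else cfg[[key]] <- as.character(val)
    } else cfg[[sec]][[key]] <- val
  }
  cfg
}

#' Run manifest
#'
#' Records, per pipeline stage, the input/output file hashes, the seed,
#' elapsed time and a config snapshot, so deterministic stages can be
#' audited for byte-identical reruns.
#'
#' @param manifest_path path of the JSON manifest (created when absent).
#' @param stage stage name.
#' @param inputs,outputs character vectors of file paths (hashed with
#'   md5).
#' @param seed the stage seed.
#' @param cfg the `pipeline_config` snapshot.
#' @param elapsed elapsed seconds.
#' @export
manifest_record <- function(manifest_path, stage, inputs = character(),
                            outputs = character(), seed = NA_integer_,
                            cfg = NULL, elapsed = NA_real_) {
  man <- if (file.exists(manifest_path))
    jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  else list(stages = list())
  hash <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  man$stages[[stage]] <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, elapsed_s = elapsed,
    inputs = hash(inputs), outputs = hash(outputs),
    config = if (!is.null(cfg)) unclass(cfg))
  jsonlite::write_json(man, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest_path)
}
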