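# File I/O, configuration and the end-to-end pipeline driver.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its study default: illumination blur
#' sigma 2048 px, Phansalkar radius 50 px, mask shrink 3% of egg width, 12
#' granularity scales, trait component counts (3, 1, 2, 2, 1), 265 + 265
#' training pairs, 10 training repeats, 500 trees, MED threshold 350, and a
#' single master seed from which all stage seeds are derived.
#'
#' @param ... overrides of the defaults (same names).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    blur_radius_px = 2048, phansalkar_radius_px = 50, shrink_fraction = 0.03,
    n_scales = 12,
    ncomp = c(colour = 3L, luminance = 1L, pattern = 2L, pattern2 = 2L, shape = 1L),
    pattern_scope = "scales_by_region",
    n_same = 265, n_diff = 265, n_repeats = 10, ntree = 500,
    med_threshold = 350,
    n_participants = 35, enumerate = FALSE,
    method = "loco", game = 2,
    use_reference_weights = FALSE,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a configuration file (YAML or JSON)
#' @param path file path.
#' @return a [pipeline_config].
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("package 'yaml' required")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

.trait_schema <- function() c("egg_id", "clutch_id", trait_names())

#' Write / read a trait table as CSV
#'
#' RFC-4180 CSV, UTF-8, '.' decimal; full double precision so a write/read
#' round trip reproduces values to 1e-12 or better.
#'
#' @param traits trait table.
#' @param path file path.
#' @export
write_traits_csv <- function(traits, path) {
  stopifnot(all(c("egg_id", "clutch_id") %in% names(traits)))
  utils::write.csv(traits, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
}

#' @rdname write_traits_csv
#' @return `read_traits_csv` returns the validated trait table.
#' @export
read_traits_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(.trait_schema(), names(out))
  if (length(missing))
    stop("traits CSV schema error; missing column(s): ",
         paste(missing, collapse = ", "))
  out
}

#' Write / read a raw feature table as CSV
#' @param features feature table from [extract_features].
#' @param path file path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, fileEncoding = "UTF-8")
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!all(c("egg_id", "clutch_id") %in% names(out)))
    stop("features CSV schema error; missing column(s): ",
         paste(setdiff(c("egg_id", "clutch_id"), names(out)), collapse = ", "))
  out
}

#' Read one calibrated egg image from per-channel files
#'
#' Loads the five channel rasters and the mask from PNG (via the `png`
#' package) or single-page TIFF (via `tiff`) files named in a metadata row
#' with columns `egg_id`, `clutch_id`, `scale_px_per_mm`, `blunt_end`,
#' `mask_file` and `R_file` ... `LUM_file` (paths relative to `dir`).
#'
#' @param meta one-row `data.frame` (a row of the sidecar metadata CSV).
#' @param dir directory the file paths are relative to.
#' @return an [egg_image].
#' @export
read_egg_image <- function(meta, dir = ".") {
  read_raster <- function(fn) {
    path <- file.path(dir, fn)
    x <- if (grepl("\\.png$", fn, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required")
      png::readPNG(path)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
      tiff::readTIFF(path)
    }
    if (length(dim(x)) == 3) x <- x[, , 1]
    x
  }
  chs <- lapply(stats::setNames(paste0(c("R", "G", "B", "UV", "LUM"), "_file"),
                                c("R", "G", "B", "UV", "LUM")),
                function(col) read_raster(meta[[col]]))
  mask <- read_raster(meta$mask_file) > 0.5
  egg_image(chs, mask, meta$scale_px_per_mm, egg_id = meta$egg_id,
            clutch_id = meta$clutch_id, blunt_end = meta$blunt_end)
}

#' Extract features for every egg listed in a metadata CSV
#'
#' @param metadata_csv path to the sidecar metadata CSV (see
#'   [read_egg_image]).
#' @param ... passed to [extract_features].
#' @return feature table with one row per egg.
#' @export
extract_features_batch <- function(metadata_csv, ...) {
  meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  need <- c("egg_id", "clutch_id", "scale_px_per_mm", "blunt_end", "mask_file")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("metadata CSV schema error; missing column(s): ",
         paste(missing, collapse = ", "))
  dir <- dirname(metadata_csv)
  rows <- lapply(seq_len(nrow(meta)), function(i)
    extract_features(read_egg_image(meta[i, ], dir), ...))
  do.call(rbind, rows)
}

#' Run the full detection pipeline on a trait table
#'
#' Stages, in order: scale traits over the full egg set; rank traits with a
#' random forest (or use the reference weights); weight traits; compute the
#' MED statistic per clutch; enumerate or sample parasitized-clutch layouts;
#' identify the parasitic egg with the configured method; summarise
#' accuracy. All artifacts are written under `out_dir` as CSV plus a
#' machine-readable JSON summary carrying the seed and configuration.
#'
#' @param traits trait table (`egg_id`, `clutch_id`, nine traits), e.g. from
#'   [synth_clutches] or [predict.egg_trait_model].
#' @param config a [pipeline_config]. `method` is one of `"med"`,
#'   `"unsupervised"`, `"loco"`, `"leo"`; `game` 1 or 2.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(traits, config = pipeline_config(), out_dir = tempdir()) {
  stopifnot(inherits(config, "pipeline_config"))
  missing <- setdiff(.trait_schema(), names(traits))
  if (length(missing))
    stop("traits schema error; missing column(s): ",
         paste(missing, collapse = ", "),
         " (produce them with synth_clutches() or predict() on an egg_trait_model)")
  seeds <- derive_seeds(config$seed, 4)
  scaled <- scale_traits(traits)
  weights <- if (config$use_reference_weights) reference_weights()
             else rank_traits(scaled, scaled$clutch_id, ntree = config$ntree,
                              seed = seeds[1])
  weighted <- weight_traits(scaled, weights)
  med <- lapply(split(weighted, weighted$clutch_id), med_statistic,
                threshold = config$med_threshold,
                weights_provenance = weights$provenance)
  med_tab <- data.frame(clutch_id = names(med),
                        med = vapply(med, `[[`, 0, "med"),
                        parasitized = vapply(med, `[[`, TRUE, "classified_parasitized"))
  sets <- if (config$enumerate) {
    cbind(participant = NA_integer_,
          enumerate_combinations(traits)$combinations)
  } else {
    sample_assessment_sets(traits, config$n_participants, seed = seeds[2])
  }
  layouts <- build_layouts(sets, scaled, game = config$game, seed = seeds[3])
  calls <- switch(config$method,
    med = NULL,
    unsupervised = lapply(layouts, unsupervised_identify, traits = weighted),
    loco = , leo = evaluate_layouts(layouts, scaled, mode = config$method,
                                    n_repeats = config$n_repeats,
                                    n_same = config$n_same, n_diff = config$n_diff,
                                    ntree = config$ntree, seed = seeds[4]),
    stop("unknown method: ", config$method))
  acc <- NULL
  if (!is.null(calls)) {
    truth <- vapply(layouts, `[[`, "", "parasite_id")
    amb <- vapply(calls, function(t) isTRUE(t$ambiguous), TRUE)
    called <- vapply(calls, function(t) t$called_egg %||% NA_character_, "")
    acc <- accuracy_summary(length(calls), sum(amb),
                            sum(!amb & called == truth, na.rm = TRUE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_traits_csv(scaled, file.path(out_dir, "traits_scaled.csv"))
  utils::write.csv(med_tab, file.path(out_dir, "med.csv"), row.names = FALSE)
  utils::write.csv(sets, file.path(out_dir, "layouts.csv"), row.names = FALSE)
  if (!is.null(calls)) {
    calls_tab <- data.frame(
      host_clutch = vapply(layouts, `[[`, "", "host_clutch"),
      parasite_egg = vapply(layouts, `[[`, "", "parasite_id"),
      called_egg = vapply(calls, function(t) t$called_egg %||% NA_character_, ""),
      ambiguous = vapply(calls, function(t) isTRUE(t$ambiguous), TRUE))
    utils::write.csv(calls_tab, file.path(out_dir, "calls.csv"), row.names = FALSE)
  }
  summary <- list(
    config = unclass(config), seed = config$seed,
    n_eggs = nrow(traits), n_clutches = length(unique(traits$clutch_id)),
    n_layouts = length(layouts),
    weights = as.list(weights$w), weights_provenance = weights$provenance,
    med_parasitized = sum(med_tab$parasitized),
    accuracy = if (!is.null(acc)) unclass(acc) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scaled = scaled, weights = weights, med = med_tab,
                 layouts = layouts, calls = calls, accuracy = acc,
                 summary = summary))
}
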