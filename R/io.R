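# Raster storage: float32 TIFF plus a JSON sidecar (<path>.json) carrying
# georeference (top-left origin, cell size), band names, value scale/offset
# and other metadata. The TIFF codec stores samples in [0, 1], so grids with
# a wider range are written linearly rescaled with the mapping recorded in
# the sidecar; the nodata mask rides along as an extra 0/1 channel.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop_input("missing sidecar metadata ", sp,
               "; write rasters with this package's writers",
               class = "lodgedetect_format_error")
  }
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

# one grayscale page per channel: the tiff codec caps samples-per-pixel at 4,
# pages are unlimited
write_grid_tiff <- function(channels, path) {
  suppressWarnings(tiff::writeTIFF(unname(channels), path, bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
  invisible(path)
}

read_grid_tiff <- function(path) {
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE))
  array(unlist(pages, use.names = FALSE),
        dim = c(dim(pages[[1]])[1:2], length(pages)))
}

#' Write / read a four-band reflectance scene
#'
#' The scene goes to a 5-channel float32 TIFF (blue, green, red, NIR,
#' validity flag) with a JSON sidecar holding the georeference; the truth
#' grid, when present, goes to `<path>` with suffix `_truth.tif` as integer
#' class codes (0 background, 1 non-lodged maize, 2 lodged maize). The
#' write/read round trip preserves values to float32 precision.
#'
#' @param scene A [reflectance_scene()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  channels <- c(scene$bands, list(valid = (!scene$nodata_mask) * 1))
  channels <- lapply(channels, function(m) { m[scene$nodata_mask] <- 0; m })
  write_grid_tiff(channels, path)
  meta <- list(kind = "reflectance_scene", bands = band_names(),
               cell_size = scene$cell_size, origin = scene$origin,
               has_truth = !is.null(scene$truth))
  write_sidecar(path, meta)
  if (!is.null(scene$truth)) {
    write_class_map_grid(scene$truth, truth_path(path))
  }
  invisible(path)
}

truth_path <- function(path) sub("(\\.[^.]+)?$", "_truth.tif", path)

#' @rdname write_scene
#' @param validate_range `"warn"` (default), `"error"`, or `"none"`:
#'   treatment of reflectance outside \[0, 1\] on read.
#' @export
read_scene <- function(path, validate_range = c("warn", "error", "none")) {
  validate_range <- match.arg(validate_range)
  meta <- read_sidecar(path)
  a <- read_grid_tiff(path)
  if (!identical(meta$kind, "reflectance_scene") || dim(a)[3] != 5) {
    stop_input("expected 4 bands plus validity channel; file has ",
               dim(a)[3] - 1, " bands", class = "lodgedetect_format_error")
  }
  bands <- stats::setNames(lapply(1:4, function(i) a[, , i]), band_names())
  nodata <- a[, , 5] < 0.5
  truth <- NULL
  if (isTRUE(meta$has_truth) && file.exists(truth_path(path))) {
    truth <- read_class_map_grid(truth_path(path))
  }
  reflectance_scene(bands, cell_size = meta$cell_size, nodata_mask = nodata,
                    truth = truth, origin = unlist(meta$origin),
                    validate_range = validate_range)
}

# integer class codes written as code/255 in an 8-bit TIFF: exact round trip
write_class_map_grid <- function(codes, path) {
  suppressWarnings(tiff::writeTIFF(codes / 255, path, bits.per.sample = 8L,
                                   compression = "none", reduce = FALSE))
  invisible(path)
}

read_class_map_grid <- function(path) {
  m <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write / read an index map
#'
#' Index values are stored linearly rescaled to \[0, 1\] (scale/offset in
#' the sidecar) alongside a validity channel; nodata is restored on read.
#'
#' @param index An `index_map`.
#' @param path Output TIFF path.
#' @return `path` invisibly; `read_index_map()` returns the `index_map`.
#' @export
write_index_map <- function(index, path) {
  v <- index$values
  lo <- if (identical(index$index_name, "NDVI")) -1 else 0
  hi <- if (identical(index$index_name, "NDVI")) 1 else 4
  scaled <- (v - lo) / (hi - lo)
  scaled[index$nodata_mask] <- 0
  write_grid_tiff(list(scaled, (!index$nodata_mask) * 1), path)
  write_sidecar(path, list(kind = "index_map", index_name = index$index_name,
                           cell_size = index$cell_size, origin = index$origin,
                           offset = lo, scale = hi - lo))
  invisible(path)
}

#' @rdname write_index_map
#' @export
read_index_map <- function(path) {
  meta <- read_sidecar(path)
  a <- read_grid_tiff(path)
  mask <- a[, , 2] < 0.5
  values <- a[, , 1] * meta$scale + meta$offset
  values[mask] <- NA_real_
  structure(
    list(values = values, nodata_mask = mask, index_name = meta$index_name,
         cell_size = meta$cell_size, origin = unlist(meta$origin)),
    class = "index_map"
  )
}

#' Write / read a lodging map
#'
#' Stored as an 8-bit single-band TIFF of state codes (0 non-maize/nodata,
#' 1 non-lodged maize, 2 lodged maize) with a JSON sidecar.
#'
#' @param map A `lodging_map`.
#' @param path Output TIFF path.
#' @return `path` invisibly; `read_lodging_map()` returns the `lodging_map`.
#' @export
write_lodging_map <- function(map, path) {
  write_class_map_grid(map$states, path)
  write_sidecar(path, list(kind = "lodging_map", cell_size = map$cell_size,
                           origin = map$origin, threshold = map$threshold))
  invisible(path)
}

#' @rdname write_lodging_map
#' @export
read_lodging_map <- function(path) {
  meta <- read_sidecar(path)
  structure(
    list(states = read_class_map_grid(path), cell_size = meta$cell_size,
         origin = unlist(meta$origin), threshold = meta$threshold),
    class = "lodging_map"
  )
}

#' Write / read labelled sample points
#'
#' CSV with columns `x`, `y`, `label` (`lodged` / `non-lodged`), `split`
#' (`train` / `validate`); or GeoJSON (FeatureCollection of Points with
#' `label` and `split` properties) when the path ends in `.geojson`/`.json`.
#'
#' @param points A `sample_points` tibble.
#' @param path Output path (`.csv`, `.geojson` or `.json`).
#' @return `path` invisibly; `read_points()` returns the tibble.
#' @export
write_points <- function(points, path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    features <- purrr::pmap(points[, c("x", "y", "label", "split")],
      function(x, y, label, split) {
        list(type = "Feature",
             geometry = list(type = "Point", coordinates = c(x, y)),
             properties = list(label = label, split = split))
      })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(points[, c("x", "y", "label", "split")], path)
  }
  invisible(path)
}

#' @rdname write_points
#' @param scene Optional [reflectance_scene()]; when given, points outside
#'   its extent raise a validation error naming the offending rows.
#' @export
read_points <- function(path, scene = NULL) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    pts <- purrr::map_dfr(gj$features, function(f) {
      tibble::tibble(x = f$geometry$coordinates[[1]],
                     y = f$geometry$coordinates[[2]],
                     label = f$properties$label,
                     split = f$properties$split %||% NA_character_)
    })
  } else {
    pts <- readr::read_csv(path, show_col_types = FALSE)
  }
  missing_cols <- setdiff(c("x", "y", "label"), names(pts))
  if (length(missing_cols) > 0) {
    stop_input("points file lacks column(s): ", paste(missing_cols, collapse = ", "),
               class = "lodgedetect_parse_error")
  }
  bad <- which(!pts$label %in% c("lodged", "non-lodged"))
  if (length(bad) > 0) {
    stop_input("row ", bad[1], ": unknown label '", pts$label[bad[1]],
               "' (allowed: lodged, non-lodged)", class = "lodgedetect_parse_error")
  }
  if ("split" %in% names(pts)) {
    bad <- which(!is.na(pts$split) & !pts$split %in% c("train", "validate"))
    if (length(bad) > 0) {
      stop_input("row ", bad[1], ": unknown split '", pts$split[bad[1]],
                 "' (allowed: train, validate)", class = "lodgedetect_parse_error")
    }
  }
  if (!is.null(scene)) {
    loc <- locate_pixels(scene, pts$x, pts$y)
    if (any(!loc$inside)) {
      stop_input("point ", which(!loc$inside)[1], " falls outside the scene extent",
                 class = "lodgedetect_validation_error")
    }
  }
  class(pts) <- c("sample_points", class(pts))
  pts
}

#' Write / read survey responses
#'
#' One-grade-per-row CSV with a `grade` column drawn from [survey_grades()].
#'
#' @param responses A `survey_responses` tibble.
#' @param path Output CSV path.
#' @return `path` invisibly; `read_survey()` returns the tibble.
#' @export
write_survey <- function(responses, path) {
  readr::write_csv(tibble::tibble(grade = as.character(responses$grade)), path)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!"grade" %in% names(tab)) {
    stop_input("survey file lacks a `grade` column", class = "lodgedetect_parse_error")
  }
  bad <- which(!tab$grade %in% survey_grades())
  if (length(bad) > 0) {
    stop_input("row ", bad[1], ": unknown grade '", tab$grade[bad[1]],
               "' (allowed: ", paste(survey_grades(), collapse = ", "), ")",
               class = "lodgedetect_parse_error")
  }
  out <- tibble::tibble(grade = factor(tab$grade, levels = survey_grades()))
  class(out) <- c("survey_responses", class(out))
  out
}

#' Read / write a pipeline configuration
#'
#' YAML (or JSON) holding scene parameters, detection settings, survey
#' settings and the seed. Configurations round-trip exactly.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_input("config file not found: ", path, class = "lodgedetect_parse_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' @rdname read_config
#' @param config Named list to write.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}

config_scene_params <- function(config) {
  sc <- config$scene %||% list()
  args <- list()
  if (!is.null(sc$class_band_means)) args$class_band_means <- lapply(sc$class_band_means, unlist)
  if (!is.null(sc$class_band_sds)) args$class_band_sds <- lapply(sc$class_band_sds, unlist)
  for (f in c("lodged_fraction", "maize_fraction", "patch_scale", "cell_size")) {
    if (!is.null(sc[[f]])) args[[f]] <- sc[[f]]
  }
  if (!is.null(sc$extent)) args$extent <- unlist(sc$extent)
  args$seed <- config$seed %||% 1L
  do.call(scene_params, args)
}

write_detection_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_index_map(result$ssi, file.path(out_dir, "ssi.tif"))
  write_lodging_map(result$map, file.path(out_dir, "lodging_map.tif"))
  readr::write_csv(result$areas, file.path(out_dir, "area_report.csv"))
  jsonlite::write_json(as.list(result$areas), file.path(out_dir, "area_report.json"),
                       auto_unbox = TRUE, digits = NA)
  tal <- tabulate(as.vector(result$map$states) + 1L, 3)
  writeLines(c(
    sprintf("threshold: %.6f", result$threshold),
    sprintf("pixels_lodged: %d", tal[3]),
    sprintf("pixels_nonlodged_maize: %d", tal[2]),
    sprintf("pixels_nonmaize_or_nodata: %d", tal[1]),
    sprintf("lodged_pct: %.2f", result$areas$lodged_pct)
  ), file.path(out_dir, "detection_log.txt"))
  invisible(out_dir)
}

#' Write a consolidated validation report
#'
#' Emits JSON (machine-readable), CSVs per check, and a plain-text summary.
#'
#' @param report A `validation_report` from [run_validation()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_validation_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- list()
  txt <- character()
  if (!is.null(report$error_matrix)) {
    em <- report$error_matrix
    js$error_matrix <- list(counts = em$counts, oa = em$oa,
                            pa = as.list(em$pa), ua = as.list(em$ua),
                            excluded = em$excluded)
    readr::write_csv(tidy(em), file.path(out_dir, "error_matrix.csv"))
    txt <- c(txt, sprintf("Overall accuracy: %.2f%%", em$oa))
  }
  if (!is.null(report$cross_comparison)) {
    cc <- report$cross_comparison
    js$cross_comparison <- list(s_coarse = cc$s_coarse, s_fine = cc$s_fine,
                                d_pct = cc$d_pct)
    readr::write_csv(cc, file.path(out_dir, "cross_comparison.csv"))
    txt <- c(txt, sprintf("Cross-comparison D: %.2f%%", cc$d_pct))
  }
  if (!is.null(report$survey)) {
    sv <- report$survey
    js$survey <- list(modal_grade = sv$modal_grade, mapped_grade = sv$mapped_grade,
                      agreement = sv$agreement)
    readr::write_csv(sv$counts, file.path(out_dir, "survey_counts.csv"))
    txt <- c(txt, sprintf("Survey: modal %s, mapped %s (%s)", sv$modal_grade,
                          sv$mapped_grade,
                          if (sv$agreement) "agreement" else "disagreement"))
  }
  jsonlite::write_json(js, file.path(out_dir, "validation_report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(txt, file.path(out_dir, "validation_summary.txt"))
  invisible(out_dir)
}
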