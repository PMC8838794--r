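new_index_map <- function(values, scene, index_name, extra_nodata = NULL) {
  mask <- scene$nodata_mask
  if (!is.null(extra_nodata)) mask <- mask | extra_nodata
  values[mask] <- NA_real_
  structure(
    list(values = values, nodata_mask = mask, index_name = index_name,
         cell_size = scene$cell_size, origin = scene$origin),
    class = "index_map"
  )
}

#' @export
print.index_map <- function(x, ...) {
  d <- dim(x$values)
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<index_map> %s, %d x %d px, range [%.4f, %.4f]\n",
              x$index_name, d[1], d[2], rng[1], rng[2]))
  invisible(x)
}

#' Spectral sum index (SSI)
#'
#' The SSI at a pixel is the plain sum of the four band reflectances,
#' `SSI = R1 + R2 + R3 + R4` (blue + green + red + NIR). Lodging flattens
#' the maize canopy and raises reflectance in every band, so the sum
#' amplifies the contrast instead of cancelling it the way a normalized
#' difference does. Valid values lie in \[0, 4\]; nodata propagates.
#'
#' @param scene A [reflectance_scene()].
#' @return An `index_map` named `"SSI"`.
#' @export
#' @examples
#' s <- generate_scene(scene_params(extent = c(32, 32), seed = 1))
#' ssi <- compute_ssi(s)
compute_ssi <- function(scene) {
  if (!inherits(scene, "reflectance_scene")) {
    stop_input("`scene` must be a reflectance_scene", class = "lodgedetect_format_error")
  }
  vals <- scene$bands$blue + scene$bands$green + scene$bands$red + scene$bands$nir
  new_index_map(vals, scene, "SSI")
}

#' Normalized difference vegetation index (NDVI)
#'
#' `NDVI = (NIR - red) / (NIR + red)`. Included as the contrast case: after
#' lodging both red and NIR reflectance rise, so the difference largely
#' cancels and NDVI moves far less than SSI. Pixels where `NIR + red = 0`
#' become nodata (undefined ratio).
#'
#' @param scene A [reflectance_scene()].
#' @return An `index_map` named `"NDVI"` with values in \[-1, 1\].
#' @export
compute_ndvi <- function(scene) {
  if (!inherits(scene, "reflectance_scene")) {
    stop_input("`scene` must be a reflectance_scene", class = "lodgedetect_format_error")
  }
  denom <- scene$bands$nir + scene$bands$red
  vals <- (scene$bands$nir - scene$bands$red) / denom
  new_index_map(vals, scene, "NDVI", extra_nodata = denom == 0)
}

#' Band-change arithmetic between class means
#'
#' For each band (and each index) compares the lodged and non-lodged class
#' means: increment = lodged - non-lodged (reflectance), amplification =
#' 100 * increment / non-lodged (%). This is the arithmetic behind the
#' published per-band change tables.
#'
#' @param nonlodged Named numeric vector of non-lodged means (names become
#'   the `band` column).
#' @param lodged Named numeric vector of lodged means, same names.
#' @return A tibble with columns `band`, `mean_nonlodged`, `mean_lodged`,
#'   `increment`, `amplification_pct` (unrounded; round at presentation).
#' @export
#' @examples
#' band_change(c(blue = 0.0188), c(blue = 0.0400))
band_change <- function(nonlodged, lodged) {
  stopifnot(length(nonlodged) == length(lodged))
  if (any(nonlodged == 0)) {
    stop_input("amplification undefined: a non-lodged mean is zero",
               class = "lodgedetect_statistics_error")
  }
  tibble::tibble(
    band = names(nonlodged) %||% paste0("b", seq_along(nonlodged)),
    mean_nonlodged = unname(nonlodged),
    mean_lodged = unname(lodged),
    increment = unname(lodged - nonlodged),
    amplification_pct = unname(100 * (lodged - nonlodged) / nonlodged)
  )
}

index_values_at <- function(map, points) {
  loc <- locate_pixels(map, points$x, points$y)
  if (any(!loc$inside)) {
    stop_input(sum(!loc$inside), " points fall outside the scene extent",
               class = "lodgedetect_validation_error")
  }
  map$values[cbind(loc$row, loc$col)]
}

# per-class pixel values of a scene band/index, from either the training
# split of a point set or the full truth grid
class_pixel_values <- function(grid, scene, points = NULL, split = "train") {
  if (!is.null(points)) {
    pts <- if (!is.null(split) && "split" %in% names(points)) {
      points[points$split == split, ]
    } else points
    loc <- locate_pixels(scene, pts$x, pts$y)
    v <- grid[cbind(loc$row, loc$col)]
    list(
      nonlodged = v[pts$label == "non-lodged"],
      lodged = v[pts$label == "lodged"]
    )
  } else {
    if (is.null(scene$truth)) {
      stop_input("need either sample points or a scene truth grid")
    }
    list(
      nonlodged = grid[scene$truth == 1L & !scene$nodata_mask],
      lodged = grid[scene$truth == 2L & !scene$nodata_mask]
    )
  }
}

#' Per-band and per-index spectral change report
#'
#' Computes lodged and non-lodged class means for each reflectance band and
#' for the SSI and NDVI maps, with increments and amplifications. Class
#' membership comes from the training split of a labelled point set, or
#' from the scene truth grid when no points are given. Index class means
#' are per-pixel means of the index (not the index of the band means).
#'
#' @param scene A [reflectance_scene()].
#' @param points Optional `sample_points` tibble; its `train` split is used.
#' @param split Which split of `points` to use (default `"train"`; `NULL`
#'   for all points).
#' @return A `band_change_report` tibble: rows blue, green, red, nir, SSI,
#'   NDVI with the [band_change()] columns.
#' @export
class_band_statistics <- function(scene, points = NULL, split = "train") {
  grids <- c(scene$bands,
             list(SSI = compute_ssi(scene)$values, NDVI = compute_ndvi(scene)$values))
  means <- purrr::map(grids, function(g) {
    cls <- class_pixel_values(g, scene, points, split)
    if (length(cls$nonlodged) == 0) {
      stop_input("no non-lodged pixels to average",
                 class = "lodgedetect_statistics_error")
    }
    if (length(cls$lodged) == 0) {
      stop_input("no lodged pixels to average",
                 class = "lodgedetect_statistics_error")
    }
    c(nonlodged = mean(cls$nonlodged, na.rm = TRUE),
      lodged = mean(cls$lodged, na.rm = TRUE))
  })
  out <- band_change(
    vapply(means, `[[`, numeric(1), "nonlodged"),
    vapply(means, `[[`, numeric(1), "lodged")
  )
  class(out) <- c("band_change_report", class(out))
  out
}

#' Five-number summary of an index per class
#'
#' Min, lower quartile, median, upper quartile and max of the index values
#' under each label of a point set — the numbers behind a class box plot,
#' used to inspect the threshold boundary between lodged and non-lodged
#' SSI distributions. Quantiles use linear interpolation
#' (`stats::quantile` type 7).
#'
#' @param index An `index_map`.
#' @param points A `sample_points` tibble (all splits used).
#' @return A tibble with columns `label`, `min`, `q1`, `median`, `q3`, `max`, `n`.
#' @export
index_distribution_summary <- function(index, points) {
  for (lab in c("lodged", "non-lodged")) {
    if (!any(points$label == lab)) {
      stop_input("no points carry label '", lab, "'",
                 class = "lodgedetect_statistics_error")
    }
  }
  vals <- index_values_at(index, points)
  dplyr::group_by(tibble::tibble(label = points$label, value = vals), .data$label) |>
    dplyr::summarise(
      min = min(.data$value), q1 = stats::quantile(.data$value, 0.25, names = FALSE),
      median = stats::median(.data$value),
      q3 = stats::quantile(.data$value, 0.75, names = FALSE),
      max = max(.data$value), n = dplyr::n(), .groups = "drop"
    )
}
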