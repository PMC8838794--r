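#' Detection configuration
#'
#' Exactly one of an explicit SSI threshold or a data-driven selection
#' method is active. The packaged default threshold is 0.62, the value that
#' separates the lodged and non-lodged SSI distributions of the study
#' areas; the selection methods recover a comparable cut from labelled
#' training values when no manual threshold is trusted.
#'
#' @param threshold Explicit SSI cut in \[0, 4\], or `NULL` to use `method`.
#' @param method `"boxplot_midpoint"` or `"variance_maximization"`; ignored
#'   when `threshold` is given.
#' @return A `detection_config` object.
#' @export
detection_config <- function(threshold = 0.62, method = NULL) {
  if (is.null(threshold) && is.null(method)) {
    stop_input("supply either a threshold or a selection method",
               class = "lodgedetect_parameter_error")
  }
  if (!is.null(threshold) && !is.null(method)) {
    stop_input("threshold and selection method are mutually exclusive",
               class = "lodgedetect_parameter_error")
  }
  if (!is.null(threshold)) {
    if (!is.finite(threshold) || threshold < 0 || threshold > 4) {
      stop_input("threshold must be finite and in [0, 4]",
                 class = "lodgedetect_parameter_error")
    }
  } else {
    method <- match.arg(method, c("boxplot_midpoint", "variance_maximization"))
  }
  structure(list(threshold = threshold, method = method),
            class = "detection_config")
}

#' Select an SSI discrimination threshold from labelled values
#'
#' Two data-driven alternatives to a manually read box-plot boundary:
#'
#' * `boxplot_midpoint` — the midpoint of `max(non-lodged)` and
#'   `min(lodged)` when the classes do not overlap, else the midpoint of
#'   the two class medians.
#' * `variance_maximization` — Otsu-style cut maximizing the between-class
#'   variance `w1 w2 (m1 - m2)^2` over the pooled values; candidate cuts
#'   are midpoints of consecutive sorted unique values, ties broken toward
#'   the lower cut.
#'
#' @param ssi_lodged,ssi_nonlodged Numeric vectors of SSI values under each
#'   label (e.g. from training ROIs).
#' @param method `"boxplot_midpoint"` or `"variance_maximization"`.
#' @return A single numeric threshold.
#' @export
#' @examples
#' select_threshold(c(0.72, 0.74), c(0.56, 0.58), "boxplot_midpoint")
select_threshold <- function(ssi_lodged, ssi_nonlodged,
                             method = c("boxplot_midpoint", "variance_maximization")) {
  method <- match.arg(method)
  if (length(ssi_lodged) == 0 || length(ssi_nonlodged) == 0) {
    stop_input("both class value lists must be non-empty")
  }
  pooled <- c(ssi_lodged, ssi_nonlodged)
  if (length(unique(pooled)) < 2) {
    stop_input("all pooled SSI values identical: no discriminating cut exists",
               class = "lodgedetect_degenerate_separation_error")
  }
  if (method == "boxplot_midpoint") {
    hi_non <- max(ssi_nonlodged); lo_lod <- min(ssi_lodged)
    if (hi_non < lo_lod) return((hi_non + lo_lod) / 2)
    return((stats::median(ssi_nonlodged) + stats::median(ssi_lodged)) / 2)
  }
  u <- sort(unique(pooled))
  cuts <- (u[-length(u)] + u[-1]) / 2
  bcv <- vapply(cuts, function(t) {
    left <- pooled[pooled <= t]; right <- pooled[pooled > t]
    w1 <- length(left) / length(pooled); w2 <- 1 - w1
    w1 * w2 * (mean(left) - mean(right))^2
  }, numeric(1))
  cuts[which.max(bcv)] # which.max takes the first (lowest) maximizer
}

#' Classify pixels into lodged / non-lodged maize
#'
#' A valid maize pixel with SSI strictly greater than the threshold is
#' lodged; a valid maize pixel at or below it is non-lodged; everything
#' else (background, outside the mask, nodata) is a single non-maize state.
#'
#' @param ssi An SSI `index_map`.
#' @param maize_mask Logical matrix, `TRUE` on maize pixels; must match the
#'   SSI grid shape and georeference.
#' @param config A [detection_config()] with a resolved threshold.
#' @return A `lodging_map`: integer states 0 = non-maize-or-nodata,
#'   1 = non-lodged maize, 2 = lodged maize.
#' @export
classify_lodging <- function(ssi, maize_mask, config = detection_config()) {
  if (!identical(dim(ssi$values), dim(maize_mask))) {
    stop_input("SSI map and maize mask shapes differ",
               class = "lodgedetect_alignment_error")
  }
  if (is.null(config$threshold)) {
    stop_input("threshold not resolved; select one from training values first",
               class = "lodgedetect_parameter_error")
  }
  valid <- !ssi$nodata_mask & maize_mask
  states <- matrix(0L, nrow(maize_mask), ncol(maize_mask))
  states[valid] <- 1L
  states[valid & !is.na(ssi$values) & ssi$values > config$threshold] <- 2L
  structure(
    list(states = states, cell_size = ssi$cell_size, origin = ssi$origin,
         threshold = config$threshold),
    class = "lodging_map"
  )
}

#' @export
print.lodging_map <- function(x, ...) {
  tal <- tabulate(as.vector(x$states) + 1L, 3)
  cat(sprintf(
    "<lodging_map> %d x %d px @ %g m; lodged %d, non-lodged %d, non-maize %d (threshold %g)\n",
    nrow(x$states), ncol(x$states), x$cell_size, tal[3], tal[2], tal[1],
    x$threshold %||% NA))
  invisible(x)
}

#' Area accounting of a lodging map
#'
#' Pixel counts times the cell area, in hectares and thousand hectares,
#' with the lodged proportion of the maize planting area in percent
#' (rounded half-up to 2 decimals, like the published area tables).
#'
#' @param map A `lodging_map`.
#' @param window Optional logical matrix restricting accounting to `TRUE`
#'   pixels (e.g. the footprint covered by a second sensor).
#' @return An `area_report` tibble: `lodged_px`, `maize_px`, `lodged_ha`,
#'   `maize_ha`, `lodged_kha`, `maize_kha`, `lodged_pct`.
#' @export
account_areas <- function(map, window = NULL) {
  states <- map$states
  if (!is.null(window)) {
    if (!identical(dim(window), dim(states))) {
      stop_input("window shape differs from the map",
                 class = "lodgedetect_alignment_error")
    }
    states <- states[window]
  }
  px_ha <- map$cell_size^2 / 1e4
  lodged_px <- sum(states == 2L)
  maize_px <- sum(states >= 1L)
  area_report(lodged_ha = lodged_px * px_ha, maize_ha = maize_px * px_ha,
              lodged_px = lodged_px, maize_px = maize_px)
}

#' Assemble an area report from areas in hectares
#'
#' @param lodged_ha,maize_ha Lodged and total maize areas in hectares.
#' @param lodged_px,maize_px Optional pixel tallies.
#' @return An `area_report` tibble (see [account_areas()]).
#' @export
#' @examples
#' area_report(112170, 205590)$lodged_pct # 54.56
area_report <- function(lodged_ha, maize_ha, lodged_px = NA_integer_,
                        maize_px = NA_integer_) {
  if (lodged_ha < 0 || maize_ha < 0 || lodged_ha > maize_ha) {
    stop_input("need 0 <= lodged area <= maize area")
  }
  out <- tibble::tibble(
    lodged_px = lodged_px, maize_px = maize_px,
    lodged_ha = lodged_ha, maize_ha = maize_ha,
    lodged_kha = lodged_ha / 1000, maize_kha = maize_ha / 1000,
    lodged_pct = if (maize_ha > 0) round_half_up(100 * lodged_ha / maize_ha, 2) else NA_real_
  )
  class(out) <- c("area_report", class(out))
  out
}

#' Run the detection pipeline on one scene
#'
#' Orchestrates SSI computation, threshold resolution, masked
#' classification, and area accounting. When the configuration names a
#' selection method, the threshold is fitted on the training split of the
#' supplied points; with an explicit threshold no points are needed. The
#' maize mask defaults to the scene's truth grid (truth > 0) when present.
#'
#' @param scene A [reflectance_scene()].
#' @param maize_mask Logical maize-extent matrix; default derived from
#'   `scene$truth`.
#' @param config A [detection_config()].
#' @param points Optional `sample_points` used for threshold selection.
#' @param out_dir Optional directory; when given, the SSI map, lodging map,
#'   area report (CSV + JSON) and a run log are written there.
#' @return A `lodging_result` list: `ssi`, `map`, `areas`, `threshold`,
#'   `config`.
#' @export
run_detection_pipeline <- function(scene, maize_mask = NULL,
                                   config = detection_config(), points = NULL,
                                   out_dir = NULL) {
  if (is.null(maize_mask)) {
    if (is.null(scene$truth)) {
      stop_input("no maize mask supplied and the scene carries no truth grid")
    }
    maize_mask <- scene$truth > 0L
  }
  ssi <- compute_ssi(scene)
  cfg <- config
  if (is.null(cfg$threshold)) {
    if (is.null(points)) {
      stop_input("threshold selection method '", cfg$method,
                 "' needs labelled sample points")
    }
    cls <- class_pixel_values(ssi$values, scene, points, split = "train")
    cfg$threshold <- select_threshold(cls$lodged, cls$nonlodged, cfg$method)
  }
  map <- classify_lodging(ssi, maize_mask, detection_config(threshold = cfg$threshold))
  areas <- account_areas(map)
  res <- structure(
    list(ssi = ssi, map = map, areas = areas, threshold = cfg$threshold,
         config = config),
    class = "lodging_result"
  )
  if (!is.null(out_dir)) write_detection_artifacts(res, out_dir)
  res
}

#' @export
print.lodging_result <- function(x, ...) {
  cat(sprintf("<lodging_result> threshold %.4f\n", x$threshold))
  print(x$map)
  cat(sprintf("  lodged %.2f kha of %.2f kha maize (%.2f%%)\n",
              x$areas$lodged_kha, x$areas$maize_kha, x$areas$lodged_pct))
  invisible(x)
}
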