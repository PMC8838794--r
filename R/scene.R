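#' Parameters for a synthetic reflectance scene
#'
#' Bundles everything the synthetic generator needs: per-class band means and
#' standard deviations (surface reflectance, unitless), the fraction of the
#' scene under maize, the fraction of maize that is lodged, the field-patch
#' edge length, the ground sampling distance, the grid extent, and a seed.
#'
#' Defaults reproduce the spectral contrast measured over Zhaodong City:
#' non-lodged maize band means (0.0188, 0.0496, 0.0327, 0.4703) and lodged
#' means (0.0400, 0.0829, 0.0639, 0.5389) for blue, green, red and
#' near-infrared, giving class SSI means of 0.5714 and 0.7256 on either side
#' of the 0.62 discrimination threshold. The default per-band class sd of
#' 0.01 puts the SSI class sd near 0.02, small enough that clipping
#' reflectance to [0, 1] leaves class means essentially unbiased.
#'
#' @param class_band_means Named list mapping class
#'   (`background`, `nonlodged_maize`, `lodged_maize`) to four band means in
#'   band order blue, green, red, NIR. Reflectance in \[0, 1\].
#' @param class_band_sds Same shape as `class_band_means`; per-band standard
#'   deviations (reflectance), all >= 0.
#' @param lodged_fraction Fraction of maize pixels that are lodged, in \[0, 1\].
#' @param maize_fraction Fraction of scene pixels that are maize, in \[0, 1\].
#' @param patch_scale Characteristic field-patch edge length in pixels
#'   (positive integer).
#' @param cell_size Ground sampling distance in metres.
#' @param extent Integer `c(rows, cols)` grid size in pixels.
#' @param seed Integer random seed; identical params (including seed) always
#'   produce bit-identical scenes.
#' @return A `scene_params` object (validated list).
#' @export
#' @examples
#' p <- scene_params(extent = c(64, 64), seed = 1)
#' s <- generate_scene(p)
scene_params <- function(class_band_means = list(
                           background      = c(0.1000, 0.1200, 0.1500, 0.2800),
                           nonlodged_maize = c(0.0188, 0.0496, 0.0327, 0.4703),
                           lodged_maize    = c(0.0400, 0.0829, 0.0639, 0.5389)
                         ),
                         class_band_sds = list(
                           background      = rep(0.01, 4),
                           nonlodged_maize = rep(0.01, 4),
                           lodged_maize    = rep(0.01, 4)
                         ),
                         lodged_fraction = 0.5456,
                         maize_fraction = 0.6,
                         patch_scale = 16L,
                         cell_size = 16,
                         extent = c(256L, 256L),
                         seed = 1L) {
  for (cls in class_names()) {
    mu <- class_band_means[[cls]]
    sd <- class_band_sds[[cls]]
    if (is.null(mu) || length(mu) != 4 || !all(is.finite(mu)) || any(mu < 0) || any(mu > 1)) {
      stop_input("band means for class '", cls, "' must be 4 finite reflectances in [0, 1]",
                 class = "lodgedetect_parameter_error")
    }
    if (is.null(sd) || length(sd) != 4 || !all(is.finite(sd)) || any(sd < 0)) {
      stop_input("band sds for class '", cls, "' must be 4 finite non-negative values",
                 class = "lodgedetect_parameter_error")
    }
  }
  check_fraction(lodged_fraction, "lodged_fraction")
  check_fraction(maize_fraction, "maize_fraction")
  if (!is.numeric(patch_scale) || length(patch_scale) != 1 || patch_scale < 1 ||
      patch_scale != as.integer(patch_scale)) {
    stop_input("`patch_scale` must be a positive integer",
               class = "lodgedetect_parameter_error")
  }
  if (!is.numeric(cell_size) || cell_size <= 0) {
    stop_input("`cell_size` must be positive", class = "lodgedetect_parameter_error")
  }
  if (length(extent) != 2 || any(extent < 1) || any(extent != as.integer(extent))) {
    stop_input("`extent` must be two positive integers (rows, cols)",
               class = "lodgedetect_parameter_error")
  }
  if (any(extent < patch_scale)) {
    stop_input("extent smaller than one patch (", patch_scale, " px)",
               class = "lodgedetect_config_error")
  }
  structure(
    list(
      class_band_means = class_band_means[class_names()],
      class_band_sds = class_band_sds[class_names()],
      lodged_fraction = lodged_fraction,
      maize_fraction = maize_fraction,
      patch_scale = as.integer(patch_scale),
      cell_size = cell_size,
      extent = as.integer(extent),
      seed = as.integer(seed)
    ),
    class = "scene_params"
  )
}

#' Construct a four-band reflectance scene
#'
#' Low-level constructor for the container every raster operation consumes:
#' four reflectance grids (blue, green, red, NIR), a nodata mask, the cell
#' size, an axis-aligned georeference (top-left origin, north up), and an
#' optional per-pixel truth grid coded 0 = background, 1 = non-lodged maize,
#' 2 = lodged maize.
#'
#' @param bands Named list of four numeric matrices (`blue`, `green`, `red`,
#'   `nir`), identical dimensions.
#' @param cell_size Ground sampling distance in metres.
#' @param nodata_mask Logical matrix, `TRUE` where pixels carry no data.
#' @param truth Optional integer matrix of class codes (0/1/2).
#' @param origin Numeric `c(x, y)` map coordinate of the grid's top-left
#'   corner.
#' @param validate_range `"warn"`, `"error"`, or `"none"`: how to treat
#'   reflectance outside \[0, 1\].
#' @return A `reflectance_scene` object.
#' @export
reflectance_scene <- function(bands, cell_size, nodata_mask = NULL, truth = NULL,
                              origin = c(0, nrow(bands[[1]]) * cell_size),
                              validate_range = c("warn", "error", "none")) {
  validate_range <- match.arg(validate_range)
  if (!is.list(bands) || !all(band_names() %in% names(bands))) {
    stop_input("`bands` must be a named list with blue, green, red, nir",
               class = "lodgedetect_format_error")
  }
  bands <- bands[band_names()]
  dims <- dim(bands[[1]])
  if (!all(vapply(bands, function(b) identical(dim(b), dims), logical(1)))) {
    stop_input("all four bands must share the same dimensions",
               class = "lodgedetect_format_error")
  }
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, dims[1], dims[2])
  if (!identical(dim(nodata_mask), dims)) {
    stop_input("nodata_mask dimensions must match the bands",
               class = "lodgedetect_format_error")
  }
  if (validate_range != "none") {
    vals <- unlist(lapply(bands, function(b) b[!nodata_mask]), use.names = FALSE)
    bad <- sum(vals < 0 | vals > 1, na.rm = TRUE)
    if (bad > 0) {
      msg <- sprintf("%d reflectance values fall outside [0, 1]", bad)
      if (validate_range == "error") {
        stop_input(msg, class = "lodgedetect_validation_error")
      }
      warning(msg, call. = FALSE)
    }
  }
  if (!is.null(truth) && !identical(dim(truth), dims)) {
    stop_input("truth grid dimensions must match the bands",
               class = "lodgedetect_format_error")
  }
  structure(
    list(bands = bands, cell_size = cell_size, nodata_mask = nodata_mask,
         truth = truth, origin = as.numeric(origin)),
    class = "reflectance_scene"
  )
}

scene_dim <- function(scene) dim(scene$bands[[1]])

# dimensions of any gridded object (scene, index map, lodging map)
grid_dim <- function(x) {
  if (!is.null(x$bands)) dim(x$bands[[1]])
  else if (!is.null(x$values)) dim(x$values)
  else dim(x$states)
}

#' @export
print.reflectance_scene <- function(x, ...) {
  d <- scene_dim(x)
  cat(sprintf("<reflectance_scene> %d x %d px, cell %g m, %d nodata px%s\n",
              d[1], d[2], x$cell_size, sum(x$nodata_mask),
              if (is.null(x$truth)) "" else ", with truth"))
  invisible(x)
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf(
    "<scene_params> %d x %d px @ %g m, maize %.3f, lodged %.4f, patch %d px, seed %d\n",
    x$extent[1], x$extent[2], x$cell_size, x$maize_fraction, x$lodged_fraction,
    x$patch_scale, x$seed))
  invisible(x)
}

# map coordinates of pixel centres; row 1 is the northern edge
pixel_centers <- function(scene, rows, cols) {
  list(
    x = scene$origin[1] + (cols - 0.5) * scene$cell_size,
    y = scene$origin[2] - (rows - 0.5) * scene$cell_size
  )
}

# containing pixel of map coordinates (pixel-is-area convention)
locate_pixels <- function(scene, x, y) {
  d <- grid_dim(scene)
  col <- floor((x - scene$origin[1]) / scene$cell_size) + 1L
  row <- floor((scene$origin[2] - y) / scene$cell_size) + 1L
  inside <- row >= 1 & row <= d[1] & col >= 1 & col <= d[2]
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Pixel table of a scene
#'
#' Long-format view used by the plotting helpers: one row per pixel with map
#' coordinates, the four band reflectances, validity, and truth class when
#' present.
#'
#' @param x A `reflectance_scene`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `blue`, `green`,
#'   `red`, `nir`, `valid`, and `truth` (if the scene carries one).
#' @importFrom tibble as_tibble
#' @method as_tibble reflectance_scene
#' @export
as_tibble.reflectance_scene <- function(x, ...) {
  d <- scene_dim(x)
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  cc <- pixel_centers(x, idx$row, idx$col)
  out <- tibble::tibble(
    row = idx$row, col = idx$col, x = cc$x, y = cc$y,
    blue = as.vector(x$bands$blue), green = as.vector(x$bands$green),
    red = as.vector(x$bands$red), nir = as.vector(x$bands$nir),
    valid = !as.vector(x$nodata_mask)
  )
  if (!is.null(x$truth)) {
    out$truth <- factor(class_names()[as.vector(x$truth) + 1L], levels = class_names())
  }
  out
}
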