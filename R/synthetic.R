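#' Survey lodging-proportion grades
#'
#' The five quintile grades a respondent can report for the lodged share of
#' the family maize plot. Bins are half-open upward: \[0, 20\], (20, 40\],
#' (40, 60\], (60, 80\], (80, 100\].
#'
#' @return Character vector of the five grade labels, lowest first.
#' @export
survey_grades <- function() c("0-20%", "21-40%", "41-60%", "61-80%", "81-100%")

#' Grade containing a lodging proportion
#'
#' @param proportion_pct Lodging proportion in percent, in \[0, 100\].
#' @return Factor with levels [survey_grades()].
#' @export
#' @examples
#' proportion_grade(54.56)
proportion_grade <- function(proportion_pct) {
  if (any(!is.finite(proportion_pct) | proportion_pct < 0 | proportion_pct > 100)) {
    stop_input("lodging proportion must lie in [0, 100] percent")
  }
  idx <- pmin(pmax(ceiling(proportion_pct / 20), 1L), 5L)
  factor(survey_grades()[idx], levels = survey_grades())
}

# patch-level class layout: rectangular fields of edge patch_scale, classes
# drawn without replacement so scene-level fractions hit their targets to
# patch-count granularity
assign_patch_classes <- function(prow, pcol, maize_fraction, lodged_fraction) {
  np <- prow * pcol
  n_maize <- round(maize_fraction * np)
  n_lodged <- round(lodged_fraction * n_maize)
  cls <- integer(np) # 0 background
  maize_ids <- sample.int(np, n_maize)
  cls[maize_ids] <- 1L
  cls[sample(maize_ids, n_lodged)] <- 2L
  matrix(cls, prow, pcol)
}

expand_patches <- function(patch, rows, cols, patch_scale) {
  patch[cbind(
    rep(pmin((seq_len(rows) - 1L) %/% patch_scale + 1L, nrow(patch)), times = cols),
    rep(pmin((seq_len(cols) - 1L) %/% patch_scale + 1L, ncol(patch)), each = rows)
  )] |> matrix(rows, cols)
}

fill_bands <- function(truth, class_band_means, class_band_sds) {
  rows <- nrow(truth); cols <- ncol(truth)
  cls_idx <- as.vector(truth) + 1L # 1 background, 2 nonlodged, 3 lodged
  mu <- do.call(rbind, class_band_means[class_names()])
  sd <- do.call(rbind, class_band_sds[class_names()])
  bands <- lapply(seq_len(4), function(b) {
    v <- stats::rnorm(rows * cols, mean = mu[cls_idx, b], sd = sd[cls_idx, b])
    matrix(pmin(pmax(v, 0), 1), rows, cols)
  })
  names(bands) <- band_names()
  bands
}

#' Generate a synthetic four-band reflectance scene
#'
#' Emulates the spectral structure of a post-storm maize landscape: three
#' classes (background, non-lodged maize, lodged maize) laid out as
#' contiguous rectangular field patches, each pixel drawing independent
#' per-band Gaussian reflectance around its class mean, clipped to \[0, 1\].
#' The truth grid is retained on the scene so downstream accuracy can be
#' scored exactly. Deterministic under `params$seed`.
#'
#' @param params A [scene_params()] object.
#' @return A [reflectance_scene()] carrying a truth grid.
#' @export
#' @examples
#' s <- generate_scene(scene_params(extent = c(64, 64), seed = 7))
#' table(s$truth)
generate_scene <- function(params) {
  if (!inherits(params, "scene_params")) params <- do.call(scene_params, params)
  rows <- params$extent[1]; cols <- params$extent[2]
  withr::with_seed(params$seed, {
    prow <- ceiling(rows / params$patch_scale)
    pcol <- ceiling(cols / params$patch_scale)
    patch <- assign_patch_classes(prow, pcol, params$maize_fraction, params$lodged_fraction)
    truth <- expand_patches(patch, rows, cols, params$patch_scale)
    bands <- fill_bands(truth, params$class_band_means, params$class_band_sds)
  })
  reflectance_scene(bands, cell_size = params$cell_size, truth = truth,
                    validate_range = "none")
}

#' Generate a co-registered coarse/fine scene pair
#'
#' Emulates a wide-swath coarse sensor and a narrow-swath fine sensor
#' observing the same landscape. One truth field is laid out on the coarse
#' grid, replicated to the fine grid (integer block ratio), and the fine
#' bands get independent pixel noise; the coarse bands are exact block means
#' of the fine bands, so cross-resolution area comparison is testable to
#' floating-point tolerance. The fine scene's nodata mask hides all but a
#' single contiguous band of rows covering about `coverage_fraction` of the
#' extent, mimicking partial swath coverage.
#'
#' @param params [scene_params()] describing the coarse grid; `params$seed`
#'   drives all randomness.
#' @param block_ratio Integer coarse/fine cell-size ratio (default 4, e.g.
#'   16 m to 4 m).
#' @param coverage_fraction Fraction of the extent covered by the fine
#'   scene, in (0, 1\].
#' @return List with elements `coarse` and `fine`, both
#'   [reflectance_scene()] objects sharing one truth field.
#' @export
generate_paired_scenes <- function(params, block_ratio = 4L, coverage_fraction = 1) {
  if (!inherits(params, "scene_params")) params <- do.call(scene_params, params)
  if (!is.numeric(block_ratio) || length(block_ratio) != 1 ||
      block_ratio < 1 || block_ratio != as.integer(block_ratio)) {
    stop_input("`block_ratio` must be a positive integer",
               class = "lodgedetect_parameter_error")
  }
  check_fraction(coverage_fraction, "coverage_fraction", closed_lo = FALSE)
  block_ratio <- as.integer(block_ratio)
  rows <- params$extent[1]; cols <- params$extent[2]
  frows <- rows * block_ratio; fcols <- cols * block_ratio
  fine_cell <- params$cell_size / block_ratio

  withr::with_seed(params$seed, {
    prow <- ceiling(rows / params$patch_scale)
    pcol <- ceiling(cols / params$patch_scale)
    patch <- assign_patch_classes(prow, pcol, params$maize_fraction, params$lodged_fraction)
    truth_coarse <- expand_patches(patch, rows, cols, params$patch_scale)
    truth_fine <- truth_coarse[rep(seq_len(rows), each = block_ratio),
                               rep(seq_len(cols), each = block_ratio)]
    fine_bands <- fill_bands(truth_fine, params$class_band_means, params$class_band_sds)
  })
  coarse_bands <- lapply(fine_bands, block_mean, ratio = block_ratio)

  # contiguous coverage window: the first k coarse rows, aligned to blocks so
  # both grids agree on what is covered
  k <- max(1L, min(rows, round(coverage_fraction * rows)))
  fine_mask <- matrix(TRUE, frows, fcols)
  fine_mask[seq_len(k * block_ratio), ] <- FALSE

  list(
    coarse = reflectance_scene(coarse_bands, cell_size = params$cell_size,
                               truth = truth_coarse, validate_range = "none"),
    fine = reflectance_scene(fine_bands, cell_size = fine_cell,
                             nodata_mask = fine_mask, truth = truth_fine,
                             origin = c(0, rows * params$cell_size),
                             validate_range = "none")
  )
}

block_mean <- function(m, ratio) {
  rows <- nrow(m) %/% ratio; cols <- ncol(m) %/% ratio
  a <- array(m[seq_len(rows * ratio), seq_len(cols * ratio)],
             dim = c(ratio, rows, ratio, cols))
  colMeans(colMeans(aperm(a, c(1, 3, 2, 4)), dims = 1), dims = 1) |>
    matrix(rows, cols)
}

#' Sample labelled ground points on a scene
#'
#' Draws `n` point locations without replacement from maize-truth pixels,
#' balanced over the lodged and non-lodged labels, and tags each point
#' train/validate. Mirrors a field campaign that places GPS points in
#' clearly lodged and clearly upright fields and reserves roughly 30% for
#' validation.
#'
#' @param scene A [reflectance_scene()] with a truth grid.
#' @param n Number of points.
#' @param train_fraction Fraction tagged `train` (largest-remainder rounding
#'   per label, so realised proportions match within one point).
#' @param seed Integer seed.
#' @param n_train Optional explicit train count overriding `train_fraction`.
#' @return A tibble (`sample_points`) with columns `x`, `y`, `label`
#'   (`lodged` / `non-lodged`), `split` (`train` / `validate`).
#' @export
generate_sample_points <- function(scene, n, train_fraction = 0.7, seed = 1L,
                                   n_train = NULL) {
  if (is.null(scene$truth)) {
    stop_input("scene has no truth grid to sample from")
  }
  check_fraction(train_fraction, "train_fraction")
  support <- list(
    lodged = which(scene$truth == 2L & !scene$nodata_mask),
    `non-lodged` = which(scene$truth == 1L & !scene$nodata_mask)
  )
  n_lodged <- round(n / 2)
  want <- c(lodged = n_lodged, `non-lodged` = n - n_lodged)
  avail <- vapply(support, length, integer(1))
  if (sum(avail) < n || any(avail == 0 & want > 0)) {
    stop_input(sprintf(
      "cannot place %d points: %d lodged and %d non-lodged maize pixels available",
      n, avail[["lodged"]], avail[["non-lodged"]]),
      class = "lodgedetect_sampling_error")
  }
  # rebalance if one label is short
  for (lab in names(want)) {
    short <- want[lab] - avail[lab]
    if (short > 0) {
      other <- setdiff(names(want), lab)
      want[lab] <- avail[lab]
      want[other] <- want[other] + short
    }
  }
  n_train <- as.integer(n_train %||% round(train_fraction * n))
  if (n_train < 0 || n_train > n) stop_input("`n_train` must lie in [0, n]")

  withr::with_seed(as.integer(seed), {
    pts <- purrr::map2_dfr(names(want), want, function(lab, k) {
      cells <- sample(support[[lab]], k)
      d <- scene_dim(scene)
      row <- ((cells - 1L) %% d[1]) + 1L
      col <- ((cells - 1L) %/% d[1]) + 1L
      cc <- pixel_centers(scene, row, col)
      tibble::tibble(x = cc$x, y = cc$y, label = lab)
    })
    # largest-remainder train allocation per label keeps both the total and
    # the per-label split within one point of the target
    quota <- want / n * n_train
    base <- floor(quota)
    extra <- order(quota - base, decreasing = TRUE)[seq_len(n_train - sum(base))]
    n_train_lab <- base
    n_train_lab[extra] <- n_train_lab[extra] + 1
    pts <- dplyr::group_by(pts, .data$label) |>
      dplyr::mutate(split = ifelse(
        seq_len(dplyr::n()) <= n_train_lab[[unique(.data$label)]],
        "train", "validate")) |>
      dplyr::ungroup()
    pts <- pts[sample.int(nrow(pts)), ]
  })
  class(pts) <- c("sample_points", class(pts))
  pts
}

#' Simulate farmer survey responses
#'
#' Each respondent reports the lodging-proportion grade containing the true
#' proportion with probability `1 - misreport_prob`, otherwise an adjacent
#' grade (uniformly over the one or two neighbours).
#'
#' @param true_proportion True lodged share of the planted area, in \[0, 1\].
#' @param n_respondents Number of questionnaires.
#' @param misreport_prob Probability a respondent picks an adjacent grade.
#' @param seed Integer seed.
#' @return A tibble (`survey_responses`) with one `grade` factor column.
#' @export
#' @examples
#' generate_survey(0.5456, n_respondents = 18, misreport_prob = 0, seed = 1)
generate_survey <- function(true_proportion, n_respondents, misreport_prob = 0.1,
                            seed = 1L) {
  check_fraction(true_proportion, "true_proportion")
  check_fraction(misreport_prob, "misreport_prob")
  if (n_respondents < 1) stop_input("`n_respondents` must be at least 1")
  true_idx <- as.integer(proportion_grade(100 * true_proportion))
  withr::with_seed(as.integer(seed), {
    idx <- vapply(seq_len(n_respondents), function(i) {
      if (stats::runif(1) >= misreport_prob) return(true_idx)
      nb <- intersect(c(true_idx - 1L, true_idx + 1L), 1:5)
      nb[sample.int(length(nb), 1)]
    }, integer(1))
  })
  out <- tibble::tibble(grade = factor(survey_grades()[idx], levels = survey_grades()))
  class(out) <- c("survey_responses", class(out))
  out
}
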