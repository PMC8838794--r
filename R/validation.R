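#' Error matrix with producer's, user's and overall accuracy
#'
#' Two-by-two cross-tabulation of reference labels (rows) against mapped
#' classes (columns) over \{lodged, non-lodged\}. Producer's accuracy is the
#' diagonal share of each reference row (omission complement), user's
#' accuracy the diagonal share of each mapped column (commission
#' complement), overall accuracy the diagonal share of the total.
#' Percentages are rounded half-up to 2 decimals; the unrounded values are
#' kept in the `accuracy_raw` field.
#'
#' @param counts 2x2 integer matrix, rows = reference (lodged, non-lodged),
#'   columns = mapped (lodged, non-lodged).
#' @param excluded Number of validation points discarded because they fell
#'   on non-maize or nodata pixels (reported, not tabulated).
#' @return An `error_matrix` object with fields `counts`, `oa`, `pa`, `ua`
#'   (rounded, `pa`/`ua` named by class), `accuracy_raw`, `excluded`.
#' @export
#' @examples
#' error_matrix(matrix(c(20, 2, 1, 19), 2))$oa # 92.86
error_matrix <- function(counts, excluded = 0L) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L)) || any(counts < 0) ||
      any(counts != as.integer(counts))) {
    stop_input("`counts` must be a 2x2 matrix of non-negative integers")
  }
  if (sum(counts) == 0) stop_input("error matrix is empty")
  dimnames(counts) <- list(reference = c("lodged", "non-lodged"),
                           mapped = c("lodged", "non-lodged"))
  dg <- diag(counts)
  raw <- list(
    oa = 100 * sum(dg) / sum(counts),
    pa = 100 * dg / rowSums(counts),
    ua = 100 * dg / colSums(counts)
  )
  structure(
    list(counts = counts,
         oa = round_half_up(raw$oa, 2),
         pa = round_half_up(raw$pa, 2),
         ua = round_half_up(raw$ua, 2),
         accuracy_raw = raw,
         excluded = as.integer(excluded)),
    class = "error_matrix"
  )
}

#' @export
print.error_matrix <- function(x, ...) {
  cat("<error_matrix> reference rows x mapped columns\n")
  print(x$counts)
  cat(sprintf("  OA %.2f%%; PA lodged %.2f%%, non-lodged %.2f%%; UA lodged %.2f%%, non-lodged %.2f%%\n",
              x$oa, x$pa[1], x$pa[2], x$ua[1], x$ua[2]))
  if (x$excluded > 0) cat(sprintf("  (%d points off the maize map, excluded)\n", x$excluded))
  invisible(x)
}

#' Build an error matrix from validation points and a lodging map
#'
#' Looks each validate-split point up in the map, tabulates its field label
#' against the mapped state, and computes the accuracies. Points landing on
#' non-maize or nodata pixels are excluded from the matrix and counted in
#' the `excluded` field.
#'
#' @param points A `sample_points` tibble; only the `validate` split is used
#'   (all points if there is no `split` column).
#' @param map A `lodging_map`.
#' @return An [error_matrix()].
#' @export
build_error_matrix <- function(points, map) {
  pts <- if ("split" %in% names(points)) points[points$split == "validate", ] else points
  if (nrow(pts) == 0) stop_input("no validation points supplied")
  loc <- locate_pixels(map, pts$x, pts$y)
  if (any(!loc$inside)) {
    stop_input(sum(!loc$inside), " validation points fall outside the map extent",
               class = "lodgedetect_validation_error")
  }
  state <- map$states[cbind(loc$row, loc$col)]
  off_map <- state == 0L
  pts <- pts[!off_map, ]; state <- state[!off_map]
  mapped <- factor(ifelse(state == 2L, "lodged", "non-lodged"),
                   levels = c("lodged", "non-lodged"))
  reference <- factor(pts$label, levels = c("lodged", "non-lodged"))
  error_matrix(unclass(table(reference, mapped)), excluded = sum(off_map))
}

#' Cross-resolution area comparison
#'
#' Signed percent difference between the lodged area mapped from the coarse
#' sensor and from the fine sensor over the same footprint:
#' `D = (S_coarse - S_fine) / S_fine * 100`.
#'
#' @param s_coarse,s_fine Lodged areas from the coarse and fine scenes, in
#'   the same unit (e.g. thousand ha), over the same spatial window.
#' @return A `cross_comparison` tibble: `s_coarse`, `s_fine`, `d_pct`
#'   (rounded half-up to 2 decimals) and `d_raw`.
#' @export
#' @examples
#' cross_compare(89.87, 88.97)$d_pct # 1.01
cross_compare <- function(s_coarse, s_fine) {
  if (!is.finite(s_fine) || s_fine <= 0) {
    stop_input("fine-scene lodged area must be positive")
  }
  d <- (s_coarse - s_fine) / s_fine * 100
  out <- tibble::tibble(s_coarse = s_coarse, s_fine = s_fine,
                        d_pct = round_half_up(d, 2), d_raw = d)
  class(out) <- c("cross_comparison", class(out))
  out
}

#' Cross-compare lodged areas of a coarse/fine map pair
#'
#' Restricts both maps to the footprint actually covered by the fine scene
#' (coarse pixels whose whole block of fine pixels is valid), accounts the
#' lodged areas there, and applies [cross_compare()].
#'
#' @param coarse_map,fine_map `lodging_map`s from [generate_paired_scenes()]
#'   output (fine grid an integer multiple of the coarse grid).
#' @param fine_valid Logical matrix of valid fine pixels (e.g.
#'   `!fine_scene$nodata_mask`).
#' @return A `cross_comparison` tibble with the window areas attached as
#'   columns `s_coarse_kha`-style fields of the underlying reports in
#'   attributes `coarse_report` / `fine_report`.
#' @export
cross_compare_maps <- function(coarse_map, fine_map, fine_valid) {
  ratio <- nrow(fine_map$states) / nrow(coarse_map$states)
  if (ratio != as.integer(ratio) ||
      ncol(fine_map$states) != ncol(coarse_map$states) * ratio) {
    stop_input("fine map grid is not an integer refinement of the coarse grid",
               class = "lodgedetect_alignment_error")
  }
  coarse_window <- block_mean(fine_valid * 1, as.integer(ratio)) == 1
  fine_report <- account_areas(fine_map, window = fine_valid)
  coarse_report <- account_areas(coarse_map, window = coarse_window)
  out <- cross_compare(coarse_report$lodged_kha, fine_report$lodged_kha)
  attr(out, "coarse_report") <- coarse_report
  attr(out, "fine_report") <- fine_report
  out
}

#' Summarize survey responses against a mapped lodging proportion
#'
#' Tallies questionnaires per lodging-proportion grade, finds the modal
#' grade (ties broken toward the higher grade), bins the satellite-mapped
#' proportion into its grade, and flags agreement between the two — the
#' survey-consistency check of the validation protocol.
#'
#' @param responses A `survey_responses` tibble (column `grade`).
#' @param mapped_proportion_pct Mapped lodged share of the maize area, in
#'   percent.
#' @return A `survey_summary` list: `counts` tibble, `modal_grade`,
#'   `mapped_grade`, `agreement`, `tie` (logical, whether the mode was tied).
#' @export
#' @examples
#' resp <- generate_survey(0.5456, 18, misreport_prob = 0, seed = 1)
#' summarize_survey(resp, 54.56)$agreement
summarize_survey <- function(responses, mapped_proportion_pct) {
  if (nrow(responses) == 0) stop_input("no survey responses supplied")
  if (!is.finite(mapped_proportion_pct) || mapped_proportion_pct < 0 ||
      mapped_proportion_pct > 100) {
    stop_input("mapped proportion must lie in [0, 100] percent")
  }
  grade <- factor(responses$grade, levels = survey_grades())
  if (anyNA(grade)) {
    stop_input("unknown grade label; allowed: ", paste(survey_grades(), collapse = ", "),
               class = "lodgedetect_parse_error")
  }
  counts <- as.integer(table(grade))
  top <- which(counts == max(counts))
  modal <- survey_grades()[max(top)] # ties toward the higher grade
  mapped <- as.character(proportion_grade(mapped_proportion_pct))
  structure(
    list(
      counts = tibble::tibble(grade = factor(survey_grades(), levels = survey_grades()),
                              n = counts),
      modal_grade = modal,
      mapped_grade = mapped,
      agreement = identical(modal, mapped),
      tie = length(top) > 1
    ),
    class = "survey_summary"
  )
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("<survey_summary> modal grade %s%s, mapped grade %s -> %s\n",
              x$modal_grade, if (x$tie) " (tie, higher grade kept)" else "",
              x$mapped_grade, if (x$agreement) "agreement" else "disagreement"))
  invisible(x)
}

#' Run the three-way validation of a lodging result
#'
#' Consolidates (1) the error matrix from labelled validation points,
#' (2) the cross-resolution area comparison against a paired fine-scene
#' result over the fine scene's coverage window, and (3) survey-grade
#' consistency, into one report. Each check runs only when its inputs are
#' supplied, unless named in `require` — then a missing input is an error
#' pointing at the stage to rerun.
#'
#' @param result A `lodging_result` from [run_detection_pipeline()].
#' @param points Optional `sample_points` (validate split used).
#' @param fine_result Optional `lodging_result` on the paired fine scene.
#' @param fine_valid Logical matrix of valid fine pixels; required with
#'   `fine_result`.
#' @param survey Optional `survey_responses`.
#' @param require Character subset of `c("points", "cross", "survey")` that
#'   must run.
#' @return A `validation_report` list with elements `error_matrix`,
#'   `cross_comparison`, `survey`, any of which may be `NULL`.
#' @export
run_validation <- function(result, points = NULL, fine_result = NULL,
                           fine_valid = NULL, survey = NULL, require = character()) {
  if ("points" %in% require && is.null(points)) {
    stop_input("error-matrix validation requires sample points: rerun the sampling stage",
               class = "lodgedetect_stage_error")
  }
  if ("cross" %in% require && (is.null(fine_result) || is.null(fine_valid))) {
    stop_input("cross-comparison requires paired fine scene: rerun detection on the fine scene",
               class = "lodgedetect_stage_error")
  }
  if ("survey" %in% require && is.null(survey)) {
    stop_input("survey validation requires survey responses: rerun the survey stage",
               class = "lodgedetect_stage_error")
  }
  em <- if (!is.null(points)) build_error_matrix(points, result$map)
  cc <- if (!is.null(fine_result)) {
    if (is.null(fine_valid)) {
      stop_input("cross-comparison requires the fine scene's validity mask",
                 class = "lodgedetect_stage_error")
    }
    cross_compare_maps(result$map, fine_result$map, fine_valid)
  }
  sv <- if (!is.null(survey)) summarize_survey(survey, result$areas$lodged_pct)
  structure(list(error_matrix = em, cross_comparison = cc, survey = sv),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  if (!is.null(x$error_matrix)) print(x$error_matrix)
  if (!is.null(x$cross_comparison)) {
    cat(sprintf("  cross-comparison: coarse %.2f vs fine %.2f kha, D = %.2f%%\n",
                x$cross_comparison$s_coarse, x$cross_comparison$s_fine,
                x$cross_comparison$d_pct))
  }
  if (!is.null(x$survey)) print(x$survey)
  invisible(x)
}
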