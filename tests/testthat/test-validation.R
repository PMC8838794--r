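test_that("error matrix accuracies follow the standard definitions", {
  em <- error_matrix(matrix(c(20, 2, 1, 19), 2))
  expect_equal(em$oa, 92.86)
  expect_equal(unname(em$pa), c(95.24, 90.48))
  expect_equal(unname(em$ua), c(90.91, 95.00))
  em2 <- error_matrix(matrix(c(18, 2, 2, 12), 2))
  expect_equal(em2$oa, 88.24)
  expect_equal(unname(em2$pa), c(90.00, 85.71))
  expect_equal(unname(em2$ua), c(90.00, 85.71))
  perfect <- error_matrix(matrix(c(7, 0, 0, 9), 2))
  expect_equal(perfect$oa, 100)
  expect_true(all(c(perfect$pa, perfect$ua) == 100))
  expect_error(error_matrix(matrix(c(-1, 0, 0, 1), 2)))
  expect_error(error_matrix(matrix(0L, 2, 2)))
})

test_that("overall accuracy is the reference-weighted mean of producer accuracies", {
  set.seed(5)
  for (i in 1:20) {
    counts <- matrix(rpois(4, 15), 2)
    if (sum(counts) == 0) next
    em <- error_matrix(counts)
    raw <- em$accuracy_raw
    weights <- rowSums(counts) / sum(counts)
    expect_equal(raw$oa, sum(weights * raw$pa), tolerance = 1e-9)
  }
})

test_that("error matrices tabulate validation points against the map", {
  s <- generate_scene(zhaodong_params(extent = c(64, 64), sds = 0, seed = 27))
  pts <- generate_sample_points(s, 140, seed = 4)
  res <- run_detection_pipeline(s)
  em <- build_error_matrix(pts, res$map)
  expect_equal(sum(em$counts), 42) # validate split only
  expect_equal(em$oa, 100)
  expect_equal(em$excluded, 0)
  # a point dropped onto background is excluded and reported
  bg <- which(s$truth == 0L, arr.ind = TRUE)[1, ]
  cc <- lodgedetect:::pixel_centers(s, bg["row"], bg["col"])
  pts_bad <- dplyr::bind_rows(pts, tibble::tibble(
    x = cc$x, y = cc$y, label = "lodged", split = "validate"))
  em_bad <- build_error_matrix(pts_bad, res$map)
  expect_equal(em_bad$excluded, 1)
  expect_equal(sum(em_bad$counts), 42)
})

test_that("cross-comparison follows the signed percent-difference formula", {
  expect_equal(cross_compare(89.87, 88.97)$d_pct, 1.01)
  expect_equal(cross_compare(8.97, 8.87)$d_pct, 1.13)
  expect_equal(cross_compare(5, 5)$d_pct, 0)
  expect_error(cross_compare(1, 0))
  # swapping the roles rescales per the formula, not by a naive sign flip
  a <- 89.87; b <- 88.97
  d1 <- cross_compare(a, b)$d_raw
  d2 <- cross_compare(b, a)$d_raw
  expect_equal(d2, -d1 * b / a, tolerance = 1e-12)
})

test_that("paired maps cross-compare over the covered window only", {
  p <- zhaodong_params(extent = c(40, 40), sds = 0, seed = 31)
  pair <- generate_paired_scenes(p, block_ratio = 4, coverage_fraction = 0.5)
  res_c <- run_detection_pipeline(pair$coarse)
  res_f <- run_detection_pipeline(pair$fine, maize_mask = pair$fine$truth > 0L)
  cc <- cross_compare_maps(res_c$map, res_f$map, !pair$fine$nodata_mask)
  expect_equal(cc$d_pct, 0) # same truth, zero noise: identical areas
  cov_rows <- sum(apply(!pair$fine$nodata_mask, 1, any)) / 4
  expect_equal(attr(cc, "coarse_report")$maize_px + 0,
               sum(pair$coarse$truth[seq_len(cov_rows), ] >= 1L))
})

test_that("survey summaries recover the modal grade and agreement", {
  zd <- tibble::tibble(grade = factor(rep(survey_grades(), c(2, 0, 7, 4, 5)),
                                      levels = survey_grades()))
  sv <- summarize_survey(zd, 54.56)
  expect_equal(sv$modal_grade, "41-60%")
  expect_equal(sv$mapped_grade, "41-60%")
  expect_true(sv$agreement)
  nj <- tibble::tibble(grade = factor(rep(survey_grades(), c(0, 1, 5, 2, 9)),
                                      levels = survey_grades()))
  sv2 <- summarize_survey(nj, 81.79)
  expect_equal(sv2$modal_grade, "81-100%")
  expect_true(sv2$agreement)
  expect_equal(summarize_survey(zd, 0)$mapped_grade, "0-20%")
  # ties break toward the higher grade and are flagged
  tie <- tibble::tibble(grade = factor(rep(survey_grades()[c(3, 5)], c(4, 4)),
                                       levels = survey_grades()))
  sv3 <- summarize_survey(tie, 90)
  expect_true(sv3$tie)
  expect_equal(sv3$modal_grade, "81-100%")
  expect_error(summarize_survey(zd, 120))
})

test_that("the modal grade survives moderate misreporting", {
  hits <- vapply(1:200, function(i) {
    resp <- generate_survey(0.5456, n_respondents = 17, misreport_prob = 0.3,
                            seed = 1000 + i)
    summarize_survey(resp, 54.56)$modal_grade == "41-60%"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("run_validation consolidates the three checks and guards stages", {
  p <- zhaodong_params(extent = c(40, 40), sds = 0, seed = 35)
  pair <- generate_paired_scenes(p, block_ratio = 4, coverage_fraction = 1)
  pts <- generate_sample_points(pair$coarse, 80, seed = 2)
  res <- run_detection_pipeline(pair$coarse)
  res_f <- run_detection_pipeline(pair$fine, maize_mask = pair$fine$truth > 0L)
  survey <- generate_survey(truth_lodged_fraction(pair$coarse), 18,
                            misreport_prob = 0, seed = 3)
  report <- run_validation(res, points = pts, fine_result = res_f,
                           fine_valid = !pair$fine$nodata_mask, survey = survey)
  expect_equal(report$error_matrix$oa, 100)
  expect_equal(report$cross_comparison$d_pct, 0)
  expect_true(report$survey$agreement)
  td <- tidy(report)
  expect_setequal(unique(td$check), c("error_matrix", "cross_comparison", "survey"))
  err <- expect_error(
    run_validation(res, points = pts, require = "cross"),
    class = "lodgedetect_stage_error")
  expect_match(conditionMessage(err), "paired fine scene")
})

test_that("tidiers expose accuracies and areas as tibbles", {
  em <- error_matrix(matrix(c(20, 2, 1, 19), 2))
  td <- tidy(em)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$n), 42)
  g <- glance(em)
  expect_equal(g$oa, 92.86)
  expect_equal(g$ua_lodged, 90.91)
  s <- generate_scene(zhaodong_params(extent = c(32, 32), sds = 0, seed = 2))
  res <- run_detection_pipeline(s)
  expect_equal(glance(res)$threshold, 0.62)
  expect_true(all(c("lodged_kha", "lodged_pct") %in% names(tidy(res))))
})
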