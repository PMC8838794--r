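test_that("zero-noise scenes carry exactly the class band means", {
  s <- generate_scene(zhaodong_params(extent = c(32, 32), sds = 0, seed = 5))
  lodged <- s$truth == 2L
  expect_true(any(lodged))
  expect_true(all(s$bands$blue[lodged] == 0.0400))
  expect_true(all(s$bands$green[lodged] == 0.0829))
  expect_true(all(s$bands$red[lodged] == 0.0639))
  expect_true(all(s$bands$nir[lodged] == 0.5389))
})

test_that("generation is bit-identical under an identical seed", {
  p <- zhaodong_params(extent = c(64, 64), sds = 0.01, seed = 42)
  expect_identical(generate_scene(p), generate_scene(p))
  pair1 <- generate_paired_scenes(p, block_ratio = 2, coverage_fraction = 0.5)
  pair2 <- generate_paired_scenes(p, block_ratio = 2, coverage_fraction = 0.5)
  expect_identical(pair1, pair2)
  expect_identical(generate_survey(0.5, 50, 0.2, seed = 9),
                   generate_survey(0.5, 50, 0.2, seed = 9))
  s <- generate_scene(p)
  expect_identical(generate_sample_points(s, 60, seed = 3),
                   generate_sample_points(s, 60, seed = 3))
})

test_that("class fractions and per-band moments are recovered at scale", {
  p <- zhaodong_params(extent = c(512, 512), sds = 0.01,
                       lodged_fraction = 0.5456, seed = 11, patch_scale = 16L)
  s <- generate_scene(p)
  expect_lt(abs(truth_lodged_fraction(s) - 0.5456), 0.02)
  expect_lt(abs(mean(s$truth >= 1L) - p$maize_fraction), 0.02)
  # per-class per-band sample means within 4 standard errors of the inputs,
  # allowing the analytic mean shift that clipping to [0, 1] induces
  clip_shift <- function(mu, sd) {
    (sd * stats::dnorm(mu / sd) - mu * stats::pnorm(-mu / sd)) -
      (sd * stats::dnorm((1 - mu) / sd) - (1 - mu) * stats::pnorm(-(1 - mu) / sd))
  }
  for (cls in c(nonlodged_maize = 1L, lodged_maize = 2L)) {
    sel <- s$truth == cls
    mu <- p$class_band_means[[if (cls == 1L) "nonlodged_maize" else "lodged_maize"]]
    for (b in seq_len(4)) {
      vals <- s$bands[[b]][sel]
      se <- stats::sd(vals) / sqrt(length(vals))
      shift <- clip_shift(mu[b], 0.01)
      expect_lt(abs(mean(vals) - mu[b] - shift), 4 * se)
      expect_lt(abs(shift), 2e-4) # clipping stays negligible at default noise
    }
  }
})

test_that("fields form contiguous patches of the requested scale", {
  p <- zhaodong_params(extent = c(64, 64), sds = 0, seed = 2, patch_scale = 8L)
  s <- generate_scene(p)
  # every aligned 8x8 block is single-class
  for (i in seq(1, 64, by = 8)) {
    for (j in seq(1, 64, by = 8)) {
      expect_length(unique(as.vector(s$truth[i:(i + 7), j:(j + 7)])), 1)
    }
  }
})

test_that("paired scenes share one truth and aggregate exactly by block mean", {
  p <- zhaodong_params(extent = c(32, 32), sds = 0.01, seed = 7)
  pair <- generate_paired_scenes(p, block_ratio = 4, coverage_fraction = 1)
  r <- 4L
  expect_identical(pair$fine$truth[seq(1, 128, by = r), seq(1, 128, by = r)],
                   pair$coarse$truth)
  for (b in band_names <- c("blue", "green", "red", "nir")) {
    agg <- lodgedetect:::block_mean(pair$fine$bands[[b]], r)
    expect_equal(agg, pair$coarse$bands[[b]], tolerance = 1e-12)
  }
  # constant fine grid aggregates to the constant
  expect_equal(unique(as.vector(lodgedetect:::block_mean(matrix(0.3, 8, 8), 4L))), 0.3)
})

test_that("partial fine coverage is one contiguous window of the right size", {
  p <- zhaodong_params(extent = c(40, 40), sds = 0, seed = 3)
  pair <- generate_paired_scenes(p, block_ratio = 4, coverage_fraction = 0.2)
  valid <- !pair$fine$nodata_mask
  expect_lt(abs(mean(valid) - 0.2), 1 / 40) # one coarse-row granularity
  rows_valid <- which(apply(valid, 1, any))
  expect_identical(rows_valid, seq_len(max(rows_valid))) # contiguous from top
  expect_true(all(valid[rows_valid, ]))
  expect_error(generate_paired_scenes(p, 4, coverage_fraction = 0),
               class = "lodgedetect_parameter_error")
})

test_that("sample points land on maize truth with a near-target split", {
  s <- generate_scene(zhaodong_params(extent = c(64, 64), sds = 0, seed = 1))
  pts <- generate_sample_points(s, 140, train_fraction = 0.7, seed = 2)
  expect_equal(sum(pts$split == "train"), 98)
  expect_equal(sum(pts$split == "validate"), 42)
  loc <- lodgedetect:::locate_pixels(s, pts$x, pts$y)
  expect_true(all(loc$inside))
  cells <- cbind(loc$row, loc$col)
  expect_false(any(duplicated(cells)))
  expect_true(all(s$truth[cells] %in% 1:2))
  expect_identical(ifelse(s$truth[cells] == 2L, "lodged", "non-lodged"), pts$label)
  # per-label split deviates from the target by at most one point
  per_label <- table(pts$label, pts$split)
  for (lab in rownames(per_label)) {
    tot <- sum(per_label[lab, ])
    expect_lte(abs(per_label[lab, "train"] - 0.7 * tot), 1)
  }
  # the explicit override reproduces an uneven historical split
  pts2 <- generate_sample_points(s, 123, seed = 2, n_train = 89)
  expect_equal(as.vector(table(pts2$split)[c("train", "validate")]), c(89L, 34L))
})

test_that("sampling more points than the maize supports is an error", {
  s <- generate_scene(zhaodong_params(extent = c(32, 32), sds = 0,
                                      maize_fraction = 0, lodged_fraction = 0))
  expect_error(generate_sample_points(s, 1), class = "lodgedetect_sampling_error")
})

test_that("survey respondents report the true grade unless misreporting", {
  expect_true(all(generate_survey(0.8179, 25, misreport_prob = 0, seed = 1)$grade == "81-100%"))
  expect_true(all(generate_survey(0.5456, 25, misreport_prob = 0, seed = 1)$grade == "41-60%"))
  resp <- generate_survey(0.5456, 1000, misreport_prob = 0.3, seed = 8)
  counts <- table(resp$grade)
  expect_equal(names(which.max(counts)), "41-60%")
  phat <- counts[["41-60%"]] / 1000
  se <- sqrt(0.7 * 0.3 / 1000)
  expect_lt(abs(phat - 0.7), 3 * se)
  # misreports only ever land in adjacent grades
  expect_true(all(resp$grade %in% c("21-40%", "41-60%", "61-80%")))
})

test_that("invalid generator parameters are rejected up front", {
  expect_error(scene_params(lodged_fraction = 1.2), class = "lodgedetect_parameter_error")
  expect_error(scene_params(extent = c(4, 4), patch_scale = 8L),
               class = "lodgedetect_config_error")
  bad_means <- list(background = c(0.1, 0.1, 0.1, 1.5),
                    nonlodged_maize = rep(0.1, 4), lodged_maize = rep(0.2, 4))
  expect_error(scene_params(class_band_means = bad_means),
               class = "lodgedetect_parameter_error")
})
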