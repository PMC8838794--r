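# Shared fixtures, all built in code.

zhaodong_nonlodged <- c(blue = 0.0188, green = 0.0496, red = 0.0327, nir = 0.4703)
zhaodong_lodged    <- c(blue = 0.0400, green = 0.0829, red = 0.0639, nir = 0.5389)
ningjiang_nonlodged <- c(blue = 0.0241, green = 0.0613, red = 0.0452, nir = 0.4346)
ningjiang_lodged    <- c(blue = 0.0346, green = 0.0803, red = 0.0613, nir = 0.5435)

# single-pixel scene with the given band reflectances
pixel_scene <- function(b, g = NULL, r = NULL, n = NULL) {
  if (is.null(g)) { g <- b[2]; r <- b[3]; n <- b[4]; b <- b[1] }
  reflectance_scene(
    list(blue = matrix(b), green = matrix(g), red = matrix(r), nir = matrix(n)),
    cell_size = 16, validate_range = "none"
  )
}

# scene_params with the Zhaodong class contrast; zero noise unless sds given
zhaodong_params <- function(extent = c(64, 64), sds = 0, lodged_fraction = 0.5456,
                            maize_fraction = 0.6, seed = 1L, patch_scale = 8L) {
  scene_params(
    class_band_means = list(
      background = c(0.10, 0.12, 0.15, 0.28),
      nonlodged_maize = unname(zhaodong_nonlodged),
      lodged_maize = unname(zhaodong_lodged)
    ),
    class_band_sds = list(
      background = rep(sds, 4), nonlodged_maize = rep(sds, 4),
      lodged_maize = rep(sds, 4)
    ),
    lodged_fraction = lodged_fraction, maize_fraction = maize_fraction,
    patch_scale = patch_scale, cell_size = 16, extent = extent, seed = seed
  )
}

truth_lodged_fraction <- function(scene) {
  sum(scene$truth == 2L) / sum(scene$truth >= 1L)
}

# independent oracle for the variance-maximizing cut: minimize the pooled
# weighted within-class variance over every candidate midpoint
otsu_oracle <- function(values) {
  u <- sort(unique(values))
  cuts <- (u[-length(u)] + u[-1]) / 2
  n <- length(values)
  wcv <- vapply(cuts, function(t) {
    a <- values[values <= t]; b <- values[values > t]
    va <- if (length(a) > 1) stats::var(a) * (length(a) - 1) / length(a) else 0
    vb <- if (length(b) > 1) stats::var(b) * (length(b) - 1) / length(b) else 0
    (length(a) * va + length(b) * vb) / n
  }, numeric(1))
  cuts[which.min(wcv)]
}
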