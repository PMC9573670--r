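mk_vol <- function(arr, spacing = c(1, 1, 1)) ct_volume(arr, spacing)

test_that("series averaging is the voxelwise arithmetic mean", {
  a <- array(0, dim = c(4, 4, 4)); b <- array(10, dim = c(4, 4, 4))
  s <- series_set(list(mk_vol(a), mk_vol(b)), "background")
  expect_equal(average_series(s)$voxels, array(5, dim = c(4, 4, 4)))
  s3 <- series_set(list(mk_vol(b), mk_vol(b), mk_vol(b)), "background")
  expect_equal(average_series(s3)$voxels, b)
  expect_error(average_series(s, integer(0)), class = "gelshot_usage_error")
})

test_that("background subtraction is exact and requires co-registration", {
  set.seed(10)
  v <- mk_vol(array(rnorm(64), dim = c(4, 4, 4)))
  expect_equal(subtract_background(v, v)$voxels, array(0, dim = c(4, 4, 4)))
  v2 <- v; v2$origin <- v$origin + 1
  expect_error(subtract_background(v, v2), class = "gelshot_geometry_error")
})

test_that("noisy background residual has near-zero mean in a gel VOI", {
  spec <- small_star_spec(seed = 6, n_background = 3, n_irradiated = 3)
  sim <- simulate_phantom(spec)
  res <- subtract_background(average_series(sim$irradiated),
                             average_series(sim$background))
  # VOI away from any beam track (off-centre corner of the gel)
  st <- voi_stats(res, voi_cylinder(c(20, 0, 20), 10, 10))
  lim <- 3 * st$std / sqrt(st$n_voxels)
  expect_lt(abs(st$mean), max(lim, 0.15))
})

test_that("mean filter leaves a constant volume unchanged", {
  v <- mk_vol(array(42, dim = c(8, 3, 8)))
  for (mode in c("2D", "3D")) {
    out <- apply_filter(v, filter_spec("mean", 3, mode, iterations = 2))
    expect_equal(out$voxels, v$voxels, tolerance = 1e-12)
  }
})

test_that("median filter removes an isolated impulse", {
  a <- array(10, dim = c(9, 3, 9)); a[5, 2, 5] <- 1010
  out <- apply_filter(mk_vol(a), filter_spec("median", 3, "3D"))
  expect_equal(out$voxels[5, 2, 5], 10)
  out2 <- apply_filter(mk_vol(a), filter_spec("adaptive_median", 5, "3D"))
  expect_equal(out2$voxels[5, 2, 5], 10)
})

test_that("Savitzky-Golay preserves polynomials up to its order", {
  # exact quadratic ramp along the x (column) axis
  d <- c(7, 3, 20)
  x <- seq_len(d[3])
  a <- array(rep(0.3 * x^2 - 2 * x + 5, each = d[1] * d[2]), dim = d)
  out <- apply_filter(mk_vol(a),
                      filter_spec("savitzky_golay", 5, "2D", polyorder = 2))
  expect_lt(max(abs(out$voxels - a)), 1e-6)
})

test_that("range-contractive filters stay inside the input range", {
  set.seed(11)
  v <- mk_vol(array(rnorm(10 * 4 * 10, 0, 50), dim = c(10, 4, 10)))
  lo <- min(v$voxels); hi <- max(v$voxels)
  for (nm in c("mean", "median", "kuwahara", "envelope")) {
    for (mode in c("2D", "3D")) {
      out <- apply_filter(v, filter_spec(nm, 3, mode, iterations = 2))
      expect_gte(min(out$voxels), lo - 1e-9)
      expect_lte(max(out$voxels), hi + 1e-9)
      expect_identical(dim(out$voxels), dim(v$voxels))
      expect_invisible(assert_coregistered(out, v))
    }
  }
})

test_that("linear filters commute with subtraction", {
  set.seed(12)
  a <- mk_vol(array(rnorm(8 * 3 * 8, 0, 30), dim = c(8, 3, 8)))
  b <- mk_vol(array(rnorm(8 * 3 * 8, 0, 30), dim = c(8, 3, 8)))
  specs <- list(filter_spec("mean", 3, "2D", iterations = 2),
                filter_spec("savitzky_golay", 5, "2D", polyorder = 2),
                filter_spec("fft_window", 3, "2D", window_name = "nuttall"))
  for (sp in specs) {
    lhs <- subtract_background(apply_filter(a, sp), apply_filter(b, sp))
    rhs <- apply_filter(subtract_background(a, b), sp)
    expect_lt(max(abs(lhs$voxels - rhs$voxels)), 1e-6)
  }
})

test_that("every FFT window is accepted and preserves geometry", {
  set.seed(13)
  v <- mk_vol(array(rnorm(12 * 2 * 12), dim = c(12, 2, 12)))
  wins <- c("hann", "hamming", "blackman", "nuttall", "blackman-nuttall",
            "blackman-harris", "flat-top", "bartlett", "welch", "cosine",
            "tukey", "rectangular")
  for (wn in wins) {
    out <- apply_filter(v, filter_spec("fft_window", window_name = wn))
    expect_identical(dim(out$voxels), dim(v$voxels))
    expect_true(all(is.finite(out$voxels)))
  }
  # rectangular window is the identity
  out <- apply_filter(v, filter_spec("fft_window",
                                     window_name = "rectangular"))
  expect_lt(max(abs(out$voxels - v$voxels)), 1e-9)
})

test_that("invalid filter specifications are usage errors", {
  expect_error(filter_spec("sharpen"), class = "gelshot_usage_error")
  expect_error(filter_spec("mean", kernel = 4), class = "gelshot_usage_error")
  expect_error(filter_spec("savitzky_golay", kernel = 3, polyorder = 3),
               class = "gelshot_usage_error")
  expect_error(filter_spec("fft_window", window_name = "gauss"),
               class = "gelshot_usage_error")
})

test_that("5-series averaging shrinks noise like 1/sqrt(5) after filtering stages", {
  spec <- phantom_spec(beams = list(), noise_std_hu = 4.986,
                       n_background = 5, n_irradiated = 1, seed = 31)
  sim <- simulate_phantom(spec)
  voi <- voi_cylinder(c(0, 0, 0), 20, 20)
  r <- voi_stats(average_series(sim$background), voi)$std /
    voi_stats(sim$background$volumes[[1]], voi)$std
  expect_lt(abs(r - 1 / sqrt(5)), 0.1 / sqrt(5))
})
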