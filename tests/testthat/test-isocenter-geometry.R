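test_that("concurrent lines give a zero-radius fit at their crossing", {
  p <- c(3, -2)
  ls <- lapply(c(10, 75, 140), function(a)
    line2d_from_point_angle(p, a))
  fit <- fit_isocenter_2d(ls)
  expect_equal(fit$center, p, tolerance = 1e-9)
  expect_lt(fit$radius_mm, 1e-9)

  p3 <- c(1, -2, 3)
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1) / sqrt(3))
  ls3 <- lapply(dirs, function(d) line3d(p3 - 5 * d, d))
  fit3 <- fit_isocenter_3d(ls3)
  expect_equal(fit3$center, p3, tolerance = 1e-6)
  expect_lt(fit3$radius_mm, 1e-6)
})

test_that("the incircle of x=0, y=0, x+y=2 is recovered in closed form", {
  ls <- list(line2d(1, 0, 0), line2d(0, 1, 0),
             line2d(1 / sqrt(2), 1 / sqrt(2), sqrt(2)))
  fit <- fit_isocenter_2d(ls)
  expect_equal(fit$center, rep(2 - sqrt(2), 2), tolerance = 1e-9)
  expect_equal(fit$radius_mm, 2 - sqrt(2), tolerance = 1e-9)
  # independent oracle agrees
  o <- oracle_minimax_2d(ls)
  expect_lt(sqrt(sum((fit$center - o$par)^2)), 1e-4)
})

test_that("lines tangent to a known circle recover its centre and radius", {
  set.seed(101)
  ls <- make_tangent_bundle_2d(c(1, 2), 0.5, n = 4)
  fit <- fit_isocenter_2d(ls)
  expect_equal(fit$center, c(1, 2), tolerance = 1e-9)
  expect_equal(fit$radius_mm, 0.5, tolerance = 1e-9)
})

test_that("two skew lines give the midpoint of the common perpendicular", {
  ls <- list(line3d(c(0, 0, 0), c(1, 0, 0)),
             line3d(c(0, 1, 0), c(0, 0, 1)))
  fit <- fit_isocenter_3d(ls)
  expect_equal(fit$center, c(0, 0.5, 0), tolerance = 1e-6)
  expect_equal(fit$radius_mm, 0.5, tolerance = 1e-6)
  expect_equal(fit$ls_center, c(0, 0.5, 0), tolerance = 1e-9)
})

test_that("2D and 3D fits match brute-force + simplex oracles on random bundles", {
  set.seed(202)
  for (rep in 1:60) {
    ls <- make_tangent_bundle_2d(runif(2, -5, 5), runif(1, 0.1, 2),
                                 n = sample(3:6, 1))
    fit <- fit_isocenter_2d(ls)
    o <- oracle_minimax_2d(ls, starts = list(fit$center + c(0.5, -0.5),
                                             fit$center, c(0, 0)))
    expect_lt(sqrt(sum((fit$center - o$par)^2)), 1e-4)
    expect_lt(abs(fit$radius_mm - o$value), 1e-4)
  }
  for (rep in 1:60) {
    ctr <- runif(3, -5, 5); rad <- runif(1, 0.05, 1.5)
    ls <- make_tangent_bundle_3d(ctr, rad)
    fit <- fit_isocenter_3d(ls)
    # constructive oracle: the sphere centre is the Chebyshev point
    expect_lt(sqrt(sum((fit$center - ctr)^2)), 1e-4)
    expect_lt(abs(fit$radius_mm - rad), 1e-4)
    o <- oracle_minimax_3d(ls, start = fit$ls_center)
    expect_lt(sqrt(sum((fit$center - o$par)^2)), 5e-4)
  }
})

test_that("no grid point near the fitted centre beats its max distance", {
  set.seed(303)
  ls <- make_tangent_bundle_2d(c(-1, 3), 0.8, n = 5)
  fit <- fit_isocenter_2d(ls)
  g <- seq(-2, 2, by = 0.01)
  fmax <- function(x) max(vapply(ls, function(l)
    abs(l$a * x[1] + l$b * x[2] - l$c), 0))
  vals <- outer(g, g, Vectorize(function(du, dv)
    fmax(fit$center + c(du, dv))))
  expect_gte(min(vals), fit$radius_mm - 1e-9)

  ls3 <- make_tangent_bundle_3d(c(0.5, -0.5, 1), 0.4)
  fit3 <- fit_isocenter_3d(ls3)
  g3 <- seq(-1, 1, by = 0.05)
  f3 <- function(x) max(vapply(ls3, function(l) line3d_distance(l, x), 0))
  worst <- Inf
  for (du in g3) for (dv in g3) for (dw in g3)
    worst <- min(worst, f3(fit3$center + c(du, dv, dw)))
  expect_gte(worst, fit3$radius_mm - 1e-9)
})

test_that("min-max radius never exceeds the worst distance at the LS centre", {
  set.seed(404)
  for (rep in 1:20) {
    ls <- lapply(1:4, function(i)
      line2d_from_point_angle(runif(2, -3, 3), runif(1, 0, 180)))
    fit <- tryCatch(fit_isocenter_2d(ls), error = function(e) NULL)
    if (is.null(fit)) next
    at_ls <- max(vapply(ls, function(l)
      abs(line2d_distance(l, fit$ls_center)), 0))
    expect_lte(fit$radius_mm, at_ls + 1e-9)
  }
})

test_that("fits are invariant under rigid in-plane rotation", {
  set.seed(505)
  ls <- make_tangent_bundle_2d(c(2, -1), 0.6, n = 4)
  ref <- c(0.5, 0.5)
  fit <- fit_isocenter_2d(ls, reference = ref)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot_line <- function(l) {
    n2 <- as.numeric(R %*% c(l$a, l$b))
    line2d(n2[1], n2[2], l$c)   # c is invariant when rotating about origin
  }
  fit_r <- fit_isocenter_2d(lapply(ls, rot_line),
                            reference = as.numeric(R %*% ref))
  expect_equal(fit_r$center, as.numeric(R %*% fit$center), tolerance = 1e-9)
  expect_equal(fit_r$radius_mm, fit$radius_mm, tolerance = 1e-9)
  expect_equal(fit_r$offset_mm, fit$offset_mm, tolerance = 1e-9)
})

test_that("degenerate line sets are rejected", {
  par2 <- list(line2d(1, 0, 0), line2d(1, 0, 2), line2d(-1, 0, 5))
  expect_error(fit_isocenter_2d(par2), class = "gelshot_geometry_error")
  par3 <- list(line3d(c(0, 0, 0), c(0, 0, 1)),
               line3d(c(1, 0, 0), c(0, 0, 1)))
  expect_error(fit_isocenter_3d(par3), class = "gelshot_geometry_error")
  expect_error(fit_isocenter_2d(list(line2d(1, 0, 0))),
               class = "gelshot_usage_error")
})

test_that("star-shot tracks are detected to sub-voxel accuracy", {
  spec0 <- small_star_spec(seed = 31, noise_std_hu = 0, n_background = 1,
                           n_irradiated = 1)
  sim <- simulate_phantom(spec0)
  sub <- subtract_background(sim$irradiated$volumes[[1]],
                             sim$background$volumes[[1]])
  plane <- extract_star_plane(sub, -1, 5)
  hints <- vapply(c(0, 90, 150, 240), gantry_to_plane_angle, 0)
  lines <- detect_beams_2d(plane, 4, angle_hints = hints, gap_mm = 2)
  for (b in 1:4) {
    tl <- sim$truth$true_lines[[b]]
    ang_true <- gantry_to_plane_angle(tl$gantry_deg)
    expect_lt(line_angle_error(lines[[b]]$angle_deg, ang_true), 0.2)
    expect_lt(abs(line2d_distance(lines[[b]],
                                  c(tl$point[1], tl$point[3]))), 0.05)
  }
})

test_that("unguided sinogram detection finds all four star angles", {
  spec0 <- small_star_spec(seed = 32, noise_std_hu = 0, n_background = 1,
                           n_irradiated = 1)
  sim <- simulate_phantom(spec0)
  sub <- subtract_background(sim$irradiated$volumes[[1]],
                             sim$background$volumes[[1]])
  plane <- extract_star_plane(sub, -1, 5)
  lines <- detect_beams_2d(plane, 4, gap_mm = 2)
  found <- vapply(lines, `[[`, 0, "angle_deg")
  truth <- vapply(c(0, 90, 150, 240), gantry_to_plane_angle, 0)
  # circular (mod 180) matching of each planned angle to one detection
  for (tr in truth)
    expect_lt(min(vapply(found, line_angle_error, 0, b = tr)), 0.3)
  expect_equal(length(found), 4L)
})

test_that("noisy star-shot line offsets stay within a quarter millimetre", {
  bad <- 0
  for (s in 1:20) {
    sim <- simulate_phantom(small_star_spec(seed = 600 + s))
    sub <- subtract_background(average_series(sim$irradiated),
                               average_series(sim$background))
    plane <- extract_star_plane(sub, -1, 5)
    hints <- vapply(c(0, 90, 150, 240), gantry_to_plane_angle, 0)
    lines <- detect_beams_2d(plane, 4, angle_hints = hints, gap_mm = 2)
    offs <- vapply(1:4, function(b) {
      tl <- sim$truth$true_lines[[b]]
      abs(line2d_distance(lines[[b]], c(tl$point[1], tl$point[3])))
    }, 0)
    if (max(offs) > 0.25) bad <- bad + 1
  }
  expect_lte(bad, 1)  # 95% of 20 seeds
})

test_that("a blank image yields a detection error with the found count", {
  blank <- structure(list(values = matrix(0, 64, 64),
                          u = seq(-31.5, 31.5), v = seq(-31.5, 31.5),
                          axial_mm = 0), class = "plane_image")
  expect_error(detect_beams_2d(blank, 4), "0 of 4",
               class = "gelshot_detection_error")
})

test_that("3D tracks are recovered within tolerance at both noise levels", {
  for (noise in c(0, 1.555)) {
    spec <- phantom_spec(beams = beams_3d(), noise_std_hu = noise,
                         fov_y_mm = 80, seed = 41)
    sim <- simulate_phantom(spec)
    sub <- subtract_background(average_series(sim$irradiated),
                               average_series(sim$background))
    lines <- detect_beams_3d(sub, spec$beams)
    lim_pos <- if (noise == 0) 0.05 else 0.3
    lim_ang <- if (noise == 0) 0.1 else 0.5
    for (b in seq_along(lines)) {
      tl <- sim$truth$true_lines[[b]]
      expect_lt(line3d_distance(lines[[b]], tl$point), lim_pos)
      dang <- acos(min(abs(sum(lines[[b]]$direction * tl$direction)),
                       1)) * 180 / pi
      expect_lt(dang, lim_ang)
    }
  }
})

test_that("coincident planned directions are a usage error", {
  v <- ct_volume(array(0, dim = c(4, 4, 4)), c(1, 1, 1))
  beams <- list(beam_spec(90), beam_spec(90))
  expect_error(detect_beams_3d(v, beams), class = "gelshot_usage_error")
})

test_that("markers are localised and the reference construction is exact", {
  spec <- small_star_spec(seed = 51, n_background = 1, n_irradiated = 1)
  sim <- simulate_phantom(spec)
  fid <- detect_markers(sim$irradiated$volumes[[1]])
  truth <- sim$truth$marker_centers
  for (m in 1:3) {
    err <- abs(fid$markers[m, ] - truth[m, ])
    expect_true(all(err <= spec$spacing[c(3, 2, 1)] / 2 + 0.35))
  }
  # markers at exact 0/90/270 degrees put the reference on the container
  # axis
  expect_lt(sqrt(sum((fid$reference_point - c(0, -1, 0))^2)), 0.5)

  # symmetric in-plane construction: (0, R), (R, 0), (-R, 0) -> origin
  centers <- rbind(c(0, -1, 40), c(40, -1, 0), c(-40, -1, 0))
  ref <- gelshot:::.marker_reference(centers, c(0, 90, 270))
  expect_equal(as.numeric(ref), c(0, -1, 0), tolerance = 1e-12)

  no_mk <- simulate_phantom(small_star_spec(seed = 52, markers = NULL,
                                            n_background = 1,
                                            n_irradiated = 1))
  expect_error(detect_markers(no_mk$irradiated$volumes[[1]]),
               class = "gelshot_detection_error")
})
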