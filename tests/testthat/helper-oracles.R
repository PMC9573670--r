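# Shared fixtures and independent oracles.

# planned line angle (mod 180, in the (u, v) = (x, z) star plane) of a
# coplanar beam at a given gantry angle
gantry_to_plane_angle <- function(gantry_deg) {
  g <- gantry_deg * pi / 180
  a <- (atan2(-cos(g), sin(g)) * 180 / pi) %% 180
  if (a >= 180 - 1e-9) 0 else a
}

# a reduced-size star phantom used where many simulations are needed:
# the smaller (80 mm) container, 1 mm in-plane grid, short axial extent
small_star_spec <- function(seed, noise_std_hu = 1.555,
                            beam_scatter_mm = 0, n_background = 3,
                            n_irradiated = 3, ...) {
  phantom_spec(container = list(inner_diameter_mm = 80),
               noise_std_hu = noise_std_hu,
               beam_scatter_mm = beam_scatter_mm,
               n_background = n_background, n_irradiated = n_irradiated,
               spacing = c(1, 2, 1), fov_xz_mm = 98, fov_y_mm = 24,
               seed = seed, ...)
}

# independent minimax oracle, 2D: multi-start Nelder-Mead on the raw
# normal-form distances plus a 0.01 mm local grid sweep
oracle_minimax_2d <- function(lines, starts = NULL) {
  f <- function(x) max(vapply(lines, function(l)
    abs(l$a * x[1] + l$b * x[2] - l$c), 0))
  if (is.null(starts))
    starts <- list(c(0, 0), c(1, 1), c(-2, 3), c(5, -5))
  best <- NULL; fb <- Inf
  for (s in starts) {
    o <- optim(s, f, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
    o <- optim(o$par, f, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
    if (o$value < fb) { best <- o$par; fb <- o$value }
  }
  g <- seq(-0.02, 0.02, by = 0.001)
  for (du in g) for (dv in g) {
    v <- f(best + c(du, dv))
    if (v < fb) { fb <- v; best <- best + c(du, dv) }
  }
  list(par = best, value = fb)
}

# independent minimax oracle, 3D
oracle_minimax_3d <- function(lines, start = c(0, 0, 0)) {
  dst <- function(l, x) {
    rel <- x - l$point
    t_ax <- sum(rel * l$direction)
    sqrt(max(sum(rel^2) - t_ax^2, 0))
  }
  f <- function(x) max(vapply(lines, dst, 0, x = x))
  best <- start; fb <- f(start)
  for (s in list(start, start + c(1, 1, 1), start - c(2, 0, 2))) {
    o <- optim(s, f, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 8000))
    o <- optim(o$par, f, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 8000))
    if (o$value < fb) { best <- o$par; fb <- o$value }
  }
  g <- seq(-0.01, 0.01, by = 0.001)
  for (du in g) for (dv in g) for (dw in g) {
    v <- f(best + c(du, dv, dw))
    if (v < fb) { fb <- v; best <- best + c(du, dv, dw) }
  }
  list(par = best, value = fb)
}

# random 2D line bundle tangent to a known circle: outward normals with
# all angular gaps < 180 degrees positively span the plane, making the
# circle centre the unique Chebyshev point
make_tangent_bundle_2d <- function(center, radius, n = 4) {
  repeat {
    ang <- sort(runif(n, 0, 2 * pi))
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    if (max(gaps) < pi - 0.1) break
  }
  lapply(ang, function(a) {
    m <- c(cos(a), sin(a))
    line2d(m[1], m[2], sum(m * center) + radius)
  })
}

# random 3D line bundle tangent to a known sphere: contact normals are a
# jittered, randomly rotated tetrahedral frame (positively spanning), so
# the sphere centre is the Chebyshev point
make_tangent_bundle_3d <- function(center, radius) {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  qr_rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_rot) < 0) qr_rot[, 1] <- -qr_rot[, 1]
  lapply(seq_len(4), function(i) {
    m <- as.numeric(qr_rot %*% tet[i, ]) + rnorm(3, 0, 0.05)
    m <- m / sqrt(sum(m^2))
    # direction orthogonal to the contact normal
    ref <- if (abs(m[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    d1 <- ref - sum(ref * m) * m; d1 <- d1 / sqrt(sum(d1^2))
    d2 <- c(m[2] * d1[3] - m[3] * d1[2], m[3] * d1[1] - m[1] * d1[3],
            m[1] * d1[2] - m[2] * d1[1])
    th <- runif(1, 0, 2 * pi)
    d <- cos(th) * d1 + sin(th) * d2
    line3d(center + radius * m + runif(1, -20, 20) * d, d)
  })
}

line_angle_error <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}
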