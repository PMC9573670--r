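# Synthetic CBCT-like phantom generator.
#
# Emulates a gel-filled cylindrical container scanned in air on the couch:
# gel + wall + air HU levels, a radially symmetric beam-hardening offset
# (inverted-parabola cupping, largest in magnitude on the container axis),
# optional concentric ring artifacts, mode-specific white Gaussian HU noise,
# dose-saturating bright beam tracks with erf-shaped penumbra, and three
# surface fiducial markers. Ground truth (beam axes, isocenter, marker
# centres, reference point) is returned alongside the image series.
#
# The container axis lies along y (the gantry rotation axis); the star-shot
# pattern therefore lives in planes of constant y with in-plane coordinates
# (u, v) = (x, z).

#' Beam specification
#'
#' @param gantry_deg,collimator_deg,couch_deg machine angles in degrees.
#' @param gap_mm MLC slit width (the thin track dimension), >= 0.
#' @param length_mm slit length (jaw-defined extent along the rotation
#'   axis), > 0.
#' @param mu monitor units, > 0.
#' @return list of class `beam_spec`.
#' @export
beam_spec <- function(gantry_deg, collimator_deg = 0, couch_deg = 0,
                      gap_mm = 2, length_mm = 20, mu = 10000) {
  if (!is.finite(gantry_deg) || !is.finite(collimator_deg) ||
      !is.finite(couch_deg)) err_usage("beam angles must be finite")
  if (gap_mm < 0) err_usage("gap_mm must be >= 0")
  if (mu <= 0) err_usage("mu must be > 0")
  structure(list(gantry_deg = gantry_deg, collimator_deg = collimator_deg,
                 couch_deg = couch_deg, gap_mm = gap_mm,
                 length_mm = length_mm, mu = mu), class = "beam_spec")
}

#' Standard beam sets
#'
#' `star_beams()` is the four-field coplanar star-shot pattern (gantry 0,
#' 90, 150, 240 degrees; 2 mm MLC gap; 10,000 MU). `beams_3d()` is the
#' non-coplanar four-beam pattern with gantry/collimator/couch of
#' (0,0,0), (90,90,90), (150,30,45) and (300,300,300) degrees and a
#' 5 x 5 mm^2 field.
#' @return list of [beam_spec()].
#' @export
star_beams <- function() {
  lapply(c(0, 90, 150, 240), function(g) beam_spec(gantry_deg = g))
}

#' @rdname star_beams
#' @export
beams_3d <- function() {
  ang <- list(c(0, 0, 0), c(90, 90, 90), c(150, 30, 45), c(300, 300, 300))
  lapply(ang, function(a)
    beam_spec(gantry_deg = a[1], collimator_deg = a[2], couch_deg = a[3],
              gap_mm = 5, length_mm = 5))
}

#' Central-axis direction of a beam
#'
#' With gantry angle g and couch angle c (degrees), the unit direction is
#' `Rz(-c) %*% c(sin g, 0, -cos g)`: gantry 0 fires straight down (-z) and
#' the couch rotates the beam plane about the vertical. The collimator
#' angle rotates the slit about the axis and does not change the direction.
#'
#' @param gantry_deg,couch_deg angles in degrees.
#' @return unit length-3 vector (x, y, z).
#' @export
beam_direction <- function(gantry_deg, couch_deg = 0) {
  g <- gantry_deg * pi / 180
  v <- c(sin(g), 0, -cos(g))
  as.numeric(.rot_z(-couch_deg) %*% v)
}

.rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# Orthonormal frame of a beam: d (axis), w1 (MLC-gap/thin direction),
# w2 (slit-length direction). Before collimator rotation w2 points along
# the couch-rotated y axis; the collimator rotates (w1, w2) about d.
beam_frame <- function(beam) {
  d <- beam_direction(beam$gantry_deg, beam$couch_deg)
  w2 <- as.numeric(.rot_z(-beam$couch_deg) %*% c(0, 1, 0))
  w1 <- c(d[2] * w2[3] - d[3] * w2[2],
          d[3] * w2[1] - d[1] * w2[3],
          d[1] * w2[2] - d[2] * w2[1])
  w1 <- w1 / sqrt(sum(w1^2))
  th <- beam$collimator_deg * pi / 180
  list(d = d,
       w1 = cos(th) * w1 + sin(th) * w2,
       w2 = -sin(th) * w1 + cos(th) * w2)
}

#' Dose-response model of the gel readout
#'
#' Piecewise-linear HU increment versus absorbed dose: linear with slope
#' `slope_hu_per_gy` up to `d_lin`, a reduced-slope ramp up to the
#' saturation plateau `hu_at_sat` at `d_sat`, constant beyond. Continuous
#' and non-decreasing. `gy_per_100mu` maps delivered monitor units to dose
#' on the central axis; only the relative track amplitude matters for the
#' isocenter geometry.
#'
#' @param slope_hu_per_gy linear-range sensitivity (HU/Gy).
#' @param d_lin end of the linear range (Gy).
#' @param d_sat saturation dose (Gy), > `d_lin`.
#' @param hu_at_sat plateau HU increment, >= `slope_hu_per_gy * d_lin`.
#' @param gy_per_100mu Gy delivered per 100 MU at the track.
#' @return list of class `dose_model`.
#' @export
dose_model <- function(slope_hu_per_gy = 2.5, d_lin = 18, d_sat = 40,
                       hu_at_sat = 60, gy_per_100mu = 1) {
  if (d_lin >= d_sat) err_usage("d_lin must be < d_sat")
  if (hu_at_sat < slope_hu_per_gy * d_lin)
    err_usage("hu_at_sat must be >= slope * d_lin (non-decreasing response)")
  structure(list(slope_hu_per_gy = slope_hu_per_gy, d_lin = d_lin,
                 d_sat = d_sat, hu_at_sat = hu_at_sat,
                 gy_per_100mu = gy_per_100mu), class = "dose_model")
}

#' HU increment produced by an absorbed dose
#'
#' @param dose_gy dose in Gy, >= 0 (vectorised).
#' @param model a [dose_model()].
#' @return HU increment(s).
#' @export
dose_to_hu <- function(dose_gy, model = dose_model()) {
  if (any(dose_gy < 0)) err_domain("dose must be >= 0")
  s <- model$slope_hu_per_gy
  brk <- s * model$d_lin
  ramp <- (model$hu_at_sat - brk) / (model$d_sat - model$d_lin)
  ifelse(dose_gy <= model$d_lin, s * dose_gy,
         ifelse(dose_gy <= model$d_sat,
                brk + ramp * (dose_gy - model$d_lin),
                model$hu_at_sat))
}

#' Phantom specification
#'
#' Defaults encode the study conditions: a 90 mm inner-diameter gel
#' container, the four-field star-shot beam set at 10,000 MU with a 2 mm
#' MLC gap, iCBCT-Pelvis noise (1.555 HU), a -20 HU beam-hardening
#' parabola, three copper-wire-like surface markers at 0/90/270 degrees in
#' the plane y = -1 mm, and three background plus three irradiated series.
#'
#' @param container list: `inner_diameter_mm`, `length_mm`, `wall_mm`,
#'   `wall_hu`, `gel_hu`, `air_hu`.
#' @param beams list of [beam_spec()].
#' @param target_point mm point the beam axes aim at (the true isocenter
#'   when `beam_scatter_mm = 0`).
#' @param beam_scatter_mm maximal random perpendicular miss distance of
#'   each beam axis from `target_point`.
#' @param noise_std_hu white Gaussian HU noise Std (see [noise_preset()]).
#' @param hardening_amp_hu depth of the radial beam-hardening parabola at
#'   the container axis (negative for cupping).
#' @param ring_amp_hu,ring_period_mm optional concentric ring-artifact
#'   amplitude and radial period.
#' @param markers data frame with columns `angle_deg`, `axial_mm` (position
#'   along the container axis), `radius_mm`, `marker_hu`; `NULL` for none.
#' @param dose_model a [dose_model()].
#' @param penumbra_sigma_mm erf-penumbra sigma of the track edges.
#' @param leak_mm quadrature widening of the slit (leaf-end transmission),
#'   keeps a closed (0 mm) gap faintly visible.
#' @param n_background,n_irradiated number of series to simulate.
#' @param spacing grid spacing `c(sz, sy, sx)` mm.
#' @param fov_xz_mm,fov_y_mm simulated extents; the in-plane field of view
#'   must cover the container plus markers.
#' @param mode_tag label stamped on the series.
#' @param seed integer seed; the same spec and seed reproduce identical
#'   volumes bit for bit.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(container = list(),
                         beams = star_beams(),
                         target_point = c(0, 0, 0),
                         beam_scatter_mm = 0,
                         noise_std_hu = 1.555,
                         hardening_amp_hu = -20,
                         ring_amp_hu = 0,
                         ring_period_mm = 5,
                         markers = default_markers(),
                         dose_model = gelshot::dose_model(),
                         penumbra_sigma_mm = 0.5,
                         leak_mm = 0.5,
                         n_background = 3,
                         n_irradiated = 3,
                         spacing = c(0.9, 2, 0.9),
                         fov_xz_mm = 108,
                         fov_y_mm = 40,
                         mode_tag = "TrueBeam iCBCT Pelvis",
                         seed = 1) {
  cont <- modifyList(list(inner_diameter_mm = 90, length_mm = 130,
                          wall_mm = 3, wall_hu = 100, gel_hu = 15,
                          air_hu = -1000), container)
  if (noise_std_hu < 0) err_usage("noise_std_hu must be >= 0")
  if (beam_scatter_mm < 0) err_usage("beam_scatter_mm must be >= 0")
  structure(list(container = cont, beams = beams,
                 target_point = target_point,
                 beam_scatter_mm = beam_scatter_mm,
                 noise_std_hu = noise_std_hu,
                 hardening_amp_hu = hardening_amp_hu,
                 ring_amp_hu = ring_amp_hu, ring_period_mm = ring_period_mm,
                 markers = markers, dose_model = dose_model,
                 penumbra_sigma_mm = penumbra_sigma_mm, leak_mm = leak_mm,
                 n_background = n_background, n_irradiated = n_irradiated,
                 spacing = spacing, fov_xz_mm = fov_xz_mm,
                 fov_y_mm = fov_y_mm, mode_tag = mode_tag, seed = seed),
            class = "phantom_spec")
}

#' Default fiducial marker layout
#'
#' Three bright copper-wire-style markers on the container surface at the
#' 0, 90 and 270 degree positions in the transversal plane y = -1 mm. The
#' in-plane position of a marker at angle a is
#' `R * (sin a, cos a)` in (x, z), with R the outer container radius plus
#' the marker radius.
#' @param marker_hu rendered HU of the marker spheres.
#' @return data frame with one row per marker.
#' @export
default_markers <- function(marker_hu = 500) {
  data.frame(angle_deg = c(0, 90, 270), axial_mm = -1,
             radius_mm = 1.5, marker_hu = marker_hu)
}

# erf-edged box profile of nominal width w and penumbra sigma s, centred
# at 0: ~1 inside |t| < w/2, smooth roll-off over ~s.
.box_erf <- function(t, w, s) pnorm((w / 2 - t) / s) - pnorm((-w / 2 - t) / s)

#' Simulate background and irradiated scan series with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom_sim` with elements `background` and
#'   `irradiated` ([series_set()]s), and `truth`: `true_lines` (list of
#'   point+direction), `true_isocenter`, `marker_centers`,
#'   `reference_point`, plus the noiseless `background_field` and
#'   `track_field` volumes for oracle checks.
#' @export
simulate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) err_usage("need a phantom_spec")
  set.seed(spec$seed)
  sp <- spec$spacing
  half_xz <- spec$fov_xz_mm / 2
  half_y <- spec$fov_y_mm / 2
  x <- seq(-half_xz, half_xz, by = sp[3])
  z <- seq(-half_xz, half_xz, by = sp[1])
  y <- seq(-half_y, half_y, by = sp[2])
  ni <- length(z); nj <- length(y); nk <- length(x)
  origin <- c(x[1], y[1], z[1])
  cont <- spec$container
  r_in <- cont$inner_diameter_mm / 2
  r_out <- r_in + cont$wall_mm

  # transversal background plane (z rows, x cols), replicated along y
  r_plane <- sqrt(outer(z^2, x^2, `+`))
  plane <- matrix(cont$air_hu, ni, nk)
  gel2d <- r_plane < r_in
  wall2d <- r_plane >= r_in & r_plane < r_out
  plane[wall2d] <- cont$wall_hu
  gel_val <- cont$gel_hu +
    spec$hardening_amp_hu * (1 - (r_plane[gel2d] / r_in)^2)
  if (spec$ring_amp_hu != 0)
    gel_val <- gel_val +
      spec$ring_amp_hu * sin(2 * pi * r_plane[gel2d] / spec$ring_period_mm)
  plane[gel2d] <- gel_val

  axial_in <- abs(y) <= cont$length_mm / 2
  bg <- array(cont$air_hu, dim = c(ni, nj, nk))
  for (j in which(axial_in)) bg[, j, ] <- plane

  # markers: bright spheres on the container surface
  marker_centers <- NULL
  if (!is.null(spec$markers) && nrow(spec$markers) > 0) {
    mk <- spec$markers
    r_m <- r_out + mk$radius_mm
    marker_centers <- cbind(x = r_m * sin(mk$angle_deg * pi / 180),
                            y = mk$axial_mm,
                            z = r_m * cos(mk$angle_deg * pi / 180))
    for (m in seq_len(nrow(mk))) {
      c_m <- marker_centers[m, ]; rad <- mk$radius_mm[m]
      reach <- rad + min(sp)
      ks <- which(abs(x - c_m[1]) <= reach)
      js <- which(abs(y - c_m[2]) <= reach)
      is <- which(abs(z - c_m[3]) <= reach)
      if (!length(ks) || !length(js) || !length(is))
        err_geometry("marker outside the simulated field of view")
      edge <- 0.5 * min(sp)   # anti-aliased rim: no knife-edge voxels
      for (j in js) for (k in ks) {
        dd <- sqrt((x[k] - c_m[1])^2 + (y[j] - c_m[2])^2 +
                     (z[is] - c_m[3])^2)
        wgt <- pmin(1, pmax(0, (rad - dd) / edge + 0.5))
        cur <- bg[is, j, k]
        bg[is, j, k] <- cur + wgt * (mk$marker_hu[m] - cur)
      }
    }
  }

  # beam tracks on the flattened voxel grid
  xx <- rep(x, each = ni * nj)
  yy <- rep(rep(y, each = ni), times = nk)
  zz <- rep(z, times = nj * nk)
  gel3d <- (zz^2 + xx^2 < r_in^2) & (abs(yy) <= cont$length_mm / 2)
  track <- numeric(ni * nj * nk)
  true_lines <- vector("list", length(spec$beams))
  half_diag <- sqrt(half_xz^2 + half_xz^2 + half_y^2)
  for (b in seq_along(spec$beams)) {
    beam <- spec$beams[[b]]
    fr <- beam_frame(beam)
    off <- c(0, 0, 0)
    if (spec$beam_scatter_mm > 0) {
      ang <- runif(1, 0, 2 * pi)
      mag <- runif(1, 0, spec$beam_scatter_mm)
      perp1 <- fr$w1; perp2 <- fr$w2
      off <- mag * (cos(ang) * perp1 + sin(ang) * perp2)
    }
    p <- spec$target_point + off
    # closest approach of the axis to the volume centre
    rel_c <- -p
    perp_c <- rel_c - sum(rel_c * fr$d) * fr$d
    if (sqrt(sum(perp_c^2)) > half_diag)
      err_geometry(sprintf("beam %d passes outside the simulated volume", b))
    amp <- dose_to_hu(beam$mu / 100 * spec$dose_model$gy_per_100mu,
                      spec$dose_model)
    w_eff <- sqrt(beam$gap_mm^2 + spec$leak_mm^2)
    t1 <- (xx - p[1]) * fr$w1[1] + (yy - p[2]) * fr$w1[2] +
      (zz - p[3]) * fr$w1[3]
    t2 <- (xx - p[1]) * fr$w2[1] + (yy - p[2]) * fr$w2[2] +
      (zz - p[3]) * fr$w2[3]
    inc <- amp * .box_erf(t1, w_eff, spec$penumbra_sigma_mm) *
      .box_erf(t2, beam$length_mm, spec$penumbra_sigma_mm)
    track <- track + inc * gel3d
    true_lines[[b]] <- list(point = p, direction = fr$d,
                            gap_mm = beam$gap_mm, gantry_deg = beam$gantry_deg,
                            collimator_deg = beam$collimator_deg,
                            couch_deg = beam$couch_deg)
  }
  track <- array(track, dim = c(ni, nj, nk))
  irr <- bg + track

  reference_point <- NULL
  if (!is.null(marker_centers) && nrow(marker_centers) == 3 &&
      all(c(0, 90, 270) %in% spec$markers$angle_deg)) {
    reference_point <- .marker_reference(marker_centers, spec$markers$angle_deg)
  }

  frame_id <- sprintf("sim-seed%d", spec$seed)
  mk_vol <- function(field) {
    noise <- if (spec$noise_std_hu > 0)
      array(rnorm(length(field), 0, spec$noise_std_hu), dim = dim(field))
    else 0
    ct_volume(field + noise, spacing = sp, origin = origin,
              frame_id = frame_id)
  }
  bg_series <- series_set(lapply(seq_len(spec$n_background),
                                 function(s) mk_vol(bg)),
                          "background", spec$mode_tag)
  irr_series <- series_set(lapply(seq_len(spec$n_irradiated),
                                  function(s) mk_vol(irr)),
                           "irradiated", spec$mode_tag)

  structure(list(
    background = bg_series,
    irradiated = irr_series,
    truth = list(
      true_lines = true_lines,
      true_isocenter = spec$target_point,
      marker_centers = marker_centers,
      reference_point = reference_point,
      background_field = ct_volume(bg, sp, origin, frame_id),
      track_field = ct_volume(track, sp, origin, frame_id)),
    spec = spec), class = "phantom_sim")
}

# Reference point: intersection of the line through the 90 and 270 degree
# markers with the perpendicular through the 0 degree marker (equivalently
# the orthogonal projection of the 0-degree marker onto that line), in the
# marker transversal plane.
.marker_reference <- function(centers, angles) {
  m0 <- centers[angles == 0, ]
  m90 <- centers[angles == 90, ]
  m270 <- centers[angles == 270, ]
  a <- c(m90[1], m90[3]); b <- c(m270[1], m270[3]); p <- c(m0[1], m0[3])
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  q <- unname(a + t * ab)
  c(x = q[1], y = mean(centers[, 2]), z = q[2])
}
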