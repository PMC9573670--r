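# Beam-track detection.
#
# 2D star shot: a sinogram sweep (weighted projections over an angle grid)
# finds the track angles — a track parallel to the projection rays gives
# the sharpest peak — then each track's offset comes from the
# intensity-weighted centroid of its projection peak, refined by
# intensity-weighted orthogonal regression over a ribbon around the line
# with the beam-crossing region excluded. 3D: voxels above a robust noise
# threshold are assigned to the nearest planned beam axis through the
# coarse centroid and each axis is the first principal axis of its
# intensity-weighted voxel cloud, iterated.

#' Extract the star-shot analysis plane
#'
#' Mean over a thin slab of transversal (constant-y) slices centred at the
#' requested axial position.
#'
#' @param volume a [ct_volume()] (normally background-subtracted).
#' @param axial_mm slab centre along the rotation/container axis.
#' @param slab number of slices averaged (odd).
#' @return object of class `plane_image`: matrix `values` (rows = v = z,
#'   cols = u = x), coordinate vectors `u`, `v`, and `axial_mm` actually
#'   used.
#' @export
extract_star_plane <- function(volume, axial_mm = 0, slab = 5) {
  co <- voxel_coords(volume)
  j0 <- which.min(abs(co$y - axial_mm))
  h <- (slab - 1) %/% 2
  js <- max(1, j0 - h):min(length(co$y), j0 + h)
  sub <- volume$voxels[, js, , drop = FALSE]
  vals <- apply(sub, c(1, 3), mean)
  structure(list(values = vals, u = co$x, v = co$z,
                 axial_mm = mean(co$y[js])),
            class = "plane_image")
}

#' @export
print.plane_image <- function(x, ...) {
  cat(sprintf("<plane_image> %d x %d px at y = %.2f mm\n",
              nrow(x$values), ncol(x$values), x$axial_mm))
  invisible(x)
}

#' Display a star-plane image
#' @param x a `plane_image`.
#' @param ... passed to [graphics::image()].
#' @export
plot.plane_image <- function(x, ...) {
  graphics::image(x$u, x$v, t(x$values), xlab = "u = x [mm]",
                  ylab = "v = z [mm]", useRaster = TRUE, asp = 1, ...)
}

# weighted projection profile at line-direction angle theta (deg):
# bin s = n . (u, v) with n the unit normal
.project_profile <- function(uu, vv, w, theta_deg, h) {
  th <- theta_deg * pi / 180
  s <- -sin(th) * uu + cos(th) * vv
  b <- floor((s - min(s)) / h)
  prof <- rowsum(w, b)
  list(value = as.numeric(prof), s0 = min(s),
       bins = as.numeric(rownames(prof)), s = s)
}

.wpca2 <- function(uu, vv, w) {
  sw <- sum(w)
  mu <- c(sum(w * uu), sum(w * vv)) / sw
  du <- uu - mu[1]; dv <- vv - mu[2]
  C <- matrix(c(sum(w * du * du), sum(w * du * dv),
                sum(w * du * dv), sum(w * dv * dv)), 2, 2) / sw
  e <- eigen(C, symmetric = TRUE)
  list(center = mu, direction = e$vectors[, 1])
}

#' Detect star-shot beam tracks in a plane image
#'
#' @param plane a [extract_star_plane()] result (background-subtracted).
#' @param n_expected number of beams to find.
#' @param angle_hints optional planned line angles (degrees, mod 180); when
#'   given the sinogram sweep is restricted to hint +/- 3 degrees per beam
#'   and the result keeps hint order.
#' @param gap_mm nominal track width, used for ribbon sizes.
#' @param angle_step_deg sinogram angular resolution.
#' @param exclude_center_mm radius around the preliminary crossing point
#'   excluded from the refinement (beams overlap there).
#' @return list of `n_expected` [line2d()] objects.
#' @export
detect_beams_2d <- function(plane, n_expected, angle_hints = NULL,
                            gap_mm = 2, angle_step_deg = 0.25,
                            exclude_center_mm = 5) {
  vals <- plane$values
  ni <- nrow(vals); nk <- ncol(vals)
  sigma <- mad(vals)
  if (max(vals) < max(6 * sigma, 1e-9))
    err_detection(sprintf(
      "no beam tracks above the noise floor (found 0 of %d)", n_expected))
  uu_all <- rep(plane$u, each = ni)
  vv_all <- rep(plane$v, times = nk)
  w_all <- as.vector(vals)
  keep <- w_all > 3 * sigma
  uu <- uu_all[keep]; vv <- vv_all[keep]; w <- w_all[keep]
  h <- mean(c(diff(plane$u)[1], diff(plane$v)[1]))

  sharp <- function(th) max(.project_profile(uu, vv, w, th, h)$value)

  if (!is.null(angle_hints)) {
    if (length(angle_hints) != n_expected)
      err_usage("angle_hints must have one angle per expected beam")
    angles <- vapply(angle_hints, function(a0) {
      grid <- (a0 + seq(-3, 3, by = angle_step_deg)) %% 180
      grid[which.max(vapply(grid, sharp, 0))]
    }, 0)
  } else {
    grid <- seq(0, 180 - 1, by = 1)
    sv <- vapply(grid, sharp, 0)
    ord <- order(sv, decreasing = TRUE)
    picked <- numeric(0)
    floor_level <- median(sv) + 3 * mad(sv)
    for (idx in ord) {
      if (sv[idx] <= floor_level) break
      a <- grid[idx]
      sep <- vapply(picked, function(p) {
        d <- abs(a - p) %% 180; min(d, 180 - d)
      }, 0)
      if (all(sep >= 5)) picked <- c(picked, a)
      if (length(picked) == n_expected) break
    }
    if (length(picked) < n_expected)
      err_detection(sprintf("found %d of %d beam angles above noise floor",
                            length(picked), n_expected))
    angles <- vapply(picked, function(a0) {
      fine <- (a0 + seq(-1.5, 1.5, by = angle_step_deg)) %% 180
      fine[which.max(vapply(fine, sharp, 0))]
    }, 0)
  }

  coarse <- lapply(angles, function(th) {
    pr <- .project_profile(uu, vv, w, th, h)
    pk <- which.max(pr$value)
    s_pk <- pr$s0 + (pr$bins[pk] + 0.5) * h
    win <- abs(pr$s - s_pk) <= 3 * gap_mm
    c_off <- sum(w[win] * pr$s[win]) / sum(w[win])
    line2d_from_point_angle(
      c(-sin(th * pi / 180), cos(th * pi / 180)) * c_off, th,
      axial_mm = plane$axial_mm)
  })

  # preliminary crossing point for the central exclusion
  prelim <- tryCatch(fit_isocenter_2d(coarse)$center,
                     error = function(e) c(sum(w * uu), sum(w * vv)) / sum(w))

  refined <- vector("list", length(coarse))
  for (b in seq_along(coarse)) {
    l <- coarse[[b]]
    d_self <- abs(line2d_distance(l, cbind(uu, vv)))
    sel <- d_self <= 3 * gap_mm
    r_c <- sqrt((uu - prelim[1])^2 + (vv - prelim[2])^2)
    sel <- sel & r_c > exclude_center_mm
    for (ob in seq_along(coarse)) {
      if (ob == b) next
      sel <- sel & abs(line2d_distance(coarse[[ob]], cbind(uu, vv))) >
        1.25 * gap_mm
    }
    if (sum(sel) < 20) { refined[[b]] <- l; next }
    fit <- .wpca2(uu[sel], vv[sel], w[sel])
    n2 <- c(-fit$direction[2], fit$direction[1])
    refined[[b]] <- line2d(n2[1], n2[2], sum(n2 * fit$center),
                           axial_mm = plane$axial_mm)
  }
  refined
}

.wpca3 <- function(P, w) {
  sw <- sum(w)
  mu <- colSums(P * w) / sw
  rel <- sweep(P, 2L, mu)
  C <- crossprod(rel * sqrt(w)) / sw
  e <- eigen(C, symmetric = TRUE)
  list(center = mu, direction = e$vectors[, 1])
}
#' Detect 3D beam tracks guided by the planned beam set
#'
#' @param volume background-subtracted [ct_volume()].
#' @param beams list of planned [beam_spec()]s (angles and gaps).
#' @param threshold_k candidate threshold as a multiple of the robust
#'   (MAD-based) noise Std.
#' @param min_voxels minimal candidate-voxel count per beam.
#' @param max_iter re-selection iterations.
#' @return list of [line3d()], one per beam, in beam order.
#' @export
detect_beams_3d <- function(volume, beams, threshold_k = 5,
                            min_voxels = 50, max_iter = 10) {
  dirs <- lapply(beams, function(b) beam_direction(b$gantry_deg, b$couch_deg))
  nb <- length(beams)
  if (nb < 1L) err_usage("no beams given")
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (i < j && abs(sum(dirs[[i]] * dirs[[j]])) > 1 - 1e-8)
      err_usage(sprintf("planned directions of beams %d and %d coincide",
                        i, j))
  }
  vox <- as.vector(volume$voxels)
  sigma <- mad(vox)
  # floor at 2% of the peak so that a noise-free volume does not admit
  # the far erf tails of the penumbra as candidates
  thr <- max(threshold_k * sigma, 0.02 * max(vox), 1e-9)
  cand <- which(vox > thr)
  if (length(cand) == 0L)
    err_detection("no voxels above the detection threshold")
  d <- dim(volume$voxels)
  idx0 <- cand - 1L
  ii <- idx0 %% d[1]
  jj <- (idx0 %/% d[1]) %% d[2]
  kk <- idx0 %/% (d[1] * d[2])
  P <- cbind(x = volume$origin[1] + kk * volume$spacing[3],
             y = volume$origin[2] + jj * volume$spacing[2],
             z = volume$origin[3] + ii * volume$spacing[1])
  w <- vox[cand]
  centroid <- colSums(P * w) / sum(w)

  gaps <- vapply(beams, `[[`, 0, "gap_mm")
  lines <- lapply(seq_len(nb), function(b) line3d(centroid, dirs[[b]]))
  dist_mat <- function(lns) vapply(lns, function(l) line3d_distance(l, P),
                                   numeric(nrow(P)))

  dm <- dist_mat(lines)
  assign <- max.col(-dm)
  assign[dm[cbind(seq_len(nrow(P)), assign)] > 4 * gaps[assign]] <- NA

  for (b in seq_len(nb)) {
    if (sum(assign == b, na.rm = TRUE) < min_voxels)
      err_detection(sprintf("beam %d: fewer than %d candidate voxels",
                            b, min_voxels))
  }

  for (it in seq_len(max_iter)) {
    changed <- FALSE
    dm <- dist_mat(lines)
    for (b in seq_len(nb)) {
      ribbon <- dm[, b] <= 2 * gaps[b]
      good <- ribbon
      for (ob in seq_len(nb))
        if (ob != b) good <- good & dm[, ob] > 1.5 * gaps[ob]
      if (sum(good) < min_voxels) next
      # slab the ribbon along the current axis and drop every slab that
      # (a) touches an exclusion region around another beam, or (b) is an
      # end slab clipped obliquely by the gel/volume boundary: partial
      # slabs have off-axis centroids that would tilt the fitted axis
      t_ax <- as.numeric(P[ribbon, , drop = FALSE] %*% lines[[b]]$direction)
      width <- max(2 * gaps[b], 4 * max(volume$spacing))
      bin <- floor((t_ax - min(t_ax)) / width)
      bad <- unique(bin[!good[ribbon]])
      bad <- c(bad, min(bin), max(bin))
      keep_bin <- !(bin %in% bad)
      sel <- logical(length(good))
      sel[which(ribbon)[keep_bin]] <- TRUE
      sel <- sel & good
      if (sum(sel) < min_voxels) sel <- good
      fit <- .wpca3(P[sel, , drop = FALSE], w[sel])
      dir_new <- fit$direction
      if (sum(dir_new * dirs[[b]]) < 0) dir_new <- -dir_new
      # guard against a degenerate cloud flipping the principal axis
      if (sum(dir_new * dirs[[b]]) < cos(20 * pi / 180)) next
      old <- lines[[b]]
      shift <- line3d_distance(old, fit$center)
      dang <- acos(pmin(abs(sum(dir_new * old$direction)), 1)) * 180 / pi
      lines[[b]] <- line3d(fit$center, dir_new)
      if (shift > 0.01 || dang > 0.01) changed <- TRUE
    }
    if (!changed) break
  }
  lines
}

#' Locate surface fiducial markers and the reference point
#'
#' Finds the brightest blob at the container rim within an angular window
#' around each expected angle, near the requested transversal plane. The
#' reference point is the intersection of the line through the 90 and 270
#' degree markers with the perpendicular through the 0 degree marker.
#'
#' @param volume a [ct_volume()] including markers (e.g. the averaged
#'   irradiated scan, before background subtraction).
#' @param expected_angles marker angles in degrees (0 = top of the
#'   container; a marker at angle a sits at `R*(sin a, cos a)` in (x, z)).
#' @param search_axial_mm marker plane position along the container axis.
#' @param window_deg angular half-window per marker.
#' @param search_halfwidth_mm axial half-window.
#' @return object of class `fiducial_set`: `markers` (matrix with rows
#'   tagged by angle), `reference_point`, `plane_axial_mm`.
#' @export
detect_markers <- function(volume, expected_angles = c(0, 90, 270),
                           search_axial_mm = -1, window_deg = 25,
                           search_halfwidth_mm = 6) {
  co <- voxel_coords(volume)
  fc <- .flat_coords(volume)
  vox <- as.vector(volume$voxels)
  slab <- abs(fc$y - search_axial_mm) <= search_halfwidth_mm
  if (!any(slab)) err_geometry("marker search plane outside the volume")
  body <- slab & vox > -500
  if (!any(body)) err_detection("no container found in the marker plane")
  r <- sqrt(fc$x^2 + fc$z^2)
  r_est <- max(r[body])
  annulus <- slab & r >= 0.8 * r_est
  vmax <- max(vox[annulus])
  if (vmax < 200)
    err_detection("no bright fiducial markers at the container rim")
  thr <- 0.5 * vmax
  theta <- (atan2(fc$x, fc$z) * 180 / pi) %% 360
  centers <- matrix(NA_real_, length(expected_angles), 3,
                    dimnames = list(expected_angles, c("x", "y", "z")))
  for (m in seq_along(expected_angles)) {
    dth <- abs(theta - expected_angles[m]) %% 360
    dth <- pmin(dth, 360 - dth)
    sel <- annulus & dth <= window_deg & vox > thr
    if (!any(sel))
      err_detection(sprintf("no marker found near %g degrees",
                            expected_angles[m]))
    wsel <- vox[sel]
    centers[m, ] <- c(sum(wsel * fc$x[sel]), sum(wsel * fc$y[sel]),
                      sum(wsel * fc$z[sel])) / sum(wsel)
  }
  reference <- NULL
  if (all(c(0, 90, 270) %in% expected_angles) &&
      length(expected_angles) == 3L)
    reference <- .marker_reference(centers, expected_angles)
  structure(list(markers = centers,
                 reference_point = reference,
                 plane_axial_mm = mean(centers[, "y"])),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("<fiducial_set>\n")
  print(round(x$markers, 3))
  if (!is.null(x$reference_point))
    cat(sprintf("reference point: (%s) mm\n",
                paste(sprintf("%.3f", x$reference_point), collapse = ", ")))
  invisible(x)
}
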