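# Beam central-axis representations and isocenter fitting.
#
# The star-shot isocenter is the centre of the smallest circle (2D) or
# sphere (3D) touching every beam axis — the Chebyshev centre of the line
# set under max perpendicular distance. The least-squares centre
# (minimising the sum of squared distances) is also reported.

#' 2D line in normal form
#'
#' `a*u + b*v = c` with unit normal `(a, b)`; the signed distance of a
#' point is `a*u + b*v - c`. Coordinates (u, v) are the star-plane in-plane
#' axes (x, z); `axial_mm` records the plane position along the rotation
#' axis.
#'
#' @param a,b,c normal-form coefficients (normalised internally).
#' @param axial_mm star-plane coordinate along the rotation axis.
#' @return list of class `line2d` with fields `a`, `b`, `c`, `angle_deg`
#'   (direction angle mod 180) and `axial_mm`.
#' @export
line2d <- function(a, b, c, axial_mm = NA_real_) {
  nrm <- sqrt(a^2 + b^2)
  if (nrm < 1e-12) err_usage("degenerate line normal")
  a <- a / nrm; b <- b / nrm; c <- c / nrm
  ang <- atan2(a, -b) * 180 / pi   # direction (-b, a)
  structure(list(a = a, b = b, c = c,
                 angle_deg = ang %% 180, axial_mm = axial_mm),
            class = "line2d")
}

#' @rdname line2d
#' @param point length-2 point (u, v) on the line.
#' @param angle_deg direction angle in degrees.
#' @export
line2d_from_point_angle <- function(point, angle_deg, axial_mm = NA_real_) {
  th <- angle_deg * pi / 180
  n <- c(-sin(th), cos(th))
  line2d(n[1], n[2], sum(n * point), axial_mm)
}

#' Signed point-line distance in 2D
#' @param line a [line2d()].
#' @param uv length-2 point or n x 2 matrix.
#' @return signed distance(s).
#' @export
line2d_distance <- function(line, uv) {
  uv <- rbind(uv)
  line$a * uv[, 1] + line$b * uv[, 2] - line$c
}

#' 3D line through a point with a unit direction
#'
#' @param point mm point on the line.
#' @param direction direction vector (normalised internally).
#' @return list of class `line3d`.
#' @export
line3d <- function(point, direction) {
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) err_usage("degenerate line direction")
  structure(list(point = as.numeric(point),
                 direction = as.numeric(direction) / nrm),
            class = "line3d")
}

#' Perpendicular point-line distance in 3D
#' @param line a [line3d()].
#' @param x mm point or n x 3 matrix.
#' @return distance(s) `||(I - dd')(x - p)||`.
#' @export
line3d_distance <- function(line, x) {
  x <- rbind(x)
  rel <- sweep(x, 2L, line$point)
  t_ax <- as.numeric(rel %*% line$direction)
  sqrt(pmax(rowSums(rel^2) - t_ax^2, 0))
}

.iso_result <- function(dim, center, lines, reference, ls_center,
                        tg142_mm = 1, mpc_mm = 0.5, axial_mm = NA_real_) {
  center <- as.numeric(center)
  ls_center <- as.numeric(ls_center)
  distfun <- if (dim == 2L) {
    function(l) abs(line2d_distance(l, center))
  } else {
    function(l) line3d_distance(l, center)
  }
  per_beam <- vapply(lines, distfun, 0)
  radius <- max(per_beam)
  offset_vector <- offset_mm <- NULL
  if (!is.null(reference)) {
    offset_vector <- center - reference[seq_len(dim)]
    offset_mm <- sqrt(sum(offset_vector^2))
  }
  structure(list(
    dim = dim,
    center = center,
    radius_mm = radius,
    ls_center = ls_center,
    per_beam = tibble::tibble(beam = seq_along(lines),
                              distance_mm = per_beam),
    reference = reference,
    offset_vector = offset_vector,
    offset_mm = offset_mm,
    axial_mm = axial_mm,
    tolerances = list(tg142_mm = tg142_mm, mpc_mm = mpc_mm),
    verdicts = list(
      tg142 = radius <= tg142_mm,
      mpc_style = if (is.null(offset_mm)) NA else offset_mm <= mpc_mm)),
    class = "isocenter_fit")
}

#' @export
print.isocenter_fit <- function(x, ...) {
  cat(sprintf("<isocenter_fit %dD> centre (%s) mm, radius %.4f mm\n",
              x$dim, paste(sprintf("%.3f", x$center), collapse = ", "),
              x$radius_mm))
  if (!is.null(x$offset_mm))
    cat(sprintf("  offset vs reference: %.4f mm\n", x$offset_mm))
  cat(sprintf("  TG-142 (radius <= %g mm): %s", x$tolerances$tg142_mm,
              if (x$verdicts$tg142) "PASS" else "FAIL"))
  if (!is.na(x$verdicts$mpc_style %||% NA))
    cat(sprintf(";  MPC-style (offset <= %g mm): %s",
                x$tolerances$mpc_mm,
                if (isTRUE(x$verdicts$mpc_style)) "PASS" else "FAIL"))
  cat("\n")
  invisible(x)
}

#' Smallest circle touching all beam lines (2D star shot)
#'
#' Solves `min_x max_i |a_i u + b_i v - c_i|` exactly as a linear program
#' (minimise r subject to `-r <= a_i u + b_i v - c_i <= r`) by enumerating
#' the basic solutions: every optimum of this 3-variable LP is determined
#' by three active constraints, so all feasible triples are solved and the
#' best kept. Exact to numerical precision for the handful of beams a star
#' shot uses.
#'
#' @param lines list of >= 2 non-parallel [line2d()].
#' @param reference optional reference point (u, v) for the offset (e.g.
#'   from fiducial markers).
#' @param tg142_mm,mpc_mm tolerance levels for the verdicts.
#' @return an `isocenter_fit` with `center`, min-max `radius_mm`,
#'   least-squares centre, per-beam distances, offset and verdicts.
#' @export
fit_isocenter_2d <- function(lines, reference = NULL, tg142_mm = 1,
                             mpc_mm = 0.5) {
  n <- length(lines)
  if (n < 2L) err_usage("need at least two lines")
  A <- t(vapply(lines, function(l) c(l$a, l$b), numeric(2)))
  cc <- vapply(lines, `[[`, 0, "c")
  # parallel check: all normals colinear?
  cross <- outer(A[, 1], A[, 2]) - outer(A[, 2], A[, 1])
  if (max(abs(cross)) < 1e-9)
    err_geometry("all lines are parallel; isocenter undefined")

  # LP rows: s*(a u + b v) - r <= s*c, s = +/-1
  rows <- rbind(cbind(A, -1, cc), cbind(-A, -1, -cc))
  m <- nrow(rows)
  best <- NULL
  combs <- utils::combn(m, 3L)
  for (ci in seq_len(ncol(combs))) {
    sel <- combs[, ci]
    M <- rows[sel, 1:3, drop = FALSE]
    rhs <- rows[sel, 4]
    det3 <- det(M)
    if (abs(det3) < 1e-10) next
    sol <- solve(M, rhs)
    if (sol[3] < -1e-9) next
    resid <- rows[, 1:3] %*% sol - rows[, 4]
    if (max(resid) > 1e-7) next
    if (is.null(best) || sol[3] < best[3]) best <- sol
  }
  if (is.null(best)) err_geometry("isocenter LP has no bounded optimum")
  center <- as.numeric(best[1:2])

  # least-squares centre from the normal equations sum(n n') x = sum(c n)
  G <- t(A) %*% A
  ls_center <- as.numeric(solve(G, t(A) %*% cc))

  axial <- stats::na.omit(vapply(lines, `[[`, 0, "axial_mm"))
  .iso_result(2L, center, lines, reference, ls_center,
              tg142_mm, mpc_mm,
              axial_mm = if (length(axial)) mean(axial) else NA_real_)
}

# max distance to a set of 3D lines
.max_dist3 <- function(lines, x) {
  max(vapply(lines, function(l) line3d_distance(l, x), 0))
}

# Minimise the max line distance: Nelder-Mead restarts seeded at the
# least-squares centre, then a 26-direction pattern-search polish for the
# non-smooth tail. The objective is convex (max of convex distances).
.minimax_lines3d <- function(lines, start) {
  f <- function(x) .max_dist3(lines, x)
  best <- start; fb <- f(start)
  for (scale in c(1, 1e-2, 1e-4)) {
    o <- optim(best, f, method = "Nelder-Mead",
               control = list(reltol = 1e-16, maxit = 4000,
                              alpha = 1, beta = 0.5, gamma = 2))
    if (o$value < fb) { best <- o$par; fb <- o$value }
  }
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  step <- 1e-2
  while (step > 1e-10) {
    improved <- FALSE
    for (r in seq_len(nrow(dirs))) {
      cand <- best + step * dirs[r, ]
      fc <- f(cand)
      if (fc < fb) { best <- cand; fb <- fc; improved <- TRUE }
    }
    if (!improved) step <- step / 2
  }
  list(par = best, value = fb)
}

#' Smallest sphere touching all beam axes (3D isocenter)
#'
#' The least-squares centre solves the closed-form normal equations
#' `sum_i (I - d_i d_i')(x - p_i) = 0`; the reported centre minimises the
#' maximum perpendicular distance (Chebyshev centre), found by convex
#' minimisation seeded at the least-squares solution.
#'
#' @param lines list of >= 2 non-parallel [line3d()].
#' @param reference optional mm reference point for the offset.
#' @param tg142_mm,mpc_mm tolerance levels for the verdicts.
#' @return an `isocenter_fit`.
#' @export
fit_isocenter_3d <- function(lines, reference = NULL, tg142_mm = 1,
                             mpc_mm = 0.5) {
  n <- length(lines)
  if (n < 2L) err_usage("need at least two lines")
  A <- matrix(0, 3, 3); b <- numeric(3)
  for (l in lines) {
    P <- diag(3) - tcrossprod(l$direction)
    A <- A + P
    b <- b + P %*% l$point
  }
  if (rcond(A) < 1e-10)
    err_geometry("all lines are parallel; isocenter undefined")
  ls_center <- as.numeric(solve(A, b))
  opt <- .minimax_lines3d(lines, ls_center)
  .iso_result(3L, opt$par, lines, reference, ls_center, tg142_mm, mpc_mm)
}
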