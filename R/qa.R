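# QA metrics: VOI statistics, Catphan-style image uniformity (peripheral
# minus centre VOI means against a +/-30 HU criterion), profile extraction,
# and the tube-heating-aware scan scheduler.

#' Cylindrical volume of interest
#'
#' @param center mm point (x, y, z) of the cylinder centre.
#' @param diameter_mm,length_mm cylinder dimensions, > 0.
#' @param axis unit axis vector; default along the volume y axis (the
#'   container/scan axis).
#' @return list of class `voi_cylinder`.
#' @export
voi_cylinder <- function(center, diameter_mm = 20, length_mm = 20,
                         axis = c(0, 1, 0)) {
  if (diameter_mm <= 0 || length_mm <= 0)
    err_usage("VOI diameter and length must be > 0")
  axis <- axis / sqrt(sum(axis^2))
  structure(list(center = as.numeric(center), diameter_mm = diameter_mm,
                 length_mm = length_mm, axis = axis),
            class = "voi_cylinder")
}

# flattened voxel-centre coordinates of a volume (index order i fastest)
.flat_coords <- function(volume) {
  co <- voxel_coords(volume)
  ni <- length(co$z); nj <- length(co$y); nk <- length(co$x)
  list(x = rep(co$x, each = ni * nj),
       y = rep(rep(co$y, each = ni), times = nk),
       z = rep(co$z, times = nj * nk))
}

#' Mean, Std and voxel count over a cylindrical VOI
#'
#' Statistics run over voxels whose centres lie inside the cylinder; the
#' Std is the sample standard deviation. The VOI must lie entirely inside
#' the volume.
#'
#' @param volume a [ct_volume()].
#' @param voi a [voi_cylinder()].
#' @return list with `mean`, `std`, `n_voxels`.
#' @export
voi_stats <- function(volume, voi) {
  co <- voxel_coords(volume)
  # bounding check: cylinder must fit inside the voxel-centre hull
  half <- voi$length_mm / 2; rad <- voi$diameter_mm / 2
  reach <- abs(voi$axis) * half +
    sqrt(pmax(1 - voi$axis^2, 0)) * rad   # per-axis extent of the cylinder
  lo <- voi$center - reach; hi <- voi$center + reach
  bounds <- rbind(range(co$x), range(co$y), range(co$z))
  if (any(lo < bounds[, 1] - 1e-9) || any(hi > bounds[, 2] + 1e-9))
    err_geometry("VOI extends outside the volume")
  fc <- .flat_coords(volume)
  rel <- cbind(fc$x - voi$center[1], fc$y - voi$center[2],
               fc$z - voi$center[3])
  t_ax <- rel %*% voi$axis
  r2 <- rowSums(rel^2) - t_ax^2
  inside <- abs(t_ax) <= half & r2 <= rad^2
  n <- sum(inside)
  if (n == 0L) err_geometry("VOI contains no voxel centres")
  vals <- as.vector(volume$voxels)[inside]
  list(mean = mean(vals), std = sd(vals), n_voxels = n)
}

#' Image-uniformity arithmetic from five positional VOI means
#'
#' Implements the installation-product-acceptance (IPA) uniformity metric:
#' each peripheral VOI mean (left, top, right, bottom) minus the centre VOI
#' mean, the mean of the four differences per series, and the mean of that
#' across series. The pass criterion is |difference| <= `criterion_hu`.
#' The arithmetic is exact on the supplied means; rounding to 2 dp (halves
#' away from zero) is applied only for display.
#'
#' @param means data frame with columns `center`, `left`, `top`, `right`,
#'   `bottom`, one row per series (an optional `series` column labels
#'   them).
#' @param criterion_hu pass/fail threshold in HU (default 30).
#' @return object of class `uniformity_report`: `per_series` tibble with
#'   the four diffs, `mean_of_four` and verdicts; `series_mean`; `pass`.
#' @export
uniformity_ipa <- function(means, criterion_hu = 30) {
  need <- c("center", "left", "top", "right", "bottom")
  if (!all(need %in% names(means)))
    err_usage(sprintf("missing position column(s): %s",
                      paste(setdiff(need, names(means)), collapse = ", ")))
  if (nrow(as.data.frame(means)) == 0L) err_usage("no series rows supplied")
  m <- as.data.frame(means)
  if (any(!is.finite(as.matrix(m[need])))) err_usage("non-finite VOI mean")
  diffs <- data.frame(left = m$left - m$center,
                      top = m$top - m$center,
                      right = m$right - m$center,
                      bottom = m$bottom - m$center)
  mean4 <- rowMeans(diffs)
  per <- tibble::tibble(
    series = if ("series" %in% names(m)) m$series else seq_len(nrow(m)),
    center = m$center, left = m$left, top = m$top, right = m$right,
    bottom = m$bottom,
    diff_left = diffs$left, diff_top = diffs$top,
    diff_right = diffs$right, diff_bottom = diffs$bottom,
    mean_of_four = mean4,
    pass = apply(abs(diffs) <= criterion_hu, 1L, all))
  structure(list(per_series = per,
                 series_mean = mean(mean4),
                 criterion_hu = criterion_hu,
                 max_abs_diff = max(abs(as.matrix(diffs))),
                 pass = all(per$pass)),
            class = "uniformity_report")
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf("<uniformity_report> %d series, criterion +/- %g HU: %s\n",
              nrow(x$per_series), x$criterion_hu,
              if (x$pass) "PASS" else "FAIL"))
  disp <- x$per_series
  num <- vapply(disp, is.numeric, TRUE)
  disp[num] <- lapply(disp[num], round_half_away)
  print(disp)
  cat(sprintf("series mean of Mean(1-4): %.2f HU (max |diff| %.2f HU)\n",
              round_half_away(x$series_mean), x$max_abs_diff))
  invisible(x)
}

#' Sample a straight-line HU profile through a volume
#'
#' Trilinear interpolation at uniform steps from `p0` to `p1`, optionally
#' smoothed with a 1D mean filter (reflect padding).
#'
#' @param volume a [ct_volume()].
#' @param p0,p1 mm endpoints (x, y, z), both inside the volume.
#' @param step_mm sampling step; default half the smallest spacing.
#' @param smooth optional odd kernel size of a 1D mean smoother.
#' @return tibble with columns `s_mm` (distance from `p0`) and `hu`.
#' @export
extract_profile <- function(volume, p0, p1, step_mm = NULL, smooth = NULL) {
  co <- voxel_coords(volume)
  bounds <- rbind(range(co$x), range(co$y), range(co$z))
  for (p in list(p0, p1))
    if (any(p < bounds[, 1] - 1e-9) || any(p > bounds[, 2] + 1e-9))
      err_geometry("profile endpoint outside the volume")
  if (is.null(step_mm)) step_mm <- min(volume$spacing) / 2
  len <- sqrt(sum((p1 - p0)^2))
  s <- seq(0, len, by = step_mm)
  dirv <- if (len > 0) (p1 - p0) / len else c(0, 0, 0)
  pts <- cbind(p0[1] + s * dirv[1], p0[2] + s * dirv[2], p0[3] + s * dirv[3])
  vals <- .trilinear(volume, pts)
  if (!is.null(smooth)) {
    if (smooth %% 2 != 1 || smooth < 1) err_usage("smooth kernel must be odd")
    h <- (smooth - 1) / 2
    n <- length(vals)
    if (h > 0 && n > h) {
      padded <- c(vals[(h + 1):2], vals, vals[(n - 1):(n - h)])
      vals <- as.numeric(stats::filter(padded, rep(1 / smooth, smooth),
                                       sides = 2))[(h + 1):(h + n)]
    }
  }
  tibble::tibble(s_mm = s, hu = vals)
}

# trilinear interpolation of (n x 3) mm points
.trilinear <- function(volume, pts) {
  co <- voxel_coords(volume)
  d <- dim(volume$voxels)
  fi <- (pts[, 3] - volume$origin[3]) / volume$spacing[1]  # z -> slice
  fj <- (pts[, 2] - volume$origin[2]) / volume$spacing[2]  # y -> row
  fk <- (pts[, 1] - volume$origin[1]) / volume$spacing[3]  # x -> col
  clamp <- function(f, n) pmin(pmax(f, 0), n - 1)
  fi <- clamp(fi, d[1]); fj <- clamp(fj, d[2]); fk <- clamp(fk, d[3])
  i0 <- pmin(floor(fi), d[1] - 2); j0 <- pmin(floor(fj), d[2] - 2)
  k0 <- pmin(floor(fk), d[3] - 2)
  i0 <- pmax(i0, 0); j0 <- pmax(j0, 0); k0 <- pmax(k0, 0)
  wi <- fi - i0; wj <- fj - j0; wk <- fk - k0
  at <- function(di, dj, dk)
    volume$voxels[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  (1 - wi) * ((1 - wj) * ((1 - wk) * at(0, 0, 0) + wk * at(0, 0, 1)) +
                wj * ((1 - wk) * at(0, 1, 0) + wk * at(0, 1, 1))) +
    wi * ((1 - wj) * ((1 - wk) * at(1, 0, 0) + wk * at(1, 0, 1)) +
            wj * ((1 - wk) * at(1, 1, 0) + wk * at(1, 1, 1)))
}

#' Scan schedule respecting X-ray tube heating
#'
#' TrueBeam tolerates up to five consecutive scans with no gap. The Halcyon
#' tube overheats after two consecutive scans, so only the first gap may be
#' zero; every further scan needs a cooling gap of 5 min (Pelvis modes) or
#' 6 min (Pelvis Large modes).
#'
#' @param accelerator `"TrueBeam"` or `"Halcyon"`.
#' @param mode acquisition mode name.
#' @param n_scans number of consecutive scans, >= 1. More than five is
#'   outside the validated range and flagged with a warning.
#' @return object of class `scan_schedule` with `gaps_min` (length
#'   `n_scans - 1`) and `beyond_tested`.
#' @export
schedule_scans <- function(accelerator = c("TrueBeam", "Halcyon"), mode,
                           n_scans) {
  accelerator <- match.arg(accelerator)
  if (n_scans < 1) err_usage("n_scans must be >= 1")
  beyond <- n_scans > 5
  if (beyond)
    warning(sprintf("%d scans exceeds the validated range of 5", n_scans))
  n_gaps <- n_scans - 1
  if (accelerator == "TrueBeam") {
    gaps <- rep(0, n_gaps)
  } else {
    cool <- if (grepl("Large", mode, ignore.case = TRUE)) 6 else 5
    gaps <- if (n_gaps >= 1) c(0, rep(cool, max(n_gaps - 1, 0))) else numeric(0)
  }
  structure(list(accelerator = accelerator, mode = mode, n_scans = n_scans,
                 gaps_min = gaps, beyond_tested = beyond),
            class = "scan_schedule")
}

#' @export
print.scan_schedule <- function(x, ...) {
  cat(sprintf("<scan_schedule> %s %s: %d scan(s), gaps [%s] min%s\n",
              x$accelerator, x$mode, x$n_scans,
              paste(x$gaps_min, collapse = ", "),
              if (x$beyond_tested) " (beyond validated range)" else ""))
  invisible(x)
}
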