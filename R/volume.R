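# CT volume container and coordinate frame.
#
# A ct_volume stores Hounsfield units on a regular grid. Array index order is
# (i, j, k) = (slice, row, col) and the voxel-centre world map is affine:
#
#   mm(i, j, k) = origin + (k * sx, j * sy, i * sz)   (x, y, z order, 0-based)
#
# so columns run along x, rows along y and slices along z. The frame is
# right-handed with x lateral (+x to the right facing the gantry), y along
# the couch toward the gantry and z vertical up. Phantom containers lie with
# their long axis along y (the gantry rotation axis), so the star-shot plane
# is a plane of constant y.

#' Construct a CT volume
#'
#' @param voxels 3D numeric array of HU, dimension order slice x row x col.
#' @param spacing numeric length-3, mm per axis in array-dim order
#'   `c(sz, sy, sx)`; all components must be > 0.
#' @param origin numeric length-3, mm world position `c(x, y, z)` of the
#'   centre of voxel (0, 0, 0).
#' @param frame_id opaque geometry token; two volumes are co-registered only
#'   if shapes, spacings, origins and `frame_id` all match.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      frame_id = "frame-0") {
  if (length(dim(voxels)) != 3L) err_usage("voxels must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    err_geometry("all spacing components must be finite and > 0")
  if (length(origin) != 3L || any(!is.finite(origin)))
    err_geometry("origin must be a finite length-3 mm point")
  if (any(!is.finite(voxels))) err_usage("voxels must be finite")
  structure(
    list(voxels = voxels,
         spacing = as.numeric(spacing),
         origin = as.numeric(origin),
         frame_id = as.character(frame_id)),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (slice x row x col)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing (sz, sy, sx): %s mm\n",
              paste(signif(x$spacing, 6), collapse = ", ")))
  cat(sprintf("  origin  (x, y, z):    %s mm\n",
              paste(signif(x$origin, 6), collapse = ", ")))
  cat(sprintf("  frame_id: %s  HU range: [%.1f, %.1f]\n", x$frame_id,
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Voxel-centre coordinates of a volume
#'
#' @param volume a `ct_volume`.
#' @return list with mm coordinate vectors `x` (along cols), `y` (rows),
#'   `z` (slices).
#' @export
voxel_coords <- function(volume) {
  d <- dim(volume$voxels)
  list(x = volume$origin[1] + (seq_len(d[3]) - 1) * volume$spacing[3],
       y = volume$origin[2] + (seq_len(d[2]) - 1) * volume$spacing[2],
       z = volume$origin[3] + (seq_len(d[1]) - 1) * volume$spacing[1])
}

#' Map voxel indices to mm
#'
#' @param volume a `ct_volume`.
#' @param ijk matrix (n x 3) or length-3 vector of 0-based (slice, row, col)
#'   indices.
#' @return n x 3 matrix of (x, y, z) mm positions of the voxel centres.
#' @export
voxel_to_mm <- function(volume, ijk) {
  ijk <- rbind(ijk)
  cbind(x = volume$origin[1] + ijk[, 3] * volume$spacing[3],
        y = volume$origin[2] + ijk[, 2] * volume$spacing[2],
        z = volume$origin[3] + ijk[, 1] * volume$spacing[1])
}

#' Assert that two volumes are co-registered
#'
#' Co-registration means identical shape, spacing, origin and `frame_id`.
#' Background subtraction and series averaging require it.
#'
#' @param a,b `ct_volume` objects.
#' @param tol mm tolerance on spacing/origin comparison.
#' @return invisibly `TRUE`; signals a geometry error naming the differing
#'   field otherwise.
#' @export
assert_coregistered <- function(a, b, tol = 1e-6) {
  if (!inherits(a, "ct_volume") || !inherits(b, "ct_volume"))
    err_usage("assert_coregistered() expects two ct_volume objects")
  if (!identical(dim(a$voxels), dim(b$voxels)))
    err_geometry("co-registration failure: shape differs")
  if (any(abs(a$spacing - b$spacing) > tol))
    err_geometry("co-registration failure: spacing differs")
  if (any(abs(a$origin - b$origin) > tol))
    err_geometry("co-registration failure: origin differs")
  if (!identical(a$frame_id, b$frame_id))
    err_geometry("co-registration failure: frame_id differs")
  invisible(TRUE)
}

#' Construct an ordered set of co-registered scan series
#'
#' @param volumes list of `ct_volume`, length >= 1, all co-registered.
#' @param label `"background"` or `"irradiated"`.
#' @param mode_tag accelerator+mode string, e.g. `"TrueBeam iCBCT Pelvis"`.
#' @return object of class `series_set`.
#' @export
series_set <- function(volumes, label = c("background", "irradiated"),
                       mode_tag = "") {
  label <- match.arg(label)
  if (!is.list(volumes) || length(volumes) < 1L)
    err_usage("series_set needs at least one volume")
  for (v in volumes[-1]) assert_coregistered(volumes[[1]], v)
  structure(list(volumes = volumes, label = label, mode_tag = mode_tag),
            class = "series_set")
}

#' @export
print.series_set <- function(x, ...) {
  cat(sprintf("<series_set> %d %s series [%s]\n",
              length(x$volumes), x$label, x$mode_tag))
  invisible(x)
}

#' @export
length.series_set <- function(x) length(x$volumes)
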