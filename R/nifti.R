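# Portable research volume format (NIfTI-1 with affine metadata), used for
# fixtures and intermediates. Data are written as float64 so HU round-trip
# to well below 1e-3.

#' Write a CT volume to a NIfTI file
#'
#' The array is stored x-fastest with an affine carrying spacing and origin,
#' so `read_volume(write_volume(v))` is co-registered with `v` (given the
#' same `frame_id`) and voxelwise equal to numerical precision.
#'
#' @param volume a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "ct_volume")) err_usage("write_volume() needs a ct_volume")
  if (!dir.exists(dirname(path))) err_io(sprintf("unwritable path '%s'", path))
  arr <- aperm(volume$voxels, c(3, 2, 1))       # (x, y, z) fastest-first
  affine <- diag(4)
  affine[1, 1] <- volume$spacing[3]
  affine[2, 2] <- volume$spacing[2]
  affine[3, 3] <- volume$spacing[1]
  affine[1:3, 4] <- volume$origin
  im <- RNifti::asNifti(arr, datatype = "double")
  im <- RNifti::`sform<-`(im, structure(affine, code = 2L))
  out <- tryCatch(RNifti::writeNifti(im, path, datatype = "double"),
                  error = function(e) err_io(conditionMessage(e)))
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path NIfTI file path.
#' @param frame_id geometry token to stamp on the result; volumes from the
#'   same session must be read back with the same token to count as
#'   co-registered.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, frame_id = "frame-0") {
  if (!file.exists(path)) err_io(sprintf("no file '%s'", path))
  im <- RNifti::readNifti(path)
  affine <- RNifti::xform(im)
  if (max(abs(affine[1:3, 1:3] - diag(diag(affine[1:3, 1:3])))) > 1e-6)
    err_geometry("only axis-aligned NIfTI volumes are supported")
  sp <- diag(affine[1:3, 1:3])
  if (any(sp <= 0)) err_geometry("negative or zero spacing in NIfTI affine")
  arr <- as.array(im)
  if (length(dim(arr)) != 3L) err_format("expected a 3D NIfTI volume")
  ct_volume(aperm(arr, c(3, 2, 1)),
            spacing = c(sp[3], sp[2], sp[1]),
            origin = affine[1:3, 4],
            frame_id = frame_id)
}
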