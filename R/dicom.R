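# Minimal single-frame CT DICOM reader/writer.
#
# Scope: uncompressed little-endian transfer syntaxes (explicit VR
# 1.2.840.10008.1.2.1 and implicit VR 1.2.840.10008.1.2), single-frame
# grayscale CT slices with axis-aligned orientation (1,0,0,0,1,0), one
# series per directory. This covers what linac CBCT exports look like after
# anonymised transfer and, importantly, what the package's own fixture
# writer emits. Multi-frame/enhanced DICOM and sequences are out of scope.

.dcm_ts_explicit <- "1.2.840.10008.1.2.1"
.dcm_ts_implicit <- "1.2.840.10008.1.2"
.dcm_ct_sop      <- "1.2.840.10008.5.1.4.1.1.2"

.u16le <- function(x) as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
.u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}
.r_u16 <- function(raw, at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
.r_u32 <- function(raw, at) {
  as.numeric(raw[at]) + 256 * as.numeric(raw[at + 1L]) +
    65536 * as.numeric(raw[at + 2L]) + 16777216 * as.numeric(raw[at + 3L])
}

# pad a string value to even length; UI pads with NUL, text with space
.dcm_pad <- function(s, vr) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L)
    r <- c(r, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  r
}

.dcm_elem <- function(group, element, vr, value) {
  if (is.character(value)) value <- .dcm_pad(value, vr)
  long_vr <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  c(.u16le(group), .u16le(element), charToRaw(vr),
    if (long_vr) c(as.raw(c(0L, 0L)), .u32le(length(value)))
    else .u16le(length(value)),
    value)
}

.dcm_us <- function(group, element, x) .dcm_elem(group, element, "US", .u16le(x))

.gs_uid_counter <- local({ n <- 0L; function() { n <<- n + 1L; n } })
.dcm_uid <- function() {
  sprintf("1.2.826.0.1.3680043.10.511.%d.%d.%d",
          as.integer(Sys.time()) %% 1000000L, Sys.getpid() %% 100000L,
          .gs_uid_counter())
}

#' Write a CT volume as a single-frame DICOM series
#'
#' One explicit-VR little-endian file per slice, axis-aligned orientation.
#' Stored values are `round((HU - intercept) / slope)` as signed 16-bit
#' integers, so integer HU with the default rescale round-trips exactly.
#'
#' @param volume a [ct_volume()].
#' @param directory output directory (created if needed).
#' @param slope,intercept rescale mapping `HU = stored * slope + intercept`.
#' @param series_uid,frame_uid optional UIDs; generated when `NULL`. Volumes
#'   written with the same `frame_uid` read back as co-registered.
#' @return invisibly, the vector of files written.
#' @export
write_dicom_series <- function(volume, directory, slope = 1,
                               intercept = -1024, series_uid = NULL,
                               frame_uid = NULL) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    err_io(sprintf("cannot create directory '%s'", directory))
  d <- dim(volume$voxels)
  if (is.null(series_uid)) series_uid <- .dcm_uid()
  if (is.null(frame_uid)) frame_uid <- .dcm_uid()
  study_uid <- .dcm_uid()
  dsfmt <- function(x) sub("0+$", "", sub("\\.$", "", sprintf("%.8f", x)))
  files <- character(d[1])
  for (i in seq_len(d[1])) {
    sop_uid <- .dcm_uid()
    ipp <- c(volume$origin[1], volume$origin[2],
             volume$origin[3] + (i - 1) * volume$spacing[1])
    slice <- volume$voxels[i, , , drop = TRUE]
    if (is.null(dim(slice))) slice <- matrix(slice, nrow = d[2])
    stored <- round((slice - intercept) / slope)
    stored <- pmax(pmin(stored, 32767), -32768)
    # DICOM pixel order is row-major: row 1 left-to-right first
    pix <- writeBin(as.integer(t(stored)), raw(), size = 2L,
                    endian = "little")
    meta <- c(
      .dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
      .dcm_elem(0x0002, 0x0002, "UI", .dcm_ct_sop),
      .dcm_elem(0x0002, 0x0003, "UI", sop_uid),
      .dcm_elem(0x0002, 0x0010, "UI", .dcm_ts_explicit),
      .dcm_elem(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.10.511.1"))
    header <- c(as.raw(rep(0L, 128L)), charToRaw("DICM"),
                .dcm_elem(0x0002, 0x0000, "UL", .u32le(length(meta))), meta)
    body <- c(
      .dcm_elem(0x0008, 0x0016, "UI", .dcm_ct_sop),
      .dcm_elem(0x0008, 0x0018, "UI", sop_uid),
      .dcm_elem(0x0008, 0x0060, "CS", "CT"),
      .dcm_elem(0x0020, 0x000D, "UI", study_uid),
      .dcm_elem(0x0020, 0x000E, "UI", series_uid),
      .dcm_elem(0x0020, 0x0013, "IS", as.character(i)),
      .dcm_elem(0x0020, 0x0032, "DS",
                paste(dsfmt(ipp), collapse = "\\")),
      .dcm_elem(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      .dcm_elem(0x0020, 0x0052, "UI", frame_uid),
      .dcm_us(0x0028, 0x0002, 1L),
      .dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcm_us(0x0028, 0x0010, d[2]),
      .dcm_us(0x0028, 0x0011, d[3]),
      .dcm_elem(0x0028, 0x0030, "DS",
                paste(dsfmt(volume$spacing[2:3]), collapse = "\\")),
      .dcm_us(0x0028, 0x0100, 16L),
      .dcm_us(0x0028, 0x0101, 16L),
      .dcm_us(0x0028, 0x0102, 15L),
      .dcm_us(0x0028, 0x0103, 1L),
      .dcm_elem(0x0028, 0x1052, "DS", dsfmt(intercept)),
      .dcm_elem(0x0028, 0x1053, "DS", dsfmt(slope)),
      .dcm_elem(0x7FE0, 0x0010, "OW", pix))
    files[i] <- file.path(directory, sprintf("slice_%04d.dcm", i))
    con <- file(files[i], "wb")
    writeBin(c(header, body), con)
    close(con)
  }
  invisible(files)
}

# Parse one DICOM file into a named list of the elements we use.
.dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    err_format(sprintf("'%s' is not a DICOM part-10 file", path))
  pos <- 133L
  ts <- .dcm_ts_explicit   # file meta group is always explicit VR
  out <- list()
  want <- c("0008,0018", "0020,000D", "0020,000E", "0020,0013", "0020,0032",
            "0020,0037", "0020,0052", "0028,0010", "0028,0011", "0028,0030",
            "0028,0100", "0028,0103", "0028,1052", "0028,1053", "7FE0,0010",
            "0002,0010", "0018,0050")
  repeat {
    if (pos + 7L > length(raw)) break
    group <- .r_u16(raw, pos); element <- .r_u16(raw, pos + 2L)
    in_meta <- group == 0x0002
    use_explicit <- in_meta || identical(ts, .dcm_ts_explicit)
    if (use_explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- .r_u32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- .r_u16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- .r_u32(raw, pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) err_format("undefined-length elements unsupported")
    val_at <- pos + hdr
    key <- sprintf("%04X,%04X", group, element)
    if (key %in% toupper(want)) {
      bytes <- raw[seq.int(val_at, length.out = len)]
      out[[key]] <- bytes
      if (key == "0002,0010")
        ts <- sub("\\x00+$", "", rawToChar(bytes), perl = TRUE)
    }
    pos <- val_at + len
    if (pos > length(raw) + 1L) err_format("truncated DICOM element")
  }
  out[["transfer_syntax"]] <- ts
  out
}

.dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(sub("\\x00+$", "", rawToChar(el), perl = TRUE))
}
.dcm_ds <- function(el) {
  s <- .dcm_str(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.dcm_us_val <- function(el) if (is.null(el)) NULL else .r_u16(el, 1L)

#' Read a single-frame CT DICOM series as a volume
#'
#' Slices are sorted by position along the slice normal;
#' `HU = stored * RescaleSlope + RescaleIntercept`; the origin is the
#' `ImagePositionPatient` of the first sorted slice (voxel-centre
#' convention) and the z spacing comes from the inter-slice distance.
#'
#' @param directory directory containing exactly one CT series.
#' @return a [ct_volume()] whose `frame_id` is derived from the frame of
#'   reference UID (falling back to the series UID).
#' @export
read_dicom_series <- function(directory) {
  if (!dir.exists(directory)) err_io(sprintf("no directory '%s'", directory))
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) err_io(sprintf("no files in '%s'", directory))
  slices <- lapply(files, .dcm_parse_file)

  ts <- unique(vapply(slices, `[[`, "", "transfer_syntax"))
  if (!all(ts %in% c(.dcm_ts_explicit, .dcm_ts_implicit)))
    err_format(sprintf("unsupported transfer syntax: %s",
                       paste(setdiff(ts, c(.dcm_ts_explicit, .dcm_ts_implicit)),
                             collapse = ", ")))
  series <- vapply(slices, function(s) .dcm_str(s[["0020,000E"]]) %||% "", "")
  if (length(unique(series)) != 1L || any(series == ""))
    err_format("mixed or missing series UIDs in directory")

  rows <- unique(vapply(slices, function(s) .dcm_us_val(s[["0028,0010"]]), 0L))
  cols <- unique(vapply(slices, function(s) .dcm_us_val(s[["0028,0011"]]), 0L))
  if (length(rows) != 1L || length(cols) != 1L)
    err_format("inconsistent Rows/Columns across series")
  ps <- unique(vapply(slices,
                      function(s) paste(.dcm_ds(s[["0028,0030"]]), collapse = ","),
                      ""))
  if (length(ps) != 1L || ps == "")
    err_format("inconsistent or missing PixelSpacing")
  pixel_spacing <- as.numeric(strsplit(ps, ",")[[1]])

  iop <- lapply(slices, function(s) .dcm_ds(s[["0020,0037"]]))
  if (any(vapply(iop, is.null, TRUE)))
    err_format("missing ImageOrientationPatient")
  iop_ref <- iop[[1]]
  if (any(vapply(iop, function(o) max(abs(o - iop_ref)) > 1e-6, TRUE)))
    err_format("inconsistent image orientation across series")
  if (max(abs(iop_ref - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    err_geometry("only axis-aligned orientation (1,0,0,0,1,0) is supported")

  has_rescale <- vapply(slices, function(s)
    !is.null(s[["0028,1052"]]) && !is.null(s[["0028,1053"]]), TRUE)
  if (!all(has_rescale)) err_format("missing rescale slope/intercept tags")

  ipp <- t(vapply(slices, function(s) {
    v <- .dcm_ds(s[["0020,0032"]])
    if (is.null(v) || length(v) != 3L) err_format("missing ImagePositionPatient")
    v
  }, numeric(3)))
  normal <- c(iop_ref[2] * iop_ref[6] - iop_ref[3] * iop_ref[5],
              iop_ref[3] * iop_ref[4] - iop_ref[1] * iop_ref[6],
              iop_ref[1] * iop_ref[5] - iop_ref[2] * iop_ref[4])
  pos_along <- as.numeric(ipp %*% normal)
  ord <- order(pos_along)
  slices <- slices[ord]; ipp <- ipp[ord, , drop = FALSE]
  pos_along <- pos_along[ord]

  n <- length(slices)
  if (n >= 2L) {
    gaps <- diff(pos_along)
    gap <- median(gaps)
    if (gap <= 0 || any(abs(gaps - gap) > 0.01 * gap))
      err_geometry("non-uniform slice spacing beyond 1% tolerance")
  } else {
    st <- .dcm_ds(slices[[1]][["0018,0050"]])
    gap <- if (is.null(st)) 1 else st[1]
  }

  vox <- array(0, dim = c(n, rows, cols))
  for (i in seq_len(n)) {
    s <- slices[[i]]
    bits <- .dcm_us_val(s[["0028,0100"]]) %||% 16L
    if (bits != 16L) err_format("only 16-bit pixel data is supported")
    signed <- (.dcm_us_val(s[["0028,0103"]]) %||% 1L) == 1L
    pix <- s[["7FE0,0010"]]
    if (is.null(pix) || length(pix) < 2L * rows * cols)
      err_format("missing or short PixelData")
    stored <- readBin(pix, "integer", n = rows * cols, size = 2L,
                      signed = signed, endian = "little")
    slope <- .dcm_ds(s[["0028,1053"]])[1]
    intercept <- .dcm_ds(s[["0028,1052"]])[1]
    vox[i, , ] <- t(matrix(stored * slope + intercept, nrow = cols))
  }

  frame <- .dcm_str(slices[[1]][["0020,0052"]])
  if (is.null(frame) || frame == "") frame <- series[1]
  ct_volume(vox,
            spacing = c(gap, pixel_spacing[1], pixel_spacing[2]),
            origin = ipp[1, ],
            frame_id = paste0("dicom:", frame))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
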