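# Series averaging, background subtraction, and the image filter bank
# applied (symmetrically to background and irradiated volumes) before
# isocenter detection.
#
# All kernels use reflect padding to avoid rim artifacts inside the
# container. "2D" kernel mode filters each transversal slice (constant-y
# plane, the star-shot view) independently; "3D" filters the whole volume.

#' Voxelwise mean of a series
#'
#' @param series a [series_set()].
#' @param subset indices of the series members to average; default all.
#' @return a [ct_volume()] with the geometry of the first member.
#' @export
average_series <- function(series, subset = NULL) {
  if (!inherits(series, "series_set")) err_usage("need a series_set")
  if (is.null(subset)) subset <- seq_along(series$volumes)
  if (length(subset) == 0L) err_usage("empty series subset")
  if (any(subset < 1L | subset > length(series$volumes)))
    err_usage("series subset out of range")
  vols <- series$volumes[subset]
  for (v in vols[-1]) assert_coregistered(vols[[1]], v)
  acc <- Reduce(`+`, lapply(vols, `[[`, "voxels"))
  out <- vols[[1]]
  out$voxels <- acc / length(vols)
  out
}

#' Subtract a background volume from an irradiated volume
#'
#' Removes the container, beam-hardening parabola and any ring pattern
#' present in both scans, leaving the beam-track increments (plus noise).
#'
#' @param irradiated,background co-registered [ct_volume()]s.
#' @return the difference volume.
#' @export
subtract_background <- function(irradiated, background) {
  assert_coregistered(irradiated, background)
  out <- irradiated
  out$voxels <- irradiated$voxels - background$voxels
  out
}

.filter_names <- c("mean", "median", "adaptive_mean", "adaptive_median",
                   "kuwahara", "fft_window", "savitzky_golay", "envelope")

.fft_window_names <- c("hann", "hamming", "blackman", "nuttall",
                       "blackman-nuttall", "blackman-harris", "flat-top",
                       "bartlett", "welch", "cosine", "tukey", "rectangular")

#' Filter specification
#'
#' @param name one of `mean`, `median`, `adaptive_mean`, `adaptive_median`,
#'   `kuwahara`, `fft_window`, `savitzky_golay`, `envelope`.
#' @param kernel odd window size in pixels, >= 3 (for `adaptive_median` the
#'   maximal window).
#' @param kernel_mode `"2D"` (per transversal slice) or `"3D"`.
#' @param iterations number of times the filter is applied, >= 1.
#' @param window_name `fft_window` only; one of the 12 named windows
#'   (default `"nuttall"`).
#' @param polyorder `savitzky_golay` only; must be < `kernel`.
#' @param inner_stat `envelope` only: `"mean"` (midpoint of the grayscale
#'   dilation/erosion envelopes, the default), `"min"` or `"max"`.
#' @param noise_var `adaptive_mean` only: HU noise variance; estimated from
#'   the median local variance when `NULL`.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(name, kernel = 3, kernel_mode = c("2D", "3D"),
                        iterations = 1, window_name = "nuttall",
                        polyorder = 2, inner_stat = c("mean", "min", "max"),
                        noise_var = NULL) {
  if (!name %in% .filter_names)
    err_usage(sprintf("unknown filter '%s'", name))
  kernel_mode <- match.arg(kernel_mode)
  inner_stat <- match.arg(inner_stat)
  if (kernel %% 2 != 1 || kernel < 3) err_usage("kernel must be odd and >= 3")
  if (iterations < 1) err_usage("iterations must be >= 1")
  if (name == "savitzky_golay" && polyorder >= kernel)
    err_usage("polyorder must be < kernel")
  if (name == "fft_window" && !window_name %in% .fft_window_names)
    err_usage(sprintf("unknown FFT window '%s'", window_name))
  structure(list(name = name, kernel = kernel, kernel_mode = kernel_mode,
                 iterations = iterations, window_name = window_name,
                 polyorder = polyorder, inner_stat = inner_stat,
                 noise_var = noise_var), class = "filter_spec")
}

# ---- neighbourhood engine ---------------------------------------------------

.pad3 <- function(a, p) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    n <- d[ax]; pa <- p[ax]
    if (pa == 0L) seq_len(n)
    else {
      if (pa > n) err_usage("kernel larger than image extent")
      c(pa:1, 1:n, n:(n - pa + 1))
    }
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# offsets for a kernel of size k: in-plane dims (1, 3) always, dim 2 only
# in 3D mode
.nb_offsets <- function(kernel, mode) {
  h <- (kernel - 1L) / 2L
  oj <- if (mode == "3D") -h:h else 0L
  expand.grid(oi = -h:h, oj = oj, ok = -h:h)
}

.nb_shift <- function(ap, d, p, o) {
  ap[(1:d[1]) + p[1] + o[1], (1:d[2]) + p[2] + o[2],
     (1:d[3]) + p[3] + o[3], drop = FALSE]
}

.nb_pads <- function(offs) c(max(abs(offs$oi)), max(abs(offs$oj)),
                             max(abs(offs$ok)))

# accumulate f over all shifted copies (f = `+`, pmax, pmin)
.nb_reduce <- function(a, offs, f) {
  p <- .nb_pads(offs)
  ap <- .pad3(a, p)
  d <- dim(a)
  acc <- NULL
  for (r in seq_len(nrow(offs))) {
    s <- .nb_shift(ap, d, p, c(offs$oi[r], offs$oj[r], offs$ok[r]))
    acc <- if (is.null(acc)) s else f(acc, s)
  }
  acc
}

# N x n_offsets matrix of neighbourhood values
.nb_stack <- function(a, offs) {
  p <- .nb_pads(offs)
  ap <- .pad3(a, p)
  d <- dim(a)
  out <- matrix(0, length(a), nrow(offs))
  for (r in seq_len(nrow(offs)))
    out[, r] <- as.vector(.nb_shift(ap, d, p,
                                    c(offs$oi[r], offs$oj[r], offs$ok[r])))
  out
}

.row_median <- function(m) apply(m, 1L, median)

# ---- individual filters (one pass each) ------------------------------------

.flt_mean <- function(a, spec) {
  offs <- .nb_offsets(spec$kernel, spec$kernel_mode)
  .nb_reduce(a, offs, `+`) / nrow(offs)
}

.flt_median <- function(a, spec) {
  offs <- .nb_offsets(spec$kernel, spec$kernel_mode)
  array(.row_median(.nb_stack(a, offs)), dim = dim(a))
}

.flt_envelope <- function(a, spec) {
  offs <- .nb_offsets(spec$kernel, spec$kernel_mode)
  up <- .nb_reduce(a, offs, pmax)
  lo <- .nb_reduce(a, offs, pmin)
  switch(spec$inner_stat,
         mean = (up + lo) / 2,
         min = lo,
         max = up)
}

.flt_adaptive_mean <- function(a, spec) {
  offs <- .nb_offsets(spec$kernel, spec$kernel_mode)
  n <- nrow(offs)
  m <- .nb_reduce(a, offs, `+`) / n
  m2 <- .nb_reduce(a * a, offs, `+`) / n
  v <- pmax(m2 - m * m, 0)
  nv <- spec$noise_var %||% median(v)
  gain <- pmax(v - nv, 0) / pmax(v, .Machine$double.eps)
  m + gain * (a - m)
}

.flt_adaptive_median <- function(a, spec) {
  x <- as.vector(a)
  out <- rep(NA_real_, length(x))
  unresolved <- rep(TRUE, length(x))
  sizes <- seq(3L, spec$kernel, by = 2L)
  for (w in sizes) {
    offs <- .nb_offsets(w, spec$kernel_mode)
    st <- .nb_stack(a, offs)
    zmin <- do.call(pmin, asplit(st, 2))
    zmax <- do.call(pmax, asplit(st, 2))
    zmed <- .row_median(st)
    ok <- unresolved & (zmed > zmin) & (zmed < zmax)
    keep <- ok & (x > zmin) & (x < zmax)
    out[keep] <- x[keep]
    out[ok & !keep] <- zmed[ok & !keep]
    unresolved <- unresolved & !ok
    if (w == spec$kernel) out[unresolved] <- zmed[unresolved]
    if (!any(unresolved)) break
  }
  array(out, dim = dim(a))
}

.flt_kuwahara <- function(a, spec) {
  q <- (spec$kernel + 1L) / 2L
  lo <- -(q - 1L):0L; hi <- 0L:(q - 1L)
  ranges <- list(lo, hi)
  jr <- if (spec$kernel_mode == "3D") ranges else list(0L)
  best_var <- NULL; best_mean <- NULL
  for (ri in ranges) for (rj in jr) for (rk in ranges) {
    offs <- expand.grid(oi = ri, oj = rj, ok = rk)
    n <- nrow(offs)
    m <- .nb_reduce(a, offs, `+`) / n
    m2 <- .nb_reduce(a * a, offs, `+`) / n
    v <- pmax(m2 - m * m, 0)
    if (is.null(best_var)) {
      best_var <- v; best_mean <- m
    } else {
      take <- v < best_var
      best_mean[take] <- m[take]
      best_var[take] <- v[take]
    }
  }
  best_mean
}

# Savitzky-Golay smoothing along one array dim. The full projection
# matrix is used (interior row for the bulk, the leading/trailing rows at
# the ends), so polynomials up to `polyorder` pass through unchanged
# everywhere, including the edges.
.sg_along <- function(a, fm, dim_ax) {
  n <- nrow(fm)
  h <- (n - 1L) / 2L
  len <- dim(a)[dim_ax]
  if (len < n) err_usage("kernel larger than image extent")
  # build a sparse-free (len x len) operator once per axis length
  op <- matrix(0, len, len)
  mid <- as.numeric(fm[h + 1L, ])
  for (i in seq_len(len)) {
    if (i <= h) {
      op[i, 1:n] <- fm[i, ]
    } else if (i > len - h) {
      op[i, (len - n + 1L):len] <- fm[n - (len - i), ]
    } else {
      op[i, (i - h):(i + h)] <- mid
    }
  }
  d <- dim(a)
  perm <- c(dim_ax, setdiff(1:3, dim_ax))
  m <- matrix(aperm(a, perm), nrow = len)
  out <- op %*% m
  aperm(array(out, dim = d[perm]), order(perm))
}

.flt_savitzky_golay <- function(a, spec) {
  fm <- unclass(signal::sgolay(p = spec$polyorder, n = spec$kernel))
  axes <- if (spec$kernel_mode == "3D") c(1L, 2L, 3L) else c(1L, 3L)
  for (ax in axes) a <- .sg_along(a, fm, ax)
  a
}

.fft_window_vec <- function(name, n) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  cosw <- function(a) {
    w <- numeric(n)
    for (k in seq_along(a)) w <- w + (-1)^(k - 1) * a[k] * cos(2 * pi * (k - 1) * t)
    w
  }
  switch(name,
    "hann" = cosw(c(0.5, 0.5)),
    "hamming" = cosw(c(0.54, 0.46)),
    "blackman" = cosw(c(0.42, 0.5, 0.08)),
    "nuttall" = cosw(c(0.355768, 0.487396, 0.144232, 0.012604)),
    "blackman-nuttall" = cosw(c(0.3635819, 0.4891775, 0.1365995, 0.0106411)),
    "blackman-harris" = cosw(c(0.35875, 0.48829, 0.14128, 0.01168)),
    "flat-top" = cosw(c(0.21557895, 0.41663158, 0.277263158, 0.083578947,
                        0.006947368)),
    "bartlett" = 1 - abs(2 * t - 1),
    "welch" = 1 - (2 * t - 1)^2,
    "cosine" = sin(pi * t),
    "tukey" = {
      al <- 0.5
      w <- rep(1, n)
      lo <- t < al / 2
      hi <- t > 1 - al / 2
      w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / al - 1)))
      w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / al - 2 / al + 1)))
      w
    },
    "rectangular" = rep(1, n))
}

.ifftshift_idx <- function(n) {
  c0 <- floor(n / 2) + 1L
  c(c0:n, seq_len(c0 - 1L))
}

.fft_filter_slice <- function(m, wname) {
  n1 <- nrow(m); n2 <- ncol(m)
  W <- outer(.fft_window_vec(wname, n1), .fft_window_vec(wname, n2))
  W <- W[.ifftshift_idx(n1), .ifftshift_idx(n2)]
  Re(stats::fft(stats::fft(m) * W, inverse = TRUE)) / (n1 * n2)
}

.flt_fft_window <- function(a, spec) {
  d <- dim(a)
  if (spec$kernel_mode == "2D") {
    for (j in seq_len(d[2]))
      a[, j, ] <- .fft_filter_slice(matrix(a[, j, ], d[1], d[3]),
                                    spec$window_name)
    a
  } else {
    W <- outer(outer(.fft_window_vec(spec$window_name, d[1]),
                     .fft_window_vec(spec$window_name, d[2])),
               .fft_window_vec(spec$window_name, d[3]))
    dim(W) <- d
    W <- W[.ifftshift_idx(d[1]), .ifftshift_idx(d[2]), .ifftshift_idx(d[3])]
    Re(stats::fft(stats::fft(a) * W, inverse = TRUE)) / prod(d)
  }
}

#' Apply a filter from the bank to a volume
#'
#' Applies the named filter `iterations` times; 2D mode filters each
#' transversal slice independently, 3D mode the whole volume. Geometry is
#' unchanged. The envelope filter is the per-voxel midpoint (or
#' `inner_stat`) of the grayscale dilation and erosion computed with a
#' square structuring element of size `kernel`; `fft_window` multiplies the
#' frequency domain by the named separable window; `adaptive_median` grows
#' its window up to `kernel` before passing the centre pixel through.
#'
#' @param volume a [ct_volume()].
#' @param spec a [filter_spec()].
#' @return the filtered [ct_volume()], co-registered with the input.
#' @export
apply_filter <- function(volume, spec) {
  if (!inherits(volume, "ct_volume")) err_usage("need a ct_volume")
  if (!inherits(spec, "filter_spec")) err_usage("need a filter_spec")
  fn <- switch(spec$name,
               mean = .flt_mean,
               median = .flt_median,
               adaptive_mean = .flt_adaptive_mean,
               adaptive_median = .flt_adaptive_median,
               kuwahara = .flt_kuwahara,
               fft_window = .flt_fft_window,
               savitzky_golay = .flt_savitzky_golay,
               envelope = .flt_envelope)
  a <- volume$voxels
  for (it in seq_len(spec$iterations)) a <- fn(a, spec)
  out <- volume
  out$voxels <- a
  out
}

#' Apply an ordered filter chain
#'
#' @param volume a [ct_volume()].
#' @param specs list of [filter_spec()]s, applied in order.
#' @return filtered volume.
#' @export
apply_filter_chain <- function(volume, specs) {
  for (s in specs) volume <- apply_filter(volume, s)
  volume
}
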