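# Configuration-driven end-to-end runs: (simulate | read DICOM) -> average
# -> filter -> background-subtract -> detect -> fit -> report.
#
# Reports are JSON (+ per-beam CSV and a plain-text log) and embed the
# resolved configuration and package version. Exit-status convention:
# 0 = pass, 1 = tolerance fail, 2 = stage error (used by the CLI).

#' Pipeline configuration
#'
#' Exactly one of `phantom` (a [phantom_spec()] to simulate) or `dicom`
#' (list with `background` and `irradiated` DICOM directory paths) must be
#' given. The default protocol encodes the optimised readout: averaging
#' over up to three series, background subtraction on, no filters.
#'
#' @param phantom optional [phantom_spec()].
#' @param dicom optional list(background=, irradiated=) of directory paths
#'   (character vectors, one directory per series).
#' @param beams planned [beam_spec()] list (detection hints); defaults to
#'   the phantom's beams.
#' @param mode_tag accelerator+mode label.
#' @param averaging number of series averaged (capped at what is
#'   available).
#' @param filters list of [filter_spec()]s applied in order.
#' @param filter_target `"both"` (default; background and irradiated are
#'   filtered identically), `"irradiated"` or `"background"`. Asymmetric
#'   filtering is allowed but flagged: subtracting an unfiltered
#'   background from a filtered image can leave ring artifacts.
#' @param markers `TRUE` to locate fiducial markers and use their
#'   reference point for the offset.
#' @param reference optional mm reference point overriding the
#'   marker-derived one.
#' @param tolerances list with `tg142_mm` (star-shot circle radius
#'   tolerance, default 1 mm) and `mpc_mm` (offset threshold, default
#'   0.5 mm).
#' @param star_axial_mm star-plane position; defaults to the marker plane.
#' @param slab slices averaged for the star plane.
#' @param voi uniformity VOI settings: `diameter_mm`, `length_mm`,
#'   `offset_frac` (peripheral offset as a fraction of the module radius),
#'   `module_radius_mm` (default: largest radius keeping the VOI inside
#'   the gel).
#' @param precomputed_means optional data frame of positional VOI means
#'   (columns center/left/top/right/bottom, one row per series) that
#'   [run_uniformity()] uses instead of re-segmenting images.
#' @param output_dir directory for report files; `NULL` for none.
#' @param seed integer seed for any stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = NULL, dicom = NULL, beams = NULL,
                            mode_tag = "TrueBeam iCBCT Pelvis",
                            averaging = 3, filters = list(),
                            filter_target = c("both", "irradiated",
                                              "background"),
                            markers = TRUE, reference = NULL,
                            tolerances = list(tg142_mm = 1, mpc_mm = 0.5),
                            star_axial_mm = NULL, slab = 5,
                            voi = list(), precomputed_means = NULL,
                            output_dir = NULL, seed = 1) {
  filter_target <- match.arg(filter_target)
  if (!is.null(phantom) && !is.null(dicom))
    err_usage("give either a phantom spec or DICOM input, not both")
  if (is.null(phantom) && is.null(dicom) && is.null(precomputed_means))
    err_usage("one of phantom, dicom or precomputed_means is required")
  tolerances <- modifyList(list(tg142_mm = 1, mpc_mm = 0.5), tolerances)
  if (any(unlist(tolerances) <= 0)) err_usage("tolerances must be > 0")
  if (is.null(beams) && !is.null(phantom)) beams <- phantom$beams
  voi <- modifyList(list(diameter_mm = 20, length_mm = 5,
                         offset_frac = 0.8, module_radius_mm = NULL), voi)
  structure(list(phantom = phantom, dicom = dicom, beams = beams,
                 mode_tag = mode_tag, averaging = averaging,
                 filters = filters, filter_target = filter_target,
                 markers = markers, reference = reference,
                 tolerances = tolerances, star_axial_mm = star_axial_mm,
                 slab = slab, voi = voi,
                 precomputed_means = precomputed_means,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  withCallingHandlers(expr, gelshot_error = function(e) {
    stop(errorCondition(sprintf("[stage %s] %s", name, conditionMessage(e)),
                        class = class(e)))
  })
}

# resolved config as embedded in reports: output location is where the
# report lives, not part of the analysis, and would break bytewise
# reproducibility across destinations
.serializable_config <- function(config) {
  config$output_dir <- NULL
  config
}

# strip classes recursively so reports serialise as plain JSON
.to_plain <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), .to_plain))
  x
}

.acquire_series <- function(config) {
  if (!is.null(config$phantom)) {
    sim <- .stage("simulate", simulate_phantom(config$phantom))
    list(background = sim$background, irradiated = sim$irradiated,
         truth = sim$truth)
  } else {
    read_set <- function(dirs, label) {
      vols <- lapply(dirs, read_dicom_series)
      series_set(vols, label, config$mode_tag)
    }
    list(background = .stage("read", read_set(config$dicom$background,
                                              "background")),
         irradiated = .stage("read", read_set(config$dicom$irradiated,
                                              "irradiated")),
         truth = NULL)
  }
}

.preprocess_pair <- function(config, acq, log) {
  n_bg <- min(config$averaging, length(acq$background$volumes))
  n_irr <- min(config$averaging, length(acq$irradiated$volumes))
  bg <- .stage("average", average_series(acq$background, seq_len(n_bg)))
  irr <- .stage("average", average_series(acq$irradiated, seq_len(n_irr)))
  log <- c(log, sprintf("averaged %d background and %d irradiated series",
                        n_bg, n_irr))
  fid <- NULL
  if (isTRUE(config$markers)) {
    fid <- tryCatch(.stage("markers", detect_markers(irr)),
                    gelshot_detection_error = function(e) {
                      if (is.null(config$reference)) stop(e)
                      NULL
                    })
    if (!is.null(fid))
      log <- c(log, sprintf("markers at y = %.2f mm; reference (%s) mm",
                            fid$plane_axial_mm,
                            paste(sprintf("%.3f", fid$reference_point),
                                  collapse = ", ")))
  }
  if (length(config$filters)) {
    if (config$filter_target != "both") {
      msg <- sprintf(paste0("asymmetric filtering (%s only): subtracting ",
                            "an unfiltered counterpart may leave ring ",
                            "artifacts"), config$filter_target)
      warning(msg)
      log <- c(log, paste("WARNING:", msg))
    }
    flt <- function(v) .stage("filter", apply_filter_chain(v, config$filters))
    if (config$filter_target %in% c("both", "background")) bg <- flt(bg)
    if (config$filter_target %in% c("both", "irradiated")) irr <- flt(irr)
    log <- c(log, sprintf("applied %d filter(s) to %s",
                          length(config$filters), config$filter_target))
  }
  sub <- .stage("subtract", subtract_background(irr, bg))
  list(bg = bg, irr = irr, sub = sub, fid = fid, log = log)
}

.resolve_reference <- function(config, pre) {
  if (!is.null(config$reference)) return(as.numeric(config$reference))
  if (!is.null(pre$fid)) return(as.numeric(pre$fid$reference_point))
  NULL
}

.write_report <- function(report, per_beam, log, output_dir, stem) {
  if (is.null(output_dir)) return(character(0))
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  js <- file.path(output_dir, paste0(stem, ".json"))
  jsonlite::write_json(.to_plain(report), js, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  files <- js
  if (!is.null(per_beam)) {
    csvf <- file.path(output_dir, paste0(stem, "_beams.csv"))
    write.csv(per_beam, csvf, row.names = FALSE)
    files <- c(files, csvf)
  }
  logf <- file.path(output_dir, paste0(stem, ".log"))
  writeLines(log, logf)
  c(files, logf)
}

.fit_to_report <- function(fit) {
  list(center_mm = as.numeric(fit$center),
       radius_mm = fit$radius_mm,
       ls_center_mm = as.numeric(fit$ls_center),
       per_beam_distance_mm = fit$per_beam$distance_mm,
       reference_mm = if (is.null(fit$reference)) NULL
                      else as.numeric(fit$reference),
       offset_vector_mm = if (is.null(fit$offset_vector)) NULL
                          else as.numeric(fit$offset_vector),
       offset_mm = fit$offset_mm,
       verdicts = fit$verdicts)
}

#' Run the 2D star-shot isocenter pipeline
#'
#' Average -> (optional filters) -> background subtraction -> star-plane
#' extraction -> sinogram beam detection -> minimal-circle fit with the
#' marker-referenced offset.
#'
#' @param config a [pipeline_config()] with >= 3 coplanar beams.
#' @return object of class `isocenter_run`: the `fit`, the serialisable
#'   `report`, the `files` written and the exit `status` (0 pass, 1
#'   tolerance fail).
#' @export
run_isocenter_2d <- function(config) {
  if (!inherits(config, "pipeline_config")) err_usage("need a pipeline_config")
  beams <- config$beams
  if (is.null(beams) || length(beams) < 3L)
    err_usage("2D star-shot analysis needs at least 3 planned beams")
  if (any(vapply(beams, function(b) abs(b$couch_deg) > 1e-6, TRUE)))
    err_usage("2D star-shot beams must be coplanar (couch = 0)")
  log <- sprintf("gelshot %s | 2D star-shot run | mode %s",
                 as.character(utils::packageVersion("gelshot")),
                 config$mode_tag)
  acq <- .acquire_series(config)
  pre <- .preprocess_pair(config, acq, log)
  log <- pre$log
  reference <- .resolve_reference(config, pre)
  axial <- config$star_axial_mm %||%
    (if (!is.null(pre$fid)) pre$fid$plane_axial_mm else 0)
  plane <- .stage("star_plane", extract_star_plane(pre$sub, axial,
                                                   config$slab))
  hints <- vapply(beams, function(b) {
    g <- b$gantry_deg * pi / 180
    (atan2(-cos(g), sin(g)) * 180 / pi) %% 180
  }, 0)
  gap <- max(vapply(beams, `[[`, 0, "gap_mm"))
  lines <- .stage("detect", detect_beams_2d(plane, length(beams),
                                            angle_hints = hints,
                                            gap_mm = max(gap, 1)))
  ref2d <- if (!is.null(reference)) reference[c(1, 3)] else NULL
  fit <- .stage("fit", fit_isocenter_2d(lines, ref2d,
                                        tg142_mm = config$tolerances$tg142_mm,
                                        mpc_mm = config$tolerances$mpc_mm))
  log <- c(log, sprintf("star plane y = %.2f mm; radius %.4f mm",
                        plane$axial_mm, fit$radius_mm))
  report <- list(tool = "gelshot",
                 version = as.character(utils::packageVersion("gelshot")),
                 analysis = "isocenter_2d",
                 config = .serializable_config(config),
                 lines = lapply(lines, function(l)
                   list(a = l$a, b = l$b, c = l$c,
                        angle_deg = l$angle_deg)),
                 result = .fit_to_report(fit),
                 log = log)
  status <- if (isTRUE(fit$verdicts$tg142) &&
                !isFALSE(fit$verdicts$mpc_style)) 0L else 1L
  files <- .write_report(report, fit$per_beam, log, config$output_dir,
                         "isocenter2d")
  structure(list(fit = fit, report = report, files = files,
                 status = status, truth = acq$truth),
            class = "isocenter_run")
}

#' Run the 3D isocenter pipeline
#'
#' As [run_isocenter_2d()] but with guided 3D track detection and the
#' minimal-sphere fit; the offset is reported against the marker reference
#' point, and an all-coplanar planned beam set is flagged in the report.
#'
#' @param config a [pipeline_config()] with >= 2 beams.
#' @return an `isocenter_run`.
#' @export
run_isocenter_3d <- function(config) {
  if (!inherits(config, "pipeline_config")) err_usage("need a pipeline_config")
  beams <- config$beams
  if (is.null(beams) || length(beams) < 2L)
    err_usage("3D analysis needs at least 2 planned beams")
  log <- sprintf("gelshot %s | 3D isocenter run | mode %s",
                 as.character(utils::packageVersion("gelshot")),
                 config$mode_tag)
  dirs <- vapply(beams, function(b)
    beam_direction(b$gantry_deg, b$couch_deg), numeric(3))
  coplanar <- FALSE
  if (length(beams) >= 3L) {
    nrm <- svd(t(dirs))$v[, 3]
    coplanar <- max(abs(t(dirs) %*% nrm)) < 1e-6
  }
  if (coplanar) {
    log <- c(log, "WARNING: all planned beams are coplanar; 3D fit is ill-conditioned along the plane normal")
  }
  acq <- .acquire_series(config)
  pre <- .preprocess_pair(config, acq, log)
  log <- pre$log
  reference <- .resolve_reference(config, pre)
  lines <- .stage("detect", detect_beams_3d(pre$sub, beams))
  fit <- .stage("fit", fit_isocenter_3d(lines, reference,
                                        tg142_mm = config$tolerances$tg142_mm,
                                        mpc_mm = config$tolerances$mpc_mm))
  log <- c(log, sprintf("radius %.4f mm%s", fit$radius_mm,
                        if (!is.null(fit$offset_mm))
                          sprintf("; offset %.4f mm", fit$offset_mm)
                        else ""))
  report <- list(tool = "gelshot",
                 version = as.character(utils::packageVersion("gelshot")),
                 analysis = "isocenter_3d",
                 config = .serializable_config(config),
                 coplanar_warning = coplanar,
                 lines = lapply(lines, function(l)
                   list(point = l$point, direction = l$direction)),
                 result = .fit_to_report(fit),
                 log = log)
  status <- if (isTRUE(fit$verdicts$tg142) &&
                !isFALSE(fit$verdicts$mpc_style)) 0L else 1L
  files <- .write_report(report, fit$per_beam, log, config$output_dir,
                         "isocenter3d")
  structure(list(fit = fit, report = report, files = files,
                 status = status, truth = acq$truth),
            class = "isocenter_run")
}

#' @export
print.isocenter_run <- function(x, ...) {
  cat(sprintf("<isocenter_run> status %d\n", x$status))
  print(x$fit)
  invisible(x)
}

#' Run the image-uniformity pipeline
#'
#' Places the five IPA VOIs (centre plus left/top/right/bottom at
#' `offset_frac * module_radius`), computes their means per series and
#' feeds them to [uniformity_ipa()]. With `precomputed_means` in the
#' config, published table rows can be re-evaluated without images.
#'
#' @param config a [pipeline_config()].
#' @return object of class `uniformity_run` with the `report`
#'   ([uniformity_ipa()] result), `files` and `status`.
#' @export
run_uniformity <- function(config) {
  if (!inherits(config, "pipeline_config")) err_usage("need a pipeline_config")
  log <- sprintf("gelshot %s | uniformity run | mode %s",
                 as.character(utils::packageVersion("gelshot")),
                 config$mode_tag)
  if (!is.null(config$precomputed_means)) {
    means <- config$precomputed_means
    log <- c(log, sprintf("using %d precomputed rows", nrow(means)))
  } else {
    acq <- .acquire_series(config)
    series <- acq$background
    vs <- config$voi
    r_module <- vs$module_radius_mm
    if (is.null(r_module)) {
      r_in <- if (!is.null(config$phantom))
        config$phantom$container$inner_diameter_mm / 2 else 45
      r_module <- r_in - vs$diameter_mm / 2 - 1
    }
    off <- vs$offset_frac * r_module
    pos <- list(center = c(0, 0, 0), left = c(-off, 0, 0),
                top = c(0, 0, off), right = c(off, 0, 0),
                bottom = c(0, 0, -off))
    rows <- lapply(seq_along(series$volumes), function(s) {
      v <- series$volumes[[s]]
      st <- lapply(pos, function(p) .stage("voi", voi_stats(
        v, voi_cylinder(p, vs$diameter_mm, vs$length_mm))))
      data.frame(series = s,
                 center = st$center$mean, left = st$left$mean,
                 top = st$top$mean, right = st$right$mean,
                 bottom = st$bottom$mean)
    })
    means <- do.call(rbind, rows)
    log <- c(log, sprintf("measured 5 VOIs on %d series (offset %.1f mm)",
                          length(series$volumes), off))
  }
  rep_u <- .stage("uniformity", uniformity_ipa(means))
  status <- if (rep_u$pass) 0L else 1L
  files <- character(0)
  if (!is.null(config$output_dir)) {
    if (!dir.exists(config$output_dir))
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    csvf <- file.path(config$output_dir, "uniformity.csv")
    tab <- as.data.frame(rep_u$per_series)
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], round_half_away)
    write.csv(tab, csvf, row.names = FALSE)
    report <- list(tool = "gelshot",
                   version = as.character(utils::packageVersion("gelshot")),
                   analysis = "uniformity",
                   config = .serializable_config(config),
                   series_mean_hu = rep_u$series_mean,
                   max_abs_diff_hu = rep_u$max_abs_diff,
                   criterion_hu = rep_u$criterion_hu,
                   pass = rep_u$pass,
                   log = log)
    jsf <- file.path(config$output_dir, "uniformity.json")
    jsonlite::write_json(.to_plain(report), jsf, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    logf <- file.path(config$output_dir, "uniformity.log")
    writeLines(log, logf)
    files <- c(jsf, csvf, logf)
  }
  structure(list(report = rep_u, files = files, status = status, log = log),
            class = "uniformity_run")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors [pipeline_config()]; a `phantom` block is converted to
#' a [phantom_spec()] (with `beams` entries becoming [beam_spec()]s and an
#' optional `dose_model` block a [dose_model()]), and `filters` entries
#' become [filter_spec()]s.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) err_io(sprintf("no config file '%s'", path))
  raw <- yaml::read_yaml(path)
  mk_beams <- function(lst) lapply(lst, function(b) do.call(beam_spec, b))
  if (!is.null(raw$phantom)) {
    ph <- raw$phantom
    if (!is.null(ph$beams)) ph$beams <- mk_beams(ph$beams)
    if (!is.null(ph$dose_model)) ph$dose_model <- do.call(dose_model,
                                                          ph$dose_model)
    if (!is.null(ph$markers)) ph$markers <- as.data.frame(
      do.call(rbind, lapply(ph$markers, as.data.frame)))
    raw$phantom <- do.call(phantom_spec, ph)
  }
  if (!is.null(raw$beams)) raw$beams <- mk_beams(raw$beams)
  if (!is.null(raw$filters))
    raw$filters <- lapply(raw$filters, function(f) do.call(filter_spec, f))
  if (!is.null(raw$precomputed_means))
    raw$precomputed_means <- as.data.frame(raw$precomputed_means)
  do.call(pipeline_config, raw)
}
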