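#' Render a diffusion-weighted image time-series
#'
#' Simulates the full MP-DW-STE acquisition of a scene: every voxel follows
#' its stimulated-echo signal series, and each displacement event covering
#' a voxel attenuates it by the incoherent phase-dispersion factor evaluated
#' at the net envelope difference between rephasing (`t = Delta_n`) and
#' dephasing (`t = 0`), `sigma_n = amplitude * |e(Delta_n) - e(0)|`. Only
#' this net difference matters: a twitch that has fully relaxed before the
#' first rephasing lobe (class M_V) leaves no trace, while one that was
#' already active at dephasing and relaxed during mixing (M_I) attenuates
#' every cycle equally.
#'
#' @param scene A [tissue_scene()].
#' @param schedule A [cycle_schedule()].
#' @param events A `displacement_events` object (or `NULL` for none); must
#'   live on the scene's grid.
#' @param repetitions Number of repetitions; defaults to
#'   `events$n_repetitions` (1 without events).
#' @param noise A [noise_spec()].
#' @param seed Seed for the noise draw.
#' @return An object of class `dwi_series`: list with `data` (array
#'   `rows x cols x cycles x repetitions`), `noiseless` (same shape, before
#'   noise), `schedule`, `noise`, `seed` and `scene`.
#' @export
render_dwi_series <- function(scene, schedule, events = NULL,
                              repetitions = NULL, noise = noise_spec("none"),
                              seed = NULL) {
  stopifnot(inherits(scene, "tissue_scene"),
            inherits(schedule, "cycle_schedule"))
  if (!is.null(events)) {
    stopifnot(inherits(events, "displacement_events"))
    if (!identical(events$dim, scene$dim))
      .stopf("events grid does not match scene grid")
  }
  if (is.null(repetitions))
    repetitions <- if (is.null(events)) 1L else events$n_repetitions
  p <- attr(schedule, "params")
  nr <- scene$dim[1]; nc <- scene$dim[2]; V <- nr * nc
  N <- nrow(schedule); R <- as.integer(repetitions)

  a <- schedule$alpha_deg * pi / 180
  defl <- sin(a) * cumprod(c(1, cos(a[-length(a)])))
  base <- (0.5 * as.vector(scene$m0) * exp(-p$te / as.vector(scene$t2))) *
    exp(-outer(1 / as.vector(scene$t1), schedule$tm_ms)) *
    exp(-outer(as.vector(scene$adc), schedule$b_s_mm2)) *
    rep(defl, each = V)

  stack <- array(rep(base, R), dim = c(V, N, R))
  if (!is.null(events) && length(events$events)) {
    g <- attr(schedule, "g_d_mt_m")
    for (e in events$events) {
      if (e$repetition > R) next
      f <- abs(event_envelope(e, schedule$delta_ms) - event_envelope(e, 0))
      idx <- e$footprint$row + (e$footprint$col - 1L) * nr
      att <- exp(-0.5 * outer(
        phase_for_displacement(g, p$delta, e$footprint$amplitude_um), f)^2)
      stack[idx, , e$repetition] <- stack[idx, , e$repetition] * att
    }
  }
  noiseless <- array(stack, dim = c(nr, nc, N, R))
  ref <- noise$reference
  if (is.null(ref) && noise$model != "none") {
    first <- noiseless[, , 1, 1]
    ref <- mean(first[first > 0])
    noise$reference <- ref
  }
  data <- add_noise(noiseless, noise, seed = seed)
  structure(list(data = data, noiseless = noiseless, schedule = schedule,
                 noise = noise, seed = seed, scene = scene),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI time-series: %d x %d, %d cycles, %d repetitions (%s noise)\n",
              d[1], d[2], d[3], d[4], x$noise$model))
  invisible(x)
}

#' Frames of the DWI series visibly affected by an event
#'
#' Predicts, from the analytic envelope alone, which imaging cycles show a
#' detectable void for one event: cycle n is visible when at least
#' `min_size` footprint voxels are attenuated to `1 - drop_threshold` or
#' below. Used as ground truth when validating the detector.
#'
#' @param event A [displacement_event()].
#' @param schedule A [cycle_schedule()].
#' @param drop_threshold Relative signal-drop threshold (fraction of the
#'   undisturbed signal).
#' @param min_size Minimum number of voxels.
#' @return List with `frames` (integer vector of visible cycles, possibly
#'   empty), `first`, `last`, `peak` (cycle of strongest attenuation among
#'   visible frames; `NA` when invisible).
#' @export
predict_visibility <- function(event, schedule, drop_threshold = 0.3,
                               min_size = 2) {
  p <- attr(schedule, "params")
  g <- attr(schedule, "g_d_mt_m")
  f <- abs(event_envelope(event, schedule$delta_ms) - event_envelope(event, 0))
  att <- exp(-0.5 * outer(
    phase_for_displacement(g, p$delta, event$footprint$amplitude_um), f)^2)
  n_below <- colSums(att <= 1 - drop_threshold)
  frames <- which(n_below >= min_size)
  if (!length(frames))
    return(list(frames = integer(0), first = NA_integer_,
                last = NA_integer_, peak = NA_integer_))
  list(frames = frames, first = min(frames), last = max(frames),
       peak = frames[which.max(n_below[frames])])
}

#' Write a DWI series as NIfTI with a JSON sidecar
#'
#' The 4D NIfTI stores one volume per frame with frame index
#' `(repetition - 1) * n_cycles + cycle` (cycle fastest); the sidecar
#' carries the schedule parameters, noise model, seed and layout version
#' needed to reconstruct the object. The scene's label map is written as a
#' separate NIfTI when `label_path` is given.
#'
#' @param series A `dwi_series`.
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param sidecar_path JSON sidecar path; default replaces the extension
#'   with `.json`.
#' @param label_path Optional path for the label-map NIfTI.
#' @return `path`, invisibly.
#' @export
write_dwi_series <- function(series, path, sidecar_path = NULL,
                             label_path = NULL) {
  stopifnot(inherits(series, "dwi_series"))
  d <- dim(series$data)
  img <- array(series$data, dim = c(d[1], d[2], 1L, d[3] * d[4]))
  pix <- series$scene$pixel_mm
  RNifti::writeNifti(RNifti::asNifti(img, pixdim = c(pix, pix, 1, 1)), path)
  if (is.null(sidecar_path))
    sidecar_path <- sub("\\.nii(\\.gz)?$", ".json", path)
  p <- attr(series$schedule, "params")
  jsonlite::write_json(list(
    schema = "mpdwste-series/1",
    layout = "cycle_fastest",
    n_cycles = d[3], n_repetitions = d[4],
    params = unclass(p),
    noise = unclass(series$noise),
    seed = series$seed,
    pixel_mm = pix,
    label_names = as.list(series$scene$label_names)
  ), sidecar_path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(label_path))
    RNifti::writeNifti(RNifti::asNifti(
      array(series$scene$label_map, dim = c(d[1], d[2], 1L)),
      pixdim = c(pix, pix, 1)), label_path)
  invisible(path)
}

#' Read a DWI series written by [write_dwi_series()]
#'
#' @param path NIfTI path.
#' @param sidecar_path JSON sidecar path; default replaces the extension
#'   with `.json`.
#' @param label_path Optional label-map NIfTI path.
#' @return A list with `data` (rows x cols x cycles x repetitions array),
#'   `params` ([sequence_params()]), `schedule` ([cycle_schedule()]),
#'   `label_map` (or `NULL`), `label_names`, `seed`, `pixel_mm`.
#' @export
read_dwi_series <- function(path, sidecar_path = NULL, label_path = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  if (is.null(sidecar_path))
    sidecar_path <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (!identical(meta$schema, "mpdwste-series/1"))
    .stopf("not an mpdwste series sidecar: %s", sidecar_path)
  img <- as.array(RNifti::readNifti(path))
  d <- dim(img)
  data <- array(img, dim = c(d[1], d[2], meta$n_cycles, meta$n_repetitions))
  pp <- meta$params
  params <- sequence_params(tm = pp$tm, trf = pp$trf, nrf = pp$nrf,
                            b1 = pp$b1, delta = pp$delta, xi = pp$xi,
                            trf_exc = pp$trf_exc, te = pp$te, tr = pp$tr,
                            t1_design = pp$t1_design)
  label_map <- NULL
  if (!is.null(label_path)) {
    label_map <- as.array(RNifti::readNifti(label_path))
    dim(label_map) <- d[1:2]
    storage.mode(label_map) <- "integer"
  }
  list(data = data, params = params, schedule = cycle_schedule(params),
       label_map = label_map,
       label_names = unlist(meta$label_names),
       seed = meta$seed, pixel_mm = meta$pixel_mm)
}
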