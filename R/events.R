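#' A single incoherent-displacement event
#'
#' Represents one muscle twitch (or turbulence patch): a transient
#' displacement of the voxels in its footprint, rising from zero at `onset`
#' to its peak at `onset + t_contract` and relaxing back to exactly zero at
#' `onset + t_contract + t_relax`. Times are in ms relative to the shot's
#' dephasing gradient (t = 0); the onset may be negative. The per-voxel
#' `amplitude_um` is the peak intra-voxel displacement spread, maximal at
#' the footprint centroid and tapering towards the rim.
#'
#' @param onset Onset time, ms (may be negative).
#' @param t_contract Rise time to peak, ms (> 0).
#' @param t_relax Fall time, ms (> 0).
#' @param footprint Data frame with columns `row`, `col`, `amplitude_um`.
#' @param repetition 1-based repetition index the event belongs to.
#' @param muscle Region name (or `NA`).
#' @param shape Envelope shape: `"triangular"` (piecewise linear, default)
#'   or `"cosine"` (smooth raised-cosine rise and fall, also exactly zero
#'   outside the support).
#' @return An object of class `displacement_event`.
#' @export
displacement_event <- function(onset, t_contract, t_relax, footprint,
                               repetition = 1L, muscle = NA_character_,
                               shape = c("triangular", "cosine")) {
  shape <- match.arg(shape)
  if (t_contract <= 0 || t_relax <= 0)
    .stopf("t_contract and t_relax must be > 0")
  stopifnot(is.data.frame(footprint),
            all(c("row", "col", "amplitude_um") %in% names(footprint)))
  structure(list(onset = onset, t_contract = t_contract, t_relax = t_relax,
                 footprint = footprint, repetition = as.integer(repetition),
                 muscle = muscle, shape = shape),
            class = "displacement_event")
}

#' Normalized displacement envelope of an event
#'
#' Evaluates the unit-peak envelope e(t): zero outside
#' `[onset, onset + t_contract + t_relax]`, peak 1 at `onset + t_contract`.
#'
#' @param event A [displacement_event()].
#' @param t Time(s), ms.
#' @return Envelope value(s) in `[0, 1]`.
#' @export
event_envelope <- function(event, t) {
  up <- (t - event$onset) / event$t_contract
  down <- (event$onset + event$t_contract + event$t_relax - t) / event$t_relax
  e <- pmin(up, down)
  e[e < 0] <- 0
  e <- pmin(e, 1)
  if (event$shape == "cosine") e <- (1 - cos(pi * e)) / 2
  e
}

#' Latent motion-pattern class of an event
#'
#' Classifies a twitch by its timing relative to the dephasing gradient
#' (t = 0) and the per-cycle rephasing times `Delta_1 .. Delta_NRF`:
#' \describe{
#'   \item{M_I}{starts before dephasing, fully relaxed by `Delta_1`: the
#'     same net displacement is seen by every cycle, so the void appears in
#'     all images.}
#'   \item{M_II}{active across `Delta_1` with onset after dephasing, ends
#'     during the cycles: visible from the first image, contraction time
#'     indeterminable.}
#'   \item{M_III}{starts after `Delta_1` and ends before `Delta_NRF`: both
#'     contraction and relaxation are sampled.}
#'   \item{M_IV}{still active at `Delta_NRF`: relaxation not sampled.}
#'   \item{M_V}{contracts and relaxes entirely between dephasing and
#'     `Delta_1` (or after `Delta_NRF`): invisible.}
#' }
#' Boundary ties use half-open intervals: `onset = 0` counts as after the
#' dephasing gradient.
#'
#' @param event A [displacement_event()].
#' @param schedule A [cycle_schedule()].
#' @return One of `"M_I" ... "M_V"`.
#' @export
classify_motion_class <- function(event, schedule) {
  d1 <- schedule$delta_ms[1]
  dN <- schedule$delta_ms[nrow(schedule)]
  onset <- event$onset
  end <- event$onset + event$t_contract + event$t_relax
  if (end <= 0 || onset > dN || (onset >= 0 && end <= d1)) return("M_V")
  if (onset < 0 && end <= d1) return("M_I")
  if (onset < d1 && end < dN) return("M_II")
  if (onset >= d1 && end <= dN) return("M_III")
  "M_IV"
}

#' Sample stochastic twitch events for a scene
#'
#' Draws spontaneous twitch events per muscle and repetition: event counts
#' are Poisson with the configured per-repetition rate, onsets are uniform
#' over `window`, contraction/relaxation times and peak displacement
#' spreads are uniform over their ranges, and the spatial footprint is an
#' ellipse elongated along the muscle fiber direction with the amplitude
#' tapering linearly from centroid to rim, clipped to the muscle.
#'
#' @param scene A [tissue_scene()] with muscle labels.
#' @param rates Named vector: expected events per repetition for each
#'   muscle (names must exist in `scene$label_names`).
#' @param repetitions Number of repetitions.
#' @param seed Integer seed (`NULL` leaves the RNG state untouched).
#' @param window Onset window `c(min, max)`, ms relative to dephasing;
#'   default covers from one maximal event length before t = 0 to the end
#'   of the readout window of `schedule`.
#' @param schedule Optional [cycle_schedule()] used for the default window
#'   (required if `window` is `NULL`).
#' @param t_contract_range,t_relax_range Uniform ranges, ms.
#' @param spread_range Peak displacement-spread range, um.
#' @param semi_axis_range Footprint semi-major-axis range, voxels.
#' @param axis_ratio_range Minor/major axis ratio range.
#' @param fiber_angle_deg Fiber direction (rotation of the major axis from
#'   the column direction), degrees.
#' @return An object of class `displacement_events`: list with `events`
#'   (list of [displacement_event()]), `n_repetitions`, `dim`.
#' @export
sample_events <- function(scene, rates, repetitions, seed = NULL,
                          window = NULL, schedule = NULL,
                          t_contract_range = c(40, 160),
                          t_relax_range = c(80, 300),
                          spread_range = c(20, 200),
                          semi_axis_range = c(3, 7),
                          axis_ratio_range = c(0.3, 0.7),
                          fiber_angle_deg = 90) {
  stopifnot(inherits(scene, "tissue_scene"))
  if (any(rates < 0)) .stopf("rates must be >= 0")
  unknown <- setdiff(names(rates), names(scene$label_names))
  if (length(unknown))
    .stopf("rates name unknown regions: %s", paste(unknown, collapse = ", "))
  if (any(c(diff(t_contract_range), diff(t_relax_range), diff(spread_range)) < 0) ||
      t_contract_range[1] <= 0 || t_relax_range[1] <= 0 || spread_range[1] < 0)
    .stopf("invalid event parameter ranges")
  if (is.null(window)) {
    if (is.null(schedule))
      .stopf("either window or schedule must be given")
    window <- c(-(max(t_contract_range) + max(t_relax_range)),
                schedule$delta_ms[nrow(schedule)])
  }
  if (!is.null(seed)) set.seed(seed)
  runif1 <- function(rng) stats::runif(1, rng[1], rng[2])
  events <- list()
  for (rep_i in seq_len(repetitions)) {
    for (muscle in names(rates)) {
      lab <- scene$label_names[[muscle]]
      vox <- which(scene$label_map == lab, arr.ind = TRUE)
      k <- stats::rpois(1, rates[[muscle]])
      for (j in seq_len(k)) {
        center <- vox[sample.int(nrow(vox), 1L), ]
        a <- runif1(semi_axis_range)
        b <- max(1, a * runif1(axis_ratio_range))
        rad <- .ellipse_radius(vox[, 1], vox[, 2], center, c(a, b),
                               fiber_angle_deg)
        inside <- rad < 1
        if (!any(inside)) next
        peak <- runif1(spread_range)
        fp <- data.frame(row = vox[inside, 1], col = vox[inside, 2],
                         amplitude_um = peak * (1 - rad[inside]))
        events[[length(events) + 1L]] <- displacement_event(
          onset = runif1(window), t_contract = runif1(t_contract_range),
          t_relax = runif1(t_relax_range), footprint = fp,
          repetition = rep_i, muscle = muscle)
      }
    }
  }
  structure(list(events = events, n_repetitions = as.integer(repetitions),
                 dim = scene$dim),
            class = "displacement_events")
}

#' Ground-truth table of an event collection
#'
#' @param events A `displacement_events` object (or list of
#'   [displacement_event()]s).
#' @param schedule Optional [cycle_schedule()]; when given, the latent
#'   motion class of each event is included.
#' @return Data frame with one row per event: `repetition`, `muscle`,
#'   `onset_ms`, `t_contract_ms`, `t_relax_ms`, `peak_spread_um`,
#'   `n_voxels` and (with a schedule) `latent_class`.
#' @export
events_table <- function(events, schedule = NULL) {
  evs <- if (inherits(events, "displacement_events")) events$events else events
  if (!length(evs)) {
    out <- data.frame(repetition = integer(0), muscle = character(0),
                      onset_ms = numeric(0), t_contract_ms = numeric(0),
                      t_relax_ms = numeric(0), peak_spread_um = numeric(0),
                      n_voxels = integer(0))
    if (!is.null(schedule)) out$latent_class <- character(0)
    return(out)
  }
  out <- do.call(rbind, lapply(evs, function(e) data.frame(
    repetition = e$repetition, muscle = e$muscle, onset_ms = e$onset,
    t_contract_ms = e$t_contract, t_relax_ms = e$t_relax,
    peak_spread_um = max(e$footprint$amplitude_um),
    n_voxels = nrow(e$footprint))))
  if (!is.null(schedule))
    out$latent_class <- vapply(evs, classify_motion_class, character(1),
                               schedule = schedule)
  out
}
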