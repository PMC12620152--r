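#' Linear motion-bead trajectory
#'
#' Position of the phantom's motion bead along its tube as a function of
#' time: stationary until `trigger_delay`, then moving at constant `speed`
#' until `duration`, stationary afterwards. The trigger delay synchronizes
#' the bead with the imaging sequence (e.g. start after the first image).
#'
#' @param speed Bead speed, mm/s (>= 0).
#' @param start_position Initial position along the tube, mm.
#' @param duration End of the motion timeline, ms.
#' @param trigger_delay Motion start time, ms relative to the shot's
#'   dephasing gradient. `trigger_delay >= duration` yields no motion.
#' @return A function `pos(t_ms)` returning position(s) in mm, with
#'   attributes `speed`, `start_position`, `duration`, `trigger_delay`.
#' @examples
#' pos <- bead_trajectory(20, 0, duration = 200, trigger_delay = 0)
#' pos(200) # 4 mm
#' @export
bead_trajectory <- function(speed, start_position = 0, duration = 1000,
                            trigger_delay = 0) {
  if (speed < 0) .stopf("speed must be >= 0")
  pos <- function(t_ms) {
    active <- pmax(0, pmin(t_ms, duration) - trigger_delay)
    start_position + speed * active / 1000
  }
  structure(pos, speed = speed, start_position = start_position,
            duration = duration, trigger_delay = trigger_delay,
            class = c("bead_trajectory", "function"))
}

#' Turbulence events swept out by a moving bead
#'
#' Converts a bead trajectory inside an intra-slice tube into displacement
#' events: each tube column the bead reaches becomes an event whose onset is
#' the arrival time and whose relaxation outlasts the readout window, so the
#' water turbulence behind the bead keeps the swept segment's signal void
#' growing while the bead moves. Positions are measured along the tube from
#' its first (lowest-column) cross-section.
#'
#' @param trajectory A [bead_trajectory()].
#' @param scene A [tissue_scene()] from [build_phantom_scene()].
#' @param tube Name of the intra-slice tube region.
#' @param spread_scale Intra-voxel displacement spread of the turbulence,
#'   um.
#' @param repetitions Number of repetitions to replicate the motion cycle
#'   over.
#' @param persist_ms How long a swept voxel keeps its turbulence, ms.
#' @return A `displacement_events` object. If the trajectory runs past the
#'   tube end it is clipped with a warning.
#' @export
turbulence_events_from_trajectory <- function(trajectory, scene,
                                              tube = "intra_slice_1",
                                              spread_scale = 150,
                                              repetitions = 1,
                                              persist_ms = 5000) {
  stopifnot(inherits(trajectory, "bead_trajectory"),
            inherits(scene, "tissue_scene"))
  lab <- scene$label_names[[tube]]
  if (is.null(lab)) .stopf("unknown tube region: %s", tube)
  vox <- which(scene$label_map == lab, arr.ind = TRUE)
  cols <- sort(unique(vox[, 2]))
  tube_len_mm <- length(cols) * scene$pixel_mm
  speed <- attr(trajectory, "speed")
  t0 <- attr(trajectory, "trigger_delay")
  t1 <- attr(trajectory, "duration")
  events <- list()
  if (speed > 0 && t1 > t0) {
    end_pos <- trajectory(t1)
    if (end_pos > tube_len_mm) {
      warning("trajectory exits tube; clipping to tube length", call. = FALSE)
      end_pos <- tube_len_mm
    }
    # columns whose start the bead reaches while moving
    col_pos <- (seq_along(cols) - 1L) * scene$pixel_mm
    reached <- which(col_pos >= trajectory(t0) & col_pos <= end_pos)
    start_pos <- attr(trajectory, "start_position")
    for (rep_i in seq_len(repetitions)) {
      for (i in reached) {
        arrival <- t0 + (col_pos[i] - start_pos) / speed * 1000
        cc <- cols[i]
        rows <- vox[vox[, 2] == cc, 1]
        fp <- data.frame(row = rows, col = cc, amplitude_um = spread_scale)
        events[[length(events) + 1L]] <- displacement_event(
          onset = arrival,
          t_contract = scene$pixel_mm / speed * 1000,
          t_relax = persist_ms,
          footprint = fp, repetition = rep_i, muscle = tube)
      }
    }
  }
  structure(list(events = events, n_repetitions = as.integer(repetitions),
                 dim = scene$dim),
            class = "displacement_events")
}
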