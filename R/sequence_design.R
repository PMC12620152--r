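#' Variable flip-angle schedule for constant stimulated-echo signal
#'
#' Computes the refocusing flip-angle series that keeps the stimulated-echo
#' signal constant over the readout cycles for a tissue with longitudinal
#' relaxation time `t1`. The last pulse deflects all remaining stored
#' magnetization (90 degrees); earlier angles follow the backward recursion
#' `alpha_n = atan(exp(-trf/t1) * sin(alpha_{n+1}))`.
#'
#' @param t1 Design T1, ms (> 0; `Inf` allowed, giving the no-decay limit).
#' @param trf Inter-pulse interval, ms (> 0).
#' @param nrf Number of refocusing pulses (integer >= 1).
#' @return Numeric vector of `nrf` flip angles in degrees, strictly
#'   increasing, ending exactly at 90.
#' @examples
#' round(flip_angle_schedule(1300, 40, 10), 1)
#' @export
flip_angle_schedule <- function(t1, trf, nrf) {
  if (!is.numeric(t1) || length(t1) != 1L || is.na(t1) || t1 <= 0)
    .stopf("t1 must be a single positive number")
  if (!is.numeric(trf) || length(trf) != 1L || is.na(trf) || trf <= 0)
    .stopf("trf must be a single positive number")
  if (!.is_count(nrf) || nrf < 1) .stopf("nrf must be an integer >= 1")
  nrf <- as.integer(nrf)
  decay <- exp(-trf / t1)
  alpha <- numeric(nrf)
  alpha[nrf] <- pi / 2
  if (nrf > 1L)
    for (n in (nrf - 1L):1L) alpha[n] <- atan(decay * sin(alpha[n + 1L]))
  alpha * 180 / pi
}

#' Per-cycle mixing and motion-sensitizing times
#'
#' The effective mixing time of cycle n is `TM_n = TM + (n-1) TRF` and the
#' motion-sensitizing time (separation of the dephasing and rephasing
#' gradient lobes seen by cycle n) is `Delta_n = Delta_1 + (n-1) TRF` with
#' `Delta_1 = TM + TRF_exc + delta`.
#'
#' @param params A [sequence_params()] object.
#' @return A data frame with columns `cycle`, `tm_ms`, `delta_ms`.
#' @examples
#' cycle_timings(sequence_params(tm = 29, trf = 40, nrf = 10, b1 = 50))
#' @export
cycle_timings <- function(params) {
  stopifnot(inherits(params, "sequence_params"))
  n <- seq_len(params$nrf)
  delta1 <- params$tm + params$trf_exc + params$delta
  data.frame(
    cycle = n,
    tm_ms = params$tm + (n - 1) * params$trf,
    delta_ms = delta1 + (n - 1) * params$trf
  )
}

#' b-value series scaled from the first cycle
#'
#' Because the gradient amplitude is fixed by the first cycle's b-value, the
#' later cycles' b-values follow from the growth of the motion-sensitizing
#' time alone:
#' `b_n = b1 * [d^2 (Delta_n - d/3) + xi^3/30 - d xi^2/6] /
#'             [d^2 (Delta_1 - d/3) + xi^3/30 - d xi^2/6]`.
#'
#' @inheritParams cycle_timings
#' @return Numeric vector of `nrf` b-values in s/mm^2; element 1 equals
#'   `params$b1` exactly.
#' @examples
#' round(b_value_series(sequence_params(tm = 29, trf = 40, nrf = 10, b1 = 50)))
#' @export
b_value_series <- function(params) {
  stopifnot(inherits(params, "sequence_params"))
  tim <- cycle_timings(params)
  den <- .gradient_bracket(params$delta, params$xi, tim$delta_ms[1])
  if (den <= 0)
    .stopf("non-physical gradient timing: bracket term <= 0 for delta1 = %g ms",
           tim$delta_ms[1])
  b <- params$b1 * .gradient_bracket(params$delta, params$xi, tim$delta_ms) / den
  b[1] <- params$b1
  b
}

#' Absolute b-value of a trapezoidal motion-sensitizing gradient pair
#'
#' `b = gamma^2 G^2 [delta^2 (Delta - delta/3) + xi^3/30 - delta xi^2/6]`,
#' the standard expression for two trapezoidal lobes of amplitude `g`,
#' flat-top-equivalent duration `delta`, ramp time `xi` and separation
#' `Delta`, ignoring imaging gradients.
#'
#' @param g Gradient amplitude, mT/m (>= 0).
#' @param delta Lobe duration, ms (>= 0).
#' @param xi Ramp time, ms (>= 0).
#' @param Delta Lobe separation, ms (>= 0). May be a vector.
#' @return b-value(s) in s/mm^2.
#' @examples
#' b_value_absolute(27, 5, 1, 40) # close to 50 s/mm^2
#' @export
b_value_absolute <- function(g, delta, xi, Delta) {
  if (any(c(g, delta, xi, Delta) < 0) || anyNA(c(g, delta, xi, Delta)))
    .stopf("all arguments must be non-negative numbers")
  br <- .gradient_bracket(.ms_to_s(delta), .ms_to_s(xi), .ms_to_s(Delta))
  .s_m2_to_s_mm2(GAMMA_H1^2 * .mT_m_to_T_m(g)^2 * br)
}

#' Gradient amplitude that realizes a target b-value
#'
#' Closed-form inversion of the trapezoidal b-value expression:
#' `G = sqrt(b / (gamma^2 [delta^2 (Delta - delta/3) + xi^3/30 - delta xi^2/6]))`.
#' Round-trips with [b_value_absolute()] to numerical precision.
#'
#' @param b Target b-value, s/mm^2 (>= 0).
#' @param delta Lobe duration, ms.
#' @param xi Ramp time, ms.
#' @param Delta Lobe separation, ms.
#' @return Gradient amplitude in mT/m.
#' @examples
#' round(gradient_amplitude(50, 5, 1, 156), 1) # 13.5 mT/m
#' @export
gradient_amplitude <- function(b, delta, xi, Delta) {
  if (any(c(b, delta, xi, Delta) < 0) || anyNA(c(b, delta, xi, Delta)))
    .stopf("all arguments must be non-negative numbers")
  br <- .gradient_bracket(.ms_to_s(delta), .ms_to_s(xi), .ms_to_s(Delta))
  if (any(br <= 0)) .stopf("gradient bracket term <= 0: delta too long for Delta")
  sqrt(.s_mm2_to_s_m2(b) / (GAMMA_H1^2 * br)) * 1e3
}

#' Displacement producing a given phase shift
#'
#' Net displacement between the dephasing and rephasing lobes that shifts
#' the spin phase by `phase` radians: `dx = phase / (gamma G delta)`. This is
#' the sequence's displacement sensitivity; a pi shift fully inverts the
#' voxel contribution.
#'
#' @param g Gradient amplitude, mT/m (> 0).
#' @param delta Lobe duration, ms (> 0).
#' @param phase Phase shift, radians (>= 0).
#' @return Displacement in micrometres.
#' @examples
#' round(displacement_for_phase(27, 5, pi)) # 87 um
#' @export
displacement_for_phase <- function(g, delta, phase) {
  if (any(c(g, delta) <= 0) || anyNA(c(g, delta, phase)) || any(phase < 0))
    .stopf("g and delta must be > 0 and phase >= 0")
  .m_to_um(phase / (GAMMA_H1 * .mT_m_to_T_m(g) * .ms_to_s(delta)))
}

#' Phase shift produced by a given displacement
#'
#' Inverse of [displacement_for_phase()]: `phase = gamma G delta dx`.
#'
#' @inheritParams displacement_for_phase
#' @param displacement_um Net displacement between the gradient lobes, um.
#' @return Phase in radians.
#' @export
phase_for_displacement <- function(g, delta, displacement_um) {
  if (any(c(g, delta) <= 0) || anyNA(c(g, delta, displacement_um)))
    .stopf("g and delta must be > 0")
  GAMMA_H1 * .mT_m_to_T_m(g) * .ms_to_s(delta) * .um_to_m(displacement_um)
}

#' Full per-cycle schedule of an MP-DW-STE acquisition
#'
#' Combines the flip-angle series, cycle timings and b-value series into one
#' table and solves for the (fixed) motion-sensitizing gradient amplitude
#' from the first cycle's b-value.
#'
#' @inheritParams cycle_timings
#' @return A data frame of class `cycle_schedule` with columns `cycle`,
#'   `alpha_deg`, `tm_ms`, `delta_ms`, `b_s_mm2`, and attributes `g_d_mt_m`
#'   (gradient amplitude, mT/m) and `params`.
#' @examples
#' cycle_schedule(sequence_params(tm = 145, trf = 40, nrf = 10, b1 = 50))
#' @export
cycle_schedule <- function(params) {
  stopifnot(inherits(params, "sequence_params"))
  tim <- cycle_timings(params)
  sched <- data.frame(
    cycle = tim$cycle,
    alpha_deg = flip_angle_schedule(params$t1_design, params$trf, params$nrf),
    tm_ms = tim$tm_ms,
    delta_ms = tim$delta_ms,
    b_s_mm2 = b_value_series(params)
  )
  attr(sched, "g_d_mt_m") <-
    gradient_amplitude(params$b1, params$delta, params$xi, tim$delta_ms[1])
  attr(sched, "params") <- params
  class(sched) <- c("cycle_schedule", "data.frame")
  sched
}

#' @export
print.cycle_schedule <- function(x, ...) {
  cat(sprintf("MP-DW-STE cycle schedule (G_D = %.2f mT/m)\n",
              attr(x, "g_d_mt_m")))
  print.data.frame(cbind(x[, 1, drop = FALSE], round(x[, -1], 2)),
                   row.names = FALSE)
  invisible(x)
}

#' Export a cycle schedule to CSV or JSON
#'
#' The CSV dialect writes one row per cycle (columns `cycle`, `alpha_deg`,
#' `tm_ms`, `delta_ms`, `b_s_mm2`). The JSON document additionally carries
#' the full parameter set and gradient amplitude under a versioned schema;
#' [import_schedule()] rebuilds the schedule from these parameters, so the
#' JSON round-trip is exact.
#'
#' @param schedule A [cycle_schedule()] object.
#' @param path Destination file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_schedule <- function(schedule, path, format = c("csv", "json")) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  } else {
    p <- attr(schedule, "params")
    doc <- list(
      schema = "mpdwste-schedule/1",
      params = unclass(p),
      g_d_mt_m = attr(schedule, "g_d_mt_m"),
      schedule = as.data.frame(schedule)
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Re-import a JSON schedule document
#'
#' Reads a document written by [export_schedule()] in JSON format and
#' recomputes the schedule from the stored parameters, guaranteeing exact
#' agreement with the original object.
#'
#' @param path JSON file written by [export_schedule()].
#' @return A `cycle_schedule` object.
#' @export
import_schedule <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || !identical(doc$schema, "mpdwste-schedule/1"))
    .stopf("not an mpdwste schedule document: %s", path)
  p <- doc$params
  cycle_schedule(sequence_params(
    tm = p$tm, trf = p$trf, nrf = p$nrf, b1 = p$b1, delta = p$delta,
    xi = p$xi, trf_exc = p$trf_exc, te = p$te, tr = p$tr,
    t1_design = p$t1_design))
}
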