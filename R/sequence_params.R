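#' Sequence parameter set for an MP-DW-STE acquisition
#'
#' Bundles the adjustable timing and diffusion-weighting parameters of a
#' multiple-point diffusion-weighted stimulated-echo acquisition. The
#' stimulated echo stores magnetization longitudinally during the mixing time
#' `tm`; a train of `nrf` variable flip-angle refocusing pulses, one every
#' `trf` milliseconds, reads it out cycle by cycle, so the effective mixing
#' time and the motion-sensitizing time grow by `trf` per cycle.
#'
#' @param tm Initial mixing time T_M, ms (> 0).
#' @param trf Interval between consecutive refocusing pulses T_RF, ms (> 0).
#'   This is also the temporal resolution of the image series.
#' @param nrf Number of refocusing cycles N_RF (integer >= 1).
#' @param b1 b-value of the first imaging cycle, s/mm^2 (>= 0).
#' @param delta Flat-top-equivalent duration of one motion-sensitizing
#'   gradient lobe, ms (> 0).
#' @param xi Gradient ramp (rise) time, ms, with `0 < xi <= delta`.
#' @param trf_exc Duration of the refocusing RF pulse, ms (>= 0).
#' @param te Echo time, ms.
#' @param tr Repetition interval between consecutive shots, ms.
#' @param t1_design Tissue T1 the flip-angle series is designed for, ms.
#'
#' @return An object of class `sequence_params` (a named list).
#' @seealso [cycle_schedule()], [validate_sequence_params()]
#' @examples
#' sequence_params(tm = 145, trf = 40, nrf = 10, b1 = 50)
#' @export
sequence_params <- function(tm, trf, nrf, b1,
                            delta = 5, xi = 1, trf_exc = 6,
                            te = 22, tr = 1000, t1_design = 1300) {
  p <- list(tm = tm, trf = trf, nrf = nrf, b1 = b1, delta = delta, xi = xi,
            trf_exc = trf_exc, te = te, tr = tr, t1_design = t1_design)
  diag <- validate_sequence_params(p)
  if (length(diag$violations) > 0L)
    .stopf("invalid sequence parameters: %s",
           paste(diag$violations, collapse = "; "))
  p$nrf <- as.integer(nrf)
  class(p) <- "sequence_params"
  p
}

#' Diagnose a sequence parameter set without throwing
#'
#' Checks a (possibly invalid) parameter list against the physical and
#' structural constraints of the sequence and reports violations together
#' with derived quantities. Unlike [sequence_params()], this never throws, so
#' it can be used to vet user input such as CLI arguments or config files.
#'
#' @param params A `sequence_params` object or a plain named list with the
#'   same fields.
#' @return A list of class `sequence_diagnostics` with elements `violations`
#'   (character vector, empty when the set is valid) and `derived` (initial
#'   motion-sensitizing time `delta1_ms`, `temporal_resolution_ms` = T_RF and
#'   `readout_window_ms` = last motion-sensitizing time), the latter `NULL`
#'   when they cannot be computed.
#' @export
validate_sequence_params <- function(params) {
  p <- unclass(params)
  v <- character(0)
  num1 <- function(field) {
    x <- p[[field]]
    if (is.null(x) || length(x) != 1L || !is.numeric(x) || is.na(x)) {
      v <<- c(v, sprintf("%s must be a single number", field))
      return(NA_real_)
    }
    as.numeric(x)
  }
  tm <- num1("tm"); trf <- num1("trf"); nrf <- num1("nrf"); b1 <- num1("b1")
  delta <- num1("delta"); xi <- num1("xi"); trf_exc <- num1("trf_exc")
  t1 <- num1("t1_design")

  chk <- function(ok, msg) if (!is.na(ok) && !ok) v <<- c(v, msg)
  chk(tm > 0, "tm must be > 0")
  chk(trf > 0, "trf must be > 0")
  if (!is.na(nrf) && (nrf < 1 || nrf != round(nrf)))
    v <- c(v, "nrf must be an integer >= 1")
  chk(b1 >= 0, "b1 must be >= 0")
  chk(delta > 0, "delta must be > 0")
  chk(xi > 0, "xi must be > 0")
  if (!is.na(xi) && !is.na(delta) && xi > delta)
    v <- c(v, "xi must not exceed delta")
  chk(trf_exc >= 0, "trf_exc must be >= 0")
  chk(t1 > 0, "t1_design must be > 0")

  derived <- NULL
  if (!anyNA(c(tm, trf, nrf, delta, xi, trf_exc)) && nrf >= 1) {
    delta1 <- tm + trf_exc + delta
    if (delta1 <= 0) v <- c(v, "delta1 = tm + trf_exc + delta must be > 0")
    if (.gradient_bracket(delta, xi, delta1) <= 0)
      v <- c(v, "gradient bracket non-positive: delta too long for delta1")
    derived <- list(
      delta1_ms = delta1,
      temporal_resolution_ms = trf,
      readout_window_ms = delta1 + (nrf - 1) * trf
    )
  }
  structure(list(violations = v, derived = derived),
            class = "sequence_diagnostics")
}

#' @export
print.sequence_diagnostics <- function(x, ...) {
  if (length(x$violations) == 0L) {
    cat("sequence parameters: OK\n")
  } else {
    cat("sequence parameter violations:\n")
    cat(paste0("  - ", x$violations, collapse = "\n"), "\n")
  }
  if (!is.null(x$derived)) {
    cat(sprintf("  delta1 = %g ms, temporal resolution = %g ms, readout window = %g ms\n",
                x$derived$delta1_ms, x$derived$temporal_resolution_ms,
                x$derived$readout_window_ms))
  }
  invisible(x)
}

#' @export
print.sequence_params <- function(x, ...) {
  cat(sprintf(
    "MP-DW-STE parameters: TM = %g ms, TRF = %g ms, NRF = %d, b1 = %g s/mm^2\n",
    x$tm, x$trf, x$nrf, x$b1))
  cat(sprintf(
    "  delta = %g ms, xi = %g ms, TRF_exc = %g ms, TE = %g ms, TR = %g ms, design T1 = %g ms\n",
    x$delta, x$xi, x$trf_exc, x$te, x$tr, x$t1_design))
  invisible(x)
}
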