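#' @keywords internal
"_PACKAGE"

# Proton gyromagnetic ratio, rad s^-1 T^-1 (gamma/2pi = 42.577 MHz/T).
GAMMA_H1 <- 2 * pi * 42.577e6

# All user-facing interfaces use ms, mT/m, s/mm^2 and um; every physical
# computation happens in SI. Conversions are kept here so no other file
# multiplies by a power of ten.
.ms_to_s <- function(x) x * 1e-3
.mT_m_to_T_m <- function(x) x * 1e-3
.s_m2_to_s_mm2 <- function(x) x * 1e-6
.s_mm2_to_s_m2 <- function(x) x * 1e6
.um_to_m <- function(x) x * 1e-6
.m_to_um <- function(x) x * 1e6

# Trapezoidal motion-sensitizing gradient bracket
# delta^2 (Delta - delta/3) + xi^3/30 - delta xi^2/6.
# Unit-agnostic: consistent time units in -> that unit cubed out.
.gradient_bracket <- function(delta, xi, Delta) {
  delta^2 * (Delta - delta / 3) + xi^3 / 30 - delta * xi^2 / 6
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}
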