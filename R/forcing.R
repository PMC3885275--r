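#' Cardiac pressure waveform and aspiration forcing
#'
#' The arterial pressure over one 1-second cardiac cycle is approximated by
#' two polynomials in kPa: a systolic piece on 0-0.32 s and a diastolic
#' piece on 0.32-1.00 s, spanning roughly 11-16 kPa (80-120 mmHg). The
#' coefficients were fitted to a typical pressure waveform and are stored
#' exactly as printed; evaluation uses Horner's scheme.
#'
#' @name forcing
NULL

# polynomial coefficients, kPa over s, highest degree first
.systolic_coeffs <- c(13415, -8508.6, 986.58, 177.3, -4.99, 11.01)
.diastolic_coeffs <- c(-1488, 6237.6, -10700, 9595.3, -4719.5, 1188.3, -102.8)

.horner <- function(coeffs, t) {
  acc <- rep_len(coeffs[1], length(t))
  for (c_i in coeffs[-1]) acc <- acc * t + c_i
  acc
}

# antiderivative evaluated at t (constant of integration 0)
.poly_antideriv <- function(coeffs, t) {
  deg <- length(coeffs) - 1L
  .horner(c(coeffs / (deg + 1L - seq_along(coeffs) + 1L), 0), t)
}

#' Systolic-phase arterial pressure
#'
#' Degree-5 polynomial valid on the systolic piece of the cycle,
#' 0 <= t <= 0.32 s.
#'
#' @param t time within the cycle (s).
#' @return pressure (kPa).
#' @examples
#' systolic_pressure(0) # 11.01 kPa
#' @export
systolic_pressure <- function(t) {
  if (any(t < 0 | t > 0.32)) {
    stop("systolic_pressure is defined on [0, 0.32] s; use cardiac_pressure",
         call. = FALSE)
  }
  .horner(.systolic_coeffs, t)
}

#' Diastolic-phase arterial pressure
#'
#' Degree-6 polynomial valid on the diastolic piece of the cycle,
#' 0.32 <= t <= 1.00 s.
#'
#' @param t time within the cycle (s).
#' @return pressure (kPa).
#' @export
diastolic_pressure <- function(t) {
  if (any(t < 0.32 | t > 1)) {
    stop("diastolic_pressure is defined on [0.32, 1.0] s; use cardiac_pressure",
         call. = FALSE)
  }
  .horner(.diastolic_coeffs, t)
}

#' Periodic cardiac pressure
#'
#' Reduces `t` modulo the cycle period (1 s) and dispatches to the systolic
#' or diastolic polynomial. The two pieces agree within 0.05 kPa at the
#' 0.32 s boundary and within 0.12 kPa across the periodic closure.
#'
#' @param t time (s), any non-negative value; vectorized.
#' @param period cycle length (s).
#' @param switch_time systole/diastole boundary (s).
#' @return pressure (kPa).
#' @examples
#' range(cardiac_pressure(seq(0, 1, by = 1e-3))) # ~10.9 to ~16.1 kPa
#' @export
cardiac_pressure <- function(t, period = 1, switch_time = 0.32) {
  tm <- (t %% period) / period  # unit-cycle time for non-default periods
  out <- numeric(length(tm))
  sys <- tm <= switch_time / period
  out[sys] <- .horner(.systolic_coeffs, tm[sys])
  out[!sys] <- .horner(.diastolic_coeffs, tm[!sys])
  out
}

#' Mean cardiac pressure over one cycle
#'
#' Exact analytic mean of the piecewise polynomial (used to centre the
#' waveform in modulation mode).
#'
#' @param switch_time systole/diastole boundary (s).
#' @return mean pressure (kPa).
#' @export
cardiac_cycle_mean <- function(switch_time = 0.32) {
  int_sys <- .poly_antideriv(.systolic_coeffs, switch_time) -
    .poly_antideriv(.systolic_coeffs, 0)
  int_dia <- .poly_antideriv(.diastolic_coeffs, 1) -
    .poly_antideriv(.diastolic_coeffs, switch_time)
  int_sys + int_dia
}

#' Force exerted by the aspiration device on the proximal clot face
#'
#' Gauge pressure times the clot cross-section, signed so that suction
#' (negative gauge pressure) yields a positive force, i.e. toward the
#' device along the positive axis.
#'
#' @param gauge_pressure gauge pressure (Pa); negative = suction.
#' @param clot_diameter clot diameter (m).
#' @return axial force (N), positive toward the device.
#' @examples
#' aspiration_force(-20e3, 2.5e-3) # ~0.098 N toward the device
#' @export
aspiration_force <- function(gauge_pressure, clot_diameter) {
  if (any(clot_diameter <= 0)) stop("clot_diameter must be > 0", call. = FALSE)
  -gauge_pressure * pi / 4 * clot_diameter^2
}

#' Evaluate the aspiration pressure programme
#'
#' @param forcing a [forcing_spec()].
#' @param t time (s); vectorized.
#' @return gauge pressure (Pa).
#' @export
aspiration_pressure <- function(forcing, t) {
  a <- forcing$aspiration
  switch(a$type,
    constant = rep_len(a$pressure, length(t)),
    ramp = a$p_start + (a$p_end - a$p_start) * pmin(pmax(t / a$t_ramp, 0), 1),
    table = stats::approx(a$time, a$pressure, xout = t, rule = 2,
                          ties = "ordered")$y)
}

#' Total applied force on the proximal partition
#'
#' Builds the function F(t) that drives the chain: the aspiration force
#' plus, when the heartbeat is enabled, the cardiac pressure acting on the
#' proximal cross-section. In `"modulation"` mode the waveform is centred
#' on its cycle mean so enabling the heartbeat does not change the mean
#' load; `"absolute"` applies the raw waveform.
#'
#' @param scenario a [scenario()].
#' @return function of time (s) returning force (N, positive toward the
#'   device).
#' @export
make_applied_force <- function(scenario) {
  forcing <- scenario$forcing
  area <- pi / 4 * scenario$clot$diameter^2
  if (isTRUE(forcing$cardiac_enabled)) {
    offset <- if (forcing$cardiac_mode == "modulation") {
      cardiac_cycle_mean(forcing$cardiac_switch_time)
    } else 0
    function(t) {
      p_kpa <- cardiac_pressure(t, forcing$cardiac_period,
                                forcing$cardiac_switch_time)
      aspiration_force(aspiration_pressure(forcing, t),
                       scenario$clot$diameter) +
        (p_kpa - offset) * 1e3 * area
    }
  } else {
    function(t) {
      aspiration_force(aspiration_pressure(forcing, t),
                       scenario$clot$diameter)
    }
  }
}

#' Export one cardiac cycle to a data frame
#'
#' @param dt sampling interval (s).
#' @return data frame with columns `t` (s), `kPa` and `mmHg`.
#' @export
cardiac_waveform_table <- function(dt = 1e-3) {
  t <- seq(0, 1, by = dt)
  p <- cardiac_pressure(t)
  data.frame(t = t, kPa = p, mmHg = kpa_to_mmhg(p))
}
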