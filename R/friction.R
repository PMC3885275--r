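#' Wall friction laws
#'
#' The clot-wall contact resists motion with a linear (Stokes-type) drag
#' while at rest on the anchor (static regime) and a lower drag once moving
#' (dynamic regime). The dynamic law is either linear with a coefficient one
#' decade below the static one, or the quadratic Stokes drag for a blunt
#' cylinder, `(C/8) * rho * pi * D^2 * v^2`.
#'
#' @name friction
NULL

#' Linear friction force
#'
#' @param R friction coefficient (N.s/m); static value 2.5e-6 by default in
#'   the model, dynamic one decade lower.
#' @param v velocity (m/s).
#' @return force `-R * v` (N), opposing motion.
#' @export
linear_friction_force <- function(R, v) {
  if (any(R < 0)) stop("R must be >= 0", call. = FALSE)
  -R * v
}

#' Quadratic (Stokes) dynamic friction force for a cylindrical clot
#'
#' Magnitude `(C/8) * rho * pi * D^2 * v^2`, directed against the velocity.
#' Below `v_reg` the law is linearized (`-k * v_reg * v`) so the force is
#' smooth through v = 0 for the ODE solver; the two branches agree at
#' `|v| = v_reg`.
#'
#' @param C dimensionless form coefficient (~1.2 for a blunt cylinder).
#' @param rho blood density (kg/m^3).
#' @param D clot diameter (m).
#' @param v velocity (m/s).
#' @param v_reg regularization half-width (m/s); 0 gives the raw law.
#' @return friction force (N), opposing motion.
#' @export
stokes_dynamic_friction <- function(C, rho, D, v, v_reg = 0) {
  if (any(c(C, rho, D) < 0) || v_reg < 0) {
    stop("C, rho, D and v_reg must be >= 0", call. = FALSE)
  }
  k <- (C / 8) * rho * pi * D^2
  ifelse(abs(v) <= v_reg, -k * v_reg * v, -sign(v) * k * v^2)
}

# dispatch on the configured dynamic-friction mode
.dynamic_friction <- function(mech, D, v) {
  if (mech$dynamic_friction_mode == "linear") {
    linear_friction_force(mech$R_dynamic, v)
  } else {
    stokes_dynamic_friction(mech$C_form, mech$rho_blood, D, v,
                            v_reg = mech$v_regularization)
  }
}

#' Friction state of the partition chain
#'
#' @param n_partitions number of partitions.
#' @param transition_displacement measurement-spring displacement (m) at
#'   which the static regime ends (single-body model; the chain model
#'   switches a partition at its detachment event).
#' @return object of class `friction_state`: per-partition regime plus the
#'   transition displacement.
#' @export
friction_state <- function(n_partitions, transition_displacement = Inf) {
  structure(list(regime = rep("static", n_partitions),
                 transition_displacement = transition_displacement),
            class = "friction_state")
}

#' Update the friction regime of a partition
#'
#' A partition is in the static regime while it is attached and its
#' measurement displacement is below the transition displacement; it is
#' dynamic otherwise. A detached partition always slides (dynamic).
#' Regime changes are one-way under monotone loading: once dynamic, a
#' partition does not revert while it keeps moving.
#'
#' @param state a [friction_state()].
#' @param displacement measurement displacement of the partition (m).
#' @param attached is the partition still attached to the wall?
#' @param index partition index (1-based).
#' @return updated `friction_state`.
#' @export
update_regime <- function(state, displacement, attached, index = 1L) {
  stopifnot(inherits(state, "friction_state"))
  state$regime[index] <-
    if (attached && displacement < state$transition_displacement) "static"
    else "dynamic"
  state
}
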