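#' Chain dynamics of the partitioned clot
#'
#' The clot is a 1-D chain of point masses (partitions) along the artery
#' axis, positive direction toward the aspiration device, partition 0 at
#' the proximal face. Neighbouring partitions are coupled by identical
#' spring-damper unions (K_union, R_union) that start unstretched; positions
#' are stored as displacements from the initial configuration, so union
#' rest gaps cancel. An attached partition is held by an exact algebraic
#' constraint (its velocity and acceleration are pinned to zero - the
#' effort source supplies whatever force keeps the net load zero); it is
#' released, permanently, when the pulling force transmitted to it exceeds
#' its adhesion force: the applied aspiration force for partition 0, the
#' union-spring tension from its already-moving proximal neighbour for
#' interior partitions.
#'
#' @name clot-dynamics
NULL

#' Build the single-body (simple) model
#'
#' One inertia `I = m` behind a measurement spring `K_eq` (the equivalent of
#' one surface-tension anchor spring per 0.1 mm of clot, combined per the
#' configured rule), anchored to the wall by a very stiff spring-damper
#' (`K_wall`, `R_wall`) that is removed once the measurement-spring
#' displacement reaches the release displacement, i.e. once the applied
#' force reaches `F_move_threshold`. Wall friction is static (linear,
#' `R_static`) while anchored and dynamic after release.
#'
#' @param scenario a [scenario()] with `model_variant = "simple"`
#'   (`n_partitions` must be 1).
#' @return object of class `clot_chain_model`.
#' @export
build_simple_model <- function(scenario) {
  if (scenario$clot$n_partitions != 1L) {
    .validation_error("build_simple_model requires n_partitions = 1")
  }
  adh <- adhesion_summary(scenario)
  structure(list(variant = "simple",
                 mass = scenario$clot$total_mass,
                 K_surface = adh$K_surface, n_spheres = adh$n_spheres,
                 K_eq = adh$K_eq,
                 release_displacement = adh$release_displacement,
                 partitions = partition_clot(scenario$artery, scenario$clot, 1L),
                 mech = scenario$mech, clot = scenario$clot,
                 artery = scenario$artery),
            class = "clot_chain_model")
}

#' Build the partitioned (extended) model
#'
#' n inertias coupled by (K_union, R_union) unions, each attached partition
#' held by a zero-net-force constraint and carrying the adhesion force of
#' its wall-contact patch from the platelet model (equal-area partitions
#' when the artery is stenosed).
#'
#' @param scenario a [scenario()].
#' @return object of class `clot_chain_model` with fields `partitions`
#'   (a `clot_partitions` data frame), `attached`, and the coupling and
#'   friction parameters.
#' @export
build_extended_model <- function(scenario) {
  parts <- partition_clot(scenario$artery, scenario$clot)
  if (any(!is.finite(parts$adhesion_force))) {
    .validation_error("partition adhesion forces are not finite")
  }
  structure(list(variant = "extended",
                 partitions = parts,
                 attached = rep(TRUE, nrow(parts)),
                 K_union = scenario$mech$K_union,
                 R_union = scenario$mech$R_union,
                 mech = scenario$mech, clot = scenario$clot,
                 artery = scenario$artery),
            class = "clot_chain_model")
}

#' @export
print.clot_chain_model <- function(x, ...) {
  cat("<clot_chain_model>", x$variant, "variant\n")
  if (x$variant == "simple") {
    cat(sprintf("  m = %.3g kg, K_surface = %.4g N/m, n_spheres = %d, K_eq = %.4g N/m\n",
                x$mass, x$K_surface, x$n_spheres, x$K_eq))
    cat(sprintf("  release displacement = %.4g m\n", x$release_displacement))
  } else {
    cat(sprintf("  %d partitions, K_union = %.3g N/m, R_union = %.3g N.s/m\n",
                nrow(x$partitions), x$K_union, x$R_union))
    cat(sprintf("  adhesion forces (N): %s\n",
                paste(signif(x$partitions$adhesion_force, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Union spring-damper force
#'
#' Force exerted on partition i by the union to partition j:
#' `K * (x_j - x_i - rest_gap) + R * (v_j - v_i)`. Equal and opposite on the
#' pair (swap the arguments to get the force on j).
#'
#' @param x_i,v_i position (m) and velocity (m/s) of partition i.
#' @param x_j,v_j position and velocity of partition j.
#' @param K_union spring stiffness (N/m).
#' @param R_union damping (N.s/m).
#' @param rest_gap unstretched spring length expressed in the same
#'   coordinates (0 when positions are displacements from the initial
#'   configuration).
#' @return force on partition i (N).
#' @export
union_force <- function(x_i, v_i, x_j, v_j, K_union, R_union, rest_gap = 0) {
  K_union * (x_j - x_i - rest_gap) + R_union * (v_j - v_i)
}

# pulling force transmitted to the most-proximal still-attached partition j
# (1-based index into the chain); x, v are full displacement/velocity vectors
.release_trigger <- function(t, x, v, j, model, F_applied) {
  if (j == 1L) {
    F_applied(t)
  } else {
    f <- model$K_union * (x[j - 1L] - x[j])
    if (model$mech$release_criterion == "net") {
      f <- f + model$R_union * (v[j - 1L] - v[j])
    }
    f
  }
}

#' Partitions due for release
#'
#' Applies the detachment rule to the current state: the most-proximal
#' still-attached partition is released when the pulling force transmitted
#' to it meets or exceeds its adhesion force. Detachment proceeds strictly
#' front-to-back; the function returns the (possibly empty) vector of
#' 0-based partition indices that should be released at this instant,
#' cascading through consecutive partitions whose triggers are already
#' exceeded.
#'
#' @param model a `clot_chain_model` (extended variant).
#' @param state list with elements `t`, `x`, `v`, `attached`.
#' @param F_applied function of time giving the applied force on the
#'   proximal partition (N).
#' @return integer vector of 0-based partition indices to release.
#' @export
detachment_event <- function(model, state, F_applied) {
  x <- state$x; v <- state$v; attached <- state$attached
  Fadh <- model$partitions$adhesion_force
  out <- integer(0)
  repeat {
    j <- which(attached)[1]
    if (is.na(j)) break
    trig <- .release_trigger(state$t, x, v, j, model, F_applied)
    if (trig >= Fadh[j]) {
      out <- c(out, j - 1L)
      attached[j] <- FALSE
    } else break
  }
  out
}

#' Union tensions along the chain
#'
#' Spring tension carried by each junction (positive when the junction is
#' stretched, i.e. transmitting a pull toward the device).
#'
#' @param model a `clot_chain_model` (extended variant).
#' @param x displacement vector (m).
#' @return numeric vector of length `n_partitions - 1`.
#' @export
union_tensions <- function(model, x) {
  n <- nrow(model$partitions)
  if (n < 2L) return(numeric(0))
  model$K_union * (x[-n] - x[-1L])
}

#' Rupture check
#'
#' The extraction fails if the force carried by any inter-partition union
#' exceeds the clot's rupture force: a long clot accumulates adhesion
#' faster than the suction can be raised and snaps before it is fully
#' detached.
#'
#' @param model a `clot_chain_model`.
#' @param x displacement vector (m).
#' @param F_rupture rupture force (N); `Inf` disables the check.
#' @return list with `ruptured` (logical) and `junction` (1-based index of
#'   the most loaded junction, or `NA`).
#' @export
rupture_check <- function(model, x, F_rupture = model$mech$F_rupture) {
  tens <- union_tensions(model, x)
  if (!length(tens) || !is.finite(F_rupture)) {
    return(list(ruptured = FALSE, junction = NA_integer_))
  }
  worst <- which.max(abs(tens))
  list(ruptured = abs(tens[worst]) > F_rupture, junction = worst)
}

#' Right-hand side of the chain ODE
#'
#' State is `c(x, v)` over all partitions. Attached partitions have zero
#' derivatives (exact constraint); each detached partition i obeys
#' `m_i a_i = F_applied(t) [i = 1] + union forces + dynamic friction`.
#'
#' @param t time (s).
#' @param state numeric vector `c(x, v)` of length `2 n`.
#' @param model a `clot_chain_model` (extended variant).
#' @param attached logical vector of attachments.
#' @param F_applied function of time, force on the proximal partition (N).
#' @return list with the derivative vector, as `deSolve` expects.
#' @export
chain_rhs <- function(t, state, model, attached, F_applied) {
  n <- nrow(model$partitions)
  x <- state[seq_len(n)]
  v <- state[n + seq_len(n)]
  dx <- numeric(n)
  dv <- numeric(n)
  free <- which(!attached)
  if (length(free)) {
    force <- numeric(n)
    force[1L] <- F_applied(t)
    if (n > 1L) {
      # union force on i from the right neighbour; reaction on the neighbour
      tens <- model$K_union * (x[-1L] - x[-n]) +
        model$R_union * (v[-1L] - v[-n])
      force[-n] <- force[-n] + tens
      force[-1L] <- force[-1L] - tens
    }
    force[free] <- force[free] +
      .dynamic_friction(model$mech, model$clot$diameter, v[free])
    dx[free] <- v[free]
    dv[free] <- force[free] / model$partitions$mass[free]
  }
  list(c(dx, dv))
}

# root functions for the event locator: (release excess, rupture excess)
.chain_root <- function(t, state, model, attached, F_applied) {
  n <- nrow(model$partitions)
  x <- state[seq_len(n)]
  v <- state[n + seq_len(n)]
  j <- which(attached)[1]
  r_release <- if (is.na(j)) -1 else {
    .release_trigger(t, x, v, j, model, F_applied) -
      model$partitions$adhesion_force[j]
  }
  r_rupture <- if (is.finite(model$mech$F_rupture) && n > 1L) {
    max(abs(union_tensions(model, x))) - model$mech$F_rupture
  } else -1
  c(r_release, r_rupture)
}
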