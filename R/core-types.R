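#' Scenario building blocks
#'
#' A simulation [scenario()] bundles four specifications: the artery
#' ([artery_spec()]), the clot ([clot_spec()]), the mechanical constants
#' ([mechanical_params()]) and the forcing programme ([forcing_spec()]).
#' Every constructor validates its invariants and stores SI values.
#'
#' @name core-types
NULL

.validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("clotbg_validation_error", "error")))
}

.check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    .validation_error(field, " must be a positive finite number (got ",
                      format(x), ")")
  }
  invisible(x)
}

#' Artery specification
#'
#' @param diameter internal artery diameter in metres.
#' @param occlusion_fraction fraction of the lumen occluded by the clot,
#'   in (0, 1]; 1 means total occlusion.
#' @param stenosis optional stenosis description: `NULL` for a straight
#'   cylindrical lumen, or a list `list(severity =)` describing a cosine-bump
#'   radial narrowing (severity is the fractional radius reduction at the
#'   bump apex, in \[0, 1)). A custom profile may be given as
#'   `list(profile = function(x) ...)` returning the local radius in metres.
#' @return object of class `artery_spec`.
#' @export
artery_spec <- function(diameter, occlusion_fraction = 1, stenosis = NULL) {
  .check_positive(diameter, "artery.diameter")
  if (!is.numeric(occlusion_fraction) || occlusion_fraction <= 0 ||
      occlusion_fraction > 1) {
    .validation_error("artery.occlusion_fraction must be in (0, 1]")
  }
  if (!is.null(stenosis)) {
    if (!is.list(stenosis)) .validation_error("artery.stenosis must be a list")
    if (!is.null(stenosis$severity)) {
      s <- stenosis$severity
      if (!is.numeric(s) || s < 0 || s >= 1) {
        .validation_error("artery.stenosis.severity must be in [0, 1)")
      }
    } else if (is.null(stenosis$profile)) {
      .validation_error(
        "artery.stenosis needs either a 'severity' or a 'profile' entry")
    }
  }
  structure(list(diameter = diameter,
                 occlusion_fraction = occlusion_fraction,
                 stenosis = stenosis),
            class = "artery_spec")
}

#' Clot specification
#'
#' Geometry and composition of the clot. Clots in the cerebral circulation
#' are roughly cylindrical, 1-5 cm long and 0.5-2 g in mass; the platelet
#' fraction `fp`, mean platelet area `MPA` and single platelet-wall bond
#' force `F_platelet` determine the adhesion force of each partition.
#' `total_mass` is an independent input rather than being derived from
#' density times volume, because reported clot masses are not consistent
#' with a nominal density for this geometry.
#'
#' @param length clot length (m).
#' @param diameter clot diameter (m).
#' @param total_mass clot mass (kg).
#' @param n_partitions number of chain partitions (>= 1).
#' @param fp platelet fraction of the clot, in (0, 1].
#' @param MPA mean platelet area (m^2).
#' @param F_platelet single platelet to artery-wall bond force (N).
#' @param sphere_spacing spacing of the adhesion anchor spheres along the
#'   clot (m); one anchor sphere per 0.1 mm by default.
#' @return object of class `clot_spec`.
#' @export
clot_spec <- function(length, diameter, total_mass, n_partitions = 3,
                      fp = 0.96, MPA = 5.31e-12, F_platelet = 32e-9,
                      sphere_spacing = 1e-4) {
  .check_positive(length, "clot.length")
  .check_positive(diameter, "clot.diameter")
  .check_positive(total_mass, "clot.total_mass")
  .check_positive(sphere_spacing, "clot.sphere_spacing")
  .check_positive(MPA, "clot.MPA")
  if (!is.numeric(fp) || fp <= 0 || fp > 1) {
    .validation_error("clot.fp must be in (0, 1]")
  }
  if (!is.numeric(F_platelet) || F_platelet < 0) {
    .validation_error("clot.F_platelet must be >= 0")
  }
  if (!is.numeric(n_partitions) || n_partitions < 1 ||
      n_partitions != round(n_partitions)) {
    .validation_error("clot.n_partitions must be a positive integer")
  }
  structure(list(length = length, diameter = diameter,
                 total_mass = total_mass,
                 n_partitions = as.integer(n_partitions),
                 fp = fp, MPA = MPA, F_platelet = F_platelet,
                 sphere_spacing = sphere_spacing),
            class = "clot_spec")
}

#' Mechanical parameters
#'
#' Stiffness, damping, friction and threshold constants of the model.
#' Defaults are the reference parameter set: inter-partition spring
#' `K_union` = 1.91 N/m and damper `R_union` = 0.035 N.s/m, linear static
#' wall friction 2.5e-6 N.s/m with the dynamic value one decade lower, a
#' very stiff wall anchor (1e10 N/m, 1e9 N.s/m) for the single-body model,
#' and a 0.01 N movement threshold.
#'
#' @param K_union inter-partition spring stiffness (N/m).
#' @param R_union inter-partition damping (N.s/m).
#' @param R_static linear static wall-friction coefficient (N.s/m).
#' @param dynamic_friction_mode `"linear"` (coefficient `R_dynamic`) or
#'   `"stokes_quadratic"` (Stokes-type drag `(C/8) rho pi D^2 v^2`).
#' @param R_dynamic linear dynamic friction coefficient (N.s/m); defaults to
#'   one tenth of `R_static`.
#' @param C_form dimensionless form coefficient of the quadratic law
#'   (blunt cylinder ~ 1.2).
#' @param rho_blood blood density (kg/m^3).
#' @param K_wall,R_wall wall anchor spring and damper (N/m, N.s/m), used by
#'   the single-body model while the clot is below the movement threshold.
#' @param F_move_threshold force at which the clot starts to move (N).
#' @param F_rupture inter-partition rupture force (N); `Inf` disables the
#'   rupture check.
#' @param release_criterion `"spring"` releases an interior partition when
#'   the union-spring tension alone exceeds its adhesion force (the printed
#'   condition); `"net"` adds the union damper force.
#' @param eq_spring_mode `"divide"` uses K/n for the equivalent anchor
#'   spring (the printed formula); `"parallel_sum"` uses the conventional
#'   K*n for parallel springs.
#' @param v_regularization velocity half-width (m/s) below which the
#'   quadratic friction law is linearized to keep the vector field smooth
#'   at v = 0.
#' @return object of class `mechanical_params`.
#' @export
mechanical_params <- function(K_union = 1.91, R_union = 0.035,
                              R_static = 2.5e-6,
                              dynamic_friction_mode = c("stokes_quadratic",
                                                        "linear"),
                              R_dynamic = R_static / 10,
                              C_form = 1.2, rho_blood = 1060,
                              K_wall = 1e10, R_wall = 1e9,
                              F_move_threshold = 0.01, F_rupture = Inf,
                              release_criterion = c("spring", "net"),
                              eq_spring_mode = c("divide", "parallel_sum"),
                              v_regularization = 1e-9) {
  dynamic_friction_mode <- match.arg(dynamic_friction_mode)
  release_criterion <- match.arg(release_criterion)
  eq_spring_mode <- match.arg(eq_spring_mode)
  for (f in c("K_union", "R_static", "rho_blood", "K_wall", "R_wall",
              "F_move_threshold")) {
    .check_positive(get(f), paste0("mechanics.", f))
  }
  if (R_union < 0 || R_dynamic < 0 || C_form < 0) {
    .validation_error("mechanics damping/form coefficients must be >= 0")
  }
  if (!is.numeric(F_rupture) || F_rupture <= 0) {
    .validation_error("mechanics.F_rupture must be > 0 (Inf to disable)")
  }
  structure(list(K_union = K_union, R_union = R_union, R_static = R_static,
                 dynamic_friction_mode = dynamic_friction_mode,
                 R_dynamic = R_dynamic, C_form = C_form,
                 rho_blood = rho_blood, K_wall = K_wall, R_wall = R_wall,
                 F_move_threshold = F_move_threshold, F_rupture = F_rupture,
                 release_criterion = release_criterion,
                 eq_spring_mode = eq_spring_mode,
                 v_regularization = v_regularization),
            class = "mechanical_params")
}

#' Forcing specification
#'
#' The aspiration programme gives the gauge pressure applied by the
#' aspiration thrombectomy device at the proximal clot face as a function of
#' time; negative values are suction. Three programme types are supported:
#' `list(type = "constant", pressure =)`,
#' `list(type = "ramp", p_start =, p_end =, t_ramp =)` (linear ramp then
#' hold), and `list(type = "table", time =, pressure =)` (linear
#' interpolation, constant extrapolation). An optional cardiac waveform
#' (see [cardiac_pressure()]) modulates the load at 1 cycle per second.
#'
#' @param aspiration aspiration programme (pressures in Pa, times in s).
#' @param cardiac_enabled add the cardiac pressure waveform to the load on
#'   the proximal partition?
#' @param cardiac_period cardiac cycle length (s).
#' @param cardiac_switch_time systole/diastole boundary within the cycle (s).
#' @param cardiac_mode `"modulation"` applies the waveform minus its cycle
#'   mean (enabling the heartbeat does not change the mean load);
#'   `"absolute"` applies the raw waveform.
#' @return object of class `forcing_spec`.
#' @export
forcing_spec <- function(aspiration = list(type = "constant", pressure = 0),
                         cardiac_enabled = FALSE, cardiac_period = 1,
                         cardiac_switch_time = 0.32,
                         cardiac_mode = c("modulation", "absolute")) {
  cardiac_mode <- match.arg(cardiac_mode)
  .check_positive(cardiac_period, "forcing.cardiac_period")
  if (cardiac_switch_time <= 0 || cardiac_switch_time >= cardiac_period) {
    .validation_error("forcing.cardiac_switch_time must lie strictly inside ",
                      "(0, cardiac_period)")
  }
  if (!is.list(aspiration) || is.null(aspiration$type)) {
    .validation_error("forcing.aspiration must be a list with a 'type'")
  }
  type <- aspiration$type
  if (type == "constant") {
    if (is.null(aspiration$pressure))
      .validation_error("forcing.aspiration.pressure missing")
  } else if (type == "ramp") {
    if (is.null(aspiration$p_end) || is.null(aspiration$t_ramp))
      .validation_error("forcing.aspiration ramp needs p_end and t_ramp")
    if (is.null(aspiration$p_start)) aspiration$p_start <- 0
    .check_positive(aspiration$t_ramp, "forcing.aspiration.t_ramp")
  } else if (type == "table") {
    if (is.null(aspiration$time) || is.null(aspiration$pressure) ||
        length(aspiration$time) != length(aspiration$pressure) ||
        length(aspiration$time) < 1L)
      .validation_error("forcing.aspiration table needs matching time and ",
                        "pressure vectors")
  } else {
    .validation_error("unknown forcing.aspiration.type '", type, "'")
  }
  structure(list(aspiration = aspiration, cardiac_enabled = cardiac_enabled,
                 cardiac_period = cardiac_period,
                 cardiac_switch_time = cardiac_switch_time,
                 cardiac_mode = cardiac_mode),
            class = "forcing_spec")
}

#' Simulation scenario
#'
#' @param artery an [artery_spec()].
#' @param clot a [clot_spec()].
#' @param mech a [mechanical_params()].
#' @param forcing a [forcing_spec()].
#' @param model_variant `"extended"` (partition chain with event-driven
#'   detachment) or `"simple"` (single body with measurement spring, wall
#'   anchor and movement threshold).
#' @param extraction_distance distance (m) the clot must travel toward the
#'   device for the extraction to count; the device is held 2-3 mm from the
#'   clot face, so the default is the midpoint 2.5 mm.
#' @return object of class `clot_scenario`.
#' @export
scenario <- function(artery, clot, mech = mechanical_params(),
                     forcing = forcing_spec(),
                     model_variant = c("extended", "simple"),
                     extraction_distance = 2.5e-3) {
  model_variant <- match.arg(model_variant)
  stopifnot(inherits(artery, "artery_spec"), inherits(clot, "clot_spec"),
            inherits(mech, "mechanical_params"),
            inherits(forcing, "forcing_spec"))
  .check_positive(extraction_distance, "simulation.extraction_distance")
  if (artery$occlusion_fraction >= 1 - 1e-12 &&
      clot$diameter > artery$diameter * (1 + 1e-9)) {
    .validation_error("clot.diameter exceeds artery.diameter at 100% occlusion")
  }
  if (model_variant == "simple" && clot$n_partitions != 1L) {
    .validation_error("the simple model variant requires n_partitions = 1")
  }
  structure(list(artery = artery, clot = clot, mech = mech,
                 forcing = forcing, model_variant = model_variant,
                 extraction_distance = extraction_distance),
            class = "clot_scenario")
}

#' @export
print.clot_scenario <- function(x, ...) {
  cat("<clot_scenario> variant:", x$model_variant, "\n")
  cat(sprintf("  artery: D = %.3g mm, occlusion = %.0f%%%s\n",
              x$artery$diameter * 1e3, 100 * x$artery$occlusion_fraction,
              if (is.null(x$artery$stenosis)) "" else ", stenosed"))
  cat(sprintf("  clot:   L = %.3g cm, D = %.3g mm, m = %.3g g, %d partition(s), fp = %.2f\n",
              x$clot$length * 1e2, x$clot$diameter * 1e3,
              x$clot$total_mass * 1e3, x$clot$n_partitions, x$clot$fp))
  cat(sprintf("  mech:   K_union = %.3g N/m, R_union = %.3g N.s/m, friction = %s\n",
              x$mech$K_union, x$mech$R_union, x$mech$dynamic_friction_mode))
  asp <- x$forcing$aspiration
  cat("  forcing:", asp$type,
      if (asp$type == "constant") sprintf("%.3g kPa", asp$pressure / 1e3)
      else if (asp$type == "ramp") sprintf("to %.3g kPa over %.3g s",
                                           asp$p_end / 1e3, asp$t_ramp)
      else sprintf("(%d points)", length(asp$time)),
      if (isTRUE(x$forcing$cardiac_enabled)) "+ cardiac waveform" else "",
      "\n")
  invisible(x)
}

# ---- configuration file I/O -------------------------------------------------

.req <- function(section, name, where) {
  if (is.null(section[[name]])) {
    .validation_error("missing field ", where, ".", name)
  }
  section[[name]]
}

#' Load a scenario from a YAML configuration file
#'
#' The file has sections `artery`, `clot`, `mechanics`, `forcing` and
#' `simulation`; every dimensional numeric field is written as a
#' `{value, unit}` pair (accepted units include mm, cm, m, g, kg, Pa, kPa,
#' mmHg, N, s, mm^2, percent). All quantities are converted to SI on input
#' and validated; violations raise an error naming the offending field.
#' A packaged example lives at
#' `system.file("extdata", "default_scenario.yaml", package = "clotbg")`.
#'
#' @param path path to the YAML file.
#' @return a validated [scenario()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    .validation_error("scenario file not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  art <- .req(cfg, "artery", "config")
  clo <- .req(cfg, "clot", "config")
  mec <- if (is.null(cfg$mechanics)) list() else cfg$mechanics
  forc <- if (is.null(cfg$forcing)) list() else cfg$forcing
  sim <- if (is.null(cfg$simulation)) list() else cfg$simulation

  stenosis <- art$stenosis
  if (!is.null(stenosis) && !is.null(stenosis$severity)) {
    stenosis$severity <- as.numeric(stenosis$severity)
  }
  artery <- artery_spec(
    diameter = as_si(.req(art, "diameter", "artery"), "length",
                     "artery.diameter"),
    occlusion_fraction = if (is.null(art$occlusion)) 1 else
      as_si(art$occlusion, "dimensionless", "artery.occlusion"),
    stenosis = stenosis)

  clot <- clot_spec(
    length = as_si(.req(clo, "length", "clot"), "length", "clot.length"),
    diameter = as_si(.req(clo, "diameter", "clot"), "length",
                     "clot.diameter"),
    total_mass = as_si(.req(clo, "total_mass", "clot"), "mass",
                       "clot.total_mass"),
    n_partitions = if (is.null(clo$n_partitions)) 3 else
      as.numeric(clo$n_partitions),
    fp = if (is.null(clo$fp)) 0.96 else
      as_si(clo$fp, "dimensionless", "clot.fp"),
    MPA = if (is.null(clo$mean_platelet_area)) 5.31e-12 else
      as_si(clo$mean_platelet_area, "area", "clot.mean_platelet_area"),
    F_platelet = if (is.null(clo$platelet_bond_force)) 32e-9 else
      as_si(clo$platelet_bond_force, "force", "clot.platelet_bond_force"),
    sphere_spacing = if (is.null(clo$sphere_spacing)) 1e-4 else
      as_si(clo$sphere_spacing, "length", "clot.sphere_spacing"))

  mech_args <- list()
  num_fields <- list(K_union = "stiffness", R_union = "damping",
                     R_static = "damping", R_dynamic = "damping",
                     C_form = "dimensionless", rho_blood = "density",
                     K_wall = "stiffness", R_wall = "damping",
                     F_move_threshold = "force", F_rupture = "force",
                     v_regularization = "dimensionless")
  for (f in names(num_fields)) {
    if (!is.null(mec[[f]])) {
      mech_args[[f]] <- as_si(mec[[f]], num_fields[[f]],
                              paste0("mechanics.", f))
    }
  }
  for (f in c("dynamic_friction_mode", "release_criterion",
              "eq_spring_mode")) {
    if (!is.null(mec[[f]])) mech_args[[f]] <- mec[[f]]
  }
  mech <- do.call(mechanical_params, mech_args)

  aspiration <- list(type = "constant", pressure = 0)
  if (!is.null(forc$aspiration)) {
    a <- forc$aspiration
    type <- .req(a, "type", "forcing.aspiration")
    aspiration <- switch(
      type,
      constant = list(type = "constant",
                      pressure = as_si(.req(a, "pressure",
                                            "forcing.aspiration"),
                                       "pressure",
                                       "forcing.aspiration.pressure")),
      ramp = list(type = "ramp",
                  p_start = if (is.null(a$p_start)) 0 else
                    as_si(a$p_start, "pressure", "forcing.aspiration.p_start"),
                  p_end = as_si(.req(a, "p_end", "forcing.aspiration"),
                                "pressure", "forcing.aspiration.p_end"),
                  t_ramp = as_si(.req(a, "t_ramp", "forcing.aspiration"),
                                 "time", "forcing.aspiration.t_ramp")),
      table = list(type = "table",
                   time = vapply(.req(a, "time", "forcing.aspiration"),
                                 as_si, numeric(1), dimension = "time",
                                 field = "forcing.aspiration.time"),
                   pressure = vapply(.req(a, "pressure", "forcing.aspiration"),
                                     as_si, numeric(1),
                                     dimension = "pressure",
                                     field = "forcing.aspiration.pressure")),
      .validation_error("unknown forcing.aspiration.type '", type, "'"))
  }
  card <- if (is.null(forc$cardiac)) list() else forc$cardiac
  forcing <- forcing_spec(
    aspiration = aspiration,
    cardiac_enabled = isTRUE(card$enabled),
    cardiac_period = if (is.null(card$period)) 1 else
      as_si(card$period, "time", "forcing.cardiac.period"),
    cardiac_switch_time = if (is.null(card$switch_time)) 0.32 else
      as_si(card$switch_time, "time", "forcing.cardiac.switch_time"),
    cardiac_mode = if (is.null(card$mode)) "modulation" else card$mode)

  scenario(
    artery = artery, clot = clot, mech = mech, forcing = forcing,
    model_variant = if (is.null(sim$model_variant)) "extended" else
      sim$model_variant,
    extraction_distance = if (is.null(sim$extraction_distance)) 2.5e-3 else
      as_si(sim$extraction_distance, "length",
            "simulation.extraction_distance"))
}

#' Write a scenario to a YAML configuration file
#'
#' Emits the scenario in SI units with explicit unit tags, in the same
#' schema that [load_scenario()] reads. Round-tripping a scenario through
#' `write_scenario()` and `load_scenario()` reproduces it exactly.
#'
#' @param x a [scenario()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "clot_scenario"))
  q <- function(value, unit) list(value = value, unit = unit)
  asp <- x$forcing$aspiration
  asp_out <- switch(asp$type,
    constant = list(type = "constant", pressure = q(asp$pressure, "Pa")),
    ramp = list(type = "ramp", p_start = q(asp$p_start, "Pa"),
                p_end = q(asp$p_end, "Pa"), t_ramp = q(asp$t_ramp, "s")),
    table = list(type = "table",
                 time = lapply(asp$time, q, unit = "s"),
                 pressure = lapply(asp$pressure, q, unit = "Pa")))
  cfg <- list(
    artery = c(list(diameter = q(x$artery$diameter, "m"),
                    occlusion = q(x$artery$occlusion_fraction, "fraction")),
               if (!is.null(x$artery$stenosis))
                 list(stenosis = list(severity = x$artery$stenosis$severity))),
    clot = list(length = q(x$clot$length, "m"),
                diameter = q(x$clot$diameter, "m"),
                total_mass = q(x$clot$total_mass, "kg"),
                n_partitions = x$clot$n_partitions,
                fp = q(x$clot$fp, "fraction"),
                mean_platelet_area = q(x$clot$MPA, "m^2"),
                platelet_bond_force = q(x$clot$F_platelet, "N"),
                sphere_spacing = q(x$clot$sphere_spacing, "m")),
    mechanics = list(K_union = q(x$mech$K_union, "N/m"),
                     R_union = q(x$mech$R_union, "N.s/m"),
                     R_static = q(x$mech$R_static, "N.s/m"),
                     dynamic_friction_mode = x$mech$dynamic_friction_mode,
                     R_dynamic = q(x$mech$R_dynamic, "N.s/m"),
                     C_form = x$mech$C_form,
                     rho_blood = q(x$mech$rho_blood, "kg/m^3"),
                     K_wall = q(x$mech$K_wall, "N/m"),
                     R_wall = q(x$mech$R_wall, "N.s/m"),
                     F_move_threshold = q(x$mech$F_move_threshold, "N"),
                     F_rupture = q(x$mech$F_rupture, "N"),
                     release_criterion = x$mech$release_criterion,
                     eq_spring_mode = x$mech$eq_spring_mode),
    forcing = list(aspiration = asp_out,
                   cardiac = list(enabled = x$forcing$cardiac_enabled,
                                  period = q(x$forcing$cardiac_period, "s"),
                                  switch_time =
                                    q(x$forcing$cardiac_switch_time, "s"),
                                  mode = x$forcing$cardiac_mode)),
    simulation = list(model_variant = x$model_variant,
                      extraction_distance = q(x$extraction_distance, "m")))
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}
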