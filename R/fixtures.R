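#' Reference scenarios
#'
#' Named scenarios built from the reference parameter set: blood density
#' 1060 kg/m^3, artery and clot diameter 2.5 mm (100% occlusion), clot
#' lengths 1.0-5.0 cm, platelet fraction 0.96, mean platelet area
#' 5.31e-6 mm^2, platelet-wall bond force 32e-9 N, K_union 1.91 N/m,
#' R_union 0.035 N.s/m.
#'
#' Choices the reference set leaves open are fixed once here: the clot mass
#' grows linearly with length from 0.5 g at 1 cm to 2.0 g at 5 cm (the
#' reported mass range over the reported length range); the default
#' aspiration programme ramps from 0 to -200 kPa over the first second and
#' then holds, strong enough to start detachment of even the 5 cm, fp =
#' 0.96 clot (worst-case partition adhesion ~0.76 N over the 4.9 mm^2
#' cross-section ~ 154 kPa).
#'
#' @section Fixtures:
#' * `table1_L1cm` ... `table1_L5cm`: extended 3-partition chain at each
#'   reference length.
#' * `simple_model_default`: the single-body model (1 cm clot, stiff wall
#'   anchor 1e10 N/m / 1e9 N.s/m, 0.01 N movement threshold, linear
#'   friction).
#' * `stenosed_5part`: 3 cm clot moulded into a cosine-bump stenosis of
#'   radial severity 0.5, five equal-area partitions.
#' * `table1_L3cm_Khigh`: stiffness perturbation (K_union = 4.91 N/m).
#' * `table1_L3cm_cardiac`: heartbeat enabled (1 Hz, mean-centred).
#'
#' @param names optional character vector to select a subset.
#' @return named list of [scenario()] objects.
#' @examples
#' fx <- fixture_scenarios()
#' names(fx)
#' fx$table1_L3cm
#' @export
fixture_scenarios <- function(names = NULL) {
  ramp <- list(type = "ramp", p_start = 0, p_end = -200e3, t_ramp = 1)
  table1 <- function(L_cm, n = 3, ...) {
    scenario(
      artery = artery_spec(2.5e-3, occlusion_fraction = 1),
      clot = clot_spec(length = L_cm * 1e-2, diameter = 2.5e-3,
                       total_mass = clot_mass_default(L_cm * 1e-2),
                       n_partitions = n),
      mech = mechanical_params(...),
      forcing = forcing_spec(aspiration = ramp),
      model_variant = "extended")
  }
  fx <- list(
    table1_L1cm = table1(1), table1_L2cm = table1(2),
    table1_L3cm = table1(3), table1_L4cm = table1(4),
    table1_L5cm = table1(5),
    simple_model_default = scenario(
      artery = artery_spec(2.5e-3),
      clot = clot_spec(length = 1e-2, diameter = 2.5e-3,
                       total_mass = clot_mass_default(1e-2),
                       n_partitions = 1),
      mech = mechanical_params(dynamic_friction_mode = "linear"),
      forcing = forcing_spec(aspiration = list(type = "constant",
                                               pressure = -20e3)),
      model_variant = "simple"),
    stenosed_5part = scenario(
      artery = artery_spec(2.5e-3, stenosis = list(severity = 0.5)),
      clot = clot_spec(length = 3e-2, diameter = 2.5e-3,
                       total_mass = clot_mass_default(3e-2),
                       n_partitions = 5),
      forcing = forcing_spec(aspiration = ramp),
      model_variant = "extended"),
    table1_L3cm_Khigh = table1(3, K_union = 4.91),
    table1_L3cm_cardiac = scenario(
      artery = artery_spec(2.5e-3),
      clot = clot_spec(length = 3e-2, diameter = 2.5e-3,
                       total_mass = clot_mass_default(3e-2),
                       n_partitions = 3),
      forcing = forcing_spec(aspiration = ramp, cardiac_enabled = TRUE),
      model_variant = "extended"))
  if (!is.null(names)) fx <- fx[names]
  fx
}

#' Default clot mass for a given length
#'
#' Linear in length: 0.5 g at 1 cm up to 2.0 g at 5 cm, clamped to that
#' range outside it.
#'
#' @param length clot length (m).
#' @return mass (kg).
#' @export
clot_mass_default <- function(length) {
  g <- 0.5 + 0.375 * (length * 100 - 1)
  pmin(pmax(g, 0.5), 2) * 1e-3
}
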