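# shared fixtures and independent oracles for the suite

ref_artery <- function(...) artery_spec(2.5e-3, ...)

ref_clot <- function(L = 0.03, n = 3, ...) {
  clot_spec(length = L, diameter = 2.5e-3, total_mass = clot_mass_default(L),
            n_partitions = n, ...)
}

# chain scenario with an explicit constant suction (Pa)
chain_scenario <- function(L = 0.03, n = 3, pressure = -150e3, mech = NULL,
                           ...) {
  scenario(artery = ref_artery(), clot = ref_clot(L, n),
           mech = if (is.null(mech)) mechanical_params() else mech,
           forcing = forcing_spec(aspiration = list(type = "constant",
                                                    pressure = pressure)),
           model_variant = "extended", ...)
}

# brute-force equal-area cut points: dense midpoint-rule cumulative sum
oracle_equal_area_cuts <- function(profile, L, n, n_grid = 1e5) {
  dx <- L / n_grid
  xm <- (seq_len(n_grid) - 0.5) * dx
  cum <- cumsum(2 * pi * profile(xm) * dx)
  targets <- cum[n_grid] * seq_len(n - 1) / n
  vapply(targets, function(a) xm[which(cum >= a)[1]], numeric(1))
}

# midpoint-rule integral of f over [lo, hi]
oracle_integral <- function(f, lo, hi, n_grid = 1e5) {
  dx <- (hi - lo) / n_grid
  sum(f(lo + (seq_len(n_grid) - 0.5) * dx)) * dx
}

# closed-form velocity of a single mass under constant force F and linear
# damping R, starting from rest
oracle_linear_velocity <- function(F, R, m, t) (F / R) * (1 - exp(-R * t / m))
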