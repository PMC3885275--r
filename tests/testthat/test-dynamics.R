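test_that("model builders wire the reference scenarios correctly", {
  fx <- fixture_scenarios()
  m <- build_simple_model(fx$simple_model_default)
  expect_equal(m$n_spheres, 100L)
  expect_equal(m$K_eq, m$K_surface / 100)
  expect_equal(m$release_displacement * m$K_eq, 0.01)
  expect_error(build_simple_model(fx$table1_L3cm), "n_partitions")

  ext <- build_extended_model(fx$table1_L3cm)
  expect_equal(nrow(ext$partitions), 3L)
  expect_equal(ext$partitions$adhesion_force, rep(0.4544, 3),
               tolerance = 1e-3)
  expect_true(all(ext$attached))

  # equal-area cuts cannot also equalize volumes for this profile; the
  # builder reports the discrepancy
  expect_warning(st <- build_extended_model(fx$stenosed_5part),
                 "volume spread")
  expect_equal(nrow(st$partitions), 5L)
  expect_equal(st$partitions$area, rep(st$partitions$area[1], 5),
               tolerance = 1e-6)
})

test_that("union force is a linear spring-damper obeying Newton's third law", {
  expect_equal(union_force(1, 2, 1, 2, 1.91, 0.035), 0)
  expect_equal(union_force(0, 0, 5.236e-3, 0, 1.91, 0.035), 0.01,
               tolerance = 1e-3)
  # equal and opposite on the pair, for arbitrary states
  set.seed(7)
  for (i in 1:20) {
    s <- runif(4, -1, 1)
    expect_equal(union_force(s[1], s[2], s[3], s[4], 1.91, 0.035),
                 -union_force(s[3], s[4], s[1], s[2], 1.91, 0.035))
  }
})

test_that("detachment is front-to-back and triggered at the adhesion force", {
  model <- build_extended_model(chain_scenario())
  state0 <- list(t = 0, x = rep(0, 3), v = rep(0, 3),
                 attached = rep(TRUE, 3))
  # zero transmitted force: nothing releases
  expect_length(detachment_event(model, state0, function(t) 0), 0)
  # applied force above the proximal adhesion releases partition 0 only
  expect_equal(detachment_event(model, state0, function(t) 0.5), 0L)
  # far above every trigger it cannot skip partitions: the interior
  # triggers depend on spring stretch, which is still zero
  expect_equal(detachment_event(model, state0, function(t) 10), 0L)
  # a stretched junction releases the next partition in the cascade
  state1 <- list(t = 0, x = c(0.3, 0, 0), v = rep(0, 3),
                 attached = c(FALSE, TRUE, TRUE))
  expect_equal(detachment_event(model, state1, function(t) 10), 1L)
})

test_that("rupture check flags the most loaded junction", {
  model <- build_extended_model(chain_scenario())
  expect_false(rupture_check(model, c(1, 0, 0), Inf)$ruptured)
  r <- rupture_check(model, c(0.3, 0, 0), 1e-9)
  expect_true(r$ruptured)
  expect_equal(r$junction, 1L)
  r2 <- rupture_check(model, c(0.1, 0.1, 0), 0.15)
  expect_true(r2$ruptured)
  expect_equal(r2$junction, 2L)
})

test_that("a fully attached chain is exactly at rest under any sub-release forcing", {
  sc <- chain_scenario(pressure = -50e3)  # 0.245 N < 0.454 N adhesion
  res <- simulate(sc, t_end = 1, dt = 1e-2)
  expect_true(all(res$attached))
  expect_identical(max(abs(res$v)), 0)
  expect_identical(max(abs(res$x)), 0)
  expect_true(all(is.na(res$detach_times)))
  # and with the heartbeat on top: still below every trigger
  sc$forcing$cardiac_enabled <- TRUE
  res2 <- simulate(sc, t_end = 1, dt = 1e-2)
  expect_identical(max(abs(res2$v)), 0)
})

test_that("a single detached mass under constant force matches the closed-form velocity", {
  sc <- scenario(
    artery = ref_artery(),
    clot = clot_spec(0.01, 2.5e-3, 1e-3, n_partitions = 1, F_platelet = 0),
    mech = mechanical_params(dynamic_friction_mode = "linear",
                             R_dynamic = 0.05),
    forcing = forcing_spec(),
    model_variant = "extended")
  F <- 0.01
  res <- simulate(sc, t_end = 0.1, dt = 1e-3,
                  applied_force = function(t) rep_len(F, length(t)),
                  rtol = 1e-10, atol = 1e-14)
  expect_equal(res$detach_times[1], 0)
  v_exact <- oracle_linear_velocity(F, 0.05, 1e-3, res$time)
  expect_equal(res$v[, 1], v_exact, tolerance = 1e-6)
})

test_that("two free masses on one union oscillate at the analytic period and conserve momentum", {
  m_i <- 5e-4
  sc <- scenario(
    artery = ref_artery(),
    clot = clot_spec(0.02, 2.5e-3, 2 * m_i, n_partitions = 2),
    mech = mechanical_params(R_union = 0, C_form = 0),  # no damping, no drag
    forcing = forcing_spec(),
    model_variant = "extended")
  stretch <- 0.01
  res <- simulate(sc, t_end = 0.75, dt = 1e-4,
                  applied_force = function(t) rep_len(0, length(t)),
                  initial_state = list(x = c(stretch / 2, -stretch / 2),
                                       v = c(0, 0),
                                       attached = c(FALSE, FALSE)),
                  rtol = 1e-10, atol = 1e-14)
  # analytic period of the symmetric mode: 2*pi*sqrt(m/(2K))
  T_exact <- 2 * pi * sqrt(m_i / (2 * 1.91))
  rel <- res$x[, 1] - res$x[, 2]
  crossings <- which(diff(sign(rel)) != 0)
  t_cross <- vapply(crossings, function(i) {
    t1 <- res$time[i]; t2 <- res$time[i + 1]
    t1 - rel[i] * (t2 - t1) / (rel[i + 1] - rel[i])
  }, numeric(1))
  expect_gte(length(t_cross), 20)  # > 10 periods observed
  T_sim <- 2 * (t_cross[length(t_cross)] - t_cross[1]) / (length(t_cross) - 1)
  expect_equal(T_sim, T_exact, tolerance = 1e-3)
  # internal forces conserve total momentum
  momentum <- res$v %*% c(m_i, m_i)
  expect_lt(max(abs(momentum)), 1e-9)
})

test_that("the located release time matches a bisection oracle on the force history", {
  sc <- chain_scenario()
  sc$forcing$aspiration <- list(type = "ramp", p_start = 0, p_end = -200e3,
                                t_ramp = 1)
  res <- simulate(sc, t_end = 0.6, dt = 1e-3)
  Fadh <- build_extended_model(sc)$partitions$adhesion_force[1]
  Ffun <- make_applied_force(sc)
  # independent bisection on F(t) - F_adh over the forcing history
  lo <- 0; hi <- 1
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (Ffun(mid) < Fadh) lo <- mid else hi <- mid
  }
  expect_equal(res$detach_times[1], (lo + hi) / 2, tolerance = 1e-6)
  # monotone loading: release times strictly ordered front-to-back
  expect_true(all(diff(res$detach_times) > 0))
})

test_that("the simple model is gated by the 0.01 N movement threshold", {
  sc <- fixture_scenarios()$simple_model_default
  below <- simulate(sc, t_end = 2, dt = 1e-2,
                    applied_force = function(t) rep_len(0.005, length(t)))
  expect_true(all(is.na(below$detach_times)))
  expect_true(all(below$attached))
  # anchored displacement is bounded by F/K_wall, far below release
  expect_lt(max(abs(below$x)), 1e-11)
  expect_true(all(below$spring_displacement <
                    build_simple_model(sc)$release_displacement))

  above <- simulate(sc, t_end = 2, dt = 1e-2,
                    applied_force = function(t) rep_len(0.02, length(t)))
  expect_equal(above$detach_times[1], 0)
  expect_gt(max(above$v), 0)
  expect_gt(max(above$x), sc$extraction_distance)
})

test_that("an overloaded junction ruptures where the tension history peaks", {
  sc <- chain_scenario(pressure = -150e3,
                       mech = mechanical_params(F_rupture = 0.3))
  res <- simulate(sc, t_end = 1, dt = 1e-4)
  expect_true(res$ruptured)
  expect_equal(res$rupture_junction, 1L)
  expect_false(any(res$events$type == "release" & res$events$index == 1))
  # post-hoc scan of the recorded tension history
  model <- res$model
  tension <- t(apply(res$x, 1, function(x) union_tensions(model, x)))
  peak <- which.max(apply(abs(tension), 1, max))
  expect_equal(unname(which.max(abs(tension[peak, ]))), res$rupture_junction)
  expect_equal(max(abs(tension)), 0.3, tolerance = 1e-3)
  # F_rupture = Inf never ruptures under the same load
  sc2 <- chain_scenario(pressure = -150e3)
  expect_false(simulate(sc2, t_end = 1, dt = 1e-3)$ruptured)
})
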