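test_that("surface-tension spring, anchor count and equivalent spring follow the printed rules", {
  expect_equal(surface_tension_spring(0, 1), 0)
  expect_equal(surface_tension_spring(0.01, pi * 2.5e-3), 1.27324,
               tolerance = 1e-5)
  # linear in the force
  expect_equal(surface_tension_spring(0.02, pi * 2.5e-3),
               2 * surface_tension_spring(0.01, pi * 2.5e-3))
  expect_error(surface_tension_spring(0.01, 0), "perimeter")

  expect_equal(sphere_count(1e-4, 1e-4), 1L)
  expect_equal(sphere_count(1e-2, 1e-4), 100L)
  expect_equal(sphere_count(5e-2, 1e-4), 500L)
  expect_error(sphere_count(-1, 1e-4), "positive|> 0")

  K <- surface_tension_spring(0.01, pi * 2.5e-3)
  expect_equal(equivalent_spring(K, 1), K)
  expect_equal(equivalent_spring(K, 100), K / 100)
  expect_equal(equivalent_spring(K, 500), K / 500)
  expect_equal(equivalent_spring(K, 100, mode = "parallel_sum"), K * 100)
  expect_error(equivalent_spring(K, 0), "n")
})

test_that("release displacement is F/K_eq and exactly inverts the spring law", {
  expect_equal(release_displacement(0, 1.91), 0)
  expect_equal(release_displacement(0.01, 1.91), 5.236e-3, tolerance = 1e-4)
  K_eq <- equivalent_spring(surface_tension_spring(0.01, pi * 2.5e-3), 100)
  x <- release_displacement(0.01, K_eq)
  expect_equal(x, 0.7854, tolerance = 1e-4)
  expect_identical(x * K_eq, 0.01)  # exact inverse, not just approximate
  # property: over a sweep of thresholds and anchor counts
  for (F in c(1e-3, 0.01, 0.05)) {
    for (n in c(1, 10, 250)) {
      K_eq <- equivalent_spring(1.2732, n)
      expect_equal(release_displacement(F, K_eq) * K_eq, F)
    }
  }
})

test_that("contact area, platelet count and adhesion force chain to the reference value", {
  expect_equal(lateral_contact_area(2.5e-3, 0.03, 1), 2.3562e-4,
               tolerance = 1e-4)
  SA <- lateral_contact_area(2.5e-3, 0.03, 3)
  expect_equal(SA, 7.854e-5, tolerance = 1e-4)
  expect_error(lateral_contact_area(2.5e-3, 0, 3), "> 0")

  expect_equal(platelet_count(0, SA, 5.31e-12), 0)
  np <- platelet_count(0.96, SA, 5.31e-12)
  expect_equal(np, 1.4200e7, tolerance = 1e-4)
  expect_equal(platelet_count(0.48, SA, 5.31e-12), np / 2)
  expect_error(platelet_count(0.96, SA, 0), "MPA")

  expect_equal(partition_adhesion_force(0, 32e-9), 0)
  expect_equal(partition_adhesion_force(np, 32e-9), 0.4544, tolerance = 1e-3)
  expect_equal(partition_adhesion_force(np, 16e-9), 0.2272, tolerance = 1e-3)
})

test_that("total adhesion force is invariant to partition count and linear in length and fp", {
  art <- ref_artery()
  total_at <- function(L, n, fp = 0.96) {
    cl <- clot_spec(L, 2.5e-3, 1e-3, n_partitions = n, fp = fp)
    sum(partition_clot(art, cl)$adhesion_force)
  }
  base <- total_at(0.03, 1)
  for (n in c(3, 5, 10)) {
    expect_equal(total_at(0.03, n), base, tolerance = 1e-9)
  }
  # linear in clot length
  for (L in c(0.01, 0.02, 0.05)) {
    expect_equal(total_at(L, 3), base * L / 0.03, tolerance = 1e-9)
  }
  # linear in platelet fraction
  for (fp in c(0.24, 0.48, 0.72)) {
    expect_equal(total_at(0.03, 3, fp), base * fp / 0.96, tolerance = 1e-9)
  }
})

test_that("anchor count times spacing brackets the clot length", {
  for (L in c(1.03e-2, 2.77e-2, 4.99e-2, 3.3e-4)) {
    for (s in c(1e-4, 3e-4)) {
      n <- sphere_count(L, s)
      expect_true(n * s >= L - s / 2 && n * s <= L + s / 2)
    }
  }
})

test_that("uniform-lumen partitioning yields identical partitions", {
  art <- ref_artery()
  cl <- ref_clot(0.03, 5)
  parts <- partition_clot(art, cl)
  expect_equal(nrow(parts), 5L)
  expect_equal(parts$area, rep(pi * 2.5e-3 * 0.03 / 5, 5))
  expect_equal(diff(parts$x_start), rep(0.03 / 5, 4))
  expect_equal(parts$mass, rep(cl$total_mass / 5, 5))
  # spans tile [0, L] without overlap
  expect_equal(parts$x_end[-5], parts$x_start[-1])
  expect_equal(parts$x_start[1], 0)
  expect_equal(parts$x_end[5], 0.03)
  # the 3-partition reference chain: 0.4544 N per partition
  parts3 <- partition_clot(art, ref_clot(0.03, 3))
  expect_equal(parts3$adhesion_force, rep(0.4544, 3), tolerance = 1e-3)
})

test_that("stenosed partitioning equalizes contact areas against a dense-grid oracle", {
  art <- artery_spec(2.5e-3, stenosis = list(severity = 0.5))
  cl <- ref_clot(0.03, 5)
  profile <- stenosis_profile(art, cl)
  parts <- suppressWarnings(partition_stenosed_clot(art, cl, 5))
  # all areas equal, and equal to the oracle total / 5
  A_tot <- oracle_integral(function(x) 2 * pi * profile(x), 0, 0.03)
  expect_equal(parts$area, rep(A_tot / 5, 5), tolerance = 1e-6)
  # cut points agree with a brute-force cumulative-sum inversion
  cuts <- oracle_equal_area_cuts(profile, 0.03, 5)
  expect_equal(parts$x_start[-1], cuts, tolerance = 1e-5)
  # equal-area spans are wider where the lumen narrows (middle partition)
  spans <- parts$x_end - parts$x_start
  expect_gt(spans[3], spans[1])
  expect_gt(spans[3], spans[5])
  # spans still tile the clot
  expect_equal(parts$x_end[-5], parts$x_start[-1])
})

test_that("repartitioning after motion matches re-integration at shifted coordinates", {
  art_u <- ref_artery()
  cl <- ref_clot(0.03, 5)
  parts_u <- partition_clot(art_u, cl)
  # identity at zero displacement, areas unchanged for a uniform lumen
  expect_identical(repartition_after_motion(parts_u, 0, art_u, cl), parts_u)
  moved_u <- repartition_after_motion(parts_u, 0.004, art_u, cl)
  expect_equal(moved_u$area, parts_u$area, tolerance = 1e-9)

  art_s <- artery_spec(2.5e-3, stenosis = list(severity = 0.5))
  profile <- stenosis_profile(art_s, cl)
  parts_s <- suppressWarnings(partition_stenosed_clot(art_s, cl, 5))
  d <- 0.003  # L/10
  moved <- repartition_after_motion(parts_s, d, art_s, cl)
  for (i in seq_len(5)) {
    a_oracle <- oracle_integral(function(x) 2 * pi * profile(x),
                                parts_s$x_start[i] - d, parts_s$x_end[i] - d)
    expect_equal(moved$area[i], a_oracle, tolerance = 1e-6)
  }
  # released partitions keep zero adhesion
  parts_s$adhesion_force[1] <- 0
  moved2 <- repartition_after_motion(parts_s, d, art_s, cl)
  expect_identical(moved2$adhesion_force[1], 0)
})
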