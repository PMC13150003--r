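# small power grid keeps the propagation scans fast; the acceptance suite
# runs the full default grids
pw6 <- c(100, 250, 600, 1500, 3000, 6000)

test_that("scenario rules map the ground-state distance to the excited one", {
  expect_equal(scenario_spec(1, 3.0)$r_j, 40)
  expect_equal(scenario_spec(2, 3.0)$r_j, 3.0)
  expect_equal(scenario_spec(3, 3.0)$r_j, 2.8)
  expect_error(scenario_spec(3, 0.1), "non-positive")
})

test_that("reference simulation system carries the documented parameters", {
  sys <- reference_artifact_system()
  expect_equal(sys$network$populations, c(GS = 0.995, ES = 0.005),
               ignore_attr = TRUE)
  expect_equal(sys$network$offsets_hz, c(0, 600), ignore_attr = TRUE)
  expect_equal(sys$partner$offset_hz, -600)
  expect_equal(sys$network$r2, c(22.5, 22.5), ignore_attr = TRUE)
  expect_equal(sys$network$r1, c(2.5, 2.5), ignore_attr = TRUE)
  expect_equal(sys$network$edges$kex, 2000)
  expect_equal(sys$tumbling$tau_c, 5.1e-9)
})

test_that("a remote neighbour leaves profiles unchanged", {
  sys <- reference_artifact_system()
  sc <- scenario_spec(1, 40)
  full <- scan_profile(sys, sc, powers_hz = pw6)
  none <- scan_profile(sys, sc, powers_hz = pw6,
                       variant = "no_cross_relaxation")
  expect_lt(max(abs(full$r1rho - none$r1rho) / none$r1rho), 0.001)
  contrib <- cross_relaxation_contribution(sys, sc, powers_hz = pw6)
  expect_lt(max(contrib$contribution_pct), 0.1)
})

test_that("excited-state coupling amplifies the artifact", {
  sys <- reference_artifact_system()
  c1 <- cross_relaxation_contribution(sys, scenario_spec(1, 3.0),
                                      powers_hz = pw6)
  c2 <- cross_relaxation_contribution(sys, scenario_spec(2, 3.0),
                                      powers_hz = pw6)
  c3 <- cross_relaxation_contribution(sys, scenario_spec(3, 3.0),
                                      powers_hz = pw6)
  expect_true(all(c2$contribution_pct >= c1$contribution_pct - 1e-9))
  expect_true(all(c3$contribution_pct >= c2$contribution_pct - 1e-9))
})

test_that("transverse pathway dominates the on-resonance artifact", {
  sys <- reference_artifact_system()
  sc <- scenario_spec(1, 2.5)
  full <- scan_profile(sys, sc, powers_hz = pw6)
  no_mu <- scan_profile(sys, sc, powers_hz = pw6, variant = "mu_only_zeroed")
  none <- scan_profile(sys, sc, powers_hz = pw6,
                       variant = "no_cross_relaxation")
  mu_part <- abs(full$r1rho - no_mu$r1rho)
  total <- abs(full$r1rho - none$r1rho)
  expect_gt(max(mu_part), 0.5 * max(total))
})

test_that("off-resonance profile responds at the neighbour's offset", {
  sys <- reference_artifact_system()
  offs <- seq(-900, 900, by = 75)
  prof <- scan_profile(sys, scenario_spec(1, 2.5), axis = "off_resonance",
                       powers_hz = 250, offsets_hz = offs)
  base <- scan_profile(sys, scenario_spec(1, 40), axis = "off_resonance",
                       powers_hz = 250, offsets_hz = offs)
  excess <- prof$r2eff - base$r2eff
  expect_equal(offs[which.max(excess)], -600, tolerance = 150)
})

test_that("distance threshold behaves monotonically in the tolerance", {
  sys <- reference_artifact_system()
  rg <- c(2.4, 2.8, 3.2, 3.6)
  expect_equal(distance_threshold(sys, 1, tolerance_pct = 100, r_grid = rg,
                                  powers_hz = pw6), 2.4)
  th <- vapply(c(2, 5, 10), function(tol)
    distance_threshold(sys, 1, tolerance_pct = tol, r_grid = rg,
                       powers_hz = pw6), numeric(1))
  expect_true(all(diff(th) <= 0))
})

test_that("synthetic tables are exact at zero noise and seed-reproducible", {
  net <- reference_network()
  scheds <- list(spinlock_schedule(1000, 0, seq(0, 0.06, length.out = 6)),
                 spinlock_schedule(250, -300, seq(0, 0.06, length.out = 6)))
  clean <- generate_synthetic_dataset(net, scheds, noise_frac = 0)
  ref <- simulate_spinlock_experiment(net, scheds[[1]])
  expect_equal(clean$table$intensity[1:6], 100 * ref$intensity,
               tolerance = 1e-12)
  a <- generate_synthetic_dataset(net, scheds, noise_frac = 0.02, seed = 7)
  b <- generate_synthetic_dataset(net, scheds, noise_frac = 0.02, seed = 7)
  expect_identical(a$table, b$table)
  # noise bookkeeping: rms reconstructed from the table equals the generating
  # rms (2% of the clean intensity)
  rms <- abs(a$table$intensity) / (2 * a$table$sino)
  expect_equal(rms, 0.02 * abs(clean$table$intensity), tolerance = 1e-12)
  expect_error(generate_synthetic_dataset(net, list(), noise_frac = 0),
               "empty")
})
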