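two_state_params <- c(kex_12 = 2000, p2 = 0.005, dw2 = 600, r1 = 2.5,
                      r2 = 22.5)

small_grid <- function() {
  rbind(data.frame(power_hz = seq(500, 6000, length.out = 8), offset_hz = 0),
        data.frame(power_hz = 250,
                   offset_hz = seq(-900, 900, length.out = 13)))
}

test_that("model prediction collapses to closed forms", {
  m2 <- exchange_model("two_state")
  # vanishing excited state: exchange-free tilted-frame rate
  p0 <- c(kex_12 = 2000, p2 = 1e-12, dw2 = 600, r1 = 2.5, r2 = 22.5)
  off <- c(0, 300, 1200)
  pred <- model_r1rho(m2, p0, 1000, off)
  th <- atan2(2 * pi * 1000, 2 * pi * (0 - off))
  expect_equal(pred, 2.5 * cos(th)^2 + 22.5 * sin(th)^2, tolerance = 1e-6)
  # eigenvalue route matches the independent closed-form oracle
  pw <- seq(500, 6000, length.out = 10)
  expect_lt(max(abs(model_r1rho(m2, two_state_params, pw, 0) -
                      trott_palmer_r1rho(2000, 0.005, 600, 2.5, 22.5, pw)) /
                  model_r1rho(m2, two_state_params, pw, 0)), 0.02)
})

test_that("topologies degenerate continuously into one another", {
  tri <- exchange_model("triangular")
  lin <- exchange_model("linear")
  base <- c(kex_12 = 2700, kex_23 = 3200, p2 = 0.006, p3 = 0.009,
            dw2 = -593, dw3 = 288, r1 = 2.5, r2 = 22.5)
  grid <- small_grid()
  p_tri <- c(base, kex_13 = 1e-9)
  expect_equal(model_r1rho(tri, p_tri, grid$power_hz, grid$offset_hz),
               model_r1rho(lin, base, grid$power_hz, grid$offset_hz),
               tolerance = 1e-6)
  # linear chain with a silent far state reduces to two-state
  two <- exchange_model("two_state")
  p_lin <- c(kex_12 = 2000, kex_23 = 1e-9, p2 = 0.005, p3 = 1e-12,
             dw2 = 600, dw3 = 100, r1 = 2.5, r2 = 22.5)
  expect_equal(model_r1rho(lin, p_lin, grid$power_hz, grid$offset_hz),
               model_r1rho(two, two_state_params, grid$power_hz,
                           grid$offset_hz),
               tolerance = 1e-5)
})

test_that("predictions have rotating-frame mirror symmetry", {
  tri <- exchange_model("triangular")
  p <- c(kex_12 = 2700, kex_13 = 500, kex_23 = 3200, p2 = 0.006, p3 = 0.009,
         dw2 = -593, dw3 = 288, r1 = 2.5, r2 = 22.5)
  pm <- p; pm[c("dw2", "dw3")] <- -pm[c("dw2", "dw3")]
  grid <- small_grid()
  expect_equal(model_r1rho(tri, p, grid$power_hz, grid$offset_hz),
               model_r1rho(tri, pm, grid$power_hz, -grid$offset_hz),
               tolerance = 1e-8)
})

test_that("information criteria follow the documented formulas", {
  fit <- structure(list(chi2 = 10, n = 20, k = 4), class = "fit_result")
  ic <- information_criteria(fit)
  # frozen arithmetic: N log(chi2/N) + 2k etc. at N = 20, k = 4, chi2 = 10
  expect_equal(ic$aic, -5.862943611198906, tolerance = 1e-12)
  expect_equal(ic$aicc, -3.19627694453224, tolerance = 1e-12)
  expect_equal(ic$bic, -1.880014516982943, tolerance = 1e-12)
  # penalty monotonicity at equal chi2
  ic5 <- information_criteria(structure(list(chi2 = 10, n = 20, k = 5),
                                        class = "fit_result"))
  expect_gt(ic5$aicc, ic$aicc)
  expect_gt(ic5$bic, ic$bic)
  # small-sample correction vanishes for large N
  icN <- information_criteria(structure(list(chi2 = 500, n = 1e6, k = 4),
                                        class = "fit_result"))
  expect_lt(icN$aicc - icN$aic, 1e-4)
  expect_error(information_criteria(structure(list(chi2 = 1, n = 5, k = 4),
                                              class = "fit_result")),
               "N > k")
})

test_that("zero-noise two-state fit recovers the generating parameters", {
  m2 <- exchange_model("two_state", fixed = list(r1 = 2.5))
  ds <- simulate_dispersion(m2, two_state_params, small_grid(),
                            noise_frac = 0, observable = "r1rho")
  fit <- fit_model(ds, m2, n_starts = 8, seed = 42)
  for (nm in c("kex_12", "p2", "dw2", "r2"))
    expect_equal(unname(fit$estimates[nm]), unname(two_state_params[nm]),
                 tolerance = 1e-4)
})

test_that("global fit of duplicated data reproduces the single fit", {
  m2 <- exchange_model("two_state", fixed = list(r1 = 2.5),
                       shared = c("kex_12", "p2", "dw2", "r2"))
  ds <- simulate_dispersion(m2, two_state_params, small_grid(),
                            noise_frac = 0.02, seed = 31,
                            observable = "r1rho")
  single <- fit_model(ds, m2, n_starts = 8, seed = 5)
  double <- fit_model(list(ds, ds), m2, n_starts = 8, seed = 5)
  expect_equal(double$estimates, single$estimates, tolerance = 1e-4)
  expect_equal(double$chi2, 2 * single$chi2, tolerance = 1e-4)
  expect_equal(double$n, 2 * single$n)
})

test_that("identifiability guard rejects underdetermined fits", {
  m2 <- exchange_model("two_state")
  ds <- dispersion_dataset("x", c(500, 1000, 2000), 0, c(25, 24, 23),
                           c(0.5, 0.5, 0.5))
  expect_error(fit_model(ds, m2, n_starts = 2), "identifiability")
})

test_that("Monte-Carlo parameter errors are seed-stable and noise-scaled", {
  m2 <- exchange_model("two_state", fixed = list(r1 = 2.5))
  ds <- simulate_dispersion(m2, two_state_params, small_grid(),
                            noise_frac = 0.02, seed = 17,
                            observable = "r1rho")
  fit <- fit_model(ds, m2, n_starts = 8, seed = 6)
  a <- mc_parameter_errors(fit, n_replicas = 60, seed = 7)
  b <- mc_parameter_errors(fit, n_replicas = 60, seed = 7)
  expect_identical(a$mc_sd, b$mc_sd)
  expect_true(all(a$mc_sd > 0))
  # replica means stay near the point estimates on well-conditioned data
  expect_lt(max(abs(a$replica_mean - fit$estimates[names(a$replica_mean)]) /
                  pmax(abs(fit$estimates[names(a$replica_mean)]), 1)), 0.5)
  # shrink the data noise: parameter uncertainty shrinks accordingly
  ds0 <- simulate_dispersion(m2, two_state_params, small_grid(),
                             noise_frac = 0.001, seed = 18,
                             observable = "r1rho")
  fit0 <- fit_model(ds0, m2, n_starts = 8, seed = 6)
  tiny <- mc_parameter_errors(fit0, n_replicas = 60, seed = 7)
  expect_lt(tiny$mc_sd["kex_12"], 0.1 * a$mc_sd["kex_12"])
})

test_that("model comparison prefers parsimony on equivalent fits", {
  m2 <- exchange_model("two_state", fixed = list(r1 = 2.5))
  ds <- simulate_dispersion(m2, two_state_params, small_grid(),
                            noise_frac = 0.02, seed = 23,
                            observable = "r1rho")
  fit <- fit_model(ds, m2, n_starts = 8, seed = 8)
  cmp <- compare_models(list(a = fit, b = fit))
  expect_equal(cmp$selected, "a")
  expect_error(compare_models(list(fit)), "2")
})

test_that("triangular estimates are canonicalised by offset order", {
  tri <- exchange_model("triangular")
  est <- c(kex_12 = 100, kex_13 = 200, kex_23 = 300, p2 = 0.01, p3 = 0.02,
           dw2 = 500, dw3 = -400, r1 = 2, r2 = 20)
  canon <- r1rhoRD:::.canonicalize(est, tri)
  expect_equal(unname(canon["dw2"]), -400)
  expect_equal(unname(canon["dw3"]), 500)
  expect_equal(unname(canon["p2"]), 0.02)
  expect_equal(unname(canon["kex_12"]), 200)
  expect_equal(unname(canon["kex_23"]), 300)
})
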