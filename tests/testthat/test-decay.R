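clean_curve <- function(rate = 20, noise = 0, seed = 1, n = 8, i0 = 100) {
  tau <- seq(0, 0.07, length.out = n)
  itrue <- i0 * exp(-rate * tau)
  withr::with_seed(seed, {
    rms <- pmax(noise * itrue, 1e-12)
    iobs <- if (noise > 0) itrue + rnorm(n, 0, rms) else itrue
    sino <- abs(iobs) / (2 * pmax(rms, 1e-12))
    decay_curve(tau, iobs, sino)
  })
}

test_that("weighted decay fit is exact on noiseless data", {
  est <- fit_decay(clean_curve())
  expect_equal(est$rate, 20, tolerance = 1e-9)
  expect_equal(est$amplitude, 100, tolerance = 1e-9)
})

test_that("estimate is invariant under replication and rescaling", {
  cv <- clean_curve(noise = 0.03, seed = 4)
  est <- fit_decay(cv)
  dup <- decay_curve(rep(cv$durations, 2), rep(cv$intensities, 2),
                     rep(cv$sino, 2))
  expect_equal(fit_decay(dup)$rate, est$rate, tolerance = 1e-9)
  scaled <- decay_curve(cv$durations, 50 * cv$intensities, cv$sino)
  est_s <- fit_decay(scaled)
  expect_equal(est_s$rate, est$rate, tolerance = 1e-9)
  expect_equal(est_s$amplitude, 50 * est$amplitude, tolerance = 1e-9)
})

test_that("fit agrees with a brute-force grid minimiser", {
  # heteroscedastic noise: rms grows along the decay
  tau <- seq(0, 0.08, length.out = 9)
  itrue <- 80 * exp(-25 * tau)
  withr::with_seed(11, {
    rms <- 0.01 * itrue * seq(1, 3, length.out = 9)
    iobs <- itrue + rnorm(9, 0, rms)
  })
  cv <- decay_curve(tau, iobs, abs(iobs) / (2 * rms))
  est <- fit_decay(cv)
  oracle <- grid_fit_monoexp(tau, iobs, rms)
  expect_equal(est$rate, unname(oracle["rate"]), tolerance = 1e-6)
  expect_equal(est$amplitude, unname(oracle["amplitude"]), tolerance = 1e-6)
})

test_that("rising intensities trigger a warning", {
  tau <- seq(0, 0.05, length.out = 5)
  iobs <- 10 * exp(3 * tau)
  expect_warning(fit_decay(decay_curve(tau, iobs, rep(100, 5))), "increase")
})

test_that("Monte-Carlo uncertainty tracks the noise level", {
  sds <- vapply(c(0.01, 0.02, 0.04), function(noise) {
    cv <- clean_curve(noise = noise, seed = 2)
    monte_carlo_rate_sd(cv, n_replicas = 300, seed = 5)$sd
  }, numeric(1))
  # approximately linear in the noise for small noise
  expect_equal(sds[2] / sds[1], 2, tolerance = 0.25)
  expect_equal(sds[3] / sds[2], 2, tolerance = 0.25)
  # near-zero noise collapses the uncertainty
  tiny <- monte_carlo_rate_sd(clean_curve(noise = 1e-6, seed = 3),
                              n_replicas = 100, seed = 6)
  expect_lt(tiny$sd, 1e-3)
})

test_that("Monte-Carlo resampling is seed-deterministic", {
  cv <- clean_curve(noise = 0.02, seed = 8)
  a <- monte_carlo_rate_sd(cv, n_replicas = 100, seed = 9)
  b <- monte_carlo_rate_sd(cv, n_replicas = 100, seed = 9)
  expect_identical(a$sd, b$sd)
  c2 <- monte_carlo_rate_sd(cv, n_replicas = 100, seed = 10)
  expect_false(identical(a$sd, c2$sd))
})

test_that("Monte-Carlo sd matches the asymptotic covariance", {
  cv <- clean_curve(noise = 0.02, seed = 12)
  est <- fit_decay(cv)
  mc <- monte_carlo_rate_sd(cv, n_replicas = 500, seed = 13)
  asym <- monoexp_asymptotic_sd(cv$durations, est$amplitude, est$rate,
                                cv$rms)
  expect_lt(abs(mc$sd - asym[2]) / asym[2], 0.2)
})

test_that("decay curve validation rejects malformed inputs", {
  tau <- c(0, 0.01, 0.02)
  expect_error(decay_curve(tau, c(1, 2), c(10, 10, 10)), ">= 3")
  expect_error(decay_curve(tau, c(1, 1, 1), c(10, 0, 10)), "sino")
  expect_error(decay_curve(c(0, -0.01, 0.02), c(1, 1, 1), c(10, 10, 10)),
               ">= 0")
})

test_that("table-level fitting returns one rate per condition", {
  net <- reference_network()
  scheds <- list(spinlock_schedule(1000, 0, seq(0, 0.06, length.out = 8)),
                 spinlock_schedule(2000, 0, seq(0, 0.06, length.out = 8)))
  fx <- generate_synthetic_dataset(net, scheds, noise_frac = 0.01, seed = 3)
  rates <- fit_decay_table(fx$table, n_replicas = 50, seed = 4)
  expect_equal(nrow(rates), 2)
  eig <- r1rho_from_eigenvalue(reference_network(), c(1000, 2000), 0)
  expect_lt(max(abs(rates$r1rho - eig) / eig), 0.05)
  expect_true(all(rates$sd > 0))
})
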