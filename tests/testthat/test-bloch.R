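tm <- tumbling_model(5.1e-9)

partner_for <- function(net, r_gs, r_es = r_gs)
  dipolar_partner(offset_hz = -600, r1 = 2.5, r2 = 22.5,
                  distances = c(GS = r_gs, ES = r_es))

test_that("generator has the expected dimensions and kinetic structure", {
  net <- reference_network()
  L <- build_generator(net, power_hz = 1000)
  expect_equal(dim(L), c(6, 6))
  Lp <- build_generator(net, 1000, partner = partner_for(net, 3), tumbling = tm)
  expect_equal(dim(Lp), c(12, 12))
  # kinetic conservation: the exchange rate matrix has zero column sums and
  # the input populations as stationary vector
  K <- kinetic_matrix(net)
  expect_equal(colSums(K), c(GS = 0, ES = 0), tolerance = 1e-15)
  expect_equal(as.numeric(K %*% net$populations), c(0, 0), tolerance = 1e-9)
  expect_error(build_generator(net, 1000, partner = partner_for(net, 3)),
               "tumbling")
  bad <- dipolar_partner(-600, 2.5, 22.5, distances = c(GS = 3))
  expect_error(build_generator(net, 1000, partner = bad, tumbling = tm),
               "missing")
})

test_that("zeroed cross-relaxation embeds the bare exchange dynamics", {
  net <- reference_network()
  L0 <- build_generator(net, 800, offset_hz = 100)
  Lp <- build_generator(net, 800, offset_hz = 100,
                        partner = partner_for(net, 2.5), tumbling = tm,
                        sigma_scale = 0, mu_scale = 0)
  geom <- tilted_frame(net, 800, 100)
  m0 <- initial_magnetization(net, geom$theta)
  m0p <- initial_magnetization(net, geom$theta, partner_for(net, 2.5))
  taus <- seq(0, 0.1, length.out = 6)
  tr0 <- propagate(L0, m0, taus)
  trp <- propagate(Lp, m0p, taus)
  obs <- rep(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2)
  expect_equal(trp[obs, ], tr0, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("propagation matches closed forms", {
  L <- diag(c(-22.5, -10, -2.5))
  m0 <- c(1, 1, 1)
  out <- propagate(L, m0, c(0, 0.05))
  expect_equal(out[, 1], m0, ignore_attr = TRUE)
  expect_equal(out[, 2], exp(diag(L) * 0.05), tolerance = 1e-12,
               ignore_attr = TRUE)
  # symmetric two-site exchange of z-magnetisation: relaxation-free analytic
  kex <- 400
  K <- matrix(c(-kex / 2, kex / 2, kex / 2, -kex / 2), 2, 2)
  taus <- seq(0, 0.02, length.out = 9)
  traj <- propagate(K, c(1, 0), taus)
  expect_equal(traj[1, ], 0.5 + 0.5 * exp(-kex * taus), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(propagate(matrix(c(1, NA, 0, 1), 2), c(1, 0), 1), "finite")
  expect_error(propagate(K, c(1, 0), -0.1), ">= 0")
})

test_that("spinlock experiment reduces to pure transverse decay", {
  one <- exchange_network(list(site_state("GS", 1, 0, 2.5, 22.5)),
                          data.frame(from = character(), to = character(),
                                     kex = numeric()))
  sched <- spinlock_schedule(2000, 0, seq(0, 0.08, length.out = 10))
  dec <- simulate_spinlock_experiment(one, sched)
  expect_equal(dec$intensity, exp(-22.5 * dec$duration_s), tolerance = 1e-9)
})

test_that("remote dipolar partner leaves the decay untouched", {
  net <- reference_network()
  sched <- spinlock_schedule(1000, 0, seq(0, 0.06, length.out = 8))
  bare <- simulate_spinlock_experiment(net, sched)
  with40 <- simulate_spinlock_experiment(net, sched,
                                         partner = partner_for(net, 40),
                                         tumbling = tm)
  r_bare <- r1rho_from_decay(bare$intensity, bare$duration_s)
  r_with <- r1rho_from_decay(with40$intensity, with40$duration_s)
  expect_lt(abs(r_with - r_bare) / r_bare, 0.001)
})

test_that("far off-resonance spinlock locks magnetisation along z at R1", {
  net <- reference_network()
  sched <- spinlock_schedule(100, 5e5, seq(0, 1.2, length.out = 8))
  dec <- simulate_spinlock_experiment(net, sched)
  rate <- r1rho_from_decay(dec$intensity, dec$duration_s)
  expect_equal(rate, 2.5, tolerance = 1e-3)
})

test_that("network validation enforces the physical invariants", {
  expect_error(two_state_network(kex = -5, p_es = 0.01, dw_hz = 100), "kex")
  expect_error(site_state("a", 1.2, 0, 2, 20), "population")
  expect_error(site_state("a", 0.5, 0, 2, 1), "r2")
  s <- list(site_state("A", 0.5, 0, 2, 20), site_state("B", 0.5, 10, 2, 20),
            site_state("C", 0.1, 20, 2, 20))
  expect_error(exchange_network(s, data.frame(from = "A", to = "B",
                                              kex = 100)), "sum to 1")
  s[[3]] <- site_state("C", 0, 20, 2, 20)
  expect_error(exchange_network(s, data.frame(from = "A", to = "B",
                                              kex = 100)), "connected")
})
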