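# Independent oracles used across the suite. These never call into the
# package's own generator/eigenvalue code paths.

# Closed-form two-state R1rho for asymmetric populations (Trott-Palmer form):
# valid for small excited-state population and effective fields well above
# the relaxation rates.
trott_palmer_r1rho <- function(kex, p_es, dw_hz, r1, r2, power_hz,
                               offset_hz = 0) {
  pg <- 1 - p_es
  w1 <- 2 * pi * power_hz
  d_gs <- 2 * pi * (0 - offset_hz)
  d_es <- 2 * pi * (dw_hz - offset_hz)
  dbar <- pg * d_gs + p_es * d_es
  theta <- atan2(w1, dbar)
  we_gs <- d_gs^2 + w1^2
  we_es <- d_es^2 + w1^2
  we <- dbar^2 + w1^2
  rex <- pg * p_es * (2 * pi * dw_hz)^2 * kex / (we_gs * we_es / we + kex^2)
  r1 * cos(theta)^2 + sin(theta)^2 * (r2 + rex)
}

# Brute-force weighted mono-exponential fit: nested grid refinement over
# (amplitude, rate), minimising the weighted SSE directly.
grid_fit_monoexp <- function(durations, intensities, rms, n_iter = 8) {
  sse <- function(a, r) sum(((intensities - a * exp(-r * durations)) / rms)^2)
  a_rng <- range(abs(intensities)) * c(0.5, 2)
  r_rng <- c(0.01, 200)
  for (it in seq_len(n_iter)) {
    a_grid <- seq(a_rng[1], a_rng[2], length.out = 31)
    r_grid <- seq(r_rng[1], r_rng[2], length.out = 31)
    val <- outer(a_grid, r_grid, Vectorize(sse))
    ij <- which(val == min(val), arr.ind = TRUE)[1, ]
    a_best <- a_grid[ij[1]]; r_best <- r_grid[ij[2]]
    da <- diff(a_rng) / 30; dr <- diff(r_rng) / 30
    a_rng <- c(a_best - da, a_best + da)
    r_rng <- c(max(r_best - dr, 1e-6), r_best + dr)
  }
  c(amplitude = a_best, rate = r_best)
}

# asymptotic covariance of the weighted mono-exponential fit at (a, r)
monoexp_asymptotic_sd <- function(durations, a, r, rms) {
  J <- cbind(exp(-r * durations), -a * durations * exp(-r * durations)) / rms
  sqrt(diag(solve(crossprod(J))))
}

reference_network <- function(p_es = 0.005)
  two_state_network(kex = 2000, p_es = p_es, dw_hz = 600, r1 = 2.5, r2 = 22.5)
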