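# R1rho extraction: eigenvalue route, decay-fit route, R2eff transform.

#' Eigenvalue R1rho of an exchange-only system
#'
#' Builds the exchange-only Bloch-McConnell generator at one spinlock
#' condition and returns the rotating-frame relaxation rate as minus the real
#' part of the selected eigenvalue. Selection rule: among all modes, the one
#' whose eigenvector contributes most to the detected tilted-frame signal;
#' when the top contributions are nearly degenerate (ratio > 0.999) the least
#' negative real part among them wins. This disambiguates the "least negative
#' real eigenvalue" prescription when R1-like and R1rho-like modes cross at
#' extreme offsets.
#'
#' @param network An [exchange_network()] (no dipolar partner: the fitting
#'   models are exchange-only).
#' @param power_hz Spinlock power, Hz (`> 0`).
#' @param offset_hz Carrier offset relative to the ground-state resonance, Hz
#'   (vectorised over `power_hz`/`offset_hz` pairs after recycling).
#' @return R1rho in s^-1 (vector).
#' @examples
#' net <- two_state_network(kex = 2000, p_es = 0.005, dw_hz = 600)
#' r1rho_from_eigenvalue(net, power_hz = 1000)
#' @export
r1rho_from_eigenvalue <- function(network, power_hz, offset_hz = 0) {
  stopifnot(inherits(network, "exchange_network"))
  k <- max(length(power_hz), length(offset_hz))
  power_hz <- rep_len(power_hz, k); offset_hz <- rep_len(offset_hz, k)
  if (any(power_hz <= 0)) stop("'power_hz' must be > 0")
  K <- kinetic_matrix(network)
  as.numeric(cpp_r1rho_grid(network$populations, network$offsets_hz,
                            network$r1, network$r2, K,
                            cbind(power_hz, offset_hz)))
}

# shared mono-exponential fitter: minimises sum(w * (I - a*exp(-r*tau))^2)
.fit_monoexp <- function(durations, intensities, weights, warn = TRUE) {
  pos <- intensities > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm.fit(cbind(1, durations[pos]), log(intensities[pos]))
    start <- c(a = exp(lf$coefficients[1]), r = -lf$coefficients[2])
  } else {
    start <- c(a = intensities[which.min(durations)], r = 1)
  }
  if (!is.finite(start[2]) || start[2] == 0) start[2] <- 1
  sw <- sqrt(weights)
  res <- minpack.lm::nls.lm(
    par = list(a = unname(start[1]), r = unname(start[2])),
    fn = function(p) sw * (intensities - p$a * exp(-p$r * durations)),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!res$info %in% 1:4)
    stop("mono-exponential fit did not converge: ", res$message,
         " (residual norm ", signif(res$deviance, 4), ")")
  if (warn && res$par$r <= 0)
    warning("fitted rate is non-positive; intensities do not decay")
  list(rate = res$par$r, amplitude = res$par$a, chi2 = res$deviance,
       fitted = res$par$a * exp(-res$par$r * durations), info = res$info)
}

#' R1rho from a mono-exponential decay
#'
#' Unweighted mono-exponential fit `I0 exp(-R tau)`; the workhorse for
#' extracting decay rates from propagated (noise-free) trajectories. For
#' measured intensities with per-point noise use [fit_decay()].
#'
#' @param intensities Peak intensities.
#' @param durations Spinlock durations, seconds (`>= 3` points, not all
#'   equal).
#' @return Fitted rate, s^-1.
#' @export
r1rho_from_decay <- function(intensities, durations) {
  stopifnot(is.numeric(intensities), is.numeric(durations))
  if (length(durations) < 3L || length(intensities) != length(durations))
    stop("need >= 3 (duration, intensity) pairs of equal length")
  if (length(unique(durations)) < 3L) stop("durations must not be degenerate")
  .fit_monoexp(durations, intensities, rep(1, length(durations)))$rate
}

#' Transform R1rho to R2eff
#'
#' `R2eff = (R1rho - R1 cos^2 theta) / sin^2 theta`: removes the longitudinal
#' projection along the tilted effective field, leaving the
#' exchange-inclusive transverse rate.
#'
#' @param r1rho Rotating-frame rate(s), s^-1.
#' @param r1 Longitudinal rate, s^-1 (population-averaged).
#' @param theta Tilt angle(s), rad, `sin(theta) > 0`.
#' @return R2eff, s^-1.
#' @seealso [r2eff_to_r1rho()] for the algebraic inverse.
#' @export
r2eff_transform <- function(r1rho, r1, theta) {
  if (any(sin(theta) <= 0)) stop("'theta' must satisfy sin(theta) > 0")
  (r1rho - r1 * cos(theta)^2) / sin(theta)^2
}

#' Transform R2eff back to R1rho
#'
#' @inheritParams r2eff_transform
#' @param r2eff Effective transverse rate(s), s^-1.
#' @return R1rho, s^-1.
#' @export
r2eff_to_r1rho <- function(r2eff, r1, theta) {
  if (any(sin(theta) <= 0)) stop("'theta' must satisfy sin(theta) > 0")
  r2eff * sin(theta)^2 + r1 * cos(theta)^2
}
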