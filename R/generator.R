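# Rotating-frame evolution generators and spinlock-experiment propagation.
#
# Basis convention: one 3-vector (Ix, Iy, Iz) per exchange state for the
# observed spin; with a dipolar partner, (Ix, Iy, Iz, Sx, Sy, Sz) per state.
# Evolution is homogeneous, dM/dt = L M (relaxation toward zero): R1rho is a
# decay-rate measurement and the artifact mechanism of a z-polarised
# neighbour is represented through the initial condition, not a recovery
# term. Sign conventions: positive offsets are downfield of the carrier; the
# spinlock field lies along +x of the rotating frame.

#' Tilted-frame geometry at a spinlock condition
#'
#' @param network An [exchange_network()].
#' @param power_hz Spinlock power nu_SL, Hz, `> 0`.
#' @param offset_hz Carrier offset relative to the ground-state resonance, Hz.
#' @param average `"population"` (default): the tilt angle uses the
#'   population-averaged offset; `"ground"`: the ground-state offset only.
#' @return Object of class `tilted_frame` with `omega_eff` (rad/s) and
#'   `theta` (rad, in (0, pi]).
#' @export
tilted_frame <- function(network, power_hz, offset_hz = 0,
                         average = c("population", "ground")) {
  average <- match.arg(average)
  stopifnot(inherits(network, "exchange_network"), power_hz > 0)
  w1 <- 2 * pi * power_hz
  deltas <- 2 * pi * (network$offsets_hz - offset_hz)
  dbar <- if (average == "population") sum(network$populations * deltas)
          else deltas[1]
  structure(list(omega_eff = sqrt(w1^2 + dbar^2),
                 theta = atan2(w1, dbar),
                 delta_bar = dbar, omega1 = w1),
            class = "tilted_frame")
}

.site_block <- function(delta, w1, r1, r2) {
  matrix(c(-r2, delta, 0,
           -delta, -r2, w1,
           0, -w1, -r1), 3, 3)
}

#' Build the rotating-frame evolution generator
#'
#' Assembles the homogeneous Bloch-McConnell generator L (dM/dt = L M) for an
#' exchanging spin system at one spinlock condition, optionally coupled to a
#' dipolar neighbour proton. Per-site blocks carry the offset precession,
#' spinlock nutation and auto-relaxation; exchange couples identical operators
#' across sites with detailed-balance rates; with a partner, cross-relaxation
#' couples Iz-Sz with -sigma and Ix-Sx, Iy-Sy with -mu, where sigma and mu are
#' evaluated from the state-specific interproton distance.
#'
#' @param network An [exchange_network()].
#' @param power_hz,offset_hz Spinlock power and carrier offset, Hz.
#' @param partner Optional [dipolar_partner()]; its `distances` must cover
#'   every state label.
#' @param tumbling A [tumbling_model()], required when `partner` is given.
#' @param sigma_scale,mu_scale Scale factors applied to the longitudinal and
#'   transverse cross-relaxation rates (set to 0 to switch a pathway off).
#' @param add_dipolar_auto If `TRUE`, the dipolar auto-relaxation
#'   contributions rho1/rho2 are added on top of the user-specified R1/R2 of
#'   both spins. Default `FALSE`: stated R1/R2 are taken as the full rates.
#' @return Square numeric matrix (3n or 6n) with a `basis` attribute naming
#'   the rows (`"<state>.Ix"`, ..., `"<state>.Sz"`).
#' @export
build_generator <- function(network, power_hz, offset_hz = 0, partner = NULL,
                            tumbling = NULL, sigma_scale = 1, mu_scale = 1,
                            add_dipolar_auto = FALSE) {
  stopifnot(inherits(network, "exchange_network"), power_hz > 0,
            is.finite(offset_hz))
  n <- length(network$labels)
  w1 <- 2 * pi * power_hz
  deltas <- 2 * pi * (network$offsets_hz - offset_hz)
  K <- kinetic_matrix(network)

  if (is.null(partner)) {
    m <- 3L
    L <- matrix(0, 3 * n, 3 * n)
    basis <- as.vector(outer(c("Ix", "Iy", "Iz"), network$labels,
                             function(a, b) paste(b, a, sep = ".")))
    for (i in seq_len(n)) {
      idx <- (i - 1) * 3 + 1:3
      L[idx, idx] <- .site_block(deltas[i], w1, network$r1[i], network$r2[i])
    }
  } else {
    stopifnot(inherits(partner, "dipolar_partner"))
    if (is.null(tumbling))
      stop("'tumbling' is required when a dipolar partner is present")
    missing <- setdiff(network$labels, names(partner$distances))
    if (length(missing))
      stop("partner distances missing for state(s): ",
           paste(missing, collapse = ", "))
    m <- 6L
    L <- matrix(0, 6 * n, 6 * n)
    basis <- as.vector(outer(c("Ix", "Iy", "Iz", "Sx", "Sy", "Sz"),
                             network$labels,
                             function(a, b) paste(b, a, sep = ".")))
    delta_s <- 2 * pi * (partner$offset_hz - offset_hz)
    for (i in seq_len(n)) {
      rr <- dipolar_rates(partner$distances[[network$labels[i]]], tumbling)
      sig <- sigma_scale * rr$sigma
      mu <- mu_scale * rr$mu
      r1_i <- network$r1[i]; r2_i <- network$r2[i]
      r1_s <- partner$r1; r2_s <- partner$r2
      if (add_dipolar_auto) {
        r1_i <- r1_i + rr$rho1_dip; r2_i <- r2_i + rr$rho2_dip
        r1_s <- r1_s + rr$rho1_dip; r2_s <- r2_s + rr$rho2_dip
      }
      idx <- (i - 1) * 6
      L[idx + 1:3, idx + 1:3] <- .site_block(deltas[i], w1, r1_i, r2_i)
      L[idx + 4:6, idx + 4:6] <- .site_block(delta_s, w1, r1_s, r2_s)
      # cross-relaxation between observed spin and neighbour within the site
      L[idx + 1, idx + 4] <- L[idx + 4, idx + 1] <- -mu
      L[idx + 2, idx + 5] <- L[idx + 5, idx + 2] <- -mu
      L[idx + 3, idx + 6] <- L[idx + 6, idx + 3] <- -sig
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || K[i, j] == 0) next
      ii <- (i - 1) * m; jj <- (j - 1) * m
      for (c in seq_len(m)) L[ii + c, jj + c] <- L[ii + c, jj + c] + K[i, j]
    }
    ii <- (i - 1) * m
    for (c in seq_len(m)) L[ii + c, ii + c] <- L[ii + c, ii + c] + K[i, i]
  }
  if (any(!is.finite(L))) stop("non-finite entries in generator")
  attr(L, "basis") <- basis
  attr(L, "n_states") <- n
  attr(L, "has_partner") <- !is.null(partner)
  L
}

#' Initial magnetisation for a spinlock experiment
#'
#' The observed spin starts aligned with the effective field (tilt angle
#' `theta`), distributed across sites proportionally to populations. A
#' dipolar partner starts at +z (selective excitation, default) or tilted
#' with the observed spin (nonselective).
#'
#' @param network An [exchange_network()].
#' @param theta Tilt angle, rad.
#' @param partner Optional [dipolar_partner()].
#' @return Numeric vector matching the [build_generator()] basis.
#' @export
initial_magnetization <- function(network, theta, partner = NULL) {
  p <- network$populations
  if (is.null(partner)) {
    as.vector(rbind(p * sin(theta), 0, p * cos(theta)))
  } else if (partner$initial_mode == "selective") {
    as.vector(rbind(p * sin(theta), 0, p * cos(theta), 0, 0, p))
  } else {
    as.vector(rbind(p * sin(theta), 0, p * cos(theta),
                    p * sin(theta), 0, p * cos(theta)))
  }
}

.detection_vector <- function(network, theta, has_partner) {
  n <- length(network$labels)
  per <- if (has_partner) c(sin(theta), 0, cos(theta), 0, 0, 0)
         else c(sin(theta), 0, cos(theta))
  rep(per, n)
}

#' Propagate magnetisation under a generator
#'
#' Computes `expm(L tau) %*% m0` by scaling-and-squaring (Armadillo
#' `expmat`), vectorised over durations.
#'
#' @param L Square evolution matrix (from [build_generator()]).
#' @param m0 Initial magnetisation vector.
#' @param tau Non-negative durations, seconds.
#' @return Matrix with `length(m0)` rows and `length(tau)` columns.
#' @export
propagate <- function(L, m0, tau) {
  stopifnot(is.matrix(L), nrow(L) == ncol(L), length(m0) == nrow(L))
  if (any(!is.finite(L))) stop("non-finite entries in evolution matrix")
  if (any(!is.finite(tau)) || any(tau < 0)) stop("'tau' must be finite, >= 0")
  out <- cpp_expm_prop(L, as.numeric(m0), as.numeric(tau))
  rownames(out) <- attr(L, "basis")
  out
}

#' Simulate a spinlock relaxation experiment
#'
#' Emulates the pulse element: z magnetisation of the observed spin is tilted
#' to the effective-field axis (-y rotation by theta), evolves under the
#' spinlock generator for each duration, and is projected back (y rotation),
#' returning the summed observed-spin signal across exchange sites. The
#' partner follows its `initial_mode`.
#'
#' @param network An [exchange_network()].
#' @param schedule A [spinlock_schedule()].
#' @param partner Optional [dipolar_partner()] (requires `tumbling`).
#' @param tumbling Optional [tumbling_model()].
#' @param ... Passed to [build_generator()] (`sigma_scale`, `mu_scale`,
#'   `add_dipolar_auto`).
#' @return `data.frame` with columns `duration_s` and `intensity`.
#' @export
simulate_spinlock_experiment <- function(network, schedule, partner = NULL,
                                         tumbling = NULL, ...) {
  stopifnot(inherits(schedule, "spinlock_schedule"))
  if (length(schedule$durations_s) == 0L) stop("empty duration list")
  L <- build_generator(network, schedule$power_hz, schedule$offset_hz,
                       partner = partner, tumbling = tumbling, ...)
  geom <- tilted_frame(network, schedule$power_hz, schedule$offset_hz)
  m0 <- initial_magnetization(network, geom$theta, partner)
  d <- .detection_vector(network, geom$theta, !is.null(partner))
  traj <- propagate(L, m0, schedule$durations_s)
  data.frame(duration_s = schedule$durations_s,
             intensity = as.numeric(crossprod(d, traj)))
}
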