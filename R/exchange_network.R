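# Domain containers: exchanging sites, exchange networks, dipolar partner,
# spinlock schedules.

#' One conformational state of the observed spin
#'
#' @param label State name (e.g. `"GS"`, `"HG"`, `"ES2"`).
#' @param population Fractional population in `[0, 1]`.
#' @param offset_hz Chemical-shift offset of this state relative to the
#'   ground-state resonance, Hz (positive = downfield).
#' @param r1,r2 Longitudinal / transverse auto-relaxation rates, s^-1
#'   (`r2 >= r1 > 0`).
#' @return An object of class `site_state`.
#' @export
site_state <- function(label, population, offset_hz, r1, r2) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  stopifnot(is.finite(population), is.finite(offset_hz),
            is.finite(r1), is.finite(r2))
  if (population < 0 || population > 1) stop("'population' must lie in [0, 1]")
  if (r1 <= 0) stop("'r1' must be > 0")
  if (r2 < r1) stop("'r2' must be >= 'r1'")
  structure(list(label = label, population = population,
                 offset_hz = offset_hz, r1 = r1, r2 = r2),
            class = "site_state")
}

#' Chemical exchange network
#'
#' A set of exchanging states plus edge exchange rates. Each edge carries the
#' total rate `kex = k_ij + k_ji`; the directional rates follow detailed
#' balance, `k_ij = kex * p_j / (p_i + p_j)`, so the input populations are the
#' stationary distribution of the kinetic matrix by construction.
#'
#' @param states List of [site_state()] objects; populations must sum to 1
#'   (tolerance 1e-9).
#' @param edges `data.frame` with columns `from`, `to` (state labels) and
#'   `kex` (s^-1, `> 0`).
#' @param topology One of `"two_state"`, `"linear"`, `"star"`, `"triangular"`,
#'   `"generic"`. Purely a tag; the kinetic matrix is determined by `edges`.
#' @return An object of class `exchange_network`.
#' @seealso [two_state_network()], [kinetic_matrix()]
#' @export
exchange_network <- function(states, edges,
                             topology = c("generic", "two_state", "linear",
                                          "star", "triangular")) {
  topology <- match.arg(topology)
  stopifnot(is.list(states), length(states) >= 1L,
            all(vapply(states, inherits, logical(1), "site_state")))
  labels <- vapply(states, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate state labels")
  pops <- vapply(states, `[[`, numeric(1), "population")
  if (abs(sum(pops) - 1) > 1e-9)
    stop("state populations must sum to 1 (tolerance 1e-9)")
  stopifnot(is.data.frame(edges), all(c("from", "to", "kex") %in% names(edges)))
  if (length(states) > 1L && nrow(edges) == 0L)
    stop("multi-state network needs at least one edge")
  if (nrow(edges) > 0L) {
    if (!all(edges$from %in% labels) || !all(edges$to %in% labels))
      stop("edge endpoints must be state labels")
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    if (any(!is.finite(edges$kex)) || any(edges$kex <= 0))
      stop("all edge 'kex' must be finite and > 0")
    key <- apply(edges[, c("from", "to")], 1L,
                 function(x) paste(sort(x), collapse = "|"))
    if (anyDuplicated(key)) stop("duplicate edges")
  }
  net <- structure(list(states = states, edges = edges, topology = topology,
                        labels = labels, populations = pops,
                        offsets_hz = vapply(states, `[[`, numeric(1), "offset_hz"),
                        r1 = vapply(states, `[[`, numeric(1), "r1"),
                        r2 = vapply(states, `[[`, numeric(1), "r2")),
                   class = "exchange_network")
  if (!.is_connected(net)) stop("exchange network must be connected")
  net
}

.is_connected <- function(network) {
  n <- length(network$labels)
  if (n == 1L) return(TRUE)
  adj <- matrix(FALSE, n, n, dimnames = list(network$labels, network$labels))
  for (e in seq_len(nrow(network$edges))) {
    adj[network$edges$from[e], network$edges$to[e]] <- TRUE
    adj[network$edges$to[e], network$edges$from[e]] <- TRUE
  }
  seen <- c(TRUE, rep(FALSE, n - 1))
  repeat {
    new <- seen | apply(adj[seen, , drop = FALSE], 2, any)
    if (all(new == seen)) break
    seen <- new
  }
  all(seen)
}

#' Two-state exchange network
#'
#' Convenience constructor for the ground-state / excited-state case.
#'
#' @param kex Total exchange rate, s^-1.
#' @param p_es Excited-state population.
#' @param dw_hz Excited-state offset relative to the ground state, Hz.
#' @param r1,r2 Relaxation rates shared by both states, s^-1 (scalars or
#'   length-2 vectors `c(GS, ES)`).
#' @param labels State labels, default `c("GS", "ES")`.
#' @return An [exchange_network()] tagged `two_state`.
#' @export
two_state_network <- function(kex, p_es, dw_hz, r1 = 2.5, r2 = 22.5,
                              labels = c("GS", "ES")) {
  r1 <- rep_len(r1, 2L); r2 <- rep_len(r2, 2L)
  states <- list(
    site_state(labels[1], 1 - p_es, 0, r1[1], r2[1]),
    site_state(labels[2], p_es, dw_hz, r1[2], r2[2])
  )
  exchange_network(states,
                   data.frame(from = labels[1], to = labels[2], kex = kex),
                   topology = "two_state")
}

#' First-order kinetic matrix of an exchange network
#'
#' Returns the n x n rate matrix `K` with `K[i, j]` (i != j) the rate from
#' state j to state i and columns summing to zero. Detailed balance with the
#' input populations holds per edge: `k_ij p_i = k_ji p_j`.
#'
#' @param network An [exchange_network()].
#' @return Numeric matrix with state labels as dimnames.
#' @export
kinetic_matrix <- function(network) {
  stopifnot(inherits(network, "exchange_network"))
  n <- length(network$labels)
  K <- matrix(0, n, n, dimnames = list(network$labels, network$labels))
  p <- network$populations
  for (e in seq_len(nrow(network$edges))) {
    i <- match(network$edges$from[e], network$labels)
    j <- match(network$edges$to[e], network$labels)
    kex <- network$edges$kex[e]
    psum <- p[i] + p[j]
    if (psum <= 0) stop("edge between two zero-population states")
    kij <- kex * p[j] / psum   # rate i -> j
    kji <- kex * p[i] / psum   # rate j -> i
    K[j, i] <- K[j, i] + kij
    K[i, j] <- K[i, j] + kji
    K[i, i] <- K[i, i] - kij
    K[j, j] <- K[j, j] - kji
  }
  K
}

#' Dipolar-coupled neighbour proton
#'
#' A single spatial neighbour whose cross-relaxation with the observed spin is
#' modulated by exchange: the interproton distance may differ between exchange
#' states (e.g. a neighbour close in the ground state but remote in the
#' excited state).
#'
#' @param offset_hz Neighbour resonance offset relative to the ground-state
#'   resonance of the observed spin, Hz.
#' @param r1,r2 Neighbour auto-relaxation rates, s^-1.
#' @param distances Named numeric vector of interproton distances in Angstrom,
#'   one entry per exchange-state label, all `> 0`.
#' @param initial_mode `"selective"` (default): the neighbour is untouched by
#'   the excitation pulse and starts at equilibrium +z; `"nonselective"`: the
#'   neighbour is tilted together with the observed spin.
#' @return An object of class `dipolar_partner`.
#' @export
dipolar_partner <- function(offset_hz, r1, r2, distances,
                            initial_mode = c("selective", "nonselective")) {
  initial_mode <- match.arg(initial_mode)
  stopifnot(is.finite(offset_hz), is.finite(r1), is.finite(r2),
            is.numeric(distances), !is.null(names(distances)))
  if (r1 <= 0 || r2 < r1) stop("need r2 >= r1 > 0")
  if (any(!is.finite(distances)) || any(distances <= 0))
    stop("all distances must be finite and > 0")
  structure(list(offset_hz = offset_hz, r1 = r1, r2 = r2,
                 distances = distances, initial_mode = initial_mode),
            class = "dipolar_partner")
}

#' Spinlock schedule
#'
#' One experimental condition: spinlock power, carrier offset and the list of
#' spinlock durations sampled for the decay.
#'
#' @param power_hz Spinlock field strength nu_SL = omega_SL / 2 pi, Hz, `> 0`.
#' @param offset_hz Carrier offset relative to the ground-state resonance of
#'   the observed spin, Hz.
#' @param durations_s Non-negative spinlock durations, seconds (at least one).
#' @return An object of class `spinlock_schedule`.
#' @export
spinlock_schedule <- function(power_hz, offset_hz = 0, durations_s) {
  stopifnot(is.finite(power_hz), is.finite(offset_hz),
            is.numeric(durations_s), length(durations_s) >= 1L)
  if (power_hz <= 0) stop("'power_hz' must be > 0")
  if (any(!is.finite(durations_s)) || any(durations_s < 0))
    stop("durations must be finite and >= 0")
  structure(list(power_hz = power_hz, offset_hz = offset_hz,
                 durations_s = sort(durations_s)),
            class = "spinlock_schedule")
}

#' @export
print.exchange_network <- function(x, ...) {
  cat(sprintf("Exchange network (%s), %d states\n", x$topology,
              length(x$labels)))
  print(data.frame(state = x$labels, population = x$populations,
                   offset_hz = x$offsets_hz, r1 = x$r1, r2 = x$r2))
  if (nrow(x$edges)) {
    cat("Edges:\n")
    print(x$edges)
  }
  invisible(x)
}
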