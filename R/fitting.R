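# Dispersion fitting: two- and three-state exchange models via eigenvalue
# R1rho, global multi-dataset fits with parameter sharing, multi-start
# Levenberg-Marquardt, Monte-Carlo errors, AICc/BIC/F-test model selection.

#' Relaxation-dispersion dataset for one spin
#'
#' @param spin_label Identifier of the observed spin (e.g. `"T9-NH3"`).
#' @param power_hz,offset_hz Spinlock power and carrier offset per point, Hz.
#' @param value Observed rate per point, s^-1.
#' @param sd Standard deviation per point, s^-1, `> 0` (fit weights are
#'   `1/sd`).
#' @param observable `"r1rho"` or `"r2eff"`.
#' @param temperature_k,field_hz Optional metadata.
#' @return `data.frame` of class `dispersion_dataset`.
#' @export
dispersion_dataset <- function(spin_label, power_hz, offset_hz, value, sd,
                               observable = c("r1rho", "r2eff"),
                               temperature_k = NA_real_, field_hz = 600.16e6) {
  observable <- match.arg(observable)
  n <- length(value)
  power_hz <- rep_len(power_hz, n)
  offset_hz <- rep_len(offset_hz, n)
  sd <- rep_len(sd, n)
  stopifnot(n >= 3L)
  if (any(!is.finite(sd)) || any(sd <= 0)) stop("all 'sd' must be > 0")
  if (any(power_hz <= 0)) stop("all 'power_hz' must be > 0")
  out <- data.frame(power_hz = power_hz, offset_hz = offset_hz,
                    value = value, sd = sd)
  attr(out, "spin_label") <- spin_label
  attr(out, "observable") <- observable
  attr(out, "temperature_k") <- temperature_k
  attr(out, "field_hz") <- field_hz
  class(out) <- c("dispersion_dataset", "data.frame")
  out
}

# Topology catalogue. State 1 is the ground state (offset fixed at 0);
# states 2 and 3 are minor states. Edge parameters are named kex_<i><j>.
.topologies <- list(
  two_state  = list(n = 2L, edges = list(kex_12 = c(1L, 2L))),
  linear     = list(n = 3L, edges = list(kex_12 = c(1L, 2L),
                                         kex_23 = c(2L, 3L))),
  star       = list(n = 3L, edges = list(kex_12 = c(1L, 2L),
                                         kex_13 = c(1L, 3L))),
  triangular = list(n = 3L, edges = list(kex_12 = c(1L, 2L),
                                         kex_13 = c(1L, 3L),
                                         kex_23 = c(2L, 3L)))
)

# nested-model pairs (simpler must be a sub-graph with fewer parameters)
.nested_pairs <- list(c("two_state", "linear"), c("two_state", "star"),
                      c("two_state", "triangular"), c("linear", "triangular"),
                      c("star", "triangular"))

#' Exchange model specification
#'
#' Defines the exchange topology, which parameters are held fixed, and which
#' are shared across datasets in a global fit. Parameters: per-edge exchange
#' rates `kex_12`, `kex_13`, `kex_23` (s^-1; state 1 = ground state, 2/3 =
#' minor states), minor-state populations `p2`, `p3`, offsets `dw2`, `dw3`
#' (Hz, relative to the ground state, sign free) and per-spin rates `r1`,
#' `r2` (s^-1). The ground-state population is `1 - p2 - p3` by construction.
#'
#' @param topology `"two_state"`, `"linear"` (1-2-3 chain), `"star"` (2-1-3)
#'   or `"triangular"` (all three edges).
#' @param fixed Named list of parameters excluded from fitting (e.g.
#'   `list(r1 = 2.5)` when R1 is known from an independent measurement).
#' @param shared Character vector of parameters shared across datasets in a
#'   global fit. Default: exchange rates and populations are global, offsets
#'   and relaxation rates per-dataset.
#' @return Object of class `exchange_model`.
#' @export
exchange_model <- function(topology = c("two_state", "linear", "star",
                                        "triangular"),
                           fixed = list(), shared = NULL) {
  topology <- match.arg(topology)
  topo <- .topologies[[topology]]
  params <- c(names(topo$edges),
              if (topo$n == 3L) c("p2", "p3", "dw2", "dw3")
              else c("p2", "dw2"),
              "r1", "r2")
  if (length(fixed)) {
    bad <- setdiff(names(fixed), params)
    if (length(bad)) stop("unknown fixed parameter(s): ",
                          paste(bad, collapse = ", "))
  }
  if (is.null(shared))
    shared <- grep("^(kex_|p[0-9])", params, value = TRUE)
  shared <- intersect(shared, params)
  structure(list(topology = topology, n_states = topo$n, edges = topo$edges,
                 params = params, fixed = fixed, shared = shared),
            class = "exchange_model")
}

# transforms keeping rates/populations in-bounds under unconstrained LM
.to_transformed <- function(name, value) {
  if (grepl("^kex_", name) || name %in% c("r1", "r2")) log(value)
  else if (grepl("^p[0-9]", name)) stats::qlogis(value)
  else value
}
.to_natural <- function(name, value) {
  if (grepl("^kex_", name) || name %in% c("r1", "r2")) exp(value)
  else if (grepl("^p[0-9]", name)) stats::plogis(value)
  else value
}
.base_name <- function(x) sub("@.*$", "", x)

#' Predicted observable of an exchange model
#'
#' Builds the exchange-only Bloch-McConnell generator for the given parameter
#' values and returns the eigenvalue R1rho at each spinlock condition,
#' transformed to R2eff when requested (using the model's own `r1` and the
#' population-averaged tilt angle).
#'
#' @param model An [exchange_model()].
#' @param params Named numeric vector/list with every model parameter
#'   (including fixed ones).
#' @param power_hz,offset_hz Spinlock conditions, Hz (equal length).
#' @param observable `"r1rho"` or `"r2eff"`.
#' @return Numeric vector of predicted rates, s^-1.
#' @export
model_r1rho <- function(model, params, power_hz, offset_hz = 0,
                        observable = c("r1rho", "r2eff")) {
  observable <- match.arg(observable)
  stopifnot(inherits(model, "exchange_model"))
  params <- unlist(params)
  missing <- setdiff(model$params, names(params))
  if (length(missing)) stop("missing parameter(s): ",
                            paste(missing, collapse = ", "))
  k <- max(length(power_hz), length(offset_hz))
  power_hz <- rep_len(power_hz, k); offset_hz <- rep_len(offset_hz, k)
  n <- model$n_states
  p_minor <- if (n == 3L) c(params[["p2"]], params[["p3"]]) else params[["p2"]]
  pops <- c(1 - sum(p_minor), p_minor)
  if (any(pops <= 0) || any(pops >= 1))
    stop("populations out of range (check p2 + p3 < 1)")
  dw <- c(0, params[["dw2"]], if (n == 3L) params[["dw3"]])
  r1 <- rep(params[["r1"]], n); r2 <- rep(params[["r2"]], n)
  K <- matrix(0, n, n)
  for (e in names(model$edges)) {
    ij <- model$edges[[e]]
    kex <- params[[e]]
    if (kex < 0) stop("negative exchange rate")
    i <- ij[1]; j <- ij[2]
    kij <- kex * pops[j] / (pops[i] + pops[j])
    kji <- kex * pops[i] / (pops[i] + pops[j])
    K[j, i] <- K[j, i] + kij; K[i, i] <- K[i, i] - kij
    K[i, j] <- K[i, j] + kji; K[j, j] <- K[j, j] - kji
  }
  r1rho <- as.numeric(cpp_r1rho_grid(pops, dw, r1, r2, K,
                                     cbind(power_hz, offset_hz)))
  if (observable == "r1rho") return(r1rho)
  dbar <- vapply(seq_len(k), function(q)
    sum(pops * 2 * pi * (dw - offset_hz[q])), numeric(1))
  theta <- atan2(2 * pi * power_hz, dbar)
  r2eff_transform(r1rho, params[["r1"]], theta)
}

# parameter bookkeeping for (possibly global) fits -------------------------

.par_layout <- function(model, datasets) {
  free <- setdiff(model$params, names(model$fixed))
  labels <- names(datasets)
  names <- unlist(lapply(free, function(b)
    if (b %in% model$shared || length(datasets) == 1L) b
    else paste0(b, "@", labels)))
  names
}

.params_for_dataset <- function(par_natural, model, label) {
  base <- .base_name(names(par_natural))
  own <- !grepl("@", names(par_natural)) |
    endsWith(names(par_natural), paste0("@", label))
  v <- par_natural[own]
  names(v) <- base[own]
  c(v, unlist(model$fixed))
}

.residual_fun <- function(model, datasets) {
  n_total <- sum(vapply(datasets, nrow, integer(1)))
  function(pt) {
    nat <- vapply(names(pt), function(nm)
      .to_natural(.base_name(nm), pt[[nm]]), numeric(1))
    names(nat) <- names(pt)
    psum <- 0
    for (b in c("p2", "p3")) {
      idx <- .base_name(names(nat)) == b
      if (any(idx)) psum <- psum + max(nat[idx])
    }
    if (psum >= 0.999) return(rep(1e6, n_total))
    out <- lapply(names(datasets), function(lab) {
      ds <- datasets[[lab]]
      pars <- .params_for_dataset(nat, model, lab)
      pred <- tryCatch(
        model_r1rho(model, pars, ds$power_hz, ds$offset_hz,
                    observable = attr(ds, "observable")),
        error = function(e) NULL)
      if (is.null(pred)) rep(1e6, nrow(ds)) else (ds$value - pred) / ds$sd
    })
    unlist(out)
  }
}

# Cascade initialisation for three-state fits: seed from a two-state prefit,
# scanning candidate offsets for the extra minor state across the probed
# offset window and a log-spaced ladder of candidate exchange rates. The
# triangular/linear/star likelihoods are multimodal; random multi-start alone
# misses the dominant basin for unlucky noise draws.
.informed_starts <- function(pre, model, par_names, datasets) {
  offs <- unlist(lapply(datasets, `[[`, "offset_hz"))
  span <- max(abs(offs), 2000)
  dw3_grid <- span * c(-1, -0.5, -0.2, 0.2, 0.5, 1)
  kex_grid <- c(500, 3000, 10000)
  pre_pt <- pre$par_transformed
  lapply(seq_len(length(dw3_grid) * length(kex_grid)), function(q) {
    dw3 <- dw3_grid[(q - 1) %% length(dw3_grid) + 1]
    kex <- kex_grid[(q - 1) %/% length(dw3_grid) + 1]
    v <- vapply(par_names, function(nm) {
      b <- .base_name(nm)
      if (nm %in% names(pre_pt)) pre_pt[[nm]]
      else if (b %in% c("kex_13", "kex_23")) log(kex)
      else if (b == "p3") stats::qlogis(0.005)
      else if (b == "dw3") dw3
      else .to_transformed(b, .random_start(b))
    }, numeric(1))
    names(v) <- par_names
    v
  })
}

.random_start <- function(base) {
  switch(sub("[0-9]+$", "", sub("_.*$", "", base)),
         kex = exp(stats::runif(1, log(50), log(5e4))),
         p = stats::runif(1, 1e-4, 0.3),
         dw = stats::runif(1, -3000, 3000),
         r = if (base == "r1") exp(stats::runif(1, log(0.5), log(5)))
             else exp(stats::runif(1, log(5), log(60))))
}

# triangular fits are label-symmetric in the two minor states; report with
# minor states ordered by increasing chemical-shift offset (first dataset)
.canonicalize <- function(est, model) {
  if (model$topology != "triangular") return(est)
  nm <- names(est)
  d2 <- nm[.base_name(nm) == "dw2"][1]
  d3 <- nm[.base_name(nm) == "dw3"][1]
  get <- function(n) if (n %in% nm) est[[n]] else unlist(model$fixed)[[n]]
  if (is.na(d2) || is.na(d3)) return(est)
  if (get(d2) <= get(d3)) return(est)
  swap <- function(a, b) {
    ia <- which(.base_name(nm) == a); ib <- which(.base_name(nm) == b)
    if (length(ia) == length(ib) && length(ia) > 0) {
      tmp <- est[ia]; est[ia] <<- est[ib]; est[ib] <<- tmp
    }
  }
  swap("dw2", "dw3"); swap("p2", "p3"); swap("kex_12", "kex_13")
  est
}

#' Fit an exchange model to dispersion data
#'
#' Minimises the weighted sum of squares `sum(((obs - pred) / sd)^2)` over
#' one or several datasets simultaneously (Levenberg-Marquardt), honouring
#' the model's sharing rules, with random multi-start initialisation
#' (exchange rates log-uniform in [50, 5e4] s^-1, populations uniform in
#' (1e-4, 0.3), offsets uniform in [-3000, 3000] Hz). The best converged
#' start by chi-squared wins. Triangular results are canonicalised by
#' ordering the two minor states by increasing offset.
#'
#' @param datasets A [dispersion_dataset()] or list of them.
#' @param model An [exchange_model()].
#' @param n_starts Number of random initialisations (default 20).
#' @param seed Optional integer seed for the starts.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param cascade For three-state topologies, additionally seed the
#'   multi-start from a two-state prefit combined with a grid of candidate
#'   offsets and exchange rates for the extra minor state (default `TRUE`;
#'   the three-state likelihoods are multimodal and purely random starts can
#'   miss the dominant basin).
#' @return Object of class `fit_result`: `estimates` (natural scale),
#'   `chi2`, `red_chi2`, `n`, `k`, `aicc`, `bic`, `residuals`, `converged`,
#'   plus internals used by [mc_parameter_errors()] and [compare_models()].
#' @export
fit_model <- function(datasets, model, n_starts = 20L, seed = NULL,
                      maxiter = 200L, cascade = TRUE) {
  stopifnot(inherits(model, "exchange_model"))
  if (inherits(datasets, "dispersion_dataset")) datasets <- list(datasets)
  labels <- make.unique(vapply(datasets, attr, character(1), "spin_label"))
  names(datasets) <- labels
  par_names <- .par_layout(model, datasets)
  N <- sum(vapply(datasets, nrow, integer(1)))
  k <- length(par_names)
  if (N < k + 2) stop("identifiability guard: need at least k + 2 points")
  fn <- .residual_fun(model, datasets)
  informed <- list()
  if (model$n_states == 3L && cascade) {
    pre_fixed <- model$fixed[names(model$fixed) %in%
                               c("kex_12", "p2", "dw2", "r1", "r2")]
    pre <- tryCatch(
      fit_model(datasets, exchange_model("two_state", fixed = pre_fixed,
                                         shared = model$shared),
                n_starts = min(n_starts, 12L), seed = seed),
      error = function(e) NULL)
    if (!is.null(pre)) {
      informed <- .informed_starts(pre, model, par_names, datasets)
      # the informed starts count against the multi-start budget
      n_inf <- min(length(informed), max(n_starts - 2L, 0L))
      informed <- informed[round(seq(1, length(informed),
                                     length.out = n_inf))]
    }
  }
  n_random <- max(n_starts - length(informed), 2L)
  if (!is.null(seed)) withr::local_seed(seed)
  starts <- c(informed, lapply(seq_len(n_random), function(s) {
    v <- vapply(par_names, function(nm) {
      b <- .base_name(nm)
      .to_transformed(b, .random_start(b))
    }, numeric(1))
    names(v) <- par_names
    v
  }))
  runs <- lapply(starts, function(st) {
    tryCatch(minpack.lm::nls.lm(
      par = as.list(st), fn = function(p) fn(p),
      control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      error = function(e) e)
  })
  ok <- vapply(runs, function(r)
    !inherits(r, "error") && r$info %in% 1:4, logical(1))
  if (!any(ok)) {
    msgs <- vapply(runs, function(r)
      if (inherits(r, "error")) conditionMessage(r) else r$message,
      character(1))
    stop("no start converged:\n", paste(unique(msgs), collapse = "\n"))
  }
  dev <- vapply(runs, function(r)
    if (inherits(r, "error")) Inf else r$deviance, numeric(1))
  dev[!ok] <- Inf
  best <- runs[[which.min(dev)]]
  pt <- unlist(best$par)
  est <- vapply(names(pt), function(nm)
    .to_natural(.base_name(nm), pt[[nm]]), numeric(1))
  names(est) <- names(pt)
  est <- .canonicalize(est, model)
  chi2 <- best$deviance
  ic <- .info_criteria(chi2, N, k)
  resid <- fn(as.list(pt))
  structure(list(
    model = model, datasets = datasets, estimates = est,
    par_transformed = pt, chi2 = chi2, n = N, k = k,
    red_chi2 = chi2 / (N - k), aicc = ic$aicc, bic = ic$bic,
    residuals = resid, converged = TRUE, info = best$info,
    n_starts = n_starts, start_chi2 = dev, seed = seed,
    mc_sd = NULL, n_replicas = 0L
  ), class = "fit_result")
}

#' Monte-Carlo parameter uncertainties
#'
#' Resamples each observed rate from `Normal(obs, sd)`, refits from the
#' converged solution, and reports per-parameter standard deviations over the
#' replicas (canonicalised consistently with the point fit). Deterministic
#' for a fixed seed; more than 10% failed replicas is an error.
#'
#' @param fit A converged [fit_model()] result.
#' @param n_replicas Number of replicas (default 500).
#' @param seed Optional integer seed.
#' @return The `fit_result` with `mc_sd`, `replica_mean` and `n_replicas`
#'   filled in.
#' @export
mc_parameter_errors <- function(fit, n_replicas = 500L, seed = NULL) {
  stopifnot(inherits(fit, "fit_result"), n_replicas >= 2L)
  if (!is.null(seed)) withr::local_seed(seed)
  datasets <- fit$datasets
  reps <- matrix(NA_real_, n_replicas, fit$k,
                 dimnames = list(NULL, names(fit$par_transformed)))
  for (b in seq_len(n_replicas)) {
    dsb <- lapply(datasets, function(ds) {
      ds$value <- stats::rnorm(nrow(ds), ds$value, ds$sd)
      ds
    })
    fn <- .residual_fun(fit$model, dsb)
    run <- tryCatch(minpack.lm::nls.lm(
      par = as.list(fit$par_transformed), fn = function(p) fn(p),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(run) || !run$info %in% 1:4) next
    pt <- unlist(run$par)
    est <- vapply(names(pt), function(nm)
      .to_natural(.base_name(nm), pt[[nm]]), numeric(1))
    names(est) <- names(pt)
    reps[b, ] <- .canonicalize(est, fit$model)[colnames(reps)]
  }
  failed <- sum(!stats::complete.cases(reps))
  if (failed > 0.1 * n_replicas)
    stop(sprintf("%d of %d Monte-Carlo replicas failed", failed, n_replicas))
  fit$mc_sd <- apply(reps, 2, stats::sd, na.rm = TRUE)
  fit$replica_mean <- colMeans(reps, na.rm = TRUE)
  fit$n_replicas <- as.integer(n_replicas - failed)
  fit
}

.info_criteria <- function(chi2, N, k) {
  if (N <= k + 1) stop("AICc undefined: need N > k + 1")
  aic <- N * log(chi2 / N) + 2 * k
  list(aic = aic,
       aicc = aic + 2 * k * (k + 1) / (N - k - 1),
       bic = N * log(chi2 / N) + k * log(N))
}

#' Information criteria of a fit
#'
#' Gaussian weighted-least-squares likelihood convention:
#' `AIC = N log(chi2 / N) + 2k`, `AICc = AIC + 2k(k+1)/(N-k-1)`,
#' `BIC = N log(chi2 / N) + k log(N)`.
#'
#' @param fit A [fit_model()] result.
#' @return List with `aic`, `aicc`, `bic`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  .info_criteria(fit$chi2, fit$n, fit$k)
}

#' Rank candidate exchange models
#'
#' Applies the three selection rules to fits of the same data: F-test on
#' nested pairs (`F = ((chi2_1 - chi2_2)/(k2 - k1)) / (chi2_2/(N - k2))`,
#' richer model accepted at `p < alpha`), BIC (richer model requires a BIC
#' drop of at least `bic_margin`) and AICc (lower wins). A richer model is
#' selected only when every applicable rule prefers it; disagreements are
#' retained in the justification trail and break toward the
#' fewer-parameters model. F-tests on non-nested pairs are skipped with a
#' note.
#'
#' @param fits Named list of [fit_model()] results on identical data (names
#'   default to topologies).
#' @param alpha F-test significance level (default 0.05).
#' @param bic_margin Required BIC difference (default 10).
#' @return Object of class `model_comparison`: `table`, `ftests`, `selected`,
#'   `justification`.
#' @export
compare_models <- function(fits, alpha = 0.05, bic_margin = 10) {
  stopifnot(is.list(fits), length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "fit_result")))
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- make.unique(vapply(fits, function(f)
      f$model$topology, character(1)))
  Ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(Ns)) != 1L)
    stop("candidate fits must be on identical data (differing N)")
  obs0 <- unlist(lapply(fits[[1]]$datasets, `[[`, "value"))
  for (f in fits[-1]) {
    if (!isTRUE(all.equal(obs0, unlist(lapply(f$datasets, `[[`, "value")))))
      stop("candidate fits must be on identical data")
  }
  tab <- data.frame(
    model = names(fits),
    topology = vapply(fits, function(f) f$model$topology, character(1)),
    k = vapply(fits, `[[`, numeric(1), "k"),
    chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
    red_chi2 = vapply(fits, `[[`, numeric(1), "red_chi2"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    row.names = NULL
  )
  res <- .select_from_table(tab, Ns[[1]], alpha, bic_margin)
  structure(c(list(table = tab), res), class = "model_comparison")
}

# selection rules applied to a summary table (shared with the CLI, which
# reconstructs the table from fit-report JSON files)
.select_from_table <- function(tab, N, alpha = 0.05, bic_margin = 10) {
  is_nested <- function(a, b) {
    any(vapply(.nested_pairs, function(p)
      p[1] == a && p[2] == b, logical(1)))
  }
  ftests <- list()
  just <- character(0)
  ord <- order(tab$k, tab$aicc)
  sel <- ord[1]
  just <- c(just, sprintf("start from simplest model '%s' (k = %d)",
                          tab$model[sel], tab$k[sel]))
  for (cand in ord[-1]) {
    t1 <- tab$topology[sel]; t2 <- tab$topology[cand]
    k1 <- tab$k[sel]; k2 <- tab$k[cand]
    chi1 <- tab$chi2[sel]; chi2 <- tab$chi2[cand]
    if (k2 <= k1) {
      if (tab$aicc[cand] < tab$aicc[sel]) {
        sel <- cand
        just <- c(just, sprintf("'%s' preferred on AICc at equal complexity",
                                tab$model[cand]))
      }
      next
    }
    nested <- is_nested(t1, t2)
    fpass <- NA
    if (nested) {
      Fstat <- ((chi1 - chi2) / (k2 - k1)) / (chi2 / (N - k2))
      pval <- stats::pf(Fstat, k2 - k1, N - k2, lower.tail = FALSE)
      ftests[[paste(tab$model[sel], "vs", tab$model[cand])]] <-
        list(F = Fstat, df1 = k2 - k1, df2 = N - k2, p = pval)
      fpass <- is.finite(pval) && pval < alpha
    } else {
      just <- c(just, sprintf("F-test skipped for non-nested pair %s / %s",
                              tab$model[sel], tab$model[cand]))
    }
    bpass <- (tab$bic[sel] - tab$bic[cand]) >= bic_margin
    apass <- tab$aicc[cand] < tab$aicc[sel]
    rules <- c(if (nested) c(ftest = fpass), bic = bpass, aicc = apass)
    if (all(rules)) {
      just <- c(just, sprintf(
        "'%s' preferred over '%s' (%s)", tab$model[cand], tab$model[sel],
        paste(names(rules), collapse = " + ")))
      sel <- cand
    } else if (any(rules)) {
      just <- c(just, sprintf(
        "rules disagree for '%s' vs '%s' (%s); keeping the simpler model",
        tab$model[cand], tab$model[sel],
        paste(sprintf("%s=%s", names(rules), rules), collapse = ", ")))
    } else {
      just <- c(just, sprintf("'%s' not supported over '%s'",
                              tab$model[cand], tab$model[sel]))
    }
  }
  list(ftests = ftests, selected = tab$model[sel], justification = just)
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table)
  cat("selected:", x$selected, "\n")
  invisible(x)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: chi2 = %.4g, red. chi2 = %.4g (N = %d, k = %d)\n",
              x$model$topology, x$chi2, x$red_chi2, x$n, x$k))
  est <- data.frame(estimate = x$estimates)
  if (!is.null(x$mc_sd)) est$mc_sd <- x$mc_sd[rownames(est)]
  print(est)
  invisible(x)
}

#' Simulate a noisy dispersion dataset from an exchange model
#'
#' Predicts the observable on a grid of spinlock conditions and adds
#' multiplicative Gaussian noise; the reported per-point standard deviation
#' equals the generating noise level.
#'
#' @param model An [exchange_model()].
#' @param params Full named parameter vector (truth).
#' @param grid `data.frame` with columns `power_hz`, `offset_hz`.
#' @param noise_frac Relative noise level (default 0.02).
#' @param seed Optional integer seed.
#' @param observable `"r1rho"` or `"r2eff"`.
#' @param spin_label Label for the resulting dataset.
#' @return A [dispersion_dataset()].
#' @export
simulate_dispersion <- function(model, params, grid, noise_frac = 0.02,
                                seed = NULL,
                                observable = c("r1rho", "r2eff"),
                                spin_label = "sim") {
  observable <- match.arg(observable)
  stopifnot(is.data.frame(grid), all(c("power_hz", "offset_hz") %in%
                                       names(grid)))
  truth <- model_r1rho(model, params, grid$power_hz, grid$offset_hz,
                       observable = observable)
  if (!is.null(seed)) withr::local_seed(seed)
  sd <- pmax(noise_frac * abs(truth), 1e-6)
  value <- truth + stats::rnorm(length(truth), 0, sd)
  dispersion_dataset(spin_label, grid$power_hz, grid$offset_hz, value, sd,
                     observable = observable)
}
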