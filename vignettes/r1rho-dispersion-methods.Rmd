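---
title: "Methods: simulating and fitting 1H R1rho relaxation dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and fitting 1H R1rho relaxation dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`r1rhoRD` addresses two coupled questions in proton-detected rotating-frame
relaxation dispersion (R1rho RD) of nucleic acids at natural abundance:

1. **When can 1H R1rho profiles be trusted?** A proton's R1rho decay can be
   contaminated by dipolar cross-relaxation (NOE/ROE transfer) with a nearby
   proton, mimicking chemical exchange. The package propagates the full
   Bloch-McConnell equations for an exchanging spin pair coupled to a
   neighbour proton and quantifies the artifact as a percentage of the
   reference transverse rate.
2. **What exchange model do the data support?** The package fits two- and
   three-state exchange models (linear, star and triangular topologies) to
   dispersion profiles through the eigenvalue route, with multi-start
   Levenberg-Marquardt optimisation, Monte-Carlo parameter uncertainties and
   AICc/BIC/F-test model ranking.

# The spin model

## Rotating-frame evolution

For each exchange state $i$ the observed magnetisation
$(I_x, I_y, I_z)$ evolves under

$$
\frac{d}{dt}\begin{pmatrix}I_x\\I_y\\I_z\end{pmatrix} =
\begin{pmatrix}
-R_2 & -\delta_i & 0\\
\delta_i & -R_2 & -\omega_1\\
0 & \omega_1 & -R_1
\end{pmatrix}
\begin{pmatrix}I_x\\I_y\\I_z\end{pmatrix},
$$

with $\delta_i = 2\pi(\Delta\omega_i/2\pi - \Omega_\mathrm{SL}/2\pi)$ the
state's offset from the spinlock carrier and $\omega_1 = 2\pi\nu_\mathrm{SL}$
the spinlock amplitude (along $+x$). Exchange couples identical operators
across states with first-order rates obeying detailed balance: for an edge
with total rate $k_\mathrm{ex} = k_{ij} + k_{ji}$,
$k_{ij} = k_\mathrm{ex}\, p_j/(p_i + p_j)$, so the input populations are the
stationary distribution by construction (and three-state cycles are
automatically thermodynamically consistent).

Evolution is homogeneous (relaxation toward zero): R1rho is a decay-rate
measurement and no thermal-recovery term is needed. The spinlock element is
modelled as in the experiment: the observed spin starts aligned with the
effective field at tilt $\theta = \arctan(\omega_1/\bar\Omega)$, where
$\bar\Omega$ is the population-averaged offset (a ground-state-only variant
is available), distributed over states in proportion to their populations.

## Dipolar neighbour

A neighbour proton at distance $r_i$ (possibly different in each exchange
state — exchange modulates the coupling) doubles the basis to
$(I_x,I_y,I_z,S_x,S_y,S_z)$ per state. With
$b = (\mu_0/4\pi)\,\hbar\gamma_H^2/r^3$, $q = b^2/10$ and the Lorentzian
spectral density $J(\omega) = \tau_c/(1 + (\omega\tau_c)^2)$ (all prefactors
carried in the rates, none in $J$):

* $\sigma = q\,(6J(2\omega_0) - J(0))$ couples $I_z \leftrightarrow S_z$
  (NOE-type),
* $\mu = q\,(2J(0) + 3J(\omega_0))$ couples $I_x \leftrightarrow S_x$ and
  $I_y \leftrightarrow S_y$ (ROE-type),
* $\rho_1 = q\,(J(0) + 3J(\omega_0) + 6J(2\omega_0))$ and
  $\rho_2 = \tfrac{q}{2}(5J(0) + 9J(\omega_0) + 6J(2\omega_0))$ are the
  dipolar auto-relaxation contributions.

All four scale exactly as $r^{-6}$. In the slow-tumbling regime relevant for
DNA duplexes ($\omega_0\tau_c \approx 19$ at 600.16 MHz and
$\tau_c = 5.1$ ns), $\sigma < 0 < \mu$ and $|\mu| > |\sigma|$, so the
transverse (ROE) pathway dominates on-resonance artifacts. By default the
dipolar auto-relaxation terms are *not* added to the user-supplied $R_1$ and
$R_2$ — the reference simulation fixes identical relaxation rates for all
species, implying auto contributions are already folded into those inputs —
but `add_dipolar_auto = TRUE` enables the additive convention.

The neighbour starts at $+z$ (selective excitation of the observed spin,
the default) or tilted with the observed spin (`initial_mode =
"nonselective"`); which convention underlay the original simulations is not
documented, so both are provided.

## R1rho extraction

Two routes are implemented and tested against each other:

* **Propagation** (`simulate_spinlock_experiment` + `r1rho_from_decay`):
  matrix exponentials of the full generator, projection of the summed
  observed-spin signal back onto the effective-field axis, mono-exponential
  refit. This is the route used for the artifact study, because
  cross-relaxation makes the decay multi-exponential in principle and the
  refit mirrors what an experimentalist fits.
* **Eigenvalue** (`r1rho_from_eigenvalue`, `model_r1rho`): minus the real
  part of the selected eigenvalue of the exchange-only generator. This is
  the fitting route. "Least negative real eigenvalue" is ambiguous where
  slow modes cross, so the mode is selected by its contribution to the
  detected signal, $|(d^\top v_k)(V^{-1}m_0)_k|$, falling back to the least
  negative (near-real) eigenvalue when the eigensystem is near-defective.

The exchange-free closed form $R_{1\rho} = R_1\cos^2\theta + R_2\sin^2\theta$
is the secular approximation; the exact Bloch eigenvalue deviates from it by
$O(((R_2-R_1)/\omega_\mathrm{eff})^2)$ (about $10^{-6}$ relative at a 1 kHz
spinlock with the reference rates). On resonance the transverse mode
decouples exactly and the identity is exact. Test tolerances reflect this.

$R_\mathrm{2eff} = (R_{1\rho} - R_1\cos^2\theta)/\sin^2\theta$ uses the
population-averaged tilt angle by default.

# The artifact study

The reference system is a two-state network (ground state GS, excited state
ES) with $k_\mathrm{ex} = 2000$ s$^{-1}$, $p_\mathrm{ES} = 0.5\%$,
$\Delta\omega_\mathrm{ES}/2\pi = +600$ Hz, a neighbour at $-600$ Hz, all
$R_1 = 2.5$ s$^{-1}$, all $R_2 = 22.5$ s$^{-1}$, $\tau_c = 5.1$ ns,
600.16 MHz. Three scenarios map the ground-state distance $r_i$ to the
excited-state distance: coupling lost in the ES ($r_j = 40$ Å), unchanged
($r_j = r_i$), or slightly stronger ($r_j = r_i - 0.2$ Å).

The artifact metric is
$100\,|R_{1\rho}^\mathrm{full} - R_{1\rho}^{\sigma=\mu=0}| / R_2^\mathrm{ref}$
with a fixed reference $R_2$ (22.5 s$^{-1}$), matching the convention of an
assumed-experimental-error band around the average $R_2$ rather than a
point-wise ratio. Default grids: 25 log-spaced on-resonance powers in
[100, 6000] Hz; off-resonance offsets $[-900, 900]$ Hz in 25 Hz steps at
$\nu_\mathrm{SL} = 250$ Hz. Decays are sampled at 8 durations spanning 1.5
expected lifetimes (auto-scaled from the exchange-only eigenvalue), which
keeps the mono-exponential refit well conditioned across regimes.

With these conventions the package reproduces the headline rules: at
$r_i \ge 3$ Å the contribution stays at or below 5% of $R_2$ when coupling is
lost in the ES, the threshold moving to about 3.2 Å when coupling persists
or strengthens; a neighbour inside the probed offset window additionally
produces a spurious off-resonance response at its own offset for
$r_i < 3$ Å.

# Decay analysis

Measured (or synthetic) intensity decays are fit to $I_0 e^{-R\tau}$ by
weighted Levenberg-Marquardt least squares with per-point weights
$1/\mathrm{rms}^2$, $\mathrm{rms} = I/(2\,\mathrm{sino})$ — the spectrometer
noise convention. Starting values come from a log-linear regression, removing
starting-point sensitivity. Uncertainties are parametric Monte-Carlo:
replicas drawn from $N(I_\mathrm{fit}(\tau), \mathrm{rms})$, refit, and
summarised by the replica standard deviation (500 replicas by default; a
residual-bootstrap variant is available since the resampling convention is
not uniquely determined by the stated procedure).

# Exchange fitting

Datasets are weighted by their per-point uncertainties and fit by
Levenberg-Marquardt on transformed parameters ($\log k_\mathrm{ex}$,
logit $p$, linear $\Delta\omega$, $\log R_{1,2}$), which enforces positivity
and population bounds without constrained optimisation. Global fits share
exchange rates and populations across spins by default while offsets and
relaxation rates stay per-spin; both rules are overridable.

**Multi-start and cascade initialisation.** Random starts draw
$k_\mathrm{ex}$ log-uniformly from $[50, 5\times10^4]$ s$^{-1}$, $p$ from
$(10^{-4}, 0.3)$ and $\Delta\omega$ from $[-3000, 3000]$ Hz. Three-state
likelihoods are multimodal (distinct exchange pathways can mimic one
another), and purely random starts miss the dominant basin for unlucky noise
draws; `fit_model` therefore also seeds three-state fits from a two-state
prefit, scanning candidate offsets for the extra state across the probed
offset window and a ladder of candidate rates. These informed starts count
against the `n_starts` budget. The best converged start by chi-squared wins.

**Label symmetry.** The triangular topology is permutation-symmetric in its
two minor states; fitted results (and every Monte-Carlo replica) are
canonicalised by ordering the minor states by increasing chemical-shift
offset. Linear and star topologies are not symmetric and are left as-is.

**Identifiability.** When the observable is $R_\mathrm{2eff}$, the transform
cancels the $R_1\cos^2\theta$ term exactly, leaving $R_1$ essentially
unidentifiable; fits of $R_\mathrm{2eff}$ data should fix $R_1$ at an
independently measured value (`exchange_model(..., fixed = list(r1 = ...))`),
as done throughout the benchmark harness. Even then, parameters of a sparsely
populated third state lie along a shallow likelihood ridge at realistic noise
(2%): single-dataset point estimates scatter substantially (reflected
honestly in the Monte-Carlo uncertainties), which is why the recovery
criteria are formulated in Monte-Carlo standard deviations and why the
reported point estimates in `scripts/acceptance.R` come from a
replicate-averaged fit (100 noisy replicates per condition, averaged
point-wise — the weighted-least-squares equivalent of a global fit over
replicate experiments).

**Model selection.** With weighted residuals, the criteria use the Gaussian
working likelihood: $\mathrm{AIC} = N\ln(\chi^2/N) + 2k$,
$\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(N-k-1)$,
$\mathrm{BIC} = N\ln(\chi^2/N) + k\ln N$. Nested pairs (two-state within
linear/star/triangular; linear/star within triangular) are compared by
F-test at 95% confidence; a richer model is selected only when the F-test,
a BIC drop of at least 10 *and* a lower AICc agree, with disagreements
reported and ties broken toward fewer parameters.

# Benchmark parameter sets

Two reference sets anchor the recovery harness, representing the
WCF-HG-ES2 equilibrium in A2 DNA:

* triangular (T9 imino proton, 298 K): $k_\mathrm{ex}^{WCF-HG}=2.7$ kHz,
  $p_{HG}=0.6\%$, $\Delta\omega_{HG}=-593$ Hz, $k_\mathrm{ex}^{WCF-ES2}=0.5$
  kHz, $k_\mathrm{ex}^{HG-ES2}=3.2$ kHz, $p_{ES2}=0.9\%$,
  $\Delta\omega_{ES2}=+288$ Hz;
* linear (purine-substituted A16, 278 K): fast edge
  $k_\mathrm{ex}^{HG-ES2}=18$ kHz with $p_{ES2}=19.3\%$; the remaining
  values are carried over from the wild-type set as this package's
  completion of the benchmark (they are not part of the reported fast-edge
  result and only define the synthetic ground truth).

$R_1 = 2.5$ s$^{-1}$ and $R_2 = 22.5$ s$^{-1}$ complete both spin systems —
the same values as the artifact-study reference, chosen because the
benchmark and the artifact study describe the same class of system at the
same field. The benchmark grid is 15 on-resonance powers (1-6 kHz) plus
off-resonance sweeps at 250/500/1000 Hz covering $\pm1.5$ kHz (78
conditions).

# What the synthetic generator does and does not emulate

`generate_synthetic_dataset` produces spectrometer-style intensity tables:
mono-exponentially decaying peak intensities with Gaussian noise whose
magnitude is a stated fraction of the clean intensity, plus a
signal-to-noise column chosen so the weighting rule
$\mathrm{rms} = I/(2\,\mathrm{sino})$ reproduces the generating noise
exactly. It does not emulate peak overlap or deconvolution errors,
temperature or field drift, water-exchange line broadening, off-resonance
pulse imperfections, or correlated noise between spectra. Passing the
recovery tests therefore demonstrates correctness of the estimation
machinery under the stated noise model, not robustness to every
spectrometer pathology.

# Problem sizes used by the test suite

The acceptance tests run the artifact scans on the full default grids, the
recovery studies at 10 noise realisations with 20 multi-starts and 50
Monte-Carlo replicas per fit, and the model-selection experiments at 10
realisations with 16 multi-starts — sizes chosen so the whole suite
completes in well under half an hour on a single core while leaving the
statistical thresholds (8/10, 9/10) meaningful. The remaining unit and
property tests use coarser grids (6-point power grids, 50-100 Monte-Carlo
replicas) since they check identities rather than statistical power.

# Known limitations

* Isotropic tumbling only; anisotropic rotational diffusion is an extension
  hook, not implemented.
* At most one dipolar partner; no cross-correlated relaxation, scalar
  coupling, or heteronuclear partners.
* The fitting models are exchange-only (no dipolar partner in the fit
  matrix) — the simulator exists precisely to delineate when that is safe.
* No bi-exponential decay fallback: decays are treated as mono-exponential
  throughout, matching the analysis convention the package implements.
* CEST band shapes, radiation damping and spectral processing are out of
  scope.
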