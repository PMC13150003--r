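# r1rhoRD

Simulation and fitting of proton rotating-frame (R1ρ) relaxation-dispersion
NMR, for studying sparsely populated "excited" conformational states of
nucleic acids at natural isotopic abundance.

## The problem

R1ρ relaxation dispersion measures how the decay rate of spin-locked
magnetisation depends on the spinlock power ν_SL and carrier offset Ω_SL.
Chemical exchange between a ground state and low-populated excited states
adds an exchange contribution R_ex to the transverse rate, and the shape of
R1ρ(ν_SL, Ω_SL) encodes the exchange rates k_ex, populations p and
chemical-shift differences Δω of the invisible states.

For proton-detected experiments there is a complication: dipolar
cross-relaxation (NOE/ROE transfer) with a nearby proton can distort the
decay and mimic exchange. `r1rhoRD` addresses both sides of the problem:

* a **Bloch–McConnell simulator** that propagates an exchanging spin system
  coupled to a dipolar neighbour proton through the spinlock pulse element
  and quantifies the cross-relaxation artifact as a percentage of the
  reference R2 — establishing when standard exchange models are safe (for
  typical nucleic-acid geometries: neighbour distances ≥ 3–3.2 Å);
* a **dispersion-fitting suite**: R1ρ from the Bloch–McConnell eigenvalue
  (the mode selected by its overlap with the spin-locked magnetisation),
  two-state and three-state (linear / star / triangular) exchange
  topologies with detailed-balance kinetics, global fits with shared
  parameters across spins, multi-start Levenberg–Marquardt with cascade
  initialisation, Monte-Carlo parameter uncertainties, and model ranking by
  AICc, BIC (difference ≥ 10) and F-test (95%);
* **decay analysis** of spectrometer-style intensity tables: weighted
  mono-exponential fits with the noise convention rms = I/(2·sino) and
  Monte-Carlo rate uncertainties;
* a **synthetic-data generator** emulating exported peak-intensity tables,
  used for the parameter-recovery and model-selection studies;
* a small **command line interface** (`inst/cli/r1rho_rd.R`) with
  subcommands `simulate`, `make-fixtures`, `fit-decays`, `fit-exchange`,
  `select-model`.

The methods vignette (`vignettes/r1rho-dispersion-methods.Rmd`) documents the
model, conventions and numerical choices.

## Worked example

Quantify the cross-relaxation artifact for a neighbour proton at −600 Hz
whose coupling is lost in the excited state (the two-state reference system:
k_ex = 2 kHz, p_ES = 0.5%, Δω_ES = +600 Hz, R1 = 2.5 s⁻¹, R2 = 22.5 s⁻¹,
τ_c = 5.1 ns at 600.16 MHz):

```r
library(r1rhoRD)
sys <- reference_artifact_system()
contrib <- cross_relaxation_contribution(sys, scenario_spec(1, 3.0))
max(contrib$contribution_pct)
#> [1] 2.534055     # percent of R2: within the 5% band, exchange fits are safe
max(cross_relaxation_contribution(sys, scenario_spec(1, 2.5))$contribution_pct)
#> [1] 7.589732     # a 2.5 A neighbour distorts the profile
```

Fit a triangular three-state model to a synthetic R2eff dispersion dataset
generated at the benchmark excited-state parameters (2% noise) and rank it
against the two-state alternative:

```r
bench <- benchmark_triangular_params()
ds <- simulate_dispersion(bench$model, bench$params, benchmark_grid(),
                          noise_frac = 0.02, seed = 101,
                          observable = "r2eff", spin_label = "T9-NH3")
fit <- fit_model(ds, bench$model, n_starts = 20, seed = 102)
fit <- mc_parameter_errors(fit, n_replicas = 100, seed = 103)
fit
#> triangular fit: chi2 = 62.94, red. chi2 = 0.8991 (N = 78, k = 8)
#>             estimate        mc_sd
#> kex_12  3.070854e+03 8.561560e+02
#> kex_13  9.096452e+01 3.306050e+02
#> kex_23  2.991112e+03 6.511874e+02
#> p2      6.381198e-03 9.987442e-04
#> p3      9.705524e-03 1.783170e-02
#> dw2    -5.767618e+02 3.475333e+01
#> dw3     2.855288e+02 6.807021e+01
#> r2      2.253454e+01 1.931635e-01

two <- fit_model(ds, exchange_model("two_state", fixed = list(r1 = 2.5)),
                 n_starts = 10, seed = 104)
compare_models(list(two_state = two, triangular = fit))
#>        model   topology k      chi2  red_chi2       aicc       bic
#> 1  two_state  two_state 4 296.79904 4.0107978 112.782968 121.66186
#> 2 triangular triangular 8  62.93841 0.8991201   1.351881  18.11859
#> selected: triangular
```

The generating values (k_ex,12 = 2700 s⁻¹, p2 = 0.6%, Δω2 = −593 Hz,
p3 = 0.9%, Δω3 = +288 Hz, k_ex,23 = 3200 s⁻¹, R2 = 22.5 s⁻¹) are recovered
within the Monte-Carlo uncertainties, and the selection rules prefer the
triangular topology over the two-state model by a wide margin (Δχ² ≈ 234 for
4 extra parameters, ΔBIC ≈ 104).

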