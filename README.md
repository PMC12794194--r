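# micellekin

Micellization kinetics and critical micelle concentration (CMC)
estimation from short, replicated simulation runs.

## The problem

The standard simulation route to a surfactant's CMC measures the free
(non-micellized) surfactant concentration after the system has fully
equilibrated — which, for strongly aggregating surfactants, can take
millions of time steps per concentration. `micellekin` implements the
short-time alternative: run several short replicas, fit the decay of the
free-surfactant mass fraction

```
p_free(t) = A + (B − A) exp(−t/τ)
```

and read the equilibrium plateau `A = p_free(∞)` off the fit. The
exponential form is not ad hoc: it is the linearized long-time behaviour
of the Becker–Döring / Aniansson–Wall stepwise association model

```
A_1 + A_n  ⇌  A_{n+1}          (forward k_n⁺, backward k_n⁻)
```

whose relaxation spectrum splits into a fast micelle-formation band (τ₁)
and one slow, well-separated micelle-redistribution mode (τ₂) that
barely moves the free monomer. A fit window τ₁ ≪ τ ≪ τ₂ therefore
recovers the equilibrium plateau long before the system itself
equilibrates. From `A`, `C_free = A·C_tot`, and the CMC follows — directly
for nonionic surfactants, or through the charge-phase inversion

```
log C_free + β log(β C_free + (1−β) C_tot/(1−φ)) = (1+β) log CMC
```

for ionic ones (β = counterion binding degree, φ = packing fraction).

The package covers the whole chain, for people building or validating
such protocols:

* a classical-nucleation free-energy landscape
  `W_n = −g(n−1) + γ(n−1)^{2/3} + h(n−1)^{5/3}` with equilibrium
  aggregate distributions, saddle detection and landscape-level CMC;
* detailed-balance stepwise kinetics with stiff integration (analytic
  Jacobian) and relaxation-spectrum eigenanalysis;
* plateau fitting with jackknife uncertainties, fit-window error-surface
  scans and automatic window selection;
* nonionic/ionic CMC conversion, Stauff–Klevens homologous-series
  extrapolation, unit helpers;
* periodic single-linkage clustering of coordinate frames into
  aggregates;
* a synthetic finite-box repeat generator (exact-fill multinomial
  sampling from the kinetic model, with the exact finite-box expectation
  of `p_free` computed by dynamic programming) so the full protocol can
  be exercised end to end without a particle simulator.

## Worked example

Calibrate the reference landscape (micellar mode at n = 20, monomer
density 0.01), inspect the relaxation spectrum, simulate ten synthetic
300-molecule repeat runs, fit the plateau, and convert to a CMC for a
1.5 wt% box of a 422.6 g/mol nonionic surfactant:

```r
library(micellekin)

params <- calibrate_to_peak(target_peak_n = 20, c1 = 0.01)
eq     <- equilibrium_distribution(params, c1 = 0.01, n_max = 60)
rates  <- build_rates(eq)
relaxation_spectrum(rates)
#> <spectral_result>  60 modes
#>   zero mode: #1 (|lambda| = 3.392e-18)
#>   slow mode: #2, lambda = -6.2185e-05, tau2 = 1.608e+04 (next mode 3.37x faster)

traj   <- integrate_kinetics(rates, times = seq(0, 2e4, by = 20))
series <- synth_repeats(traj, n_molecules = 300, n_repeats = 10, seed = 7)$series
fit    <- jackknife_plateau(series, window = c(5000, 15000))
fit
#> <plateau_fit>
#>   window   [5000, 15000]  (501 frames)
#>   A    = 0.112506 +/- 0.00181 (jackknife, j_ratio = 0.9)
#>   B    = 0.148455
#>   tau  = 3808.64

C_tot <- wtpercent_to_mM(1.5, molar_mass = 422.6)   # 35.49 mM
cf <- pfree_to_cfree(fit$A, C_tot, fit$sigma_A)
cmc_nonionic(cf$C_free)
#> 3.993  (± 0.064 mM)
```

Reading: the zero eigenvalue is the exact mass-conservation mode; the
next eigenvalue is the slow micelle-redistribution pathway (τ₂ ≈ 16000
time units), distinctly slower than the rest of the spectrum. The fitted
plateau says 11.3 ± 0.2 % of surfactant stays free at equilibrium —
extracted from a window ending at t = 15000, far before the τ₂
relaxation completes — giving C_free, and hence the CMC estimate,
3.99 ± 0.06 mM.

Series too long-chained to simulate directly extrapolate geometrically:

```r
sk <- stauff_klevens(data.frame(tail_length = c(5, 6), cmc = c(1.19, 0.11)))
sk$ratio          # 0.092 per added tail bead
predict(sk, 8)    # 9.4e-4 mM, three beads further
```

An end-to-end run (`run_pipeline()`) chains calibrate → rates →
integrate → synthesize repeats → window → fit → CMC from a single YAML
config (see `inst/extdata/example-config.yaml`), and a thin CLI wraps
the same functions: `inst/cli/micellekin run --config config.yaml`, with
subcommands `simulate-kinetics`, `synth`, `cluster`, `fit-cmc`,
`scan-window` and `extrapolate`.

The methods vignette (`vignettes/micellekin-methods.Rmd`) documents the
model, the calibration closure, every protocol default and the
generator's scope.

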