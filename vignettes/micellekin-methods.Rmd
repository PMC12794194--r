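---
title: "Methods: micellization kinetics and short-time CMC estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micellization kinetics and short-time CMC estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
```

```{r setup}
library(micellekin)
```

## The problem

Measuring a surfactant's critical micelle concentration (CMC) in particle
simulations usually means waiting for the free (non-micellized) surfactant
concentration to reach steady state, which for strongly aggregating
surfactants can take millions of time steps. The alternative implemented
here is to run several short replicate simulations, fit the decay of the
free-surfactant mass fraction `p_free(t)` with a theoretically motivated
exponential, and read the equilibrium plateau off the fit — trading one
long run for a handful of short ones plus an extrapolation whose validity
rests on the relaxation structure of stepwise micelle kinetics.

`micellekin` implements that whole chain: the aggregate free-energy
landscape and its equilibrium distributions, the stepwise association
kinetics and their relaxation spectrum, the plateau-fitting protocol with
jackknife uncertainties and fit-window diagnostics, the conversion of the
plateau into a CMC for nonionic and ionic surfactants, aggregate
clustering for coordinate frames, and a synthetic finite-box generator
that emulates replicate runs so the whole protocol can be exercised and
validated end to end without a particle simulator.

## Free-energy landscape

The excess free energy of an aggregate of $n$ surfactants, relative to
$n$ free monomers, is modelled as

$$W_n^{\mathrm{ex}} = -g\,(n-1) + \gamma\,(n-1)^{2/3} + h\,(n-1)^{5/3}$$

in units of $k_BT$: a bulk driving force $g$, a surface penalty $\gamma$
(classical nucleation theory), and a superextensive packing penalty $h$
accounting for the co-localization of head and tail groups, which is what
caps micelles at a finite size — without it ($h = 0$) the landscape has no
micellar minimum and aggregates grow without bound once $g$ exceeds the
surface term. Concentration enters through the ideal mixing term, shifting
$g \to g + \log c_1\Lambda^3$, and aggregate concentrations follow
$c_n\Lambda^3 = e^{-W_n}$ with $W_1$ arranged so the identity
$c_1 = c_1$ holds exactly at $n = 1$. All distribution arithmetic is done
in log space; $\Lambda^3 = 1$ by default (reduced concentration units).

Above a threshold monomer concentration the landscape develops a saddle at
$n^*$ and the distribution becomes bimodal; `find_saddle()` locates the
interior minimum (returning the configured pragmatic cutoff, default
$n^* = 6$, when the region around the minimum is numerically flat), and
`cmc_from_landscape()` locates the threshold by bisection with a discrete
saddle test refined by the continuous stationarity condition.

```{r landscape}
params <- calibrate_to_peak(target_peak_n = 20, c1 = 0.01)
params
eq <- equilibrium_distribution(params, c1 = 0.01, n_max = 60)
autoplot(eq)
```

### Calibration of the reference system

The reference ("toy surfactant") system used throughout the package's
tests and examples fixes the micellar mode at $n = 20$ with monomer
density $c_1 = 0.01$. Two coefficients are solved from two stationarity
conditions of $\log c_n$ in continuous $n$: the micellar maximum at the
target size, and the minimum — the saddle — pinned at the submicellar
cutoff $n^* = 6$. This closure makes the free/micellar partition cutoff
coincide exactly with the distribution minimum, which is where such a
cutoff belongs, and reduces the calibration to a linear solve.

The packing penalty $h$ is not identifiable from the two mode locations;
it controls the barrier depth and through it the overall kinetic
sharpness. It is set from the surfactant's length-to-girth (aspect) ratio
as $h = h_{\mathrm{ref}}\,(r/5)^{-4/3}$ — the $-4/3$ power follows a
Gaussian chain-stretching estimate for spherical packing — with
$h_{\mathrm{ref}} = 0.12$ chosen once for the reference 5:1 surfactant so
the toy system reproduces the phenomenology the short-time protocol is
designed for: an equilibrium free fraction of order 0.1, a plateau decay
time of a few thousand reduced time units (so runs of $2\times10^4$ units
resolve the plateau), and a clearly bimodal distribution. Both the aspect
ratio and any explicit `h` override are recorded in the returned
parameter object.

## Stepwise association kinetics

Aggregates evolve by monomer exchange only,
$A_1 + A_n \rightleftharpoons A_{n+1}$, the standard stepwise association
model. Forward rates are diffusion-limited (Smoluchowski rate for a
monomer meeting a sphere of radius $\propto n^{1/3}$, with
Stokes–Einstein diffusivities):

$$k_n^+ = \tfrac{1}{16}\,(1 + n^{1/3})(1 + n^{-1/3}),$$

normalised so the dimer formation rate is $k_1^+ = 1/4$, a convention that
fixes the unit of time. (The unnormalised form evaluates to 4 at $n = 1$;
the $1/16$ reconciles the two statements and is the only normalisation
used here.) Backward rates follow from detailed balance against the
equilibrium distribution, so every stepwise flux vanishes identically
there — a property the test suite asserts to round-off.

The rate equations conserve $\sum_n n\,c_n$ exactly; the truncation at
`n_max` (default $3\times$ the micellar mode, i.e. 60) is reflecting
(no flux beyond `n_max`) so conservation holds in the truncated system
too. The system is stiff — the monomer couples to every reaction — and is
integrated with `deSolve`'s `lsoda` using the analytic Jacobian
(tridiagonal plus a dense first row and column), relative tolerance
$10^{-8}$ and absolute tolerance $10^{-12} C_{\mathrm{tot}}$.

```{r kinetics}
rates <- build_rates(eq)
traj <- integrate_kinetics(rates, times = seq(0, 2e4, by = 20))
glance(traj)
autoplot(traj)
```

## Relaxation spectrum

Linearizing about a state gives decay modes from the eigenvalues of the
kinetic Jacobian. Mass conservation contributes one exact zero eigenvalue
(left null vector $(1, 2, \ldots, n_{max})$), classified by the threshold
$|\lambda| < 10^{-9}\,\max|\lambda|$ and excluded from time scales. At
equilibrium the smallest remaining decay constant is the slow
micelle-number redistribution pathway ($\tau_2$); the faster band
($\tau_1$) is not a single mode and is left unreduced.

Right-eigenvector components are reported both raw and per unit
equilibrium concentration. The raw components are dominated by the
monomer simply because $c_1$ exceeds any single micellar $c_n$ by orders
of magnitude; in the relative normalisation the slow mode shows its
physical structure — near-zero monomer component, negative below the
micellar mode and positive above it (micelles grow while their number is
quasi-conserved, and the free monomer barely moves during the final
relaxation). Under the default calibration the slow mode is a factor
$\approx 3$–4 slower than the next mode, a distinct gap relative to the
quasi-continuum above it (consecutive ratios elsewhere stay below
$\approx 1.6$); deeper barriers widen the gap but push the equilibration
time beyond what a short-run protocol can observe, so the default sits
deliberately at the protocol-friendly end.

```{r spectrum}
sp <- relaxation_spectrum(rates)
sp
autoplot(sp)
```

The separation of time scales is what justifies the protocol: fitting on
a window $\tau_1 \ll \tau \ll \tau_2$ captures the exponential approach of
`p_free` to its plateau, and because the monomer component of the slow
mode is nearly zero, partial $\tau_2$ relaxation hardly moves `p_free` —
so the plateau read off a short window is already the equilibrium value.

## Plateau fitting, jackknife, and window choice

`p_free(t)` — the mass fraction of surfactant in aggregates of size
$\le n^*$ — is fitted on a window with

$$p_{\mathrm{free}}(t) = A + (B - A)\,e^{-t/\tau},$$

by Levenberg–Marquardt least squares on the repeat-averaged series
(averaging first minimizes noise; the jackknife then resamples repeats,
not time points). Start values are the decile-averaged window end points;
$\tau$ is bounded positive. Failed or nonsensical fits ($A < 0$,
$\tau \le 0$, non-convergence, $\tau$ vastly exceeding the window) are
returned as flagged data rather than errors, because mapping where fits
fail is itself part of the protocol. A constant series returns
$A = B$ with $\tau$ flagged unidentifiable.

Uncertainty comes from jackknife resampling over the $m$ repeats: with
`j_ratio` $= (m-1)/m$ (the default 0.9 at $m = 10$) each of the $m$
leave-one-out subsets is averaged and refitted, and
$\sigma_A^2 = \frac{m-1}{m}\sum_i (A_i - \bar A)^2$; smaller ratios
enumerate all $\binom{m}{k}$ subsets with the delete-$d$ variance
(computationally heavier, available but not the default).

Window choice matters more than anything else in the protocol.
`window_scan()` maps $\sigma_A$ — and, when a reference plateau from long
runs exists, the squared error — over a grid of start times and
durations; regions of high $\sigma_A$ co-localize with regions of high
error, which is what makes $\sigma_A$ usable as a self-contained guide
when no reference exists. `auto_window()` implements the resulting
heuristic: start where the repeat mean has decayed to $1/e$ of its
initial deviation from a running plateau estimate (exactly $t = \tau$ for
a pure exponential; the normalised-deviation reading is used because the
raw value of `p_free` at $1/e$ has no model-independent meaning), fit for
1.5 fitted decay times, iterate to self-consistency, and floor the
duration at $10^4$ time units to prevent false convergence. The packaged
default window (start 5000, duration 10000 time units) reflects the same
reasoning applied to the reference system.

```{r fit}
series <- synth_repeats(traj, n_molecules = 300, n_repeats = 10,
                        seed = 7)$series
fit <- jackknife_plateau(series, window = c(5000, 15000))
fit
```

## From plateau to CMC

`C_free = A C_tot` with $\sigma_{C_{free}} = \sigma_A C_{tot}$. For
nonionic (and zwitterionic) surfactants `C_free` estimates the CMC
directly; an optional accessible-volume factor $1/(1-\phi)$, with
$\phi = V_m C_{tot}$ the surfactant packing fraction, compensates the
volume excluded by micelles (labelled an approximation — the full
treatment lives in its own literature, and the factor used here mirrors
the counterion-crowding factor of the ionic model). For ionic surfactants
the charge-phase relation

$$\log C_{\mathrm{free}} + \beta\,\log\!\Big(\beta C_{\mathrm{free}} +
  (1-\beta)\tfrac{C_{\mathrm{tot}}}{1-\phi}\Big) = (1+\beta)\log
  \mathrm{CMC}$$

is inverted in closed form. Natural logarithms are used throughout (any
consistent base cancels). $\beta$, the counterion binding degree, is a
required explicit input for charged systems — it is surfactant-specific
and no universal default is defensible. Note the direction of the
correction: at fixed measured $C_{\mathrm{free}}$ the inferred CMC
*grows* with $C_{\mathrm{tot}}$, because added counterions depress the
free surfactant below the CMC (the common-ion effect the model exists to
undo). Molar volumes assume unit mass density,
$V_m = M/(1000\,\mathrm{g/L})$.

When several total concentrations are sampled, per-concentration CMCs are
combined as an unweighted mean ± standard deviation
(`combine_cmc()`). Homologous series extrapolate geometrically:
`stauff_klevens()` fits $\log \mathrm{CMC}$ linear in tail length (exact
ratio for two points) and predicts members whose CMCs are too low to
measure directly.

## The synthetic finite-box generator

`synth_repeats()` stands in for replicate coarse-grained runs. Its
defaults mirror the conditions the protocol targets: 300 surfactant
molecules per box, 10 repeats, frames every 20 reduced time units, runs
of $2\times10^4$ units, submicellar cutoff 6, and a pure-monomer initial
state. At each frame it draws the box's aggregate composition from the
kinetic model's evolving size distribution: aggregates are sampled iid
with probability $c_n(t)/\sum_m c_m(t)$, conditioned — through a renewal
dynamic program over the remaining mass — on filling the box exactly.
Every frame conserves molecules exactly; a master seed spawns one
substream per repeat, so output is reproducible and repeats are
independent.

A box of 300 molecules is a genuinely biased observer of mass fractions:
the expected sampled `p_free` exceeds the macroscopic
$\sum_{n\le n^*} n c_n / \sum_n n c_n$ by $O(1/N)$ (a ratio-of-sums
effect intrinsic to aggregate-level sampling, about $+2/N$ here — roughly
$+0.006$ at $N = 300$ against a plateau of $0.11$). Rather than leaving
that bias implicit, `expected_box_pfree()` computes the exact finite-box
expectation by dynamic programming, and the tests compare fitted plateaus
against that exact generator truth. The deviation shrinks as $1/N$ across
the box-size series 75–600, and the repeat-to-repeat variance of `p_free`
scales the same way — both asserted as properties in the suite.

What the generator does emulate: multinomial composition noise at fixed
box mass, the pure-monomer start, finite frame spacing, repeat-to-repeat
independence. What it does not: frame-to-frame autocorrelation (real
trajectories sample configurations much more slowly than iid draws, so
real $\sigma_A$ at equal frame counts is larger), hydrodynamics and
electrostatics, fusion/fission pathways, multi-monomer exchange, and any
deviation of the real free-energy landscape from the three-coefficient
model. Passing tests therefore validate the statistical machinery and
the kinetic theory chain, not the force-field fidelity of any particular
simulator.

## Numerical choices and degenerate inputs

* Saddle detection works on integer sizes; the landscape-CMC threshold
  refines the discrete bisection with the continuous stationarity
  condition. Far above threshold the minimum exits the lattice below
  $n = 2$; the bracketing grid handles the reappearance.
* The zero mode is classified at $10^{-9}$ of the spectral radius;
  complex eigenvalue pairs (not observed at equilibrium, possible along
  strongly driven transients) are reported with real parts used for time
  scales.
* Fit windows are expressed in recorded frame times and never
  interpolated; a window must contain at least 10 frames.
* Jackknife subset fits that fail are excluded and counted
  (`n_failed`); only if all fail is an error raised.
* Clustering uses molecule-level single linkage through bead contacts
  with a cell list (cells at least one cutoff wide, 27-neighbourhood);
  the cutoff defaults to 1.0 reduced length units — the solvent-bead
  interaction range — and must stay below half the box edge for the
  minimum image to be unambiguous. Degenerate boxes (fewer than three
  cells per edge) fall back to the all-pairs path.

Test problem sizes were chosen to keep the full suite comfortably
interactive: the reference system at $n_{max} = 60$ integrates in
under a second; the statistical acceptance checks use 100 replicate
draws of 10 repeats for plateau-recovery coverage and 25 draw pairs for
the repeat-scaling trend.

## Limitations

* Monomer exchange only: no fusion/fission, no multi-monomer steps, so
  the slow-pathway structure is exact for the model, not for surfactants
  whose aggregates coalesce.
* The landscape model is nonionic; for charged surfactants it remains
  qualitatively adequate (the bimodal shape survives) but the
  charge-phase correction enters only at the CMC-conversion stage.
* The $h$(aspect-ratio) prescription is a scaling estimate anchored at
  the reference surfactant, not a first-principles map.
* Jackknife coverage is validated under the generator's iid frame noise;
  autocorrelated real trajectories will need the effective number of
  independent frames, not the raw count, to carry the same guarantees.
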