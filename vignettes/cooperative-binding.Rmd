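---
title: "Modeling cooperative ligand binding with coopbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cooperative ligand binding with coopbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopbind)
```

# The microscopic scheme and its assumptions

`coopbind` models the binding of a ligand L to a macromolecule M with
two binding sites as a four-state mass-action network: the empty state
M00, the two singly bound states (site 1 or site 2 occupied) and the
doubly bound state, with eight rate coefficients connecting adjacent
states. The model is phenomenological: cooperativity enters only as a
change of the association coefficients for the second binding step
(`k1(2)`, `k2(1)`), with no structural mechanism implied. Assumptions
worth keeping in mind:

* **Mass action in a well-mixed, closed volume.** Concentrations are
  deterministic; stochastic fluctuations (relevant at very low copy
  numbers) are out of scope.
* **Detailed balance.** The scheme is a closed cycle, so the two paths
  from M00 to the doubly bound state must give the same overall
  equilibrium constant. `rate_constants()` enforces this within a
  relative tolerance of 1e-6 and refuses other parameter sets unless
  `allow_cycle_violation = TRUE` (useful for exploring driven,
  non-equilibrium steady states — but then none of the closed-form
  equilibrium results apply).
* **Fixed totals.** Total macromolecule and total ligand are conserved;
  there is no ligand input or degradation.

Units are fixed package-wide: concentrations in uM, time in s,
association coefficients in uM^-1 s^-1, dissociation coefficients in
s^-1, free energies in kJ/mol.

# Parameters that matter

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `ko` (`ko1`, `ko2`) | uM^-1 | — | intrinsic association constant(s), `k_on/k_off` per site |
| `omega` | — | — | cooperativity factor; multiplies the intrinsic constant of the second step (1 = independent, >1 positive, <1 negative) |
| `off_rate` | s^-1 | 1 | common dissociation coefficient of the convenience constructors |
| `m_total` | uM | 1 | total macromolecule |
| `convergence_threshold` | — | 1e-5 | relative concentration change per recorded step (10^-3 %) below which the system counts as equilibrated |
| `temperature` | K | 298.15 | thermodynamic context for free energies |

The defaults encode the reference study conditions used throughout the
package's presets: `[M]o` fixed at 1 uM, all dissociation coefficients
at 1 s^-1, and association coefficients between 0.01 and 100
uM^-1 s^-1 — the range covered by most experimentally characterized
second-order biochemical reactions. With `off_rate = 1` the intrinsic
constants equal the association coefficients numerically, which keeps
the kinetic and thermodynamic parameterizations aligned.

The standard state for free energies is 1 uM, so a constant of
1 uM^-1 gives `dG_assoc = 0`. This is a convention, not physics; it is
chosen so numeric constants in the package's units enter the
logarithms directly. `interaction_free_energy()` is independent of the
standard state.

# Numerical design

**Integrator.** The rate equations are integrated with the classic
fixed-step 4th-order Runge–Kutta scheme in compiled code. The two
linear conservation laws are satisfied identically by the right-hand
sides, so RK4 preserves them to rounding error at every step — the test
suite asserts better than 1e-9 relative over whole runs. The default
step is `0.01 / (max association coefficient x max(L_total, M_total) +
max dissociation coefficient)`, i.e. one hundredth of the fastest
process time scale; halving it changes equilibrium concentrations by
less than 1e-6 relative. A negative-concentration excursion beyond
-1e-9 of the total concentration scale triggers an automatic retry with
a halved step (up to 8 halvings), then a hard error.

**Equilibrium detection.** States are recorded every ~2 % of the
slowest dissociation time scale (`1/min(k_off)`), and the run stops
when the relative change of every species per recorded step has stayed
below the threshold for 10 consecutive records. The trailing window
guards against declaring convergence on a slow transient; tying the
recording cadence to the slowest relaxation scale (rather than the
integration step) makes the criterion meaningful — per-integration-step
changes are tiny long before equilibrium. Runs that do not converge
within `max_time` (default 60 slow time constants) return
`converged = FALSE` and are refused by downstream isotherm assembly,
naming the offending ligand concentration. `detect_equilibrium()` with
`threshold = 0` errors: the criterion is a strict inequality.

**Ligand grids.** Logarithmic grids with 25 points per decade spanning
two decades below the dissociation constant of the strongest binding
step to two decades above that of the weakest step
(`default_ligand_grid()`). For negatively cooperative systems the weak
step's constant is `omega * Ko`, so the grid widens automatically —
sampling only around `1/Ko` would truncate the second transition and
make the plateau (hence the site number N) unknowable. The hidden-site
preset deliberately uses a linear grid ("regular steps" of 0.06 uM up
to 6 uM), emulating a typical titration design.

# Hill analysis: the choices behind `hill_analysis()`

The Hill coefficient is the extremal slope of the Wyman Hill plot
`y = ln(<n>/(N - <n>))` against `x = ln [L]`. Three ingredients are
genuinely open design choices and deserve justification.

**Site number N.** N is taken as the asymptotic binding density,
estimated blind from the data (never assumed known): if a rectangular
hyperbola describes the isotherm within 1 % RMS of its plateau, N is
the fitted asymptote — this is exactly what an experimenter reads off
an apparently simple saturation curve, and it is what makes the
hidden-site scenario come out as "one site" (N near 1.05). Otherwise
(sigmoid or biphasic isotherms, where a hyperbola misfits and its
asymptote is biased) N is the intercept of a linear regression of the
last five points on 1/L — the leading-order plateau approach of any
saturating binding curve. The estimate is continuous, not rounded.
Isotherms whose largest binding density is below 90 % of the estimated
plateau are rejected with an "extend the ligand range" error.

**Transition region.** The cubic is fitted to points with fractional
saturation between 0.25 and 0.75. A wider window (say 0.1–0.9) looks
attractive but measurably biases the estimator for negative
cooperativity: the transition then spans several decades, the slope
profile develops a deep central minimum, and a third-order polynomial
cannot follow it — the recovered minimum slope lands several percent
above the true value (and, e.g., fails to drop below 0.5 at
`omega = 0.1` although the exact slope there is 0.48). Restricted to
the central half of the transition, the cubic tracks the analytic
mid-saturation slope `2 / (1 + omega^-1/2)` to better than 2 % across
`omega` from 0.05 to 20 (asserted in the test suite), while leaving
enough points for stable fits on 25-points-per-decade grids. At least
5 transition points are required; fewer raise an error rather than a
silent extrapolation.

**Which extremum.** The fitted derivative is a parabola. When its
stationary point (vertex) lies inside the transition x-interval, that
is the extremal slope — the maximum for positive, the minimum for
negative cooperativity, resolved automatically by the sign of `a3`.
When the vertex falls outside the fitted range, the boundary value
deviating most from 1 is reported instead: extrapolating a cubic
beyond its data is meaningless. If the extremal slope equals 1 within
1e-6 the operator is reported as `"none"` and `n_H = 1` — the
tie-break for non-interacting sites.

One consequence is worth stating plainly: for the truncated
hidden-site isotherm the procedure returns an extremal slope slightly
below 1 (about 0.96), not exactly 1. That small deviation is real —
the truncated data are not exactly hyperbolic because the second site
already creeps in below 6 uM — and suppressing it would mean tuning
the estimator to a foregone conclusion.

# Equivalence and kinetic discrimination

For `omega <= 1` the mapping `Ko1, Ko2 = Ko (1 ± sqrt(1 - omega))`
produces a two-different-sites model with an identical binding
polynomial; `equivalent_cooperative()` inverts it. The arithmetic–
geometric mean inequality forces `omega <= 1` on the inverse mapping:
site heterogeneity can imitate negative cooperativity but never
positive, and for `omega > 1` the forward mapping has complex roots
and errors out.

`paired_timecourses()` simulates both members of a matched pair on
identical time grids and steps and returns `delta_n(t)`; the traces
vanish at both ends (identical equilibria) and peak at an interior,
concentration-dependent time. `fit_kinetics()` implements the
discrimination strategy: the macroscopic constants `K1`, `K2` from the
equilibrium stage are imposed exactly by reparameterization (they
eliminate two degrees of freedom; the free parameters are only the
dissociation coefficient scales), both models are fitted to the same
time courses, and AICc decides. A coarse log-grid scan over the free
parameters precedes the gradient refinement because the constrained
RSS surface can hold local minima. The infeasibility condition
`K1 < 4 K2` (no real two-site-class roots) errors out before any
optimization.

`classify_kinetics()` counts resolvable kinetic phases with the
extra-sum-of-squares F-test at `alpha = 0.01`, plus two practical
resolvability conditions: the minor phase must carry at least 2 % of
the total amplitude and the rates must differ by at least a factor 3.
On noiseless simulated traces the bare F-test would always prefer the
bi-exponential (the comparison degenerates to a ratio of rounding
errors), which is statistically correct and experimentally
meaningless; the amplitude and separation thresholds encode what a
stopped-flow experiment could actually distinguish.

# Synthetic data and what passing tests show

The generator produces exactly the study conditions of the presets:
deterministic isotherms and time courses from the four-state scheme,
plus optional additive, homoscedastic Gaussian noise on the binding
density (`add_noise()`, seeded and RNG-state-preserving). Defaults for
the recovery studies are `sigma = 0.02` on isotherms and `sigma = 0.01`
on time courses — a few percent of the dynamic range, typical of good
optical binding data.

Real experiments differ in ways the generator does not emulate:
heteroscedastic and correlated errors, baseline and amplitude
calibration uncertainty, instrument dead time in kinetics, ligand
depletion artifacts, and slow processes (aggregation, conformational
drift) outside the binding scheme. Passing recovery tests therefore
show that the estimators are consistent and well-conditioned under the
model's own assumptions — not that any particular experimental dataset
will be as kind.

Problem sizes in the test and acceptance runs are chosen for
single-CPU convenience: isotherms of 50–150 points, time courses of
30–60 observed times, 20 noise replicates per condition in recovery
checks and 50 in the model-selection power check. All are
package-level choices; every quantitative statement in this vignette
is asserted by the test suite or recomputed by `scripts/acceptance.R`.

# Known limitations

* Exactly two binding sites; no extension to N > 2, and no mechanistic
  (concerted/sequential) allostery models — the cooperativity factor is
  purely phenomenological.
* Fixed-step RK4 is robust here because the auto-step tracks the
  fastest process, but it is not a stiff solver; pathological rate
  ratios (beyond ~10^6) will be slow rather than wrong.
* The Hill-coefficient estimator inherits the cubic-fit bias discussed
  above; it stays below 2 % for `omega` in [0.05, 20] and grows slowly
  outside (about +3 % at `omega = 0.01`), always preserving
  monotonicity in `omega`.
* `fit_kinetics()` assumes all observed traces share `m_total` and the
  constraint constants; global fits across different macromolecule
  concentrations are not implemented.
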