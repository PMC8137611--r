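---
title: "Myelosuppression dynamics and crypt injury position: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myelosuppression dynamics and crypt injury position: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstox)
```

qstox implements two quantitative systems toxicology simulators for
oncology drug safety: a transit-compartment model of chemotherapy-induced
myelosuppression with a linear-stability toolkit, and an agent-based model
of the small intestinal crypt feeding a villus. This vignette documents
the models, their assumptions, the tunable parameters, and the numerical
and design choices behind the implementation.

## The myelosuppression model

The model tracks five states: a proliferating progenitor pool `prol`,
three maturation ("transit") compartments `transit_1..transit_3`, and the
circulating mature pool `circ`, all in units of $10^9$ cells/L. With a
common rate constant $k = (n+1)/\mathrm{MTT}$ ($n$ transit compartments,
mean transit time MTT):

$$
\begin{aligned}
\mathrm{Prol}' &= k\,\mathrm{Prol}\left(\frac{\mathrm{Circ}_0}{\mathrm{Circ}}\right)^{\gamma} - k\,\mathrm{Prol},\\
T_1' &= k(\mathrm{Prol} - T_1), \quad\ldots,\quad
\mathrm{Circ}' = k(T_n - \mathrm{Circ}).
\end{aligned}
$$

The feedback exponent $\gamma$ is the strength of the negative feedback
from circulating mature cells onto progenitor proliferation: when counts
fall below the baseline $\mathrm{Circ}_0$, proliferation is stimulated.
Because all first-order rates are equal, the unique positive equilibrium
has every compartment at $\mathrm{Circ}_0$.

**Parameters and defaults.** `circ0 = 5.05` ($10^9$ cells/L), `mtt = 125`
h, `gamma = 0.17`, `n_transit = 3` — the canonical human neutrophil
parametrization of this model family. All are overridable; the stability
results below depend only on `gamma` and `n_transit`.

**Treatment events.** Drug effect is an instantaneous fractional kill of
the proliferating pool only (`prol <- prol * (1 - f)`); there is no
pharmacokinetic driving function. Events at the same time compose through
their survival fractions, $1-(1-f_1)(1-f_2)$, which the schedule
constructor applies on ingestion.

**Integration.** lsoda (via deSolve) with `rtol = 1e-8`,
`atol = 1e-10`, stop-and-restart at each event time so the discontinuity
never passes through the step-size controller. Oscillation amplitudes near
the bifurcation are tolerance-sensitive, hence the tight defaults. Inside
the feedback term the circulating count is floored at $10^{-12}\cdot
\mathrm{Circ}_0$; any activation is counted and surfaced as a warning.
Output values at an event time are post-dose.

## Stability and the Hopf bifurcation

At the equilibrium the Jacobian is a bidiagonal $k$-chain whose
proliferating row has an exactly zero self-term and a single feedback
entry $-k\gamma$ from the circulating pool. In $\mu = \lambda/k$ the
characteristic relation is

$$\mu(\mu+1)^{n+1} = -\gamma,$$

parameter-free given $\gamma$ and $n$ — so the critical exponent is
independent of `circ0` and `mtt`. Setting $\mu = i\omega$ and matching the
phase gives $\omega = \tan\!\big(\pi/(2(n+1))\big)$ and

$$\gamma^* = \omega\,(1+\omega^2)^{(n+1)/2},$$

which for $n = 3$ evaluates to $0.568542\ldots$ `hopf_gamma()` locates the
same value by bracketed root-finding (`uniroot`) on the maximal eigenvalue
real part over $\gamma \in [10^{-3}, 10]$; the closed form is kept as an
analytic cross-check, and the test suite verifies agreement to $10^{-6}$
for chains of length 1–8.

Classification (`classify_stability`) follows the dominant pair: negative
real part with a real dominant eigenvalue is non-oscillatory asymptotic
stability; a complex dominant pair gives damped oscillations; positive real
part gives sustained or growing oscillations. A marginality tolerance of
$10^{-9}$ per hour separates the measure-zero exact-Hopf case from
numerics. Two degeneracies worth knowing:

- At $\gamma = 0$ the proliferating pool decouples and the spectrum is
  $\{0, -k\,(\times\, n+1)\}$; the zero eigenvalue is reported with an
  explicit `degenerate` flag rather than silently classified stable.
- The maximal real part is *not* monotone over all of $[0, 1]$: below the
  real-root collision (near $\gamma \approx 0.09$ for $n = 3$) the
  dominant eigenvalue is the real branch $\approx -k\gamma$, which
  decreases; the familiar strict increase towards the crossing holds on
  the complex-dominant (oscillatory) branch. `hopf_gamma`'s bracket works
  because the sign change lies inside that monotone region.

## Recovery: two notions, deliberately

After a 95% kill, trajectories with $\gamma$ well below $\gamma^*$ dip to
a nadir and rebound with an overshoot (for $\gamma = 0.3$ the rebound
peaks near 2.6× baseline) before damped oscillations die out.
`recovery_summary()` therefore reports both:

- `first_return_time` — first time at or after the nadir at which the
  circulating count re-enters the band
  $\mathrm{Circ}_0(1 \pm \text{tol})$. This is the clinical reading of
  neutropenia recovery: the count is back at baseline, and a later
  rebound above baseline does not count against it. With tol = 0.02,
  single 95% kills give 506 h ($\gamma=0.17$) and 364 h ($\gamma=0.3$) —
  under a month — versus a settling that takes months for $\gamma=0.5$.
- `settling_time` — first time after the last dose from which the count
  permanently remains in the band: return to the constant basal value.
  Under damped oscillations this exceeds the first return by the decay
  time of the dominant mode, $\sim |\mathrm{Re}\,\lambda_1|^{-1}$, and
  for $\gamma = 0.5$ runs to several thousand hours.

Collapsing these into one number misrepresents one regime or the other;
both are computed and the package's reports state which is which.

CTCAE neutropenia grading uses the standard concentration bands (grade 1
< 1.5, 2 < 1.0, 3 < 0.5, 4 < 0.25, in $10^9$ cells/L), configurable, with
values exactly at a threshold assigned the more severe grade. Under the
defaults a single 95% kill reaches a nadir of 0.54, i.e. grade 2; grade 3
is reached only when the nadir falls below 0.5 (e.g. shorter transit
times).

## The crypt–villus agent-based model

The crypt is a cylindrical lattice, 16 columns × 30 positions (~480
cells, the order of a mouse crypt). Position (0-based, from the base)
determines fate: stem cells at positions 0–4 (24 h cycle), the
transit-amplifying (TA) compartment of rapidly cycling progenitors at
positions 5–20 (21.5 h mean cycle, ±20% uniform jitter per division),
differentiated cells above. The villus is a well-mixed cell-count
compartment: spatial villus structure is not needed for any output the
package reports.

**Rules per time step (dt = 0.5 h, a tenth of the shortest cycle):**

1. Cycling cells whose clock elapses divide, in seeded-random order to
   break ties. The daughter is inserted at the mother's site; the column
   above is pushed up one row; the cell leaving the top row transfers to
   the villus. Both mother and daughter draw fresh cycle clocks.
2. Fate follows position after each push: stem cells entering the TA band
   become proliferative; cycling cells pushed above it differentiate.
3. Arrested cells (see injuries) age; on reaching the senescence lifetime
   (72 h, comparable to the absorptive epithelial lifetime) they are
   removed, the column above collapsing down into the vacancy and an
   empty site remaining at the column top until subsequent pushes refill
   it (evicting an empty site transfers nothing to the villus).
4. The villus sheds at a constant rate, floored at zero.

Full occupancy therefore holds exactly as long as no arrested cell reaches
senescence inside the crypt — which is the case in all default scenarios,
where arrested cells are pushed out onto the villus first; the time series
record occupancy so any violation is visible.

**Burn-in and calibration.** `init_crypt` draws initial clocks uniformly
over each cell's cycle time and runs a 48 h burn-in during which the
crypt-to-villus influx is measured (≈15 cells/h under defaults: every
division evicts exactly one top cell). The shedding rate, unless supplied,
is set to that influx, so the villus (3,500 cells initially, the order of
a mouse villus) is in balance; a 240 h homeostasis run stays within a few
percent. Cell transfers minus shed cells equals the villus change exactly,
every run — the bookkeeping is tested to float precision.

**Injuries.** `injury_spec(arrest_fraction, band, time)` arrests each
proliferative cell in the positional band independently with the given
probability (Bernoulli; an exact-fraction variant is available via
`exact = TRUE` since "approximately 85%" is ambiguous between the two).
Arrest is irreversible: arrested cells never divide, never revert, keep
their sites, and are pushed upward like any cell until shed or senescent.
The standard scenarios arrest 85% in the lower (5–12) or upper (13–20)
half of the TA band; the halving of the band is a package choice, the
band boundaries not being fixed by anything sharper than "low" and "high".

**Scenario clock.** Recorded series start at 0 h after burn-in; the
injury defaults to t = 24 h so that every series carries a measured
pre-injury reference window. Recovery times are reported in hours since
the injury: the first time the TA proliferative count is back within 10%
of its pre-injury mean and stays there for 12 h.

**What the generator emulates — and what it does not.** The lattice
captures proliferation-driven upward migration, positional fate, and the
division-rate dependence of migration speed: cells above more dividing
neighbours move faster, which is exactly why a low-positioned arrest
(fewer unaffected dividers below the lesion) clears more slowly than a
high-positioned one, and dents the villus influx for longer. Under the
defaults, ten replicates give mean TA recovery ≈44 h (low band) versus
≈14 h (high band), and villus nadirs of ≈96% versus ≈99% of the
pre-injury mean. The column-push rule is, however, a deterministic
simplification of off-lattice mechanics: it transmits every division
instantly up the whole column, with no mechanical relaxation, crowding
resistance, or downward motion. Absolute recovery times and villus dips
therefore carry model error of order tens of percent, and the robust
outputs are the orderings and timescales (low slower than high, days not
weeks, crypt cellularity untouched), not exact counts. In particular, the
~44 h low-band mean sits at, not above, the two-day mark, and the villus
dip under a 3,500-cell villus with ~15 cells/h turnover cannot reach 10%
for any recovery shorter than the senescence window — a structural
consequence of the villus size and calibrated shed rate, worth keeping in
mind when comparing against spatially resolved models.

## Scenario bundles and noise

`hematology_scenarios()` emits the six standard treatment bundles
($\gamma \in \{0.17, 0.3, 0.5\}$ × {single 95% kill at t = 0, 95% kill
every 21 days × 6 cycles}); horizons are 2,160 h for single doses
(4,320 h for $\gamma = 0.5$, whose settling takes months) and six cycles
for the repeated schedules. The cycle count is a package default — any
fixed number ≥ 3 shows the same qualitative split. `crypt_scenarios()`
emits the two positional-injury bundles with 10 seeds each.
`noisy_observations()` overlays unit-mean multiplicative lognormal noise
(counts are positive and right-skewed) for robustness exercises; nothing
downstream depends on it.

All bundles serialize to JSON/YAML config, schedule, and injury files and
reload to equal bundles, so every reported analysis can be driven from
files alone (see the CLI script under `inst/cli/`).

## Problem sizes and determinism

The test suite and the acceptance script run the ODE scenarios on 1 h
output grids over horizons of 2,160–10,000 h, and the agent-based model
at 16 × 30 × 264 h with 10 seeds per injury band — sizes chosen so the
full analysis reruns in well under a minute per scenario set on a single
core while keeping binomial seed-to-seed spread in the recovery means
near ±1 h. Every stochastic path is seeded: crypt runs are bitwise
reproducible from `config$seed`, and replicate seeds are carried in the
scenario bundles.

## Known limitations

- No pharmacokinetics: kills are instantaneous fractions, so schedule
  effects enter only through event times.
- No parameter estimation; the package simulates and analyses, it does
  not fit.
- Single lineage; no platelet/erythrocyte chains or cytokine-mechanistic
  feedback variants.
- The crypt model excludes crypt fission/extinction, dedifferentiation,
  molecular signalling, and off-lattice mechanics; the villus is a count,
  not a tissue.
- Limit cycles beyond the bifurcation are not continued; the toolkit
  stops at locating and classifying the crossing.
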