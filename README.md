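# qstox

Quantitative systems toxicology simulators for two classic adverse-effect
domains of oncology therapy: chemotherapy-induced **myelosuppression** and
**gastrointestinal epithelial injury**. The package is aimed at
pharmacometricians and systems modellers who need reproducible, tested
engines for dose-schedule toxicity simulation and for reasoning about
model qualitative behaviour, rather than one-off scripts.

## What it implements

**1. Transit-compartment myelosuppression model.** Five states — a
proliferating progenitor pool, three maturation compartments, circulating
neutrophils — with a common rate constant $k = (n+1)/\mathrm{MTT}$ and a
feedback term $(\mathrm{Circ}_0/\mathrm{Circ})^\gamma$ stimulating
proliferation when circulating counts fall:

$$
\mathrm{Prol}' = k\,\mathrm{Prol}\left[\left(\tfrac{\mathrm{Circ}_0}{\mathrm{Circ}}\right)^{\gamma} - 1\right],
\qquad T_1' = k(\mathrm{Prol}-T_1),\;\ldots,\;
\mathrm{Circ}' = k(T_n - \mathrm{Circ}).
$$

Treatments are instantaneous fractional kills of the proliferating pool
(e.g. 95% kill at t = 0, or repeated every 21 days). The package
simulates trajectories (deSolve/lsoda, stop-and-restart at dose events),
grades the circulating count on the CTCAE neutropenia bands, and — the
analytical core — linearizes the model, classifies equilibrium stability
from the Jacobian spectrum, and locates the Hopf bifurcation in the
feedback exponent. For $n$ transit compartments the critical exponent has
the closed form $\gamma^* = \omega(1+\omega^2)^{(n+1)/2}$ with
$\omega = \tan(\pi/(2(n+1)))$; for $n = 3$ this is 0.5685, independent of
baseline and transit time. Below $\gamma^*$ blood counts recover after a
drug insult (with damped oscillations as $\gamma$ grows); above it they
oscillate indefinitely — behaviour not representative of reversible
cytopenia, hence worth detecting before using a fitted $\gamma$.

**2. Agent-based crypt–villus model.** A cylindrical lattice crypt
(16 × 30 sites) with stem cells at base positions 0–4, a
transit-amplifying (TA) compartment at positions 5–20, and differentiated
cells above, feeding a well-mixed villus compartment. Divisions insert a
daughter at the mother's site and push the column up; the cell leaving
the crypt top joins the villus, which sheds at a rate calibrated to the
homeostatic influx. Positional cycle-arrest injuries (e.g. irreversible
arrest of 85% of proliferative cells in the lower vs upper half of the TA
band) let you quantify how injury *position* — not size — determines TA
recovery time and villus integrity: arrests low in the crypt sit above
fewer unaffected dividers, clear more slowly, and dent the villus influx
for longer.

See `vignettes/qst-toxicology-models.Rmd` for the full model and methods
account.

## Worked example

```r
library(qstox)

p <- friberg_params(gamma = 0.5)        # circ0 5.05, mtt 125 h, 3 transit
classify_stability(p)
#> Linear stability of the homeostatic equilibrium
#>   classification : asymptotically stable (damped oscillations)
#>   max Re(lambda) : -0.000525287 per h
#>   dominant freq  : 0.0126565 per h
#>   gamma*         : 0.568542

tr <- simulate_friberg(p, treatment_schedule(0, 0.95), horizon = 4320)
str(recovery_summary(tr))
#> List of 6
#>  $ nadir            : num 0.904
#>  $ nadir_time       : num 214
#>  $ nadir_grade      : int 2
#>  $ first_return_time: num 289
#>  $ settling_time    : num 4316
#>  $ settled          : logi TRUE
```

γ = 0.5 sits below the critical 0.5685, so the equilibrium is stable but
the dominant eigenvalue pair is complex: after a 95% progenitor kill the
neutrophil count dips to 0.90 × 10⁹ cells/L (grade 2 neutropenia) at
214 h, is first back at baseline by 289 h, but keeps overshooting in
damped cycles and only settles permanently into the ±2% band around
baseline after ~4,300 h — months, not weeks. Rerun with `gamma = 0.17`
and the same insult settles in ~1,300 h with first return at ~500 h.

```r
cfg <- crypt_config(seed = 101)
ser <- run_crypt_scenario(cfg, injury_spec(0.85, c(5, 12)), horizon = 264)
ser
#> Crypt-villus time series: 265 points over [0, 264] h
#>   injury: 85% arrest at positions 5-12, t = 24 h
#>   crypt cells: 480-480; villus: 3384-3539; TA proliferative: 150-256
crypt_recovery_time(ser)   # hours since injury: 38
villus_nadir(ser)$nadir_fraction  # 0.962
```

The low-band arrest drops the TA proliferative count from 256 to 150;
the crypt stays at exactly 480 cells throughout (arrested cells are
replaced by pushing before any senescence removal), the TA compartment
needs 38 h to return within 10% of its pre-injury level, and the villus
dips to 96% of its pre-injury mean. The same injury at positions 13–20
recovers in ~14 h with the villus essentially untouched — the package's
headline position effect, summarized over seeds by `run_crypt_report()`.

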