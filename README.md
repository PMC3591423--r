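# platekin

Steady-state survival-curve models for cell populations with two competing
fates: **senescent death** at the end of an intrinsically programmed,
distributed natural lifespan, and **random loss** — consumption in clots,
destruction, any age-independent removal — at a constant rate. The package
was built for in-vivo pulse-label platelet kinetics (where the balance of
these two fates quantifies the fixed hemostatic requirement for platelets),
but applies to any renewing population with both fates.

## The models

Let `L` be the natural-lifespan distribution and `r` the random-loss rate
constant (hr⁻¹). A cell survives to age `a` with probability

```
P(a) = exp(-r a) · Pr(L > a)
```

At steady state the circulating age density is proportional to `P(a)`, and a
label applied to all circulating cells at time 0 decays as the population
survival curve

```
D(t) = ∫ₜ^∞ P(u) du / ∫₀^∞ P(u) du
```

The random loss fraction — the proportion of cells removed by the
age-independent route before their lifespan expires — is
`f = 1 − E[exp(-r L)]`, the count obeys `N = S·f/r` with production rate
`S`, and the absolute loss rate `R = r·N` (per day: `24 r N`) satisfies the
budget identity `f = R/S`.

Three nested lifespan laws are provided:

| model | natural lifespan | random loss | parameters |
|---|---|---|---|
| LS | lognormal(m, s) | none | m, s |
| Dornhorst | fixed at `T` | rate `r` | T, r |
| DLS | lognormal(m, s) | rate `r` | m, s, r |

plus labelling-efficiency parameters (`e1`, and `e2`/`b_half` for
double-label "cohort" curves, predicted by solving the age-structured
transport equation along characteristics). Fitting is multi-start bounded
least squares against every replicate point; confidence intervals come from
Monte Carlo refitting of noise-perturbed curves; nested models are compared
with an F-test. An individual-based stochastic simulator provides an
independent validation route, and a simulation-study driver reproduces the
relationship between experimental noise and how well `f` can be
constrained. The methods vignette (`vignettes/platelet-kinetics.Rmd`)
documents the model, the numerics and the design choices.

## Worked example

Simulate a wild-type-like study (lognormal lifespan with mean 100 hr, s.d.
25 hr, random loss fraction 0.3, label efficiency 0.9, 6 replicate curves,
0.3% s.e.m. noise), fit the DLS model, and bootstrap confidence intervals:

```r
library(platekin)

law   <- lognormal_from_moments(100, 25)
truth <- lifespan_model(law, r = r_from_f(law, 0.3))
lab   <- labeling_config(e1 = 0.9)
ds    <- generate_dataset(truth, lab, sem_percent = 0.3, n_replicates = 6,
                          platelet_count = 1183, count_sem = 70, seed = 42)

fit <- fit_survival(ds, "DLS", starts_patience = 10, seed = 1)
ens <- monte_carlo(fit, ds, n_iterations = 200, seed = 2)
report(fit, ensemble = ens)
compare_fits(fit$nested$LS, fit)
```

```
DLS model [synthetic]  (78 points, 4 parameters, df = 74, ssr = 46)
  m       4.6 [4.55,4.63]
  s       0.226 [0.192,0.251]
  r       0.00421 [0.00295,0.0056]
  e1      0.904 [0.897,0.909]
  mu      102 [98.1,105]
  sigma   23.2 [20.2,25.7]
  f       0.345 [0.251,0.437]
  S       14.4 [13.9,15]
  R       120 [83.8,159]
Nested-model F-test
  ssr_null = 62.18 (df 75), ssr_alt = 46 (df 74)
  F(1, 74) = 26.03, p = 2.5e-06
```

Each parameter row is `best fit [2.5%, 97.5%]` from the Monte Carlo
ensemble. The generating values (mean lifespan 100 hr, s.d. 25 hr,
`f = 0.3`, `e1 = 0.9`) all fall inside their intervals; note how wide the
interval on `f` is even at this noise level — the central identifiability
finding the simulation tools explore. The F-test row says the random-loss
parameter earns its place against the nested LS fit on this dataset.

A thin command-line interface over the same functions ships in
`inst/cli/platekin.R` (subcommands `fit`, `mc`, `ftest`, `simulate`,
`study`, `oracle`; run it with `Rscript`).

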