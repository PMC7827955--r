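---
title: "Time-independent drug-efficacy estimation from growth curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-independent drug-efficacy estimation from growth curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemofit)
```

## The problem

The IC50 reported from an endpoint viability assay (MTT and relatives) is
not a property of the drug alone: it depends on when the plate is read.
Cells keep dividing during the assay, so the same drug looks more potent
on day 8 than on day 2 simply because untreated wells have pulled further
ahead. `chemofit` implements the alternative: fit a growth model in which
the drug acts on the *rate* of proliferation, so the fitted potency
parameters do not depend on the measurement day, and then demonstrate the
drift of the naive endpoint IC50 by forward-simulating the viability assay
from the fitted model.

## The model

Untreated cells follow logistic growth,

$$\frac{dN}{dt} = \lambda N \left(1 - \frac{N}{K}\right),$$

with growth rate $\lambda$ (day$^{-1}$), carrying capacity $K$
(cells/well) and initial count $N_0$ (the plating density). A drug at
concentration $D$ (µg/mL) reduces the growth rate by the efficacy
$\varepsilon$ of an Emax model,

$$\varepsilon(D) = \frac{E_{\max} D}{D + IC_{50}}, \qquad
  r(D) = \lambda\,(1 - \varepsilon(D)),$$

so $E_{\max}$ is the maximum fractional rate reduction and $IC_{50}$ the
concentration at half of it. Because $r$ is constant in time the ODE has
the closed form

$$N(t) = \frac{N_0 K}{N_0 + (K - N_0)\,e^{-r t}},$$

which the package evaluates directly (the decaying-exponential form never
overflows; a numeric integrator appears only as an independent oracle in
the test suite). $E_{\max} > 1$ gives $r < 0$: net cell death, which
complete growth suppression at the top dose can require. The fit bound
`Emax_upper` defaults to 2 and can be set to 1 to forbid that regime —
whether published fits constrained $E_{\max} \le 1$ is generally not
stated, so the bound is configuration, not hard-coded.

## Two-step fitting

1. **Control step** — dose-0 wells only; minimise the sum of squared
   residuals (SSR) over $(\lambda, K)$, every replicate well entering
   individually. $N_0$ is normally the known plating density; it can be
   freed (`estimate_N0 = TRUE`) because counting starts only on day 2.
2. **Treated step** — all dose $> 0$ curves *jointly*: one
   $(E_{\max}, IC_{50})$ pair minimises the pooled SSR across every
   treated record, with $(\lambda, K, N_0)$ held fixed at the control
   estimates. Never per-dose fits — the Emax model is the thing being
   estimated, and a single dose cannot identify both parameters (the fit
   records an identifiability warning if you try).

Optimisation is Nelder–Mead (`stats::optim`) on transformed coordinates —
$\log\lambda$, $\log K$, $\log IC_{50}$ and
$\mathrm{logit}(E_{\max}/E_{\max}^{\mathrm{upper}})$ — so positivity and
the bound hold by construction rather than by penalties. Settings:
relative function tolerance $10^{-8}$, at most 5000 iterations, and up to
3 restarts from the incumbent optimum; restarting rebuilds the simplex,
which is the practical guard against premature simplex collapse
(`stats::optim` exposes neither a parameter tolerance nor the initial
simplex, so restarts stand in for both). Starting points: $\lambda$ from
a log-linear regression of the early control counts, $K$ at 1.5× the
maximum observed count, $E_{\max} = 0.5$, $IC_{50}$ at the geometric mean
of the tested doses. On noise-free data this recovers all four parameters
to ~machine precision, comfortably inside the 0.1% the tests demand.

Degenerate inputs: all-zero control counts are an error; counts constant
at the plating density are treated as a saturated well ($K$ = the
constant, $\lambda$ flagged unidentifiable rather than invented).

## Bootstrap confidence intervals

`bootstrap_ci()` refits on resampled datasets (1000 replicates by
default) and reports percentile 2.5/97.5 intervals. Two design choices
matter, and both were made on measured coverage rather than taste:

* **Resample the whole two-step procedure.** Bootstrapping only the
  treated step, conditional on the point $(\hat\lambda, \hat K)$, ignores
  control uncertainty that propagates into $E_{\max}$; in simulation at
  the package's stated world (σ = 0.1, 3 replicates) that scheme covered
  the true $E_{\max}$ in only ~65% of nominal 95% intervals. Passing a
  `fit_two_step()` result to `bootstrap_ci()` repeats both steps per
  replicate and is the intended usage.
* **Pairs (case) resampling of wells, not within-cell resampling.** The
  obvious stratified scheme — resample the 3 replicate wells within each
  (dose, day) cell — shrinks each cell's plug-in variance by
  $(n-1)/n = 2/3$ and measured 84.5% coverage. The standard global pairs
  bootstrap of wells measured 92% on the same simulated datasets and is
  the default; `boot_scheme = "stratified"` and `"residual"` (the
  fallback when a design has no true replicates) remain available.

Identical seeds give bit-identical bootstrap sample matrices; all
randomness flows from the one seed argument.

## Simulated MTT assays and the apparent IC50

`simulate_mtt()` defines viability as the treated/control count ratio at
the measurement day — i.e. it assumes formazan absorbance is proportional
to viable cell number, which any model-to-MTT comparison implicitly does.
`apparent_ic50()` reads off the 50% crossing by linear interpolation on
log10 dose between the bracketing doses (assumption-free and exactly
testable against bisection on the closed form); a four-parameter logistic
fit is available as `method = "ll4"`. Non-monotone series are pre-smoothed
by decreasing isotonic regression and tagged; series that never reach 50%
return "not reached" rather than a number; a crossing below the lowest
tested dose returns that dose tagged `left-censored`.

**Where the downward trend holds — and where it genuinely does not.** In
the pre-saturation window (control still in near-exponential growth) the
apparent IC50 falls with measurement day: the minimum viability at fixed
dose is roughly $e^{-\lambda \varepsilon(D) t}$, so later readouts need
less drug to cross 50%. The package's property tests assert this over
days 2–8 with $K/N_0 = 200$. But the trend is *not* a theorem of the
model: once the control approaches $K$, mildly suppressed wells catch up
(both trajectories tend to $K$ for $r > 0$), viability ratios recover,
and the apparent IC50 ticks back up — at $K/N_0 = 20$ this reversal is
visible between days 6 and 8, and a dedicated test documents it. For the
same reason the apparent IC50 has a long-run limit only in the net-death
regime ($E_{\max} > 1$, limit dose $IC_{50}/(E_{\max}-1)$); for
$E_{\max} \le 1$ every dose eventually reads "not reached". A day-2
readout can also be genuinely undefined: if
$\lambda E_{\max} t < \ln 2$ no concentration halves relative growth by
day $t$. The tests and the comparison sweep stay inside the regime where
the quantity exists, and the model-level $(E_{\max}, IC_{50})$ — the
package's point — do not care.

## Synthetic data: the stated world

The generators emulate two designs: a 14-day count time course
(1000 cells/well plated, counted every other day from day 2, doses
$\{0, 5\cdot10^{-5}, 5\cdot10^{-4}, 5\cdot10^{-3}, 5\cdot10^{-2}\}$
µg/mL, 3 replicate wells per (dose, day)) and an MTT plate
(5000 cells/well, nine-point twofold dilution series 0.00625–1.6 µg/mL —
the twofold structure is inferred from the printed endpoints,
$0.00625 \cdot 2^8 = 1.6$ — read on days 2, 4, 6, 8). The default truth
used by the CLI and the acceptance world is $\lambda = 0.5$/day,
$K = 10^5$ cells/well, $E_{\max} = 0.9$, $IC_{50} = 0.002$ µg/mL: a
fast-growing adherent line in a 12-well tray whose top tested dose nearly
suppresses growth. These were chosen once as realistic and are not tuned.

Default noise is multiplicative lognormal with σ = 0.1 — proportional
error matching hemocytometer counting — with counts rounded to integers
and floored at 0 *only when noise is applied*, so σ = 0 output lies
exactly on the model trajectories for recovery tests. Additive-Gaussian
and Poisson-count models are available. What the generator does **not**
emulate: the day-10/12 growth decline from overcrowding and waste
build-up (the logistic has no death phase; `max_day` exists to truncate
real data instead), systematic inter-day counting drift, plate-position
effects, or multi-cell-line heterogeneity. A green recovery test
therefore establishes correctness of the estimation machinery under the
assumed error model, not robustness to everything a real plate can do.

## Numerical choices

* Closed-form logistic throughout; $N_0 = K$ short-circuits to $K$ (fixed
  point), and overflowing $e^{-rt}$ harmlessly underflows the ratio to 0.
* SSR is order-invariant and treats every replicate individually.
* Boundary handling: an $E_{\max}$ estimate at ≥ 99.9% of its bound, or an
  $IC_{50}$ more than three decades outside the tested dose range, sets a
  flag on the result instead of erroring.
* More than 20% failed bootstrap refits flags the intervals unreliable; a
  percentile interval that misses the point estimate is also flagged.

## Limitations

Single shared $(E_{\max}, IC_{50})$ per formulation (no per-dose or
mixed-effects structure); no Gompertz/exponential model selection; no
profile-likelihood intervals; the MTT simulation ignores formazan
chemistry and absorbance calibration; CTCF is a scalar formula on
pre-measured image statistics, not an image pipeline.
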