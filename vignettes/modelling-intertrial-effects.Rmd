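---
title: "Modelling inter-trial effects in pop-out search: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling inter-trial effects in pop-out search: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intertrial)
```

## The scientific problem

In visual singleton ("pop-out") search, responses are faster when
response-relevant properties of the display repeat across consecutive
trials: repeating the required response (target present vs. absent, or the
response-mapped dimension) speeds responding, and repeating the
target-defining dimension (color vs. orientation) speeds it further even
when the response does not change. Two mechanistic explanations compete:
the observer's *decision bias* may track recent stimulus statistics
(shifting the starting point of an evidence-accumulation process toward
the more probable response), or repeated stimuli may be *processed more
efficiently* (raising the rate of evidence accumulation). These produce
different RT distributions, so fitting accumulator models to full
distributions — not just mean RTs — can tell them apart.

The package implements a factorial model space crossing four factors:

1. **Accumulator**: LATER or DDM.
2. **Non-decision time**: absent (fixed 0) or a free parameter `t_er`.
3. **RDF-based updating** (response-defining feature: presence/absence in
   the detection tasks, dimension in the discrimination task): six levels.
4. **TDD-based updating** (target-defining dimension): the same six levels.

The full product is 2 x 2 x 6 x 6 = 144 models; the comparison space used
by default drops the full-memory starting-point level on the dimension
factor, whose fits are prone to parameter degeneration (one hyperprior per
dimension, each receiving very asymmetric evidence), leaving 120. Each
model is fitted per participant by maximum likelihood and models are
ranked by mean relative AIC across participants.

## Accumulators

**LATER.** Evidence rises linearly from a starting point to a single
boundary at distance `D` (evidence units); the rate is constant within a
trial and varies across trials as `R ~ Normal(mu, sigma)`. The RT is
`t_er + D_eff / R`, giving a "recinormal" density

```
f(t) = D_eff / (t - t_er)^2 * phi((D_eff/(t - t_er) - kappa*mu) / sigma) / sigma
         / Phi(kappa*mu / sigma)
```

where the division by `Phi(kappa*mu/sigma)` renormalizes after truncating
the rate to positive values — negative rates would never reach the
boundary, and for the mu/sigma ratios seen in fits (around 5) the
truncated mass is below 1e-6, so this choice is numerically safe and
yields a proper density (verified by quadrature in the tests).

**DDM.** A Wiener diffusion with boundary separation `a`, diffusion scale
`s` and drift `v` between two absorbing boundaries; the likelihood of a
correct response at time `t` is the *defective* first-passage density at
the correct (upper) boundary — its integral is the probability of a
correct response, not 1. Error trials are excluded from the likelihood
(below), so no error-boundary term is evaluated; using the defective
(rather than correctness-conditioned) density means fast error-prone
parameter regions are penalized through the missing correct-response
mass. The diffusion scale is a free parameter per stimulus class because
starting-point updating (log prior odds, below) fixes the evidence scale,
making `s` non-arbitrary.

The density is computed by the standard pair of series expansions for the
Wiener first-passage time (small-time and large-time), selecting per
evaluation whichever needs fewer terms at truncation tolerance 1e-7, with
the upper-boundary density obtained from the lower-boundary series by
reflection (`z -> a - z`, `v -> -v`). The implementation is cross-checked
in the test suite against two independent routes: the closed-form
absorption probability `(1 - exp(-2vz/s^2)) / (1 - exp(-2va/s^2))` and
Euler–Maruyama path simulation at `dt = 1e-4`.

**History modulations.** Both accumulators accept a per-trial
starting-point offset `s0` (the log prior odds of the trial's correct
response class) and a rate scaling `kappa`:

* LATER: `D_eff = max(D - s0, 1e-3)`; `mu_eff = kappa * mu`.
* DDM: start `z = clamp(a/2 + s0, 1e-3, a - 1e-3)`; `v_eff = kappa * v`.

`kappa` multiplies the mean rate/drift only, not the spread (`sigma`,
`s`): the updating rules are described as scaling *the rate*, and scaling
the spread as well would change the RT distribution's shape in ways none
of the rules motivates. The clamps (1e-3 evidence units) keep likelihoods
finite when the optimizer visits extreme prior odds.

## Updating rules

Each scope (RDF, TDD) carries one of six levels. Per trial the order is:

1. **Forgetting** (starting-point levels): the hyperprior is mixed with
   its initial distribution, `w <- alpha*w + (1-alpha)*w0` — the
   predictive prior for the upcoming trial.
2. **Read**: `s0` = sum of log-prior-odds contributions of the active
   starting-point rules; `kappa` = product of the active rate scalings.
3. **Update**: Bayes step / rate step with the trial's *true* stimulus
   values (never the response, and error or outlier trials update too).

The starting-point levels learn a Bernoulli rate `p` through a hyperprior
represented on a uniform grid of 401 midpoints on (0, 1). The Beta family
is not closed under the forgetting mixture, so discretization is the
natural representation; 401 points reproduce the conjugate Beta closed
forms (available when `alpha = 1`) to well below the 1e-3 oracle
tolerance while keeping per-trial updates cheap. For RDF updating a
single prior over `P(u1)` is learned; for TDD updating a separate prior
is learned per dimension, contributing `log(p_d/(1-p_d))` on
target-present trials in dimension `d` and 0 on target-absent trials
(the display contains no dimension to bias toward).

The rate levels follow repeat/switch logic:

* **Binary**: scaling `kappa0` (constrained to (0,1)) on switch trials, 1
  on repeats; under TDD scope it applies only when the *immediately*
  preceding trial was target-present with the other dimension — an
  intervening absent trial resets the comparison.
* **Decay**: one factor `kappa` (start 1) scales each applicable trial;
  after the trial it moves by `+delta` (repeat) or `-delta` (switch) and
  relaxes toward 1 via `kappa <- alpha*kappa + (1-alpha)`. The update
  from trial *n*'s transition therefore reaches the rate from trial
  *n + 1* on: that indexing is what the level's defining recursion
  states, and it is the only convention under which `alpha = 0` collapses
  the level onto no-updating — an equivalence the test suite asserts
  trial-by-trial. Under TDD scope, absent trials receive no `delta` step
  and no scaling, but the forgetting step still runs, and the
  repeat/switch comparison spans absent gaps (the most recent dimension
  seen).
* **Weighted**: one factor per dimension with `kappa1 + kappa2 = 2`
  invariant under both the transfer (`+delta`/`-delta`) and forgetting
  steps — a shared, conserved weight resource. The trial is scaled by its
  own dimension's current factor (the update applying afterwards, so the
  level starts from scaling 1 as its recursion specifies).

When both scopes carry rate rules their scalings compose
multiplicatively — the natural composition for gain factors; the data
sets that would distinguish multiplicative from additive composition
(both scopes winning rate rules at once) do not arise in this design
family.

First trials have no predecessor: binary/decay skip their `delta` step
there (scaling 1), and updating runs continuously across block and
section boundaries within a participant (feedback screens are not
modelled; the descriptive summaries, by contrast, do not label pairs
across block boundaries, since the design interposes feedback displays
there and Exp 1 alternates dimensions between blocks).

## Fitting

Likelihood: the updating rules run over **all** trials; the likelihood
sums log densities only over included trials. Exclusions: error trials;
RT > 2 s; RT more than 1.5 interquartile ranges *below* the mean. The
mean and IQR are computed per participant over correct trials within the
2-s cap — computing them over all correct trials would let a single very
slow trial drag the mean upward and sweep the entire fast mode out in
small samples. A separate descriptive mask (inverse RT more than 3 SDs
from the mean) serves the mean-RT summaries; both masks never affect what
the updating rules see.

The search is nested: the **outer** optimization covers `t_er` (when
present) and the updating parameters; for each outer candidate the
per-trial modulations are fixed, so the likelihood factorizes over
stimulus classes (absent / color / orientation; 2 classes in the
discrimination experiment) and the **inner** optimization fits each
class's accumulator triplet separately. Both loops use `stats::nlminb`
(bounded local search with numerical gradients; relative tolerances 1e-6
inner, 1e-4 outer), with the outer loop multi-started (default 5 starts:
one deterministic mid-range start plus seeded random draws within
bounds) and the inner loop warm-started from the previous candidate's
solution. Inner starting values come from moment heuristics
(`mu ~ mean(1/(rt - t_er))` at `D = 1`). Bounds: `D, a` in [0.1, 10];
`mu, v` in [0.1, 60]; `sigma, s` in [0.01, 30]; `alpha` in [0, 1];
`beta0` in [0.05, 100]; `delta` in [0, 0.5]; `kappa0` in (0, 1); `t_er`
in [0, 0.95 x min included RT].

One identifiability note: without starting-point updating the LATER
likelihood is invariant under a common rescaling of `(D, mu, sigma)`
(`T = D/R`), so only ratios such as `D/mu` (the median decision time) are
identified; any starting-point level pins the scale through the log-odds
offset. The DDM's free diffusion scale has the same character.

Model comparison uses AIC (`2k - 2*loglik`, `k` = inner + outer count).
For each participant the AIC of the *overall* winner (lowest mean AIC
across participants) is subtracted from every model's AIC before
averaging; the winner's mean relative AIC is 0 by construction.

## Design generators

* **Blocked detection** (Exp 1): 3 sections x 10 blocks x 40 trials;
  target-present ratios 75/50/25% per section; blocks alternate color-only
  and orientation-only targets. Per-block counts are exact — each block
  shuffles a fixed multiset rather than drawing i.i.d. Bernoulli trials —
  so the stated proportions hold in every block. The alternation starts
  with color and the section order defaults to 75/50/25; both are
  configurable, as the counterbalancing across participants is a
  between-subject matter the generator need not fix.
* **Dimension discrimination** (Exp 2): as Exp 1 but a target on every
  trial and the color/orientation mix at the section ratio within blocks.
* **Mixed detection** (Exp 3): each 65-trial block is a linear order-2 De
  Bruijn sequence over 8 labels — the four target types plus four
  placeholder labels that all render as target-absent displays. A random
  Eulerian circuit on the complete 8-vertex digraph (Hierholzer's
  algorithm with randomized edge order) gives 64 transitions covering
  every ordered label pair exactly once, hence 65 trials; collapsing the
  placeholders, every target type is followed equally often by each
  target type and equally often by present as by absent. Eight labels is
  the smallest alphabet delivering that balance, and it reproduces the
  design's printed 65-trial block length. The default session is 20
  blocks (1300 trials), matching the 1200-trial length of the other two
  designs; the source design does not state its block count.

## Synthetic data and what it does (not) emulate

The simulator draws the schedule from the design generator, computes
modulations exactly as the fitting code does, samples RTs from the
generating accumulator, and flips responses with a lapse probability
(RT then uniform on 0.15–2 s). Lapses are the only error source for
LATER — a single-boundary model cannot err — while the DDM also produces
natural wrong-boundary absorptions. Default lapse rates in the shipped
configurations (1.5%, 2.5%, 3.3%) mirror the error rates observed in the
three experiments, and the default accumulator parameters (`D = 1`,
`mu = 6.5 /s`, `sigma = 1.3`, `t_er = 0.3 s`) put median correct RTs near
0.45 s, in the range typical of easy singleton search. Updating-rule
defaults are `alpha = 0.8`, `beta0 = 2` (response prior), `alpha = 0.9`,
`delta = 0.1` (dimension rate), `kappa0 = 0.8`.

Passing recovery tests on these data shows the estimation machinery is
consistent for data generated by the model family. Real data differ in
ways the generator deliberately omits: practice and fatigue trends,
feature-level (within-dimension) priming, post-error slowing,
trial-to-trial variability of the non-decision time, and any RT
dependence of the updating itself. Conclusions about real data rest on
the model comparison, not on these simulations.

## Problem sizes in the test suite

The suite exercises full single-participant sessions (1200–1300 trials)
throughout; the simulation-heavy checks use 10–12 participants for
parameter recovery and behavioral signatures, and 10 replicates of a
4-participant, 6-block mixed-detection experiment against a 12-model
candidate subset for model recovery — sizes at which the generating
model's AIC margin is already an order of magnitude larger than its
standard error, while a full suite run stays in the minutes range on one
core.

## Interfaces

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` (simulate, descriptives, fit/compare, recovery) are
thin narrative drivers over the exported functions and write tidy CSVs
under `results/`; there is no shell wrapper beyond them. Generator
settings travel in YAML configuration files (three ready-made ones under
`inst/extdata/`), and trial tables in a flat CSV schema with 1-based
human-readable indices at the file boundary and 0-based indices in
memory.

## Known limitations

* The DDM likelihood has no trial-to-trial variability in non-decision
  time or drift; misfit from that source loads onto the scale parameter.
* Only one updating rule per scope is active per model; parallel
  mechanisms within a scope are outside the space.
* Feature-level priming is not modelled (its observed effects are small
  and confined to the discrimination task).
* Group-level inferential statistics on the summaries (ANOVA, Bayes
  factors) are intentionally out of scope; the reporting module emits
  per-participant cell means for external tools.
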