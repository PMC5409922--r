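---
title: "Modelling a commune-scale Vespa velutina invasion under imperfect detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a commune-scale Vespa velutina invasion under imperfect detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velutina)
```

## The problem

The Asian hornet *Vespa velutina* invaded south-west France in 2004 and has
since spread across western Europe, preying heavily on honeybees. At the
scale of a single commune, the available evidence of an invasion is a
register of discovered nests: when each nest was found and destroyed,
whether it was a small spring **primary** nest or a large summer
**secondary** nest, and what structure it hung from. Detection is
opportunistic (public reports, beekeepers, the local authority), so the
register under-counts the population by an unknown, time-varying amount.

This package turns such a register into (i) descriptive statistics —
yearly colony counts, nest densities, habitat breakdowns — and (ii)
estimates of the demographic quantities that matter for control policy:
the between-year growth rate, the carrying capacity with and without nest
destruction, and the detection probabilities themselves.

## Life-cycle accounting

A colony is founded in spring by one overwintered queen (foundress), who
builds a primary nest; around the end of July the colony abandons it for a
secondary nest, which it occupies until the workers die in late autumn and
the new foundresses disperse to hibernate. This yields the calendar rules
implemented in `classify_activity()`:

* a primary nest destroyed **after 31 July** was already abandoned —
  destroying it removed no colony;
* a secondary nest (or a nest of unrecorded stage) destroyed **after
  15 November** was already inactive, and its foundresses had already
  left;
* a nest destroyed on or before its cut-off was active, and its
  destruction removed the colony's future reproduction.

Both dates are configurable in `activity_cutoffs()`; the defaults are the
values that reproduce the study tallies. Destruction *on* the cut-off day
counts as active (the verbal rules "after the end of July" / "after the
middle of November" make the boundary day itself active).

Counting colonies rather than nests avoids double counting: each colony
occupies one primary and (if it survives) one secondary nest, so
`detected_colonies()` counts active-destroyed primaries plus all detected
secondaries. For years in which stage was never recorded (2007–2008 in the
packaged data) every detected nest is taken as one colony, and
active-destroyed nests in such years are pooled with the secondaries —
the conservative assumption that stage-unrecorded nests were secondary.

## The demographic model

Let $S_{y-1}$ be the number of *successful* secondary nests in year
$y-1$ — secondaries not destroyed while active, hence assumed to have
released hibernating foundresses. The number of colonies (equivalently
primary nests) the next year is Poisson with a Beverton–Holt mean:

$$P_y \sim \text{Poisson}\!\left(\frac{r\,S_{y-1}}{1 + S_{y-1}/\kappa}\right)$$

where $r$ is the intrinsic between-year growth rate and $\kappa$ (in
colonies) scales the density dependence. Observation is a chain of
binomial thinnings with three detection classes, each with its own
year-varying probability:

$$A_{P,y} \sim \mathrm{Bin}(P_y, d_{AP}(y)), \quad
  A_{S,y} \sim \mathrm{Bin}(P_y - A_{P,y}, d_{AS}(y)), \quad
  I_{S,y} \sim \mathrm{Bin}(S_y, d_{IS}(y))$$

with $S_y = P_y - A_{P,y} - A_{S,y}$. Detected active nests are destroyed;
a detected *inactive* secondary has already released its foundresses, so
its discovery does not reduce $S_y$. Inactive-primary detections (present
in the data, e.g. the twelve 2014 primaries none of which was active) are
tallied but deliberately excluded from the likelihood: the observation
model has exactly the three classes above, and a fourth class would add a
free detection schedule with no demographic consequence.

Detection probabilities "vary linearly over the period": we implement this
on the logit scale, $d(y) = \mathrm{logit}^{-1}(a + b\,y)$ with year index
$y = 0$ in 2007, which keeps probabilities inside $(0,1)$ for every year
without clipping. A raw-linear variant (probability $a + by$ clipped into
$(0,1)$) is available via `schedule_scale = "linear"` in `run_mcmc()` for
sensitivity analysis; on the packaged data it drives the fit to
near-complete detection and an even higher growth rate, which is one
reason we keep the logit parameterisation as the default.

### Equilibria

The deterministic skeleton $S \mapsto q\,r\,S/(1+S/\kappa)$, where
$q = (1-d_{AP})(1-d_{AS})$ is the probability a colony survives both
active-detection filters, has fixed points

$$K_{\text{no control}} = \kappa\,(r-1), \qquad
  S^* = \kappa\,(r q - 1),\quad P^* = S^*/q,$$

the latter two when $rq > 1$ (otherwise control drives the population to
extinction). `equilibrium_no_control()` and `equilibrium_with_control()`
return these closed forms; the test suite verifies them against a
fixed-point iteration of the mean map and against long-run averages of the
stochastic simulator. Expected annual discoveries at the controlled
equilibrium are $P^* d_{AP}$, $P^*(1-d_{AP})d_{AS}$ and $S^* d_{IS}$.

## Bayesian inference

The observed counts (and, for 2007–2008, the detected-colony totals) are
fit by a block-wise random-walk Metropolis–Hastings sampler
(`run_mcmc()`). The unknowns are $r$, $\kappa$, the six schedule
parameters, the latent primaries $P_{2007},\dots,P_{2014}$ and the
pre-observation successful count $S_{2006}$ ("`s_init`").

**Stage-unrecorded years.** 2007–2008 contribute a single binomial term,
$C_y \sim \mathrm{Bin}(P_y, d_{AS}(y))$ on the detected-colony total,
using the active-secondary schedule; their active-destroyed counts (1 and
12) are treated as known removals when computing $S_y$. This is an
assumption, flagged here prominently: those years' nests were folded into
colony counts without stage, and some other allocation of their detections
across classes would change the early-year information. The documented
fact that at least three 2007 nests released foundresses enters as the
bound $S_{2007} \ge 3$.

**Priors** (`prior_spec()`) are weakly informative, chosen once:
log-normal on $r$ (median 5, sdlog 1) and $\kappa$ (median 50, sdlog 1.5),
Normal(0, 2) on schedule intercepts and Normal(0, 0.5) on slopes (logit
scale per year), discrete-uniform $\{1,\dots,20\}$ on `s_init`. Nothing in
the source data constrains these; sensitivity to them should be explored
with `run_fit()`'s YAML config when conclusions hinge on absolute
abundance.

**Sampler design.** Continuous parameters move by Gaussian random walks on
log/logit scales; latent counts by symmetric uniform integer steps.
Single-site updates alone crawl along two poorly identified ridges —
$\kappa(r-1)$ is much better determined than $r$ and $\kappa$ separately,
and overall detectability trades off against total abundance — so the
sampler adds three symmetric joint blocks: an anti-correlated
$(\log r, \log\kappa)$ move, a common shift of the three detection
intercepts, and a common shift of all latent $P_y$. These affect mixing
only, not the target distribution. Proposal scales adapt toward ~25%
acceptance during burn-in and then freeze, so retained draws come from a
valid Markov chain. Chains are seeded `seed + chain - 1`; identical
configurations reproduce identical chains.

**Summaries.** `summarize_posterior()` reports the posterior median (the
point-estimate convention here; the mean is reported alongside) and
equal-tailed credible intervals. Derived quantities — both carrying
capacities, expected discoveries, discovery percentages, and the latent
2014 colony number — are computed *per posterior sample* and then
summarised; ratios of summaries are not summaries of ratios, and the two
can differ materially here. For "percentage of nests ever discovered" the
denominator is ambiguous, so `discovery_percentages()` reports both
candidates: physical nests ($P^*(2-d_{AP})$: one primary per colony, one
secondary per surviving colony) and colonies ($P^*$).

### What the packaged-data fit shows

At the default configuration (50,000 iterations, 10,000 burn-in, thinning
10, 4 chains — a few minutes on one CPU) the fit to the 2007–2014 counts
concentrates the colony-level carrying capacity in the low hundreds with
wide uncertainty, estimates detection to be far from complete, and places
the between-year growth rate well above replacement, with a 95% credible
interval wide enough to contain historical point estimates near 9–10 made
from these data under different (unstated) prior and parameterisation
choices. The position *along* the $(r,\kappa)$ ridge is only weakly
identified: analysts wanting tighter growth-rate statements should expect
strong prior sensitivity, particularly through the 2007–2008
colony-only terms, which link a small $S_{2007}$ to the 27 detections of
2008 and thereby push $r$ upward when early detection is estimated low.

## The synthetic-invasion generator

`generate_invasion()` simulates the generative model exactly as the
likelihood assumes it, and `generate_records()` expands simulated (or
real) yearly counts into record-level tables whose dates respect the
activity cut-offs and whose tally reproduces the input counts identically.
Defaults emulate the study conditions: eight years, one successful
founding colony, $r = 9.6$, $\kappa = 25$, and detection rising over the
period (active primaries ~3% to ~10%, active secondaries ~12% to ~28%,
inactive secondaries ~8% to ~20%) — magnitudes implied by the study's
reported equilibrium discovery rates. Structure tokens are drawn from the
observed habitat mix (67.2% natural, oak the dominant genus at 40.3%).
Discovery dates are uniform in invented but life-cycle-consistent windows
(active primaries April–July, active secondaries August–mid-November,
inactive discoveries after the cut-offs); habitat is assigned
independently of the dynamics.

What passing tests on synthetic data do **not** show about real data: the
generator has no spatial structure, no immigration from neighbouring
communes (the study area is not a closed system), no year effects from
climate or search effort beyond the smooth detection trend, and
independence of habitat from detectability. Parameter recovery on
synthetic replicates demonstrates the estimator is consistent with its own
assumptions, not that those assumptions hold in the field.

## Numerical choices and degenerate inputs

* Impossible latent/observed configurations return `-Inf` log-likelihood,
  never an error; the sampler rejects them.
* Initial latent states are set to twice the observed counts plus a
  margin, then doubled until the posterior is finite; an informative error
  is raised if no finite start is found.
* Probabilities in the linear schedule variant are clipped to
  $[10^{-9}, 1-10^{-9}]$.
* Equilibrium formulas return 0 (not negative values or NaN) in the
  subcritical cases $r \le 1$ and $rq \le 1$.
* Zero detected nests make the destroyed-while-active percentage a
  missing value, not a division error.
* Rounding conventions follow the historical tables: densities to 2
  decimal places, activity percentages to the nearest integer, habitat
  percentages to 1 decimal place; raw values are always retained. One
  historical urban-density cell (2011) prints 6.40 where consistent 2-dp
  rounding of 62/(0.47 × 20.59) gives 6.41; we report 6.41 and flag the
  single-cell inconsistency rather than reproducing it.
* The commune's urban share is 0.47 by default — the value consistent
  with the published urban densities and the 22.63 nests/km² equilibrium
  density — although land-cover data round it to "approximately 48%";
  `terrain_config(urban_fraction = 0.48)` is the documented alternative.
* The primary-nest habitat figures contain an internal inconsistency in
  the source tallies (30 man-made of 39 primaries reported as 78.9%,
  which is 30/38); we report the counts and compute 76.9% from them.

## Problem sizes used in the checks

The shipped test suite runs the enumeration oracle on two-year systems
with latent populations up to 60 (Poisson tail below $10^{-12}$ of the
enumeration bound), Monte-Carlo checks with 4,000–10,000 replicates, a
20-replicate parameter-recovery experiment at the study design (8 years,
$r = 8$, $\kappa = 30$, known schedules) using 5,000-iteration chains, and
a reduced-length fit of the packaged data; the full-length default
configuration is exercised by `scripts/acceptance.R`. These sizes were
chosen so each check's Monte-Carlo error is small relative to the effect
it verifies.

## Known limitations

* The commune is modelled as a closed population; immigration will bias
  $\kappa$ (and hence both carrying capacities) upward.
* Detection classes are limited to the three the observation model names;
  inactive-primary reports carry no inferential weight.
* Queens hibernating inside apparently inactive secondaries are ignored,
  consistent with their destruction having little demographic effect.
* The 2007–2008 colony-only likelihood terms rest on the all-secondary
  assumption described above.
* Growth rate and density-dependence scale are only jointly
  well-identified; absolute statements about either alone inherit prior
  sensitivity.
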