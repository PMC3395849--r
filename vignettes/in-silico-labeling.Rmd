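---
title: "In silico labeling: time-dependent half-lives and transit-times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico labeling: time-dependent half-lives and transit-times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silabel)
```

## The problem

For a species $x$ in a biochemical reaction network, two natural
"how long" questions have different answers. The *species half-life*
(SHL) asks: if production stopped now, how long until the pool decayed to
half? The *label half-life* (LHL) asks the question a tracer experiment
answers: if every molecule currently in the pool were tagged, how long
until half the tagged molecules have left? The two coincide only for
isolated pools or first-order removal. A third quantity, the *label
transit-time* (LTT), asks how long until half of the tagged molecules
have reached some target pool *at least once* — for example, completed a
full cycle through the nucleus and back.

`silabel` computes all three for arbitrary ODE reaction networks by
running the tracer experiment computationally: the network is extended
with labeled and free counterparts of the tracked species, the label is
injected at a chosen time, and the characteristic times are read off the
labeled trajectories.

## Model representation

A network is a set of species $x_i$, reactions $r_j$ with ordered
reactant and product lists and stoichiometries $b_{ij}$ (reactant side)
and $a_{ij}$ (product side), parameters, and optional tabulated input
functions $u_k(t)$. The dynamics are

$$\dot x_i = \sum_j a_{ij} v_j - \sum_j b_{ij} v_j,$$

with flux $v_j$ given by an explicit rate-law expression. Rate laws are
parsed arithmetic expressions over declared names (`+ - * / ^`, `exp`,
`log`, `sqrt`); there is no implicit mass-action generation, so the model
file states exactly the equations that are integrated. Inputs are
(time, value) tables with linear or cubic interpolation and constant
extrapolation — a reproducible, format-stable way to supply measured
driving functions.

## Species half-life

The SHL at reference time $t_0$ is computed by adding one artificial
variable $y$ with $\dot y = -\sum_j b_{ij} v_j$ and $y(t_0) = x_i(t_0)$:
only the outfluxes of the species of interest, no influx. Two details
matter:

* **$y$ is a decay-only clone.** Inside the outflux rate laws, $y$
  replaces the species' own concentration while every *other* species and
  input evolves live. If the live concentration were used instead,
  production would leak into the supposedly influx-free decay through
  nonlinear rate laws, and the order-2 half-life $1/(x_0 k)$ would not be
  recovered in the presence of influx.
* **The crossing is interpolated.** The half-life is the first time $y$
  crosses $y_0/2$, located by linear interpolation between adjacent
  integration samples. The integrator's maximum step is therefore bounded
  (default: 1/300 of a first-order guess $\ln 2 \cdot y_0 /
  \text{outflux}(t_0)$), because the crossing accuracy is limited by the
  sample spacing, not by the solver tolerance.

Closed forms for isolated processes (orders 0, 1, 2, general $n > 1$,
and Michaelis–Menten via its implicit integral form) are provided in
`analytic_half_life()` and serve as oracles in the test suite; numeric
and analytic values agree to better than $10^{-4}$ relative.

If the pool is empty at $t_0$, has no outflux, or never reaches half
within the (expanding, capped) search horizon, the result is flagged
undefined with a reason rather than raising an error — on a bounded
observation window these are legitimate outcomes, not failures.

## The extended labeled/free network

Tracked single entities $x$ get a labeled ($x^L$) and a free ($x^F$)
counterpart. A tracked complex with $s$ tracked monomer slots gets all
$2^s$ combinations, in the order of the original composition; e.g. a
phospho-dimer yields $pS^F\_pS^F$, $pS^L\_pS^F$, $pS^F\_pS^L$,
$pS^L\_pS^L$. Throughout the package, enumeration is deterministic with
free before labeled and the *first* slot varying fastest, so extended
networks are byte-stable across runs.

For every reaction touching tracked species, stoichiometric counts are
first expanded into repeated ordered slots ($A + A$ is two slots),
untracked reactants and products are removed, and all $2^p$ labeled/free
assignments over the $p$ tracked reactant slots become labeled reactions.
Each carries the original flux $v$ scaled by the weight

$$w_j = \frac{\prod_{x^{LF}_k \in I_j} x^{LF}_k}{\prod_{x_k \in I} x_k},$$

the ratio of the assigned variant concentrations to the original
reactant concentrations — the tracer assumption that label flows in
proportion to its share of each pool. The weights over one reaction sum
to 1 whenever all original reactant concentrations are positive, which
makes the variant sums of every tracked species reproduce the original
trajectory exactly (marginalization). When the denominator falls below
the absolute solver tolerance the weight is defined as 0: for mass-action
laws the original flux vanishes with any factor, and for other laws this
is the conservative continuous extension.

Labels flow positionally from reactant slots to product slots (i-th
tracked reactant slot to i-th tracked product slot). The source never
states such a mapping for general reactions; positional flow reproduces
the shuttling example and is documented here as the package's convention.
A labeled slot with no tracked product slot (e.g. degradation into an
untracked species) destroys the label, with a build-time warning.

Two pruning rules distinguish the two characteristics:

* **LHL mode**: any labeled product equal to the source species is
  replaced by its free counterpart. Label can leave the source pool but
  never re-enter it — no double-counting of cycling label, and upstream
  production never inflates the labeled pool.
* **LTT mode**: any labeled product equal to the target species is
  replaced by its free counterpart *and* one unit of the artificial
  returned-label pool `RL` is produced per removed label. `RL` is a pure
  accumulator counting how much label has arrived at the target at least
  once.

With source equal to target, the labeled-source trajectory is identical
in both modes — asserted in the tests to $10^{-9}$.

Symmetric variants (such as $pS^L\_pS^F$ and $pS^F\_pS^L$) are *not*
merged: both are kept and their trajectories come out identical, which
the test suite asserts rather than assumes.

## Injection protocol and curves

For each injection time $t$: integrate the joint original+labeled system
from 0 with all labeled pools empty; at $t$, move the source pool's
entire concentration into its labeled variant (a state reset with
integrator restart, not an impulse term — this matches the protocol
exactly and avoids stiff impulse handling); continue integrating. The
LHL at $t$ is the duration until $S^L$ first crosses $S^L(t)/2$; the LTT
is the duration until `RL` first exceeds the same threshold. Crossings
are linearly interpolated between samples; a sample exactly at the
threshold is the crossing; a point with zero injected label is undefined
with reason "source concentration zero".

The crossing error is second-order in the sampling step $h$, with
coefficient $|y''|/(8|y'|)$ at the crossing; the test suite checks this
envelope against a closed-form first-passage oracle (a two-stage linear
chain, whose label-arrival curve is a gamma CDF and whose LTT is the
gamma median). Defaults: 31 injection times over the observation window,
post-injection horizon 10 times the window (cyclic systems can return
label slowly), sampling step horizon/2000.

## Calibration and confidence envelopes

Weighted least squares $\chi^2(\theta) = \sum ((\text{model} -
\text{data})/\text{sd})^2$ is minimized with Levenberg–Marquardt over
log-parameters (rates are positive), with seeded log-uniform multistarts.
The profile likelihood of one parameter re-fits all others over a
log-spaced grid spanning $[0.01, 100] \times k_{fit}$ (21 points by
default), scanning outward from the optimum with continuation. Grid
intervals crossing $\chi^2_{best} + 3.84$ (the 95% quantile of
$\chi^2_1$; separate, pointwise intervals) are refined by bisection, and
the refined settings — each an actually-refit, feasible parameter vector,
not an interpolation — are collected. The confidence envelope of an LHL
or LTT curve is the pointwise min/max of the curves recomputed at all
collected settings plus the best fit, so the best-fit curve lies inside
by construction and the band reflects only parameter uncertainty that
the data leave open.

## The JAK-STAT example

`build_jakstat()` implements the nucleocytoplasmic STAT shuttling model:
receptor-driven phosphorylation ($k_1 = 1.37$), dimerization
($k_2 = 0.22$, consuming two $pS$), nuclear import ($k_3 = 0.63$),
dissociation with dephosphorylation ($k_4 = 0.59$, producing two $nS$),
and export ($k_5 = 0.59$), with $S(0) = 0.96$. The three monomeric forms
are tracked; the dimers are two-slot complexes of the phospho-monomer
lineage, so a label follows one STAT molecule through modification and
relocalization.

The receptor input is a **surrogate pulse** $a\,t^{2} e^{-r t}$ with
peak 1 at 5 minutes, decayed below 5% by 30 minutes — a synthetic
stand-in chosen to produce a single transient activation wave on the
0–30 min window. It is *not* a measured receptor profile; consequently
the package reproduces the qualitative behavior of the pathway's label
characteristics (an interior minimum of the label half-life near peak
receptor activity, recovery as the stimulus decays, an interior minimum
of the cycle transit-time, and a transit-time band wider than the
half-life band) but no specific published minute values, which depend on
the measured input shape.

Observables follow the common immunoblot convention: phosphorylated
cytoplasmic STAT `scale_pS*(pS + 2*pS_pS)` and total cytoplasmic STAT
`scale_S*(S + pS + 2*pS_pS)` with scales 1.45 and 0.98. Whether dimers
should count twice is a convention, so the factor is configurable
(`jakstat_observables(dimer_factor = 1)` counts complexes once).

### What the synthetic-data generator does and does not emulate

`generate_synthetic_data()` adds iid Gaussian noise (default sd: 5% of
each observable's signal maximum, a typical densitometry-scale error) to
the model observables on a measurement grid (the analyses here use
minute-resolution sampling over 0–30 min). It emulates measurement
noise only: no systematic blotting bias, no correlated errors between
time points, no biological replicate variability, and the receptor input
is known exactly rather than estimated from data. Passing recovery tests
on such data therefore demonstrates correctness of the estimation
machinery under the stated noise model, not expected performance on real
immunoblots.

### Identifiability

Two structural facts limit parameter precision with purely cytoplasmic
observables, and are worth knowing before fitting this model:

* With dimers counted twice, the phospho-pool $pS + 2\,pS\_pS$ is
  *invariant under the dimerization reaction*, so $k_2$ is seen only
  indirectly through the import flux; the $(k_2, k_3)$ pair is sloppy.
* At the point $k_4 = k_5$ the two-step nuclear cascade's response is
  symmetric under exchanging the two rates, so the Fisher information in
  their difference vanishes: the individual nuclear rates are locally
  non-identifiable from cytoplasmic data. Tying $k_4 = k_5$ (suggested by
  their identical calibrated values) restores identifiability of the
  tied rate.

At 5% noise these sloppy directions leave individual-rate uncertainties
above 10% even for dense minute sampling, which the profile-likelihood
machinery makes visible as flat or wide profiles; at noise below ~1% all
five rates are recovered to within a few percent. Profiles are computed
for the phosphorylation, dimerization, import and export rates.

## Numerical choices

* Integrator: `deSolve::ode` (lsoda), rtol $10^{-8}$, atol $10^{-10}$,
  output grid and internal step bounded by `max_step` (default: span/500
  for plain integration; finer, crossing-driven defaults for half-life
  searches as above). Fitting uses rtol $10^{-7}$ and a coarser grid —
  residuals are evaluated at data times only, where crossing accuracy is
  irrelevant.
* Negative round-off: state values are clipped to zero inside rate-law
  evaluation only. No abort on small negative excursions: zero-order
  sinks legitimately drive a species through zero after the half-life
  crossing has already been located, and killing the trajectory there
  would lose the result.
* Threshold crossings: first bracketing interval, linear interpolation;
  exact sample hits return the sample time; a series already past the
  threshold returns its first time (reachable only with zero injection,
  which is flagged undefined upstream).
* Test problem sizes: unit tests run on two- and three-species toys in
  seconds; the end-to-end shuttling analyses use 8–9 injection times, a
  60-minute post-injection horizon and a 0.05-minute sampling step, and
  the inference checks use 9-point profiles over four decades.

## Known limitations

* Rate laws are explicit expressions; rule-based or implicitly generated
  networks are out of scope, as are events other than label injection,
  stochastic simulation, and compartment-volume handling.
* The exported extended network (`extended_to_network()`) divides by
  original reactant concentrations symbolically; it is re-integrable
  only where those stay positive, whereas the internal integrator guards
  the zero limit. Use the internal path for production runs and the
  export for inspection.
* `RL` counts labels, not molecules: a doubly-labeled dimer arriving at
  the target contributes two units.
* Simultaneous (curve-wise) confidence bands are not provided; the
  envelopes are pointwise 95% constructs.
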