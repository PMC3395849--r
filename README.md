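# silabel

Computational tracer experiments ("in silico labeling") for ODE
reaction-network models, for systems biologists who want to know not just
*how much* of a species there is, but *how long* its molecules persist
and travel: the time-dependent species half-life (SHL), label half-life
(LHL) and label transit-time (LTT), with profile-likelihood confidence
envelopes.

## The method in brief

A network $\dot x_i = \sum_j a_{ij} v_j - \sum_j b_{ij} v_j$ is extended
with labeled (`^L`) and free (`^F`) counterparts of user-declared tracked
species. Complexes and ordered reactant lists expand combinatorially: a
reaction whose reactants carry $p$ tracked monomer slots yields $2^p$
labeled reactions, each with flux

$$v_j^{LF} = \frac{\prod_{x^{LF}_k \in I_j} x^{LF}_k}{\prod_{x_k \in I} x_k}\; v,$$

so label flows in proportion to its share of each reactant pool, and the
labeled/free variants of every species sum exactly to the original
trajectory. Injecting label into a source pool at time $t$ and reading
threshold crossings of the labeled trajectories gives:

* **SHL(t)** — time for an artificial outflux-only decay clone to halve;
* **LHL(t)** — time for the labeled source pool to halve, with label
  re-entry into the source prohibited (no double-counting in cycles);
* **LTT(t)** — time until half the injected label has reached a target
  pool at least once, accumulated in a returned-label pool `RL`.

Least-squares calibration (Levenberg–Marquardt, log-parameters,
multistart) and profile likelihoods supply the parameter settings at the
95% $\chi^2$ threshold; recomputing the curves there yields pointwise
confidence envelopes.

## Worked example

The bundled JAK-STAT nucleocytoplasmic shuttling model: cytoplasmic STAT
is phosphorylated by a transient receptor pulse, dimerizes, cycles
through the nucleus and returns.

```r
library(silabel)

net <- build_jakstat()            # k1 = 1.37 ... k5 = 0.59, S(0) = 0.96
proto <- injection_protocol(seq(0, 14, by = 2), horizon = 60,
                            max_step = 0.05)
lhl <- label_half_life_curve(net, "S", proto)
ltt <- label_transit_time_curve(net, "S", "S", proto)
round(lhl$value, 2)
#> [1] 2.12 0.78 0.52 0.54 0.69 1.04 1.78 3.73
round(ltt$value, 2)
#> [1] 10.70  9.35  9.53  9.90 10.40 11.50 14.07 22.67
```

Under the surrogate receptor pulse (peak at 5 min), the label half-life
of cytoplasmic STAT drops from ~2.1 min to ~0.5 min near peak receptor
activity — molecules are consumed fastest then — and recovers as the
stimulus decays. A full cycle through the nucleus takes ~9–10 min at its
fastest (the curve's interior minimum) and grows steeply once
phosphorylation wanes, since unphosphorylated molecules injected late
barely enter the cycle. These numbers depend on the input pulse shape;
with a measured receptor profile as `input_function()` table they would
be quantitative estimates.

Models can equally be written as YAML (`read_model_yaml()`,
`write_model_yaml()`), and a thin command-line front end is installed as
`exec/silabel` (`shl`, `lhl`, `ltt`, `extend`, `demo` subcommands).

See `vignettes/in-silico-labeling.Rmd` for the construction rules
(combinatorial multiplicity, label-removal, returned label), numerical
choices, and identifiability notes on the example model.

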