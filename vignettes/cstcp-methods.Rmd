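---
title: "Methods: stochastic TCP for a cancer stem cell hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic TCP for a cancer stem cell hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cstcp)
```

## The problem

Under the cancer stem cell (CSC) hypothesis, a tumour is controlled when its
stem compartment is extinct: only stem cells self-renew indefinitely, so a
tumour with zero stem cells cannot regrow. The corresponding tumour control
probability, TCP_S, is the natural objective of radiotherapy — but it is not
observable, because no assay identifies stemness directly. What can be
measured is the disappearance of cells carrying a CSC-associated surface
biomarker (CD133 in glioma), a population that also contains the first few
generations of progenitor cells. `cstcp` computes both the theoretical TCP_S
and the measurable biomarker TCP, TCP_CD+, for the same stochastic model, so
that the cost of using the measurable quantity as a surrogate — extra
treatment days, extra dose — can be quantified.

## The stochastic model

The tumour is a multitype continuous-time Markov branching process over
compartments `S, P1, ..., PN, M`:

* `S -> S+S` at rate `r_S * p_sym_renew`, `S -> S+P1` at `r_S * p_asym`,
  `S -> P1+P1` at `r_S * p_sym_diff` (the three probabilities sum to 1);
* `Pj -> 2 P(j+1)` at rate `r_P`, with `PN -> 2 M`: a progenitor divides
  exactly `N` times before terminal differentiation;
* natural apoptosis at rates `d_S`, `d_P`, `d_M`;
* at each radiation fraction of dose `d`, every cell of compartment `i`
  survives independently with probability
  `SF_i(d) = exp(-(alpha_i d + beta_i d^2))` (linear–quadratic model).

All cell fates are independent (no density dependence), the hierarchy is
strictly unidirectional (no dedifferentiation), and all radiation-induced
death is attributed to the fraction instant itself.

The biomarker-positive set is `S, P1, ..., Pk` with `k <= min(N, 3)` by
default; later generations and mature cells are biomarker-negative and by
default carry three-fold `alpha` and `beta` (CD133− cells are markedly more
radiosensitive than CD133+ cells). An optional distinct stem pair
(`alpha_stem`, `beta_stem`) expresses the alternative regime in which stems
are even more radioresistant than CD+ progenitors; in that regime the stem
population dominates TCP_CD+ and the two TCP variants nearly coincide
(tested as a limit property).

### Progenitor division fate

Only the chain `S -> P1 -> ... -> PN -> M` and the fixed number of divisions
are specified by the biology; we read each progenitor division as binary and
symmetric (`Pj -> 2 P(j+1)`), the standard convention in hierarchical
compartment models. The division fate is confined to one internal function
of each solver and to one reaction of the simulator, so a budding variant
(`Pj -> Pj + P(j+1)`) could be added without changing any interface.

## TCP_S: closed form

Progenitors never produce stem cells, so the stem count alone is a linear
birth–death process with birth rate `b = r_S p_sym_renew` (only symmetric
self-renewal adds a stem), death rate `delta0 = r_S p_sym_diff + d_S`
(symmetric differentiation removes one; asymmetric division is neutral), and
multiplicative survival `SF_S(d_f)` at each fraction time. For one initial
stem lineage the extinction probability by time `t` solves the backward
Kolmogorov (Riccati) equation; with the mean-population factor
`Omega(t) = exp((b - delta0) t) * prod_{t_f <= t} SF_S(d_f)` the solution is

```
q(t) = 1 - 1 / ( 1/Omega(t) + b * ∫_0^t ds / Omega(s) )
```

and `TCP_S(t) = q(t)^{n_S0}` by lineage independence. A detail worth
flagging: the superficially similar form `1 - Omega / (1 + b ∫ Omega)`
solves the *forward* Riccati equation and is equivalent only for
time-constant rates; with kills at fraction times it is wrong (it even
decreases after a fraction, violating the absorbing-extinction property).
The backward form implemented here is verified against an independent
numerical Riccati integration and against both oracles.

The integral is accumulated segment-by-segment between fractions, where the
integrand is a pure exponential, so the evaluation is analytic — no
quadrature, no error beyond floating point. Initial progenitors and mature
cells never enter TCP_S.

## TCP_CD+: method of characteristics

The generating function of a branching process satisfies a first-order PDE
whose characteristics are ODEs in the per-ancestor extinction probabilities.
Concretely, let `u_i(s)` be the probability that a single cell of type `i`
alive at time `s` has no biomarker-positive descendants at the horizon `T`.
Moving backward in time,

```
du_i/ds = -[ a_i (f_i(u) - u_i) + d_i (1 - u_i) ]
```

with `a_i` the division rate and `f_i` the one-division offspring PGF
(`f_S = p1 u_S^2 + p2 u_S u_P1 + p3 u_P1^2`, `f_Pj = u_P(j+1)^2`). Radiation
enters as the jump `u_i <- (1 - SF_i) + SF_i u_i` when the backward sweep
crosses a fraction time: a killed cell contributes certain CD+ extinction, a
survivor continues. The terminal condition at `s = T` is `u_i = 0` on the
CD+ set and 1 elsewhere, and

```
TCP_CD+(T) = prod_i u_i(0)^{n_i0} .
```

Biomarker-negative compartments can never spawn biomarker-positive cells,
so `u_i = 1` identically outside `S, P1..Pk` and the system closes on `k+1`
equations. The reduced system is the default; the full `(N+2)`-dimensional
system is retained as an option and the equality of the two is asserted
numerically in the test suite.

## Oracles

Two independent engines certify the solvers on desk-scale instances:

* **Exact simulation.** Between consecutive fraction times all propensities
  are constant, so plain Gillespie is exact; at a fraction every cell is
  thinned binomially. The core loop is C++ (Rcpp) and uses R's RNG, so a
  single `set.seed` root makes a whole replicate batch bit-reproducible.
  Because the target set (stem, or `S..Pk`) sits at the top of the
  unidirectional hierarchy it can never be repopulated once empty, so
  replicates stop early when it empties; TCP estimates carry Wilson score
  intervals.
* **Truncated master equation.** The full joint forward master equation
  over the compartment counts, truncated at per-compartment caps, integrated
  as a sparse linear ODE system between fractions; at a fraction the
  probability vector is pushed through the product-binomial thinning kernel
  (applied axis-by-axis on the probability array). Transitions that would
  exceed a cap route their flux to an absorbing escape account, so the
  truncation bias is bounded by the reported escaped mass and the function
  refuses to answer when that bound exceeds `escape_tol`. Mature cells
  produce nothing and are marginalised out exactly by default (the
  marginalisation is itself tested against `track_mature = TRUE`).

The central validation (mirrored in the acceptance script) is three-way
agreement: solver vs master equation to 1e-6 on instances with a few cells
and a few fractions, and solver inside the 99% Wilson interval of
100,000-replicate simulation estimates.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha_pos`, `beta_pos` | 0.1, 0.01 | /Gy, /Gy² | alpha/beta = 10 Gy, typical tumour LQ scale |
| `alpha_neg`, `beta_neg` | 3× positive | /Gy, /Gy² | three-fold radioresistance of biomarker+ cells |
| `r_S` | 0.1 | /day | slowly cycling glioma stem pool (~10 d between divisions) |
| `r_P` | 0.5 | /day | progenitors cycle ~5× faster than stems |
| `p1, p2, p3` | 0.3, 0.6, 0.1 | — | asymmetric division dominant; net stem growth `r_S(p1-p3)` = 0.02/day |
| `N`, `k` | 5, 3 | — | five progenitor generations, first three biomarker+ |
| `d_S, d_P, d_M` | 0 | /day | radiation kill dominates on the treatment timescale |
| `n_S0`; `n_P0`; `n_M0` | 100; 200…3200 (doubling); 10⁴ | cells | micro-tumour scale, each generation ~doubles the previous |
| `bid_gap_hours` | 6 | h | typical b.i.d. spacing; configurable |

The default parameter set (`default_glioma_model()`) is **synthetic**: it is
assembled once from typical values in the glioma radiobiology modelling
literature and labelled as such — it is not a fit to any specific tumour.
It emulates the regime the method is designed for: a radioresistant,
slowly-expanding stem pool under a 6-week course, with TCP curves that rise
through the final treatment weeks. What passing tests show is that the
*solvers* are exact for the stated stochastic model and that the surrogate
cost and schedule rankings hold under these reference parameters; they do
not show that any specific clinical tumour has these rates, and real tumours
additionally violate model assumptions (hypoxia, cell-cycle structure,
plasticity) listed under limitations.

Schedules: scheme 1 = 30 × 2 Gy (1/weekday), scheme 2 = 50 × 1.2 Gy
(2/weekday), scheme 3 = 40 × 1.5 Gy (2/weekday); all 60 Gy total, Monday
start at `t = 0`, weekends untreated.

## Numerical design

* **Discontinuities.** TCP curves jump at fractions. The stem solver is
  piecewise-analytic, so jumps are exact. The characteristic solver never
  lets the integrator step across a fraction: interior fractions are deSolve
  event times (integration restarts there); fractions at the horizon or at
  `t = 0` are applied outside the integration. An explicitly segmented sweep
  is kept as a cross-check and the two paths are asserted equal.
* **Tolerances.** lsoda with `rtol = 1e-8`, `atol = 1e-10` for TCP_CD+
  (tightened to 1e-10/1e-12 where 1e-6 oracle agreement is asserted — note
  the `n`-cell product amplifies per-lineage error `n`-fold); master
  equation at `rtol = 1e-10`, `atol = 1e-12`, switching from lsoda to the
  Jacobian-free Adams method above 3000 states, where lsoda's dense internal
  Jacobian would be quadratic in memory.
* **Fraction-at-sample convention.** A fraction exactly at the evaluation
  time counts (right-continuity), consistently across `cumulative_dose`,
  both solvers, the simulator and the master equation.
* **Instantaneous vs finite fractions.** Fractions are instantaneous
  multiplicative survival events by default. An optional
  `fraction_duration` mode delivers the same `-log SF` as a constant hazard
  over a window; the two agree in the short-duration limit (tested).
* **Degenerate inputs.** `n_S0 = 0` gives TCP ≡ 1; `r_S = 0` reduces to
  exact binomial/exponential limits (tested); empty time grids, negative
  rates, off-simplex probabilities and `k > N` are rejected with named
  errors; characteristic states outside `[0, 1]` beyond 1e-6 abort rather
  than clamp silently.
* **Evaluation grid.** Default: every fraction time plus interval midpoints
  plus a one-day tail, so each jump is sampled on both sides; the TCP curves
  themselves are grid-independent per horizon (tested under refinement).
* **Scheme-ranking comparison.** "Qualitative consistency" between the
  TCP_S and TCP_CD+ families is operationalised as identical ranking of the
  three schemes at every common dose level (multiples of 6 Gy). Levels where
  any curve is below 0.01 are skipped: in the pre-rise tail all schemes give
  essentially zero control and the ordering of values like 1e-40 is
  numerically real but scientifically meaningless (and invisible at any
  plotting resolution).
* **Problem sizes.** Oracle fixtures use a few cells, `N <= 4`, at most ten
  fractions and horizons of a few days, with truncation caps chosen so the
  escaped mass is at most 1e-7 (usually 1e-8) — two orders below the 1e-6
  agreement bound. These sizes make the master equation exact to the stated
  tolerance while its state space stays in the 10³–10⁵ range; the production
  solvers are population-size-independent in cost.

## Limitations

* No dedifferentiation: plasticity between non-CSC and CSC states would
  break the absorbing-extinction property the whole formalism rests on.
* No spatial structure, hypoxia or oxygen-enhancement modelling; no
  cell-cycle (active/quiescent) compartments; no inter-fraction repair
  kinetics or dose-rate effects; no NTCP.
* The oracles are for desk-scale validation only; at clinically realistic
  cell numbers (10⁹) only the analytic/ODE solvers apply.
* TCP_CD+ is an extinction probability, not a joint distribution of the
  surviving population; questions about residual disease burden need the
  simulator.

```{r example, eval = FALSE}
model <- default_glioma_model()
sens <- default_radiosensitivity()
sched <- build_schedule(1)
stem <- tcp_s(model, sched, sens)
cd3 <- tcp_cd(model, sched, sens)
surrogate_cost(stem, cd3, levels = 0.5)
```
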