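---
title: "scaffpop: model, conventions and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scaffpop: model, conventions and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffpop)
```

## The biological system and the model

Human iPSC-derived neural progenitors are aggregated into roughly
spherical clusters of a few thousand cells and seeded onto fibrous melt
electrospun scaffolds, where scaffold contact triggers terminal neuronal
differentiation. `scaffpop` models the aggregate as three well-mixed
compartments — stem cells $S$, progenitors $P$ and differentiated cells
$D$ (cells, continuous) — plus, optionally, the local oxygen $O$ and
waste $W$ concentrations (%, CO$_2$ as waste proxy):

$$
\begin{aligned}
\dot S &= -\alpha S - d_1 S + \frac{2 p_1 S}{1+S+P+D} + r P\\
\dot P &= -\beta P - d_2 P - r P + \frac{2 p_2 P}{1+P+D} + d_1 S\\
\dot D &= -\gamma D + d_2 P\\
\dot O &= -f_{13}(O)\,(u_1 S + u_2 P + u_3 D) + \Phi_O\\
\dot W &= \phantom{-}f_{13}(O)\,(w_1 S + w_2 P + w_3 D) + \Phi_W
\end{aligned}
$$

Assumptions worth keeping in mind:

* **Well-mixed compartments.** No age structure, no delays, no spatial
  gradients inside the aggregate. Differentiation is terminal
  ($D$ only dies); progenitors can revert to the stem state at rate $r$.
* **Crowding feedback.** Proliferation of a compartment is inhibited by
  its own and all later compartments through the saturating
  $2p/(1+\text{crowd})$ terms. A factor of 2 appears because one
  division yields two daughters.
* **Continuum validity.** Populations are continuous; the model is
  meaningful for roughly $10^2$–$10^4$ cells. Equilibria below about a
  hundred cells are outside its domain, and the random-draw utilities
  reject parameter sets whose equilibria fall there.
* **Units.** Rates are proportion per minute; time is minutes
  internally (1 day = 1440 min; trajectories also report days); gas
  levels are percentages hard-clamped to $[0,100]$.

Four variants are available: `pd` and `spd` hold the environment
constant (continuous medium replacement), `pdow` and `spdow` evolve $O$
and $W$; in the latter two the rates are recomputed from the
instantaneous environment at every derivative evaluation.

## Environmental coupling

Each rate is a baseline ("experimental") value times a product of
thirteen fitted effect functions of oxygen, waste and the cell–scaffold
contact rate $C$, e.g. $p_2 = \bar p_2 f_5(O) f_6(W) f_{10}(C)$. The
contact rate summarises porosity as $C = (100-\text{porosity}) \cdot
0.1 \in [1, 10]$: 0.1 is the maximum fraction of a spherical aggregate
that can touch the scaffold, $C=10$ is a solid substrate, and
porosities above 90% mean the aggregate falls through the gaps — the
conversion then returns $C=1$ with a non-adherence warning rather than
an error, so porosity scans degrade gracefully.

Two conventions are deliberate choices:

* **Compound bounds.** Optimization box constraints multiply each
  experimental-rate bound by the extreme of its effect product,
  computed from the effect formulas at full precision (not from rounded
  tabulations). The proliferation product $f_5 f_6 f_{10}$ is the one
  exception: its operating cap is fixed at 11.81, the model's
  calibration constant for that product. The product of the individual
  factor maxima is $\approx 10.95$ (the factors peak at different
  oxygen levels), so the cap is a joint convention carried with the
  rate table; `compound_rate_bounds()` documents and implements it.
* **Scaffold attenuation of diffusion.** Dense scaffolds restrict flow
  under the aggregate. The gas flux is multiplied by the near-unity
  decreasing contact effects — $f_{11}(C)$ for oxygen, $f_{12}(C)$ for
  waste — which are the two functions shaped as mild diffusion
  penalties. An alternative convention (oxygen flux $\times f_{10}$,
  waste $\times f_{11}$) is available via `attenuation = "f10f11"` for
  sensitivity checks; no headline result depends on the choice.

## Geometry, flux and the area conversion

The aggregate is a sphere of constant density anchored at 4500 cells for
radius 0.5 mm, giving $R = (T/3.6\times 10^7)^{1/3}$ cm and the imaged
cluster-area conversion $N = 36000\,(A/\pi)^{3/2}$ (counts rounded half
away from zero). The flux is the lumped 1-D expression
$\Phi = D_\text{gas} \cdot \tfrac{760}{100} \cdot (\text{air} -
\text{local}) \cdot 5.1737\times10^{-8} \cdot 60 / d \cdot \pi R^2$,
with diffusion coefficients $3.0\times10^{-5}$ (O$_2$) and
$2.5\times10^{-5}$ (CO$_2$) cm$^2$/s and $d = H - R$ the medium column
above the aggregate centre.

Defaults that are package conventions, not measurements (override in
configuration when calibrated values exist):

* medium volume 2.4 cm$^3$ in a 9.6 cm$^2$ well;
* per-cell metabolic rates $u = (2, 1.5, 1)\times10^{-9}$ %/min/cell
  with $w_i = u_i \cdot 2.5/3.0$, honouring the stem > progenitor >
  differentiated consumption ordering. Note these magnitudes are
  inconsistent with the flux constants at equilibrium population sizes:
  the diffusion flux can only balance per-cell consumption around
  $10^{-14}$ %/min/cell, so `solve_air_levels()` reports infeasibility
  with the defaults and any flux-balance study should calibrate $u_i$
  first. No package result outside that helper depends on $u_i$, and
  gas drift over a 12-day run is negligible either way.

## Equilibria and stability

For the `pd` variant everything is closed-form: a positive fixed point
exists iff $2p_2 > \beta + d_2$ (a transcritical bifurcation — below
threshold all cultures decay to the stable extinction state), with
$T^* = 2p_2/(\beta+d_2) - 1$, and it is globally stable within the
invariant box $P \le 2p_2/(\beta+d_2)$,
$D \le 2p_2 d_2/(\gamma(\beta+d_2))$.

For `spd`, after eliminating $D = d_2 P/\gamma$, the fixed points are
intersections of two hyperbolic nullclines in the $(P, S)$ plane.
`spd_asymptote_fixed_point()` intersects their large-$P$ asymptotes,
giving explicit approximate equilibria; `spd_numeric_fixed_point()`
refines them:

1. reduce to a scalar equation in $P$ along the $P$-nullcline, scan
   $10^{\pm4}$ around the asymptote $P^*$ on a logarithmic grid, and
   bracket sign changes with `uniroot`;
2. among scalar roots take the one nearest the asymptote value
   (tie-break in log distance), then polish with damped Newton on the
   full 3-D system using the analytic Jacobian (residual below
   $10^{-10}$ relative to the population and rate scales);
3. if no root brackets, fall back to relaxation along the flow (the
   positive equilibrium is attracting in practice) and re-polish.

The root-nearest-the-asymptote tie-break matters: at the extreme
parameter sets that independently maximise $P^*$ or $D^*$, the asymptote
intersection is *not* close to the true nullcline intersection, and the
Jacobian evaluated at the tabulated (asymptote) equilibrium has an
unstable direction while the true intersection is elsewhere and stable.
The stability verdicts quoted for those tabulated equilibria are
therefore computed at the asymptote points, which is also what the test
suite asserts.

Extinction-state stability uses the Routh–Hurwitz conditions
($2p_1 + 2p_2 < \alpha+\beta+d_1+d_2+r$ and
$(2p_1-\alpha-d_1)(2p_2-\beta-d_2) > (2p_1-\alpha)r$), cross-checked
against eigenvalues of the analytic Jacobian on hundreds of random
draws. Eigenvalue real parts within $10^{-12}$ of zero are reported as
`"marginal"`, never silently rounded.

## Optimization conventions

* **Waste and contact.** $W=5$ and $C=3.75$ throughout environment
  optimization. $W=0$ would be mathematically optimal, but 5% CO$_2$
  buffers the medium and costs little in the effect values; $C=3.75$
  is where the proliferation effect $f_{10}$ peaks. Both are arguments,
  not constants.
* **Oxygen search.** Dense scan (default $10^4+1$ points) over
  $[0, 100]$ plus Brent refinement of the best bracket; the optimum is
  invariant to grid refinement below $10^{-3}$. Objective values come
  from the fast asymptote fixed point; the reported optimum is then
  re-evaluated with the numeric fixed point and both are returned.
* **Interior optima.** $P^*$ is maximised at an intermediate $d_1$
  (stem cells live longest — keep a reservoir) and $D^*$ at an
  intermediate $d_2$ (differentiation is terminal — don't drain the
  progenitor pool). `interior_optimum()` uses a 1000-point scan plus
  Brent to relative tolerance $10^{-6}$; for the `pd` variant the
  closed-form $d_2^*$ is evaluated alongside as a cross-check. For the
  differentiated-cell objective, $d_1^*$ is determined first (under the
  progenitor objective, as the optimal sets share it) and $d_2^*$
  sequentially after it; a joint search was considered and rejected
  because the sequential order matches how the optimal sets are
  defined and the joint optimum differs negligibly here.
* **Conditional entries.** At the progenitor-optimal co-parameters the
  reversion rate has an interior optimum just above the bottom of its
  range (within the lowest 1%), not strictly below it;
  `sensitivity_signs()` reports the honest `interior-max`, while
  `optimal_compound_rates()` keeps $r$ at its minimum — the convention
  under which the reference equilibria were tabulated.
* **Sensitivity classification.** Endpoint comparison plus a
  1000-point scan with Brent refinement; `no-effect` when the relative
  spread is below $10^{-10}$ (golden search alone can miss a narrow
  interior peak on a range four orders of magnitude wide).

## Simulation

`deSolve::ode` with `lsoda` (stiff-capable), relative tolerance
$10^{-8}$, absolute tolerance $10^{-8}$. The right-hand side is
evaluated with populations clamped at zero so that adaptive trial steps
probing marginally negative states stay well-behaved; after
integration, states below $-10^{-6}$ cells abort with an error and
smaller negatives are zeroed. Gas variables are hard-clamped to
$[0,100]$ with the derivative zeroed at the saturated boundary. Output
is daily by default (configurable); a 12-day culture is 17,280 minutes.

## The synthetic-data generator

No public repository of daily aggregate-area measurements exists, so
every pipeline stage is exercised on synthetic data. The generator
simulates a scenario, converts totals to imaged cluster areas through
the spherical geometry, and applies measurement noise — by default
mean-one multiplicative lognormal (areas are positive and errors scale
with size; `sd` is the relative scale, default 5%, a convention since
the real assay's noise is unreported), with an additive-Gaussian option
for robustness checks. Sampling mimics the reference cadence (every
second day, days 0–12). All randomness flows through explicit seeds and
generation does not disturb the caller's RNG stream.

What it emulates: growth-curve shape, the area/cell-number geometry,
size-proportional measurement error. What it does not: imaging
segmentation artefacts, aggregate merging/splitting, scaffold
heterogeneity, day-to-day culture drift. Passing recovery tests
therefore show internal consistency of the inverse problem, not
robustness to those real-world effects.

**Identifiability of the contact rate.** Under the standard scenario
(5000-cell progenitor seed, 12 days) the simulated area series spans
only about 2% across the admissible contact range — the population is
near its crowding-limited plateau, so $C$ is effectively unidentifiable
at 5% measurement noise. The noisy recovery study in the test suite
therefore uses an identifiability-oriented design: a 100-cell seed
still in its growth phase (the low end of the continuum-validity range)
with daily imaging, where the growth curve carries usable information
about $C$. Noise-free recovery works under either design. The fitted
residual is a plain least-squares distance on areas, minimised by a
25-point scan over $[1,10]$ plus Brent refinement (tolerance
$10^{-3}$); the scan guards against the two-sided ambiguity around the
$f_{10}$ peak at $C=3.75$, and a flat or irreducibly large residual is
flagged as non-identifiable.

## Known limitations

* Fiber diameter, pore size and topography are not modelled — only
  their porosity summary through $C$.
* The flux is a lumped 1-D expression; there is no spatial oxygen
  gradient inside the aggregate, which becomes questionable for radii
  beyond a few hundred micrometres.
* Baseline rates were calibrated from sparse data; quantitative
  population sizes are not expected to match culture measurements,
  though the qualitative orderings (porosity and oxygen effects,
  overshoot of the two-stage strategy) are reproduced by the scenario
  suite.
* Stochastic effects at small populations are outside scope; results
  involving fewer than ~100 cells should not be trusted.
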