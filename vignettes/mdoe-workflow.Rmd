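---
title: "Model-assisted DoE for fed-batch bioprocesses: models, uncertainty and design ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-assisted DoE for fed-batch bioprocesses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mdoebox)
```

This vignette is the package's account of the science it implements: the
mechanistic process model and its assumptions, the uncertainty model, the
design-planning and ranking machinery, the numerical choices, and what the
bundled synthetic studies can and cannot tell you about real data.

## 1. The structured six-compartment process model

### States and compartments

The reference model (`yeast_model()`) tracks concentrations (g/l) of
glucose, ethanol, a lumped nitrogen source, ethyl acetoacetate (EAA) and
(S)-ethyl-3-hydroxybutyrate (E3HB), six biomass compartments, the reactor
volume V (l), and cumulative O2 consumed / CO2 produced (mol).  Total dry
cell weight is the sum of the compartments:

* **Xpri** — autocatalytically active biomass: carries all substrate
  uptake and growth;
* **Xp** — product-forming biomass: carries the biocatalytic EAA
  reduction; fed from Xpri by first-order maturation (`k_xp`);
* **Xs / Xsi** — structurally active / inactive biomass; Xs can be
  re-activated into Xpri when glucose is available (`k_act`, gated by a
  steep glucose sigmoid);
* **Xi** — biocatalytically inactive biomass, produced from Xpri by
  stress-driven inactivation (`k_inact`);
* **Xd** — dead biomass, fed from all living pools by stress-driven
  mortality (`k_d`).

The wiring of the compartments (which pool converts into which, and what
gates each transfer) is this package's own design: the compartment names
and their metabolic roles are fixed, the transfers are first-order with
double-sigmoid stress factors (ethanol, EAA).  Any alternative wiring can
be supplied through the model plug-in contract (`is_mdoe_model()`): a
model is a list with state names, a bounded flat parameter table, a
`make_rhs(params, feeds, env)` factory, an `observe()` hook for derived
observables, and carbon fractions for the mass-balance audit.  Everything
downstream (calibration, design simulation, ranking) only uses that
surface — the tests exercise it with a deliberately trivial single-feed
toy model (`toy_model()`).

### Kinetics

Uptake rates are Monod terms multiplied by double-sigmoid modifiers,

$$rS = rS_{\max}\frac{S}{K_s+S}\prod_i f_{\mathrm{Dsig}}(x_i),$$

$$f_{\mathrm{Dsig}}(x)=\Big(Y_l+\frac{Y_{mid}-Y_l}{1+e^{-K_{sl}(x-X_{50,l})}}\Big)\Big(1+\frac{Y_h/Y_{mid}-1}{1+e^{-K_{sl}(x-X_{50,h})}}\Big).$$

The double sigmoid gives three plateaus (low/mid/high) with two logistic
transitions; we implement the shared-slope form as the primary
parameterization and expose an optional separate slope `K_sl_h` for the
upper flank, since both conventions are in circulation.  Four modifiers do
the metabolic work:

* *glucose overflow* (Crabtree): the fermentation pathway switches on as
  glucose rises past `crab_X50l` (default 0.6 g/l); the oxidative pathway
  loses capacity at very high glucose;
* *ethanol inhibition*: all uptakes shut down around `etoh_inh_X50`
  (default 25 g/l, full inhibition ~15 g/l higher); a second, right-shifted
  sigmoid (`etoh_stress_X50`, 38 g/l) accelerates inactivation and death;
* *EAA inhibition* (biocatalysis): uptake and conversion fall beyond
  0.5 g/l, stress rises beyond ~0.8 g/l — the reason EAA feeding must be
  tightly controlled;
* *pH*: a low/optimum/high profile with transitions at `pH_X50l` (3.8) and
  `pH_X50h` (6.6), matching a yeast optimum near pH 5.  pH, temperature
  and DO are exogenous constant setpoints (the experiments this mimics
  controlled them); they never appear as dynamic states.

### Stoichiometry

Every pathway is an elementally balanced conversion
$$C_xH_yO_z+\nu_1\mathrm{O}_2+\nu_2\mathrm{H}_g\mathrm{O}_h\mathrm{N}_i\to\nu_3\mathrm{C}_a\mathrm{H}_b\mathrm{O}_c\mathrm{N}_d+\nu_4\mathrm{CO}_2+\nu_5\mathrm{H}_2\mathrm{O},$$
with free coefficients solved from the C/H/O/N balances
(`balance_pathway()`) and mass yields $Y_{i/S}=\nu_i\,MW_i/MW_S$.  The
reference model carries four pathways: oxidative growth on glucose (the
biomass coefficient is the free degree of freedom, set by the yield
parameter `Y_XS_ox`), overflow fermentation (glucose → 2 ethanol + 2 CO2,
fully determined), oxidative growth on ethanol (`Y_XS_et`), and the EAA →
E3HB reduction with a fixed glucose co-substrate coefficient
(`nu_glc_bc`, default 0.25 mol/mol) supplying the reducing equivalents.
Biomass is the standard C-mol formula CH1.8O0.5N0.2; the yeast-extract +
peptone nitrogen pool is lumped into assimilable-ammonia equivalents
(H3N) with a configurable fraction per gram (default 0.12 g/g) — the data
this emulates feed both together and report no separate kinetics.
Because every pathway closes elementally, total carbon
(pools + cumulative CO2) is conserved up to solver error; the test suite
audits this on every growth run.

### Mass balances and integration

Each component obeys
$$\frac{dc_i}{dt}=rc_i^+X_v-rc_i^-X_v+c_{i,feed}\frac{F_{c_i}}{V}-c_i\frac{F_{V,in}}{V},\qquad \frac{dV}{dt}=\sum_k F_k.$$

Feeds are constant, linearly rising, or pulsed.  The linear ramp is
implemented exactly as $F(t)=F_{end}/t_{end}\cdot(t-t_{start})$ (zero
before $t_{start}$); note this reaches
$F_{end}(t_{end}-t_{start})/t_{end}$, not $F_{end}$, at $t_{end}$ — the
alternative convention is available as
`ramp_convention = "reach_Fend_at_tend"`.  Flow rates are accepted in
ml/min (pump units) and converted internally (× 0.06 l/h).

Numerical choices:

* stiff-capable adaptive integration (`deSolve::ode`, lsoda) with
  `rtol = 1e-7`, `atol = 1e-9`.  At 1e-6 the accumulated global error of a
  pure-dilution run is a few 1e-6 relative — too close to the 1e-6
  accuracy the simulator promises — while 1e-7 gives ~1.5e-7 at
  unchanged runtime, so 1e-7 is the default;
* integration restarts at every feed-window edge and pulse time, so rate
  discontinuities never cross a solver step; pulses are applied as exact
  volume/concentration updates between segments;
* concentrations are clamped at zero inside the rate evaluation only;
  trajectories are clamped after the fact and a warning is raised if any
  state dips below −1e-6 g/l;
* the trajectory's volume is cross-checked against the analytic feed
  integral (`feed_volume()`), and the respiratory quotient is offered both
  as interval (quasi-instantaneous) and cumulative ratio, with an `NA`
  marker where no oxygen was consumed.

### Reference parameter values

The default parameter vector (uptake maxima, half-saturations, yields,
transfer rates, sigmoid midpoints — see `yeast_model()$params` for units
and bounds) is this package's own reference parameterization, chosen once
so that the bundled scenarios behave like a Crabtree-positive yeast
fed-batch: mostly oxidative growth at moderate feeds (RQ slightly above
1), overflow ethanol at high glucose, growth arrest near 40–50 g/l
ethanol, biocatalysis poisoned above ~0.5 g/l EAA.  They are defaults to
calibrate away from, not literature constants.

## 2. Monte-Carlo uncertainty quantification

Measurement noise is modelled as independent normal with the dataset's
per-point standard deviations (falling back to 5 % relative), 5 % on
initial values and setpoints (pH, feed rates, feed concentrations), and
10 % on the unobserved split of the initial biomass over the six
compartments (`noise_spec()`).  Each of `n_fits` cycles perturbs
*everything* — measured series, initials, setpoints, compartment split —
re-simulates under the perturbed conditions and re-fits the free
parameters; the fitted vectors form the parameter ensemble, summarized by
medians and 10/90 % quantiles (R-7, i.e. linear interpolation at
$h=(n-1)p+1$ — the same definition used everywhere in the package).
Draws that would make a non-negative quantity negative are redrawn
(truncated normal) rather than clipped, so no artificial probability mass
accumulates at zero; the perturbed compartment split is renormalized.

The fit minimizes the weighted RMSD
$$RMSD=\sqrt{\sum_i\frac{(y_{s,i}-y_{m,i})^2}{n}k_{weighting}},$$
with $k_{weighting}=0.5$ for dry-cell-weight points above 100 g/l and 1
otherwise.  Because the observables carry different units and magnitudes,
residuals are normalized per observable by the mean absolute measured
value before pooling (switchable off with `normalize = FALSE`); without
this, a pooled multi-observable RMSD is unit-inconsistent.  Fit quality is
reported as $R^2=1-\sum(y_i-y_{s,i})^2/\sum(y_i-\bar y)^2$, which is 1 for
a perfect fit and negative when the data mean beats the model.

The optimizer is a bounded derivative-free simplex search: Nelder–Mead on
logistic-transformed coordinates (so box bounds are enforced smoothly),
with multi-starts jittered 10 % around the nominal values; a
zero-iteration budget degenerates to evaluating the start point, which
the tests use to pin the optimizer contract.  Ensemble runs derive one
seed per cycle from the base seed, so the whole ensemble is reproducible
bit-for-bit.  Parameters that are expensive and separable (e.g.
pH-related constants identified from dedicated pre-experiments) can
simply be left out of `free` and kept at their previously fitted values —
that is the intended way to stage the calibration.

Defaults: `n_fits = 30`, `n_starts = 3`, `maxit = 150`.  The number of
fits is a budget choice, not a statistical one; at 30 fits the 10/90 %
band of a well-identified parameter is stable to a few percent, and the
package's own recovery experiment (synthetic growth study, 5 % noise,
five free parameters) puts the known truth inside the band for all five
with a median parameter error of ~7 %.

## 3. Planning the design

`plan_design()` draws `n_random` uniform points in the factor box
(optionally rejection-filtered by a feasibility predicate), min–max
scales every factor to [0, 1] so units cannot dominate the distance, runs
k-means (10 random restarts, MacQueen; Hartigan–Wong trips its
Quick-TRANSfer limit on large uniform clouds) and returns the k cluster
centers in factor units.  Cluster centers of a uniform cloud are a
space-filling design: in the package's own benchmark the 29-point k-means
design beat a 29-point random design on worst-case distance-to-nearest
in 100 of 100 seeded repetitions.  The default cloud is 1e6 points; tests
and the acceptance script use 1e4–1e5, which is distributionally
equivalent for k ≤ 29 and much faster.

## 4. Simulating the planned experiments

Each design point is mapped onto the scenario through declarative
setpoint paths (`maps_to`: e.g. `feed.glc.F_end`, `pH`), so ramped-feed
growth studies and constant-feed biocatalysis studies use the same
machinery.  Parameters are drawn by Latin Hypercube Sampling over the
ensemble's per-parameter [q10, q90] box (`lhs::randomLHS`: exactly one
draw per equal-width stratum per dimension).  Independent-per-dimension
draws ignore ensemble correlations — deliberately, to match the interval
description of the uncertainty; `mode = "members"` resamples whole
ensemble members instead and preserves correlations, which is the safer
choice when parameters are strongly collinear.  Each point is simulated
once per draw (default 30), the trajectory is reduced to a scalar
response (`value_at_time` or `max_over_time`; for the growth study the
default is the dry cell weight at 48 h, with the maximum over time
available), and the point is summarized by the response mean r̄ᵢ and the
10–90 % width νᵢ.  Failed simulations are excluded but counted; a point
with more than 20 % failures is flagged.

## 5. Desirability ranking and response surfaces

With L/U the anchors over all planned points,
$d(\bar r_i)=(\bar r_i-L)/(U-L)$ rewards high mean response,
$d(\nu_i)=(\nu_i-U)/(L-U)$ rewards low variability, and
$D_i=w_1d(\bar r_i)+w_2d(\nu_i)$ with $w_1+w_2=1$ (checked hard; defaults
0.8/0.2) combines them into a risk-aware score.  Only linear min–max
rescaling is offered — no one-sided or target-value desirability shapes.
Degenerate anchors (all responses equal) set all desirabilities to 1 with
a warning rather than dividing by zero.  Ranking ties break on lower
`exp_id` for reproducibility; the top `n_select` (default 4) points are
the recommended experiments.  A quadratic response surface (intercept,
linear, two-way interactions, squares) is fitted to Dᵢ by OLS for
visualization and exported as contour grids over each factor pair, other
factors held at the best point's values; selection always uses the raw
Dᵢ, never the surface.

## 6. The synthetic studies, and what the tests do and do not show

`generate_synthetic_study()` simulates a ground-truth scenario, samples
observables every 2–4 h, applies the noise model, and returns dataset plus
truth.  Shape "S1" mimics a growth study — 0.70 l, 2 g/l inoculum,
15 g/l initial glucose, glucose (400 g/l) and nitrogen feeds ramping to
their endpoint rates between 1 and 48 h, factors F_Glc ∈ [0.1, 1],
F_N ∈ [0.05, 0.6] ml/min, pH ∈ [3, 7], biomass response.  Shape "S2"
mimics a biocatalysis study — 0.64 l, 30 g/l directly inoculated biomass,
constant pure-EAA (1021 g/l), glucose and nitrogen feeds
(F_EAA ≤ 0.04, F_Glc ≤ 0.2, F_N ≤ 0.03 ml/min), product response.

The generator reproduces the *statistical* structure of such experiments
(sampling schedule, noise magnitudes, unobserved compartment split) under
the *same* model family that is being fitted.  Passing recovery tests
therefore demonstrates that the estimation machinery is consistent and
correctly propagates uncertainty — not that the reference model is an
adequate description of any particular organism: there is no model
mismatch, no autocorrelated sensor drift, no missing-at-worst data, and
real cultivations will violate all three.  The end-to-end test uses the
toy model with a constructed unimodal optimum (response mean peaks at
mid-range feed, response variance grows quadratically away from it) and
checks that the ranking puts a middle-third design point first in ≥ 90 %
of seeded runs — a functional test of the whole chain, again not a claim
about biology.

Problem sizes in the shipped tests are scaled for a laptop-class run:
30-fit ensembles with single-start, 120-iteration searches for the
recovery experiment; 1e4–2e4-point clouds for the planner; 15 × 15
(points × simulations) for the end-to-end study; 100 seeded repetitions
for the space-filling benchmark.  All are configuration values, not code
constants.

## 7. Known limitations

* No gas–liquid mass transfer (kLa), temperature dynamics, or pH
  titration chemistry: DO, temperature and pH are constant setpoints.
* The compartment wiring is one defensible choice among several; nothing
  in the data the package generates can distinguish, e.g., autocatalytic
  growth of Xp from maturation out of Xpri.  Use the plug-in contract to
  test alternatives.
* LHS over per-parameter intervals ignores ensemble correlations (see
  `mode = "members"` for the alternative).
* The local simplex search offers no global-optimization guarantee;
  multi-starts mitigate, not eliminate, local minima.
* Ensemble spread is an uncertainty heuristic, not a posterior: there is
  no likelihood, no MCMC, and no identifiability analysis beyond the
  spread itself.
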