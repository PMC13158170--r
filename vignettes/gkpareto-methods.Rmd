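---
title: "Batched ADMM planning for Gamma Knife radiosurgery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batched ADMM planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The planning problem

Gamma Knife radiosurgery delivers focal radiation through sources grouped
into 8 sectors, each of which can be set to one of 3 collimator sizes.  A
plan is a set of shots: isocenter positions with per-sector collimator
states and irradiation times.  With the isocenter positions fixed, the dose
at any point is linear in the sector times $t(i,s,c) \ge 0$,

$$ d(v) \;=\; \sum_{i,s,c} \phi_{i,s,c}(v)\, t(i,s,c), $$

where $\phi_{i,s,c}$ is the precalculated dose-rate kernel (Gy/min) of
isocenter $i$, sector $s$, collimator $c$.  `gkpareto` scalarizes the four
clinical goals into one linear objective with weights
$(w_T, w_S, w_{LD}, w_{BOT})$:

* target underdose: $w_T \sum_{j \in \text{target}} (D_{presc} - d_j)_+$
  (drives coverage),
* shell overdose: $w_S \sum_{j \in \text{shell}} (d_j - D_{presc})_+$
  (drives selectivity),
* low-dose spillage: $w_{LD} \sum_{j \in \text{LD}} (d_j - D_{LD})_+$
  (drives the gradient index),
* beam-on time: $w_{BOT} \sum_i \tau_i$, where $\tau_i \ge
  \sum_c t(i,s,c)$ for every sector $s$ of isocenter $i$.

Dose points are sampled from the target surface and interior, a 2 mm shell
outside the target, one or more low-dose volumes, and OAR surfaces; OAR
maximum doses are hard constraints.  The penalties are *sums* over points
(not means): this is what makes the relative importance of the beam-on-time
term shrink as cases grow, and is the reason for the BOT column scaling
below.  Each weight vector yields one Pareto-optimal plan; the planner's
two sliders $(s_{LD}, s_{BOT}) \in [0,1]^2$ index the weight grid.

## The dual linear program

The solver works on the LP dual,

$$ \min_x\; c^\top x \quad \text{s.t.}\quad A x \le b,\; 0 \le x \le u, $$

with one dual variable per dose point ($\alpha$ target, $\beta$ shell,
$\gamma$ low-dose, $\delta$ OAR) plus 8 sector variables $\mu(i,s)$ per
isocenter, and 25 rows per isocenter: one per $t(i,s,c)$ (24) plus one per
$\tau_i$.  Thus $m = 25\,n_{iso}$ and $n = N_{points} + 8\,n_{iso}$.  The
dose levels appear in $c$ ($-D_{presc}$ on $\alpha$, $+D_{presc}$ on
$\beta$, $+D_{LD}$ on $\gamma$, $+D_{OAR}$ on $\delta$, 0 on $\mu$), the
influence matrices in $A$, and the objective weights *only* in the bounds:
$u = (w_T, w_S, w_{LD})$ on the $\alpha/\beta/\gamma$ columns ($+\infty$ on
$\delta$ and $\mu$, since OAR constraints are hard and carry no weight) and
$b = w_{BOT}$ on the shot-time rows (0 on the others).  Because $A$ is
shared, hundreds of weight vectors differ only in the bound columns $B$ and
$U$ — this is what makes batching possible.  The treatment plan is
recovered from the converged scaled dual variable of the $Ax \le b$ block
as $\rho\,y^\ast$ (un-scaled by the row normalization); its rows split into
the $t(i,s,c)$ and $\tau_i$.  Strong duality of this construction is
audited in the test suite against an independently assembled primal LP.

## Batched ADMM

Splitting $x$ into box-projected copies gives the three-step scaled-form
iteration: a coupled least-squares step that reduces, via the Schur
complement $S = AA^\top + I$, to

$$ v^k = S^{-1}\!\left[A\,(z_1^k - y_1^k - c/\rho) - z_2^k + y_2^k\right], $$

followed by element-wise clipping of $z_1$ to $[0, u]$ and $z_2$ to
$(-\infty, b]$, and a dual ascent step.  $S$ is fixed across iterations,
weight vectors and both optimization passes at fixed $A$, so its explicit
inverse is computed once (always in double precision) and cached; each
iteration is then only matrix products, additions and clips, batched over
all weight-vector columns.  All iterates start at zero.  A fixed iteration
budget (default 3000 per pass) replaces adaptive stopping: it keeps the
batch synchronized and the runtime predictable.  Iterations run in IEEE
single precision by default (double is available); the package checks that
full dose distributions from single-precision iterations agree with
double-precision ones to within 0.5% or 0.05 Gy per dose point.

Residual traces (primal $\|x - z\|$, dual $\rho\|z^{k+1}-z^k\|$, each
normalized by the current iterate norms) are recorded every 10 iterations.

## Preconditioning and step size

Three transforms standardize the LP before iterating; all are exact
equivalence transforms whose effect is undone during plan recovery:

1. **Row normalization.**  Rows of $A$ are scaled to unit Euclidean norm
   (with $b$ scaled identically), which fixes $\operatorname{diag}(S) = 2$
   and puts all off-diagonal entries of $S$ in $[-1, 1]$.
2. **BOT column scaling.**  The $\mu$ columns are multiplied by
   $\beta = (N_{TS} + N_{TI} + N_S + N_{LD}) / 2000$ (OAR points excluded —
   they carry no objective term), counteracting the shrinking relative
   weight of the BOT columns in large cases.  This is a change of variables
   $\mu' = \mu/\beta$; the recovered times are unchanged.
3. **Step size.**  One $\rho$ per weight vector from the rule
   $\rho = 2.5\times 10^{-3}\, w_{0,BOT} / w_{BOT}$, where $w_{0,BOT}$ is
   the lowest allowed BOT weight.  The rule's base constant is tied to the
   unit conventions of the clinical formulation it was tuned for; this
   package's Gy/minute/per-point scales differ by one overall factor, so
   `solve_batch()` multiplies the rule by a formulation-scale constant
   `rho_scale` (default 5600).  That constant was calibrated once, before
   any validation statistics were computed, by the same procedure used to
   tune the original rule: a grid search over $\rho \in \{0.1/2^n\}$
   against the exact LP oracle on validation phantoms at 2000 iterations.
   The calibration reproduced the rule's qualitative structure — the
   optimal $\rho$ scales as $1/w_{BOT}$, is insensitive to the other
   weights, and sits in a shallow optimum more than a decade wide — so the
   single factor is stable across case sizes and weights.

## Slider-to-weight map

The clinical map from slider positions to weights is not public.  The
package fixes $w_T = w_S = 1$ and maps each slider log-linearly onto its
weight range, by default $w_{LD} \in [0.05, 2]$ and $w_{BOT} \in [5, 150]$.
The BOT range was chosen once, via exact-oracle sweeps on validation
phantoms, so that the slider's ends span clinically meaningful trade-offs
under sum-form penalties: at $s_{BOT} = 0$ the BOT term is a light
regularizer (coverage $\approx$ 0.95, generous beam-on time), at
$s_{BOT} = 1$ it buys a markedly shorter treatment at a visible coverage
cost, and no slider corner collapses to the empty plan.  A 21x21 grid
corresponds to slider steps of 0.05 (441 weight vectors).

## Two-pass optimization and overlap sampling

Low-dose control focuses effort where the dose is near the threshold
$D_{LD}$ (default $0.5\,D_{presc}$, aligning with the half-prescription
isodose of the gradient index).  In the **first pass** the low-dose points
are sampled from a geometric expansion of the target: the band between
$0.2\,r_{\mathrm{eff}}$ and $0.6\,r_{\mathrm{eff}}$ beyond the target
surface (margins configurable), which is weight-independent, so one shared
point set serves the whole batch.  In the **second pass** each weight
vector gets its own volume: the voxels outside the target whose first-pass
dose lies in $[D_{LD}, D_{LD} + \Delta)$, with $\Delta = 0.15\,D_{LD}$ by
default ($\Delta$ is a package choice; an instance whose band is empty
falls back to the first-pass volume so its column stays solvable).

Per-instance volumes would break batching, so the package samples them
non-redundantly: volumes are visited in order of non-increasing target
density $\omega_j = N_{LD,j}/|V_j|$ (ties broken by instance index); at
each step the running point union is thinned to the current density,
thinned points inside the current volume are reused, and only the
not-yet-covered part $V_j \setminus V^\cup_{j-1}$ receives fresh points.
The union $P$ of all per-instance sets forms the low-dose block of the
shared second-pass $A$; instance $j$ assigns upper bound $w_{LD}$ to its
own points and 0 to the rest of $P$, which inactivates them exactly.  The
number of reused points is binomial, so the relative noise in an
instance's point count is at most $\sqrt{(1-r)/(\omega_j |V_j|)} <
1/\sqrt{\omega_j |V_j|}$ — keeping a minimum of a few hundred points per
volume (default cap 250–5000) limits it to a few percent.  The test suite
verifies the expectation and this bound by Monte-Carlo.

Volumes are voxel sets (measure = voxel count x voxel volume); sampled
points are voxel centers jittered uniformly within their voxel, drawn with
replacement so densities above one point per voxel remain possible.

## The synthetic phantom generator

Real planning data (anatomy, the treatment planning system's measured
dose-rate kernels, the clinical isocenter placement) are proprietary, so
the package generates phantoms
that emulate the *attributes* of clinical cases: 1–9 spherical targets
(total volume 0.5–55 cm^3, radius corrected so the voxelized volume matches
the request), an ellipsoidal skull, small spherical OARs placed 2–10 mm
from a target surface, 1 mm isotropic voxels by default.

* **Kernels** are anisotropic Gaussians per (isocenter, sector,
  collimator): widths 2/4/8 mm (half the nominal 4/8/16 mm collimator
  sizes), elongated along fixed per-sector axes, peaks rising with
  collimator size and normalized so 24 sectors at the largest collimator
  deliver the 3 Gy/min calibration rate at the isocenter.  They are smooth,
  positive and collimator-ordered — the properties the solver claims
  depend on — but they are a stand-in, not a beam model.
* **Isocenters** fill each target by a deterministic lattice whose step
  grows with the effective radius ($\max(2.5,\,1.32\,r_{\mathrm{eff}}^{0.56})$
  mm), chosen so counts across the clinical volume envelope fall within
  the clinically reported 17–214 range.
* **Dose points** are sampled per category with density x measure counts
  clipped to the observed clinical min/max envelopes (e.g. 250–5000
  first-pass low-dose points).

What the phantoms do *not* emulate: irregular target shapes, real tissue
heterogeneity, measured beam profiles, or the clinical isocenter optimizer.
Passing validation on this suite therefore demonstrates the *solver* and
*sampling* guarantees (objective agreement with an exact LP solver,
precision policy, sampling statistics) — not dosimetric accuracy on
patients.

## Validation suite and problem sizes

The built-in suite (`validation_suite()`) holds five cases spanning total
target volumes 0.66–8 cm^3 across the three emulated indications (one
small two-OAR case, three single-target cases of increasing size, one
two-target case), each optimized for a 3x3 slider grid.  These sizes are
the package's desk-scale validation choice: they exercise first-pass
constraint matrices from about 425 x 1550 to about 1250 x 2100 while
keeping the full validation (ADMM at 2000 and 3000 iterations, the exact
oracle on every instance, and both-precision two-pass runs) in the
minutes range on one CPU.  In `case_validation()` the 3000-iteration
solve continues the 2000-iteration stream — exactly equivalent to a
fresh longer run, since the iteration state round-trips losslessly — and
the precision comparison reuses the same problem instances.  The exact LP oracle is HiGHS
(`scipy.optimize.linprog`) behind `solve_lp_exact()`; it is cross-checked
in the tests against brute-force vertex enumeration on tiny LPs.

## Numerical choices and degenerate inputs

* Schur inversion via Cholesky, validated by
  $\|S S^{-1} - I\|_{\max} < 10^{-8}$ at build time; a 1-norm condition
  estimate is stored.
* Recovered plans clip small negative entries (below
  $10^{-3}\times$ column maximum, floored at $10^{-6}$ min) to zero;
  larger negatives raise a warning with a count.
* Weighted-sum LPs can have non-unique optima; all quantitative
  comparisons are on objective values and clinical metrics, never on
  argmin identity.  Point-by-point dose comparisons are made only between
  runs that solve the *identical* problem instances (same sampled points).
* Metrics: coverage uses each target's own prescription; selectivity and
  gradient index are reported as NA with a reason code when prescriptions
  differ between targets or the prescription isodose volume is empty.
  Doses are evaluated on a region extending
  $\max(12, 1.4\,r_{\mathrm{eff}})$ mm beyond the targets, which contains
  the half-prescription isodose for the phantom geometries.
* Empty second-pass dose bands fall back to the first-pass volume with a
  warning; zero rows of $A$ (a kernel identically zero on all points) are
  an error naming the offending row.

## Known limitations

* The Gaussian kernel bank makes sector kernels of one isocenter and
  collimator highly collinear, so optimal plans are more degenerate than
  clinical ones; objective-level agreement is unaffected but individual
  sector times are not comparable across solvers.
* Only the wide-$A$ Schur variant ($AA^\top + I$) is implemented; planning
  matrices always have more columns (dose points) than rows.
* Plan sequencing, shot pruning and clinical dose engines are out of
  scope; beam-on time is reported at the 3 Gy/min calibration rate.

```{r}
library(gkpareto)
case <- make_phantom(phantom_spec(1800, n_oars = 1, d_presc = 20, seed = 13))
sweep <- run_two_pass(case, sliders = "3x3", n_iter = 3000, seed = 5)
sweep$metrics
```
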