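# gkpareto

Batched generation of Pareto-optimal Gamma Knife radiosurgery treatment
plans, for medical-physics researchers studying multicriteria inverse
planning and for anyone who needs hundreds of LP-based treatment plans —
one per objective weighting — solved simultaneously rather than one at a
time.

## The problem and the method

With isocenter positions fixed, Gamma Knife inverse planning is a linear
program: the dose at any point is the kernel-weighted sum
`d(v) = Σ φ_{i,s,c}(v) t(i,s,c)` of nonnegative sector times, and the
clinical goals are scalarized with weights `(w_T, w_S, w_LD, w_BOT)` into

```
min  w_T Σ_target (D_presc − d_j)_+  +  w_S Σ_shell (d_j − D_presc)_+
   + w_LD Σ_lowdose (d_j − D_LD)_+   +  w_BOT Σ_i τ_i
s.t. d_j ≤ D_OARmax on organs at risk,   Σ_c t(i,s,c) ≤ τ_i,   t ≥ 0,
```

each weight vector yielding one Pareto-optimal plan.  The package solves
the LP **dual**, `min c'x s.t. Ax ≤ b, 0 ≤ x ≤ u`, where the weights
enter only through the bounds `b` and `u`.  Since the constraint matrix
`A` is shared by every weighting, a whole slider grid is solved at once
with a batched ADMM splitting: the coupled update reduces, via the cached
inverse of the Schur complement `S = AA' + I`, to matrix products and
element-wise clipping, batched over all weight-vector columns.  The plan
of each instance is recovered as `ρ y*` from its converged scaled dual
variable.  A two-pass procedure refines the low-dose objective — pass 2
re-samples low-dose points from the band `[D_LD, D_LD + Δ)` of each
instance's pass-1 dose — with a non-redundant sampling algorithm that
lets heavily overlapping per-instance volumes share one point union.

Preconditioning follows the method's tuning recipe: rows of `A`
normalized to unit norm (diagonal of `S` equals 2), beam-on-time columns
rescaled by `β = (#non-OAR dose points)/2000`, and one step size per
weight vector from `ρ = 2.5e-3 · w0_BOT / w_BOT` (times a single
formulation-scale calibration; see the methods vignette in
`vignettes/gkpareto-methods.Rmd`).

Everything is testable without patient data: a synthetic phantom
generator emulates clinical case attributes (target volumes, OARs,
isocenter counts, dose-point budgets) with Gaussian sector/collimator
dose-rate kernels, and an exact LP solver (HiGHS) serves as the
validation oracle.

## Worked example

```r
library(gkpareto)

# a synthetic 1.8 cm^3 single-target case with one OAR
case <- make_phantom(phantom_spec(1800, n_oars = 1, d_presc = 20, seed = 13))
case
#> gk_case 'case': 1 target(s), total 1809 mm^3, 1 OAR(s), 27 isocenters

# nine plans (3x3 slider grid), two passes of 3000 ADMM iterations
sw <- run_two_pass(case, sliders = "3x3", n_iter = 3000, seed = 5)
sw$metrics
#>   s_ld s_bot coverage selectivity    gi    bot sel_reason gi_reason
#> 1  0.0   0.0   1.0000      0.9486 4.502  30.62                     
#> 2  0.5   0.0   1.0000      0.9778 3.247  54.90                     
#> 3  1.0   0.0   0.9779      0.9994 1.750 116.68                     
#> 4  0.0   0.5   0.9923      0.9750 4.543  29.79                     
#> 5  0.5   0.5   0.9834      0.9911 4.616  29.60                     
#> 6  1.0   0.5   0.8657      1.0000 2.928  60.29                     
#> 7  0.0   1.0   0.8867      1.0000 4.967  28.78                     
#> 8  0.5   1.0   0.8502      1.0000 5.129  28.56                     
#> 9  1.0   1.0   0.6263      1.0000 6.270  26.71
```

Each row is one weight vector: moving the low-dose slider `s_ld` to the
right buys a steeper fall-off (gradient index `gi` drops from 4.5 toward
1.8) at the price of beam-on time; moving the BOT slider `s_bot` buys a
shorter treatment (`bot`, minutes at the 3 Gy/min calibration rate) at
the price of coverage.  `pareto_table(sw$metrics)` flags any dominated
plans; `compare_to_oracle()` and `case_validation()` quantify solver
quality against the exact LP oracle.

A thin command-line front end over the same functions lives in
`inst/cli/gkpareto.R` (`synth`, `sweep`, `plan`, `validate`, `metrics`
subcommands).

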