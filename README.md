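# coexdyn

Deterministic compartmental dynamics of two interacting social contagions —
racism and corruption — treated as transmissible "mind infections" in a
well-mixed community.

## The model

The total population `N` is split into seven classes: susceptible `S`,
corrupted `C`, racist `R`, co-affected `C1` (simultaneously corrupted and
racist), and the recovered classes `R1` (stopped corruption), `R2` (stopped
racism) and `R3` (stopped both). Corruption spreads by standard incidence
and racism by mass action:

    lambda_C = (beta / N) (C + omega1 C1),      lambda_R = alpha (R + omega2 C1),

and the flow is

    dS/dt  = Lambda + theta1 R1 + theta2 R2 + theta3 R3 - (lambda_R + lambda_C + mu) S
    dC/dt  = lambda_C S + sigma1 C1 - (gamma1 + xi lambda_R + mu) C
    dR/dt  = lambda_R S + sigma2 C1 - (eta lambda_C + gamma2 + mu) R
    dC1/dt = eta lambda_C R + xi lambda_R C - (sigma1 + sigma2 + gamma3 + mu) C1
    dR1/dt = gamma1 C  - (theta1 + mu) R1
    dR2/dt = gamma2 R  - (theta2 + mu) R2
    dR3/dt = gamma3 C1 - (theta3 + mu) R3

with recruitment `Lambda`, natural removal `mu`, recovery rates `gamma1`,
`gamma2`, `gamma3`, re-susceptibility rates `theta1`, `theta2`, `theta3`,
reversion rates `sigma1`, `sigma2` out of the co-affected class, and
modification factors `eta`, `xi` (acquisition of the second contagion) and
`omega1, omega2 >= 1` (extra infectivity of the co-affected class). The
derivatives always sum to `Lambda - mu N`, so the region
`Omega = {x >= 0 : N <= Lambda/mu}` is forward invariant.

Next-generation analysis at the contagion-free equilibrium
`E0 = (Lambda/mu, 0, ..., 0)` gives the basic reproduction numbers

    R_r = Lambda alpha / ((gamma2 + mu) mu),   R_c = beta / (gamma1 + mu),
    R_rc = max(R_r, R_c),

with the usual threshold behaviour: `E0` is locally (and, by a linear
Lyapunov function, globally) stable in each submodel when the corresponding
number is below 1, each submodel has a unique endemic equilibrium in closed
form exactly when its number exceeds 1, and the full system undergoes a
forward transcritical bifurcation at the critical corruption transmission
rate `beta* = gamma1 + mu` (center-manifold coefficients `a < 0 < b`).

The package provides, for the full model and both single-contagion
submodels: the right-hand sides and analytic Jacobians, NGM reproduction
numbers, closed-form and Newton-located equilibria, eigenvalue and
Routh-Hurwitz stability reports, sampled Lyapunov decay certificates,
center-manifold bifurcation coefficients, normalized forward sensitivity
indices (elasticities) with threshold scans, a stiff-capable integrator, a
seeded scenario generator, and a discrepancy audit that recomputes the
published headline figures for this model from the closed forms and
tabulates the disagreements instead of asserting them.

## Worked example

```r
library(coexdyn)

p <- reference_parameters(alpha = 1.37, beta = 1.51)  # reference rates
reproduction_number("full", p)
#> <coex_ngm> model = full
#>   spectral radius rho(F V^-1) = 428125
#>   closed form                 = 428125
#>   R_r = 428125, R_c = 88.82352941, R_rc = 428125
```

Both numbers are far above 1 at these transmission rates: a racism
transmission coefficient of 1.37 per contact per year against a susceptible
pool of 5000 makes `R_r` astronomically large under mass action, and
`beta = 1.51` against a mean infectious period of `1/(gamma1+mu) = 59`
years gives `R_c = 88.8`. (The published values 3.51 and 6.03 for the same
inputs are not reproducible from the closed forms; see
`discrepancy_audit()`.)

```r
sensitivity_table(p)
#>   target parameter analytic      fd published consistent
#> 1     Rr    Lambda   1.0000  1.0000     1.000       TRUE
#> 2     Rr     alpha   1.0000  1.0000     1.000       TRUE
#> 3     Rr    gamma2  -0.3750 -0.3750    -0.850      FALSE
#> 4     Rr        mu  -1.6250 -1.6250        NA         NA
#> 5     Rc      beta   1.0000  1.0000     1.000       TRUE
#> 6     Rc    gamma1  -0.4118 -0.4118    -0.546      FALSE
#> 7     Rc        mu  -0.5882 -0.5882    -0.346      FALSE
#> 8     Rc    Lambda   0.0000  0.0000     1.000      FALSE
```

The elasticities of the transmission rates and of recruitment (for the
racism number) are exactly +1: a 10% change in `alpha`, `Lambda` or `beta`
moves the corresponding reproduction number by 10%, which is why the
transmission rates are the natural control targets. Raising the recovery
rates lowers the numbers with elasticity `-gamma/(gamma+mu)`.

A reproducible supercritical scenario, its coexistence equilibrium, and the
agreement with long-time dynamics:

```r
sc <- scenario(42, "supercritical")        # R_r = 4.46, R_c = 4.67
res <- coexistence_endemic_equilibrium(sc$params, seed = 42)
res$found
#> [1] TRUE
round(res$point$state, 2)
#>       S       C       R      C1      R1      R2      R3
#> 1068.66 2054.78 1691.66   96.76   44.25   39.81    4.07
dfe_stability("full", sc$params)$classification
#> [1] "unstable"
```

A command-line front end over the same functions is installed at
`inst/cli/coexdyn` (subcommands `r0`, `equilibria`, `stability`,
`bifurcation`, `sensitivity`, `scan`, `simulate`, `scenario`, `audit`),
reading the 16 rates from a YAML/JSON config file.

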