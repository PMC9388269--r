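---
title: "Methods: a two-contagion coexistence model of racism and corruption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-contagion coexistence model of racism and corruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexdyn)
```

## The model and its assumptions

`coexdyn` treats racism and corruption as two interacting social contagions
spreading in a well-mixed, demographically open community. The population is
divided into seven compartments — susceptible `S`, corrupted `C`, racist
`R`, co-affected `C1`, and three recovered classes `R1`, `R2`, `R3` — with
recruitment `Lambda` (individuals/year) into `S`, uniform natural removal
`mu` (1/year) from every class, and no contagion-induced mortality. Time is
labelled in years throughout; nothing in the mathematics depends on the
unit.

The two incidence mechanisms differ deliberately:

* **Corruption** uses *standard incidence*,
  `lambda_C = (beta/N)(C + omega1 C1)`: the per-susceptible risk depends on
  the *prevalence* of corruption, which is the usual assumption for
  behaviours transmitted through a roughly fixed number of social contacts.
* **Racism** uses *mass action*, `lambda_R = alpha(R + omega2 C1)`: the risk
  scales with the *absolute number* of racist individuals.

`N` in the standard-incidence denominator is the live sum of all seven
compartments, not the equilibrium value `Lambda/mu`; the two coincide only
at steady state. At `N = 0` we define `lambda_C = 0` (no population, no
contacts), so the right-hand side is defined on the whole closed orthant.
An optional switch (`racism_incidence = "standard"`) divides the racism
force by `N` as well, for users who want both contagions
prevalence-driven; every analysis in the package defaults to the
mass-action form.

The modification factors have clear roles: `omega1, omega2 >= 1` make the
co-affected class at least as infectious as the singly affected classes;
`eta` and `xi` scale how easily an already-affected individual acquires the
*other* contagion; `sigma1`, `sigma2` return co-affected individuals to the
single classes; `gamma1`, `gamma2`, `gamma3` are recovery rates and
`theta1`, `theta2`, `theta3` the rates at which recovered individuals
become susceptible again.

Two structural identities anchor all the numerics and are enforced by
tests: the derivatives sum to `Lambda - mu*N` for every state (so
`Omega = {x >= 0, N <= Lambda/mu}` is forward invariant and solutions are
bounded), and every compartment's derivative is nonnegative on its zero
face (so the nonnegative orthant is invariant).

## Reference parameter values

`reference_parameters()` carries the reference rate set used in the numerical
experiments:

| rate | value | meaning |
|------|-------|---------|
| `Lambda` | 50/year | recruitment |
| `mu` | 0.01/year | natural removal (≈100-year residence) |
| `gamma1, gamma2, gamma3` | 0.007, 0.006, 0.008/year | recovery |
| `theta1, theta2, theta3` | 0.3, 0.25, 0.2/year | re-susceptibility |
| `sigma1, sigma2` | 0.6, 0.7/year | reversion from `C1` |
| `eta, xi` | 1.3, 1.2 | second-contagion acquisition factors |
| `alpha, beta` | user-supplied | transmission coefficients |
| `omega1, omega2` | 1 | co-affected infectivity amplification |

No reference values exist for `omega1` and `omega2`; the package defaults
them to 1 (no amplification) and documents that as its own choice rather
than asserting it as part of the reference set. The implied contagion-free
population is `Lambda/mu = 5000`.

## Reproduction numbers

The next-generation decomposition at the contagion-free equilibrium
`E0 = (Lambda/mu, 0, ..., 0)` uses infected compartments `(R, R2)` for the
racism submodel, `(C, R1)` for the corruption submodel, and `(C, R, C1)`
for the full model (the stored `F` and `V` matrices depend on this
ordering; the spectral radius does not). The closed forms are

$$\mathcal R_r = \frac{\Lambda\alpha}{(\gamma_2+\mu)\mu},\qquad
  \mathcal R_c = \frac{\beta}{\gamma_1+\mu},\qquad
  \mathcal R_{rc} = \max(\mathcal R_r, \mathcal R_c).$$

`reproduction_number()` records both the spectral radius of `F V^{-1}` and
the closed form; the property suite checks their agreement to `1e-10`
relative over a thousand random draws and the exact `max` identity.

Note the asymmetry: `R_r` is proportional to `Lambda/mu` (mass action sees
the absolute pool) while `R_c` is independent of it. This is why
plausible-looking transmission coefficients of order 1 produce an enormous
`R_r` at the reference scale — see the audit section below.

## Equilibria

Each submodel has a unique endemic equilibrium exactly when its
reproduction number exceeds 1, obtained in closed form through the endemic
force of infection

$$\lambda_R^* = \frac{(\gamma_2+\mu)(\theta_2+\mu)}{\gamma_2+\theta_2+\mu}
  (\mathcal R_r - 1),\qquad
  \lambda_C^* = \frac{(\gamma_1+\mu)(\theta_1+\mu)}{\gamma_1+\theta_1+\mu}
  (\mathcal R_c - 1).$$

The corruption form is re-derived from the equilibrium balance
`beta = (gamma1+mu) + lambda_C (1 + gamma1/(theta1+mu))` (with
`N = Lambda/mu` at steady state), and the recovered classes follow from
flow balance (`R2* = gamma2 R*/(theta2+mu)`, `R1* = gamma1 C*/(theta1+mu)`).
Every returned equilibrium carries an independently re-evaluated residual
`max|f|`, required to be below `1e-9 max(1, Lambda/mu)` for the closed
forms; both endemic states sum to `Lambda/mu` exactly. Tests confirm the
uniqueness claim against an independent oracle that solves the equilibrium
conditions linearly at a fixed force of infection and scans/bisects the
scalar self-consistency gap.

The full coexistence equilibrium has no tractable closed form (the system
is genuinely nonlinear in seven dimensions), so
`coexistence_endemic_equilibrium()` runs damped Newton iteration with the
analytic Jacobian, seeded in order from (i) a user guess, (ii) the terminal
state of a probing integration, (iii) the superposition of the two embedded
submodel equilibria, and (iv) ten seeded multiplicative perturbations
(`U(0.5, 1.5)` componentwise) of the best candidate. Step lengths are
halved (up to 25 times) until the residual norm decreases; iterates are
projected onto the nonnegative orthant. The internal target residual is
`1e-11 max(1, Lambda/mu)`; a root is *accepted* at `1e-8 max(1, Lambda/mu)`
and labelled a coexistence equilibrium only when every compartment exceeds
`1e-8 Lambda/mu`. Otherwise the best root — typically a boundary
equilibrium — is returned with `found = FALSE`, together with the embedded
racism-only and corruption-only boundary equilibria whenever they exist.

### Above threshold does not mean coexistence

A point worth stressing because it shapes the dynamic tests:
`R_r > 1` and `R_c > 1` do **not** guarantee a coexistence attractor.
Corruption at its endemic level depresses the susceptible pool to
`S* < Lambda/mu`, and because racism incidence is mass action its effective
invasion condition is `alpha S* > gamma2 + mu`, i.e.
`R_r > (Lambda/mu)/S*`. When that fails, trajectories converge to the
corruption-only boundary equilibrium even though `R_r > 1` (the package's
scenario seeds 201 and 202 exhibit exactly this, and the Newton solver
reproduces the boundary attractor to residuals near machine precision).
The dynamic test suite therefore asserts, for supercritical scenarios,
persistence of at least one contagion and agreement between the settled
state and the root-found equilibrium, and requires an interior
`found = TRUE` verdict exactly when the attractor is interior.

## Stability machinery

Jacobians are hand-derived in closed form — including the quotient-rule
terms of standard incidence, where every compartment enters through `N` —
and evaluated numerically; a central-difference oracle
(`h = 1e-6 max(1, |x|)`) checks them to `1e-6` relative at random states.
Submodels return the reduced 3×3 Jacobian over their active compartments.

`classify_local()` uses a relative dead band: with
`tol = 1e-8 * max|eigenvalue|`, a spectrum is stable when every real part
is below `-tol`, unstable when some real part exceeds `+tol`, and marginal
otherwise. The threshold-concordance property (contagion-free point stable
iff the reproduction number is below 1) is exercised on 500 random draws
per model, skipping draws within `1e-6` of the threshold where the verdict
is genuinely ill-conditioned.

`routh_hurwitz_cubic()` implements the classical first-column test for
cubics (`b1 = (a1 a2 - a0 a3)/a1`, `c1 = a3`); a zero pivot (`a1 = 0`)
returns an explicit `"indeterminate"` verdict rather than an epsilon
perturbation — the model never produces that case, and silently perturbing
would hide it if it ever arose. On the racism-endemic characteristic cubic
the Routh-Hurwitz verdict is checked against direct eigendecomposition on
200 supercritical draws.

`lyapunov_gas_check()` turns the global-stability argument into a sampled
certificate. The linear Lyapunov functions `V = R` and `V = C` satisfy
structural bounds on `Omega` that hold for *any* parameters
(`dR/dt <= (gamma2+mu)(R_r-1)R` because `alpha S <= alpha Lambda/mu`;
`dC/dt <= (gamma1+mu)(R_c-1)C` because `S/N <= 1`); below threshold these
bounds certify decay. The check samples `Omega` uniformly (Dirichlet
scaling of the simplex) with an explicit seed and reports both the worst
structural-bound margin (expected nonpositive always) and the worst decay
margin `dV/dt` (nonpositive iff the reproduction number is at most 1);
above threshold the decay violations are reported, not raised. The full
model is rejected: no linear certificate of this form exists for it.

## Bifurcation analysis

At `beta* = gamma1 + mu` the full-model Jacobian at the contagion-free
point has a simple zero eigenvalue provided `R_r < 1` (the racism direction
must be stable; `R_r = 1` simultaneously is a codimension-2 point and is
rejected, as is `R_r > 1`). The right and left null vectors `u`, `v` are
taken from the numeric eigendecomposition (residuals required below
`1e-10` of the Jacobian norm), normalized so that `v·u = 1` with `u_2 > 0`
— the center-manifold coefficient `a` is invariant under the remaining
positive rescaling freedom.

The coefficients use the *full* second-order sums

$$a = \sum_k v_k\, u^\top H_k u,\qquad
  b = \sum_k v_k \sum_i u_i\, \partial^2 f_k/\partial x_i\,\partial\beta,$$

with all Hessians generated analytically from the four nonlinear building
blocks of the right-hand side (two standard-incidence quotients, two
mass-action bilinears) and verified against a directional finite-difference
oracle to `1e-6` relative. Working at the contagion-free point with the
quotient rule kept intact changes individual Hessian entries relative to a
fixed-`N` reading — for instance `∂²f₂/∂x₁∂x₂ = 0` there, because the
`x₁/N` factor is stationary at `x₁ = N` — so the package also reports the
reduced two-term expression `2 v₂u₂(u₁β* + u₃ξα)` for comparison
(`a_reduced`); both are negative, and the verdict (forward bifurcation,
`a < 0 < b`) does not depend on the choice. Similarly `b = v₂u₂` is
reported alongside the `beta*`-scaled variant. One structural fact the
package asserts in its tests: the left null vector necessarily has a
nonzero co-affected component,
`v₄ = v₂(β*ω₁ + σ₁)/(σ₁+σ₂+γ₃+μ)`, forced by the reversion inflow
`sigma1 C1` into the corrupted class; `v₄` is harmless for `a` and `b`
because `u₃ = u₄ = 0` and the corresponding second-order terms vanish at
the contagion-free point.

Across 200 random admissible draws the verdict is forward in every case;
the test is written so that any counterexample would surface as a failure,
not be filtered out.

## Sensitivity analysis

`sensitivity_index()` computes elasticities
`SI(p) = (∂R/∂p)(p/R)` from the closed forms:
`+1` for `Lambda` and `alpha` on `R_r` and for `beta` on `R_c` (exactly —
these parameters enter multiplicatively), `-gamma2/(gamma2+mu)` and
`-(gamma2+2mu)/(gamma2+mu)` for `gamma2` and `mu` on `R_r`, and
`-gamma1/(gamma1+mu)`, `-mu/(gamma1+mu)` on `R_c` (which therefore sum to
−1 exactly). Parameters a target does not depend on get index 0 with an
explanatory note, as does a parameter sitting at 0 (the elasticity scaling
`p/R` vanishes there). Every analytic index is cross-checked against a
central finite difference with relative step `1e-6 p` (absolute fallback
`1e-9`).

`threshold_value()` solves `R = 1` for one rate in closed form
(e.g. `beta = gamma1 + mu`, `alpha = mu(gamma2+mu)/Lambda`, the positive
root of `mu² + gamma2 mu = alpha Lambda` for `mu`), returning `NA` with a
note when the crossing would require a negative rate; tests compare
against a bisection oracle on the closed form. `threshold_scan()` spans
`[0, 2 threshold]` by default — the published figures do not state their
ranges, so the package centres the scan on the crossing.

## Simulator and scenario generator

`coex_integrate()` wraps `deSolve::ode` (default `lsoda`, stiff-capable)
with relative tolerance `1e-8` and absolute tolerance `1e-10`, a default
output grid of 400 intervals, and a default demonstration start of 95%
susceptibles with the remaining 5% split evenly between `C`, `R` and `C1`.
Solver excursions in `[-1e-9, 0)` are clipped to zero before incidence
terms are formed and in the returned samples; the worst pre-clip minimum is
kept in the diagnostics so positivity is checkable. Tests verify the pure
demographic decay closed form, conservation of a population starting at
`Lambda/mu`, boundedness `N(t) <= max(N(0), Lambda/mu)(1+1e-6)`, and that
tightening the tolerances tenfold moves terminal states by less than
`1e-6` relative.

`steady_state()` declares convergence when the span of every compartment
over a trailing window is at most `tol` times that compartment's largest
magnitude over the whole trajectory — a scale-aware criterion that treats
fully decayed compartments as converged instead of dividing by a vanishing
terminal value.

`scenario()` generates the study conditions reproducibly: the slow rates
are jittered by ±10% around the reference set (enough variation to
exercise the code without leaving the regime the reference rates
describe), `Lambda`, `mu`, `eta`, `xi` and the `omega`s stay fixed, and
the transmission coefficients are set by drawing target reproduction
numbers and inverting the closed forms — `U(0.15, 0.7)` per contagion for
subcritical draws (comfortably below threshold, so extinction is
exponential at a usable rate) and `U(1.5, 6)` for supercritical draws
(bracketing the magnitudes reported for the reference scenario). The
regime is re-verified through `reproduction_number()` before the scenario
is returned, and all draws run under a private RNG state so the caller's
stream is untouched.

What the generator emulates is the parameter *regime* of the reference
analysis, not data: there is no demographic stochasticity, no contact
structure, no time-varying rates, and no observation noise. Passing tests
therefore validate the mathematics and the numerics of the deterministic
model, not its adequacy for any empirical population.

`gamma3_sweep()` integrates the full model across a grid of coexistence
recovery rates and records the settled co-affected class; on supercritical
scenarios the terminal `C1` is monotonically non-increasing in `gamma3`
over the examined range 0.54–0.73, matching the qualitative claim the
sweep is designed to probe.

Problem sizes in the shipped test-suite were chosen to keep the full run
around half a minute while still exercising every property at meaningful
scale: 1000 draws for the NGM/closed-form identity, 500 per model for
threshold concordance, 200 for the Routh-Hurwitz and bifurcation suites,
and long-horizon integrations (up to `t = 20000` years) where slow
`O(mu)` modes govern convergence.

## Discrepancy audit

Several headline numbers published for this model cannot be produced from
its own closed forms with the reference rates: the reproduction numbers
3.51 and 6.03 at `alpha = 1.37`, `beta = 1.51` (the closed forms give
428125 and 88.82), the sensitivity entries −0.85, −0.546, −0.346 and a +1
recruitment elasticity for `R_c` (which has no `Lambda` dependence), the
single-parameter thresholds 0.059, 0.508, 0.17 and 0.322 (0.508 would be
consistent only had `beta = 0.518` been used), a sign slip on the
corruption-free eigenvalue `-(theta1+mu)`, and the reduced bifurcation
expressions discussed above. `discrepancy_audit()` recomputes every one of
these quantities at run time and tabulates computed against published with
a per-row consistency flag at printed precision. The three entries that
*are* formula-consistent — the +1 elasticities — are the ones the
acceptance script (`scripts/acceptance.R`) reports.

## Known limitations

* The coexistence equilibrium is found numerically; the solver reports the
  best residual and never claims uniqueness. Multiple interior roots, if a
  parameter regime produced them, would require user-supplied guesses to
  enumerate.
* Global stability is certified only for the submodels and only by sampled
  inequality checking, not symbolically.
* The bifurcation analysis covers the corruption threshold (`beta` as the
  bifurcation parameter) with `R_r < 1`; the racism threshold is analysed
  only through its (closed-form) eigenvalue.
* No fitting to data, no demographic stochasticity, no age/contact
  structure; the model is a mechanistic caricature for policy reasoning
  about transmission and recovery rates.
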