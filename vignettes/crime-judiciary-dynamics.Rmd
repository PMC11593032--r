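---
title: "Modelling organized crime and a corruptible judiciary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling organized crime and a corruptible judiciary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(crimdyn)
```

## The model

`crimdyn` implements a four-compartment nonlinear ODE model of the densities
(persons per area unit) of criminal gang members $G$, non-corrupt judges $J$,
corrupt judges $C$, and prisoners $P$:

$$
\begin{aligned}
\dot G &= \alpha G(\sigma - G) - \delta G J + \beta P\\
\dot J &= \gamma - \eta J - \rho G J\\
\dot C &= \rho G J - \phi C J\\
\dot P &= \delta G J + \phi C J - \kappa P
\end{aligned}
$$

The gang grows logistically with intraspecific-competition coefficient
$\alpha$ (per density per time) towards a carrying capacity $\sigma$
(density) set by rival competition, black-market demand and policing. The
gang–judge interactions are classic Lotka–Volterra contact terms: honest
judges jail gang members at rate constant $\delta$, and gang members co-opt
judges at rate constant $\rho$ (predator and prey swap roles between the two
terms). Honest judges enter at a constant influx $\gamma$ (density per time)
and retire or die at rate $\eta$ per time, so a judicial career lasts
$1/\eta$ on average; there is no judge–judge competition term because judges
act individually under fixed career rules. Corrupt judges are themselves
jailed on contact with honest ones at rate constant $\phi$. Prisoners leave
at rate $\kappa$ per time, and a fraction of releases relapses into the gang
at rate $\beta$, constrained to $\beta \le \kappa$ since relapse cannot
outpace release. All nine parameters are positive, except that $\beta$ and
$\rho$ may be exactly zero.

Whether $\rho$ and $\beta$ are zero or positive is *structural*: it changes
which equilibria exist and which closed forms apply. `classify_case()`
therefore dispatches on exact zero tests — a user who wants the
no-co-optation analysis passes a literal zero, never a small number.

| case | $\rho$ | $\beta$ | equilibria |
|------|-------|--------|------------|
| 1 | 0 | 0 | $E_0$, $E_1$ |
| 2 | 0 | $>0$ | $E_0$, $E_2$ |
| 3 | $>0$ | 0 | $E_0$, $E_3$, $E_4$ |
| 4 | $>0$ | $>0$ | $E_0$, $E_5$, $E_6$ |

$E_0 = (0, \gamma/\eta, 0, 0)$ is the crime-free state, present in every
case. The basic reproduction number is

$$R_0 = \frac{\alpha\eta\sigma}{\gamma\delta},$$

by analogy with epidemic thresholds: it compares the gang's intrinsic growth
$\alpha\sigma$ against the jailing pressure $\delta\gamma/\eta$ exerted by
the equilibrium judge density. Because $R_0$ is a monomial, its elasticities
are exact: $+1$ for $\alpha$, $\eta$, $\sigma$ and $-1$ for $\gamma$,
$\delta$ (`r0_elasticity()`), so proportional interventions on any of the
five constituent rates are equally powerful.

## Thresholds and the backward bifurcation

In case 1, $E_0$ and $E_1$ exchange stability in a transcritical bifurcation
at $R_0 = 1$. Recidivism alone (case 2) lowers the eradication threshold to
$R_0 < 1 - \beta/\kappa$; at total recidivism $\beta = \kappa$ the endemic
gang density reaches the carrying capacity $\sigma$ and eradication is
impossible even with a fully honest judiciary.

With co-optation ($\rho > 0$) the endemic gang density solves a quadratic
$A G^2 + B G + \text{const} = 0$ with $A = \alpha\rho/(\gamma\delta)$,
$B = \alpha(\eta - \rho\sigma)/(\gamma\delta)$, and constant term $1 - R_0$
(case 3) or $H = 1 - R_0 - (\beta/\kappa)(1 + \rho/\delta)$ (case 4). Two
positive roots — a stable upper state and an unstable lower one — appear in
a *backward bifurcation* at

$$r = \frac{4\eta\rho\sigma}{(\eta + \rho\sigma)^2} \le 1,
\qquad r_2 = 1 - \frac{\beta}{\kappa}\Bigl(1 + \frac{\rho}{\delta}\Bigr),
\qquad r_1 = r\, r_2,$$

so that for $r_1 < R_0 < r_2$ (case 4; $r \le R_0 < 1$ in case 3) the stable
endemic state coexists with the stable crime-free state and the outcome
depends on the initial condition. `bifurcation_thresholds()` reports these;
when $(\beta/\kappa)(1+\rho/\delta) \ge 1$ makes $r_2 \le 0$ the set is
flagged "no bistability window" rather than reporting a negative threshold,
since $R_0 > 0$ then trivially exceeds $r_1$.

Numerical choices around the quadratic: a discriminant within $10^{-12}$ of
zero is treated as exactly zero so the saddle-node point (double root) is
stable under floating-point noise; complex roots are returned as `NA` and
the corresponding equilibria flagged `physical = FALSE` but *retained*, so
bifurcation sweeps can draw unphysical branches (the negative-$G$ branch of
$E_1$ below the transcritical point is part of the standard diagram).

```{r}
m <- crime_model(alpha = 6, beta = 30, gamma = 10, delta = 8, eta = 0.1,
                 kappa = 50, rho = 0.1, sigma = 20, phi = 0.2)
summary(m)
```

## Stability: numeric truth, analytic validation

Local stability comes from the eigenvalues of the analytic Jacobian
(`crime_jacobian()`, validated against central finite differences in the
test suite). `stability_numeric()` is the authoritative classifier in every
case; a marginality band of $10^{-9}$ on eigenvalue real parts yields a
`marginal` verdict at bifurcation points instead of forcing a side.

The closed-form eigenvalues are exposed in parallel
(`analytic_eigenvalues()`, `charpoly_coefficients()`): explicit factors plus
quadratic roots for cases 1–3, where they agree with the numeric route to
machine precision, and the cubic
$\lambda^3 + y_1\lambda^2 + y_2\lambda + y_3$ for the endemic states of
case 4. That cubic is derived under $\rho \ll 1$, $\phi \ll 1$ (co-optation
and corrupt-judge jailing are rare events), so case-4 analytic reports carry
an `analytic_regime_ok` flag; the defaults $\rho \le 10^{-3}$,
$\phi \le 10^{-2}$ cover the real-world scenario below
($\rho = 1/40000$, $\phi = 1/100$) and are configurable. Outside the regime
the report is labelled approximate (or refused in strict mode) and the
numeric classifier should be used — which is why it, not the closed form, is
what `summary()`, sweeps and attractor checks consume. The Routh–Hurwitz
determinant $\Delta = y_1 y_2 - y_3$ is strictly positive at the upper
endemic state whenever it is physical, so it can never undergo a Hopf
bifurcation — no limit cycles arise from it; the lower state has $y_3 < 0$
and is always unstable.

## Simulation

`simulate_crime()` integrates with the classic fixed-step 4th-order
Runge–Kutta scheme, default step $dt = 0.01$ time units, recording every
step. Two honesty rules apply: non-finite states abort as divergence, and
any component dropping below $-10^{-6}$ aborts with advice to reduce `dt` —
we prefer a hard failure to silently projecting the state back onto the
positive orthant, which would mask instability. Genuine trajectories of this
model stay nonnegative; material undershoot is always a step-size artefact.

The step size deserves care. The fast "jailing mode" of the linearized gang
equation has rate $\approx \delta J$, and explicit RK4 is stable only while
$dt\,\delta J \lesssim 2.78$. At the figure-scale parameters
($\delta = 8$) an initial judge density of 102 gives $\delta J \approx 816$,
so $dt = 0.01$ sits far outside the stability region and the integration
blows up in a handful of steps; $dt = 0.002$ is comfortably inside and
reproduces the reference limits. The shipped scenarios therefore carry
per-scenario steps: `fig3a`, `fig3b`, `fig3d` use $dt = 0.002$, the others
$dt = 0.01$. Horizons are likewise a numerical choice (none are inherent to
the model): the slowest eigenvalue near the crime-free state at the
figure-scale parameters is $-\eta = -0.1$, so judge-density transients decay
with time constant 10, and a horizon of 100 time units is needed before the
trailing window is quasi-stationary at the default convergence tolerance;
the real-world scenario uses 300 years. All of these runs take well under a
second.

`detect_attractor()` matches the trailing 10% of a trajectory against the
closed-form equilibria: the window must be quasi-stationary (per-component
range within tolerance) and its mean must match a candidate component-wise
within a relative tolerance of $10^{-4}$, with an absolute floor of
$10^{-6}$ for components whose target is zero. `probe_basin()` maps initial
conditions to attractors in the bistable window; it reports empirical labels
only and makes no claim about the geometry of the separatrix between basins.

```{r}
res <- run_scenario("fig3c")   # alpha = 6, start at (20, 20, 20, 20)
res
plot(res$trajectory)
```

Starting instead from a high judge density eradicates the gang under the
same parameters:

```{r}
p <- crime_params(alpha = 6, beta = 30, gamma = 10, delta = 8, eta = 0.1,
                  kappa = 50, rho = 0.1, sigma = 20, phi = 0.2)
probe_basin(p, list(c(20, 102, 20, 20), c(20, 20, 20, 20)),
            t_end = 100, dt = 0.002)
```

## Bifurcation diagrams

Because every equilibrium has a closed form, branches are computed exactly on
an $\alpha$ grid (`sweep_alpha()`; no continuation machinery is needed) and
classified point-by-point with the numeric eigenvalues. The critical
$\alpha$ values come from inverting $R_0(\alpha) = \text{target}$, which is
exact since $R_0$ is linear in $\alpha$ and the targets $1$, $1-\beta/\kappa$,
$r$, $r_1$, $r_2$ do not involve $\alpha$; they are inserted into the grid so
diagrams show the touching point of coalescing branches. The default grid of
500 points keeps adjacent-point jumps well below 5% of $\sigma$ away from
the critical values (near a saddle-node the square-root branch has unbounded
slope, so no finite grid bounds the jump there).

```{r}
plot(sweep_alpha(p, c(1, 25), n_points = 300), main = "case 4: backward bifurcation")
```

## Scenarios and the real-world parameterization

Seven fixtures ship with the package (`load_scenario()`), carrying the
figure-scale reference parameterizations: the case-1 pair `fig1a`
($\alpha = 30$, $R_0 = 0.75$) and `fig1b` ($\alpha = 50$, $R_0 = 1.25$), the
case-4 quartet `fig3a`–`fig3d` spanning below, inside and above the
bistability window, and `fig5`, a real-world-scale scenario (time in years,
area unit 1000 km²): a 30-year judicial career ($\eta = 1/30$), about 10
judges and 40 gang members per area unit, 1% corrupt judges, 5-year average
incarceration ($\kappa = 1/5$), and 5/6 of ex-convicts relapsing
($\beta = 1/6$), giving $R_0 = 5$. The `fig1` experiments print no initial
condition; the fixtures use $(1, \gamma/\eta, 0, 0)$ — one gang member per
area unit entering a crime-free region — and their expected limits are
initial-condition independent in those monostable regimes. Each fixture's
`expected` block stores the reference two-decimal limits, compared with an
absolute tolerance of 0.005 (the rounding half-width) plus the relative
convergence tolerance.

```{r}
run_scenario("fig5")
```

## What the fixtures do and do not show

The fixtures exercise the model under the reference parameterizations, so
passing them demonstrates that the implementation reproduces the analytic
equilibria, thresholds and attractor structure of the model itself. They say
nothing about how well the model describes any real region: the model is
deterministic, spatially homogeneous, and constant-parameter, with no age or
hierarchy structure in the gang, no police compartment, and no data-fitting
layer. The real-world scenario's rates are order-of-magnitude estimates
assembled from public statistics, not fitted quantities.

## Known limitations

* Fixed-step RK4 only; stiff initial transients need a manually reduced
  step (the error message says so), and there is no adaptive or implicit
  fallback.
* Stability is local (eigenvalues); no Lyapunov functions or global basin
  geometry.
* The case-4 analytic eigenvalues are an asymptotic device, not a
  replacement for the numeric classifier.
* One-parameter sweeps in $\alpha$ only; other parameters are held fixed
  during a sweep.
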