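---
title: "Stochastic CSF dynamics: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic CSF dynamics: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfsde)
```

## The model and its assumptions

Intracranial pressure $p(t)$ (mmHg) in a constant-rate infusion study is
driven by the conservation of cerebrospinal fluid: formation (the external
infusion $I$ plus endogenous production) balances storage and reabsorption.
With the hyperbolic compliance law $C(p) = 1/(E\,p)$ and linear reabsorption
$(p - p_b)/R$, the mean dynamics are

$$\frac{1}{E p}\frac{dp}{dt} + \frac{p - p_b}{R} = I,$$

a logistic (Verhulst) equation in disguise: writing
$\alpha = E(I + p_b/R)$ and $\beta = E/R$, the drift is
$\alpha p - \beta p^2$, with stable equilibrium
$\alpha/\beta = R I + p_b$ — Davson's relation.

The CSF formation rate is not constant in reality; its fluctuations are the
dominant noise source in ICP recordings. The package perturbs the formation
rate with white noise of intensity $\sigma$ (mL/min) and adopts the Itô
convention, yielding the stochastic logistic diffusion

$$dp = \left\{E p I - \frac{E p (p - p_b)}{R}\right\}dt + \sigma E p\, dW.$$

Key structural assumptions, inherited from the pressure–volume modeling
tradition and kept fixed here:

* the reference pressure in the compliance law is 0 mmHg (`p0_ref`); the
  nonzero case has no known closed-form solution and is out of scope,
  though the parameter field is reserved;
* reabsorption is referenced to the baseline pressure $p_b$ throughout (the
  sagittal-sinus pressure that appears in circuit formulations is never
  related to $p_b$ quantitatively in the source tradition; we expose only
  $p_b$, as the working equations do);
* the Itô interpretation is fixed — there is no Stratonovich mode;
* units are fixed to minutes, mmHg, mL; no conversion layer.

Because the noise is multiplicative ($\sigma E p\,dW$), it cannot be
averaged away: the stationary mean lies *below* the deterministic
equilibrium (see below), and the model's risk quantities depend on $\sigma$
in a strongly nonlinear, threshold-like way.

## Parameters

| parameter | meaning | unit | default | why |
|---|---|---|---|---|
| `E` | brain elastance | mL⁻¹ | 0.15 | typical infusion-study estimate; elevated elastance is reported above 0.18 |
| `R` | CSF outflow resistance | mmHg·mL⁻¹·min | 7 | typical reported range 6–10 |
| `p_b` | baseline pressure | mmHg | 8 | typical baseline in published ICP plots (study averages near 6) |
| `I` | infusion rate | mL/min | 1.5 | standard constant-rate infusion protocol |
| `sigma` | formation-rate noise intensity | mL/min | 0.5 | not directly observable; rule of thumb `0.33 * I` rounded to one decimal (`default_sigma()`) |

The defaults satisfy the stationary-existence condition with a wide margin
(`stationary_existence_bound()` returns 35.24 (mL/min)² against
$\sigma^2 = 0.25$).

## Closed-form solutions

The deterministic solution (`deterministic_icp()`) is the logistic curve
$p(t) = p_0\alpha/(p_0\beta + (\alpha - p_0\beta)e^{-\alpha t})$, evaluated
in its decaying-exponential form so it is stable for arbitrarily large $t$.

The SDE itself is explicitly solvable along any Brownian path:
$p(t) = N(t)/D(t)$ with $N(t) = \exp[(\alpha - \gamma^2/2)t + \gamma W(t)]$,
$\gamma = \sigma E$, and
$D(t) = 1/p_0 + \beta\int_0^t \exp[(\alpha - \gamma^2/2)s + \gamma W(s)]ds$.
The coefficient of the integral is $\beta = E/R$: substituting the solution
into the SDE via Itô's formula forces the coefficient of $p^2$ in the drift,
and dimensional analysis agrees (mmHg⁻¹·min⁻¹ × min = mmHg⁻¹, matching
$1/p_0$). `exact_icp()` implements this.

**Quadrature choice.** The path integral in $D(t)$ is evaluated per grid
interval by an *exponential trapezoid* rule: the exponent is interpolated
linearly between grid points and the interval integral
$\int e^{g(s)}ds = \Delta t\, e^{\bar g}\,\mathrm{sinhc}(\Delta g/2)$ is
taken exactly. This is exact whenever the sampled $W$ is linearly
interpolated — in particular it reproduces the noise-free logistic solution
to machine precision on any grid, which a plain trapezoid rule on
$e^{g}$ cannot do. All accumulation happens in log space with incremental
log-sum-exp: at the default parameters the exponent reaches $\approx 790$
after 2000 min, far beyond double-precision overflow in linear space.

## Simulation schemes

* **log-Euler** (default): Euler–Maruyama applied to $y = \ln p$ after the
  Itô correction, $dy = (\alpha - \beta e^{y} - \gamma^2/2)dt + \gamma dW$.
  Positivity is structural, which matters because the exact solution shows
  the true process never touches 0.
* **Euler–Maruyama**: the literal discretization of the SDE. It can step
  below zero at coarse steps or extreme noise; this is *signaled* as a
  "positivity breach" error with the step index, never silently continued.
  It is retained because it discretizes the model equation directly and
  anchors the strong-convergence validation.

Both schemes consume the identical Gaussian increment stream for a given
seed, and `brownian_path(t_max, dt, seed)` exposes exactly that stream, so
a path can be re-evaluated through the closed-form solution. Ensembles
derive per-path seeds from a master seed by a counter-based rule
(`seed + 1299709·i mod 2147483629`), making them reproducible and
order-independent. The default step is `dt = 1e-3` min.

`strong_convergence_order()` measures the strong error of Euler–Maruyama
against the closed-form solution on a refined common path (reference step
`1e-4` min, 200 paths over 10 min in the validation runs); the fitted
order is ≈ 0.5, as expected for multiplicative noise, and the suite
requires ≥ 0.4.

## Stationary analysis

The stationary Fokker–Planck solution (zero-flux, density
$\propto \exp(\int 2\,\mathrm{drift}/\mathrm{diffusion}^2)/\mathrm{diffusion}^2$)
is a gamma distribution:

$$\text{shape} = \frac{2(RI + p_b)}{RE\sigma^2} - 1,\qquad
  \text{rate} = \frac{2}{RE\sigma^2}.$$

These parameter formulas are pinned by two independent anchors that the
test suite asserts over random parameter draws to $10^{-10}$ relative:

* mean $=$ shape/rate $\equiv (RI + p_b) - RE\sigma^2/2$ — the published
  mean formula $\mu$;
* shape $> 0 \iff \sigma^2 < 2(RI + p_b)/(RE)$ — the published existence
  condition.

Consequences carried by the same algebra: $\mu$ decreases in $\sigma^2$
(noise lowers the average steady-state ICP), and
$\partial\mu/\partial R = I - \sigma^2 E/2$, so resistance raises the mean
ICP exactly when $\sigma^2 E/2 < I$ — fluctuations dampen the effect of
resistance. The rate (inverse-scale) parameterization is used throughout;
scale $= 1/\text{rate}$.

At $\sigma = 0$ the stationary law degenerates to a point mass at the
deterministic equilibrium; `stationary_gamma()` refuses and points to
`equilibrium_icp()`.

## First-passage risk probabilities

The clinical question — starting from ICP $x$, what is the probability of
reaching a critical level $b$ (default 40 mmHg, the low end of the
tolerated 40–50 mmHg range) — is answered by the scale-function machinery
of one-dimensional diffusions. The scale density here is elementary:

$$\log s(p) = -\frac{2}{\sigma^2 E}\left[(I + p_b/R)\ln p - p/R\right],$$

minimized exactly at the deterministic equilibrium $RI + p_b$. (The inner
integral of $2\,\mathrm{drift}/\mathrm{diffusion}^2$ is elementary; only
the outer integral $S(x) = \int^x s$ is not, and is done numerically.)

**The lower boundary.** The textbook formulation poses $u(0) = 0$,
$u(b) = 1$. But whenever the stationary distribution exists, $s(p)\sim
p^{-(\text{shape}+1)}$ near 0 is non-integrable, $S(0^+) = -\infty$, and 0
is an *entrance* boundary: the exact $a\to 0$ limit of
$u(x) = (S(x)-S(a))/(S(b)-S(a))$ is identically 1 for every $x > 0$. The
well-posed clinical quantity therefore uses a positive lower absorbing
level $a$; the package default is $a = 30$ mmHg for the standard scenario
($x = 35$, $b = 40$): "drops 5 mmHg before rising 5 mmHg".
`bvp_hitting_probability()` is kept as an explicit replication of the
boundary-value formulation with the lower condition at a small
$\varepsilon > 0$; shrinking $\varepsilon$ drives every probability to 1,
which the tests demonstrate. A practical consequence: the published
threshold locations for this family of curves (near $\sigma = 1.1$ mL/min
and $R = 10$ mmHg·mL⁻¹·min) depend on an unspecified discretization of the
singular boundary and are not exactly reproducible; the two-barrier
formulation reproduces the *shape* — near-zero plateau, convex rise — which
is what the acceptance suite checks. Likewise "probabilities approach one"
holds in the $R\to\infty$ direction and in the $\varepsilon\to 0$
replication limit, but the $\sigma\to\infty$ limit of the two-barrier
probability is $(x-a)/(b-a)$, not 1.

**Numerics.** All scale arithmetic is in log space; linear-space evaluation
is never used. At the default $\sigma = 0.5$ the log-integrand spans
$> 500$ units between 0.1 and 40 mmHg, i.e. hundreds of orders of magnitude.
`log_scale_increment()` uses 16-node Gauss–Legendre panels, doubled until
the log value changes by $< 10^{-8}$ (deterministic, no RNG);
`hitting_probability()` combines two increments through a logistic ratio
`plogis(log I(a,x) − log I(x,b))`, which is exact at the barriers and
monotone in between. The finite-difference route divides the ODE by its
diffusion coefficient (the reduced ODE $u'' + c(x)u' = 0$ has moderate
coefficients) and solves the tridiagonal system by the Thomas algorithm;
with $10^4$ grid intervals it agrees with the scale route to $10^{-6}$ in
the tested configurations.

**Monte-Carlo validation.** `mc_hitting_probability()` simulates log-Euler
paths (default $n = 20000$, $dt = 5\times10^{-4}$ min, horizon 60 min) and
detects crossings by level comparison between steps — no Brownian-bridge
correction — so analytic-vs-MC comparisons carry a 0.005 discretization
allowance on top of $3\,\mathrm{SE}$. Censored paths (neither barrier hit)
are counted and an error is raised if they exceed 1% of paths, never
silently dropped.

## The synthetic recording generator

`synth_infusion_recording()` emulates the structure of a clinical infusion
study: a baseline phase with $I = 0$ (default 10 min, pressure settling
around $p_b$) followed by constant-rate infusion (default 50 min at 1.5
mL/min), simulated at `dt = 1e-3` min and resampled at 0.1 min (6 s). The
defaults were chosen once to mirror standard practice: baseline segments of
about ten minutes and infusion continued to plateau. What it emulates:
multiplicative-noise fluctuations around the logistic rise with the correct
stationary amplitude (the infusion-phase fluctuation SD at defaults is
≈ 1.5 mmHg, consistent with the stationary SD of ≈ 1.55 mmHg). What it
does **not** emulate: cardiac and respiratory pulsatility, slow vasogenic
waves, measurement artifacts, drifting baselines. Tests that pass against
this generator therefore validate the model mechanics and the pipeline, not
the full richness of bedside recordings.

## Problem sizes used in validation

The shipped validation runs use: a single 5000-min log-Euler run at
`dt = 1e-2` with 500-min burn-in and 1-min thinning for stationary
recovery (batch-means SE over 15 batches; KS distance to the gamma law
< 0.03); 200 paths over 10 min for the strong-convergence study
(`dt` ∈ {1e-2, 5e-3, 2.5e-3} against a 1e-4 reference); and 20000 paths at
`dt = 5e-4` for the Monte-Carlo cross-check of the analytic hitting
probability at $\sigma = 1.2$. These sizes give standard errors comfortably
inside the assertion margins while keeping a full validation run in the
tens of seconds on one core.

## Known limitations

* Parameter estimation from patient recordings is out of scope; the model
  is forward-only here.
* The nonzero reference-pressure variant is not implemented (no closed
  form is known).
* No jump noise: fluctuations are continuous by construction.
* Finite-horizon (time-resolved) first-passage densities and expected
  hitting times are not provided; only the two-barrier probabilities.
* The Euler–Maruyama scheme is first-order (strong order 0.5); no
  higher-order schemes are included beyond what validation needs.
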