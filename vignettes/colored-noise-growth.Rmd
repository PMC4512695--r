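---
title: "Colored-noise models of clonal population growth: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colored-noise models of clonal population growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalgrowth)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, the numerical
choices, what the synthetic ensembles do and do not emulate, and the design
decisions that were genuinely open. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## 1. The noise process and what it stands for

All randomness enters through a fluctuating per-capita growth rate
$g_c(t)$: a stationary, zero-mean Gaussian process with autocovariance
$$\langle g_c(t)\,g_c(t')\rangle = D\,e^{-|t-t'|/\tau_c},$$
i.e. an Ornstein–Uhlenbeck process. The two parameters are

* $D$ — noise magnitude, the stationary *variance* of the growth rate
  (units $1/\mathrm{time}^2$). Default test values span $0.1$–$100$.
* $\tau_c$ — autocorrelation time (time units), the model's proxy for
  cellular memory: regulatory state, epigenetic marks, bursting kinetics —
  anything that makes a colony's growth rate today predictive of its growth
  rate tomorrow.

The white-noise limit is $\tau_c \to 0$ at fixed $D\tau_c$ (the effective
diffusivity of $\log C$); it is exposed as that limit, not as a separate
generator, because at any single time point white and colored noise are
indistinguishable — only the temporal correlations differ.

**Generation is exact in distribution.** The defining ODE form of the
process printed in the source literature is dimensionally inconsistent with
the autocovariance above, so the autocovariance is taken as the binding
contract: paths are generated by the exact discrete update
$$g(t+\Delta t) = g(t)\,e^{-\Delta t/\tau_c} +
  \sqrt{D\left(1 - e^{-2\Delta t/\tau_c}\right)}\,\xi,\qquad
  \xi \sim N(0,1),$$
with $g(0) \sim N(0, D)$ (stationary start; a cold start at $0$ is available
but non-default — no published statement fixes which initialization the
original validation used, and the stationary choice makes every ensemble
statistic time-translation invariant from $t=0$). This update has no
discretization error at any step size; the test suite verifies the
autocovariance against a brute-force double-quadrature oracle and recovers
$(D, \tau_c)$ from simulated ensembles within 10–15%.

Replicate streams are derived deterministically from one root seed by
drawing per-replicate seeds sequentially, so enlarging an ensemble never
changes its existing replicates.

**Intermittency.** Thresholding the noise at zero (exact zeros, a
probability-zero event, go to state 0 for determinism) gives a two-state
decay/growth process whose stay probabilities $p_{00}, p_{11}$ grow with
$\tau_c$; the $1\!\to\!1$ frequency at sampling interval $\Delta t$ is
checked against the orthant probability of a bivariate normal with
correlation $e^{-\Delta t/\tau_c}$, computed by an independent 2-D grid
integration.

## 2. Linear model: multiplicative noise

$dC/dt = (\gamma + g_c)\,C$ integrates exactly to
$\ln(C/C_0) = \gamma t + \Gamma(t)$, $\Gamma(t)=\int_0^t g_c$. Because
$\Gamma$ is Gaussian with variance
$\langle\Gamma^2\rangle = 2D\tau_c[t - \tau_c(1-e^{-t/\tau_c})]$, the
population is log-normal. The simulator therefore *never steps the SDE*: it
samples exact noise paths and exponentiates their trapezoid integral, so the
only error in the headline moment tests is the quadrature of an exactly
sampled path (second order in the internal step; default
$\min(\tau_c/10,\,0.01\cdot\min(1/\gamma, 1))$).

The effective exponent $\alpha(t) = \langle\Gamma^2\rangle/(2t)$ rises
monotonically to the plateau $D\tau_c$. Three consequences carried by the
closed forms and asserted by tests:

* mean $C_0 e^{(\gamma+\alpha)t}$ grows even for $\gamma < 0$ when
  $|\gamma| < \alpha$, while the density mode collapses toward zero;
* the dispersion grows at the faster rate $\gamma + 2\alpha$
  asymptotically — heterogeneity outpaces the mean;
* splitting a given total growth rate between drift and noise
  ($\gamma_L = \gamma + 0.99\,\alpha$, $\alpha_L = 0.01\,\alpha$, i.e.
  $D$ reduced 100-fold at the same $\tau_c$) preserves the mean trajectory
  exactly while cutting the dispersion exponent to $\gamma + 1.01\alpha$ —
  variance is adjustable independently of the average.

`linear_moments()` reports the *exact* dispersion
$C_0 e^{\gamma t}\sqrt{e^{4\alpha t}-e^{2\alpha t}}$ and, separately, its
asymptotic exponential form `dispersion_approx` $= C_0e^{(\gamma+2\alpha)t}$.
The acceptance target for the adjustable-variance exponent uses the
asymptotic form: at the prescribed measurement times ($t \in \{8, 16\}$ with
$\alpha_L = 0.01$) the exact form still carries the transient
$\sqrt{1-e^{-2\alpha_L t}}$ factor (log-slope 1.049), whereas both its
$t\to\infty$ slope and the asymptotic form's slope equal the quoted
$1.01$.

## 3. Logistic model: stochastic self-regulation

$dC/dt = \gamma C - (\epsilon + g_c)C^2$ arises from a coupled growth-input
system ($dC/dt = GC$, $dG/dt = \gamma - (\epsilon+g_c)C - G$) when the input
$G$ relaxes fast; `simulate_coupled()` integrates the full system and the
tests confirm the reduction improves as the population dynamics slow
relative to the unit relaxation rate of $G$.

In inverse coordinates $y = 1/C$ the model is *linear*:
$dy/dt = -\gamma y + \epsilon + g_c$ (the printed form of this equation in
the source carries sign typos; the solution printed alongside it, which
everything downstream depends on, solves the equation above and is what the
package implements — verified against quadrature oracles at $10^{-8}$).
Hence $y(t) = A(t) + z(t)$ with
$A(t) = e^{-\gamma t}/C_0 + (\epsilon/\gamma)(1-e^{-\gamma t})$ and Gaussian
$z$, variance $\langle z^2\rangle(t)$ in closed form with stationary limit
$D/(\gamma(\gamma + 1/\tau_c))$. The removable singularity at
$\gamma\tau_c = 1$ is evaluated by its limit branch
$D/(2\gamma^2) - (D/\gamma)(t + 1/(2\gamma))e^{-2\gamma t}$, switched on at
relative distance $10^{-6}$ (cancellation error at the switch is
$\sim 10^{-10}$ relative).

The population density is the reciprocal truncated Gaussian
$$P(C) = \frac{N}{C^2}\,e^{-\beta(1/C - A)^2},\qquad
  \beta = \frac{1}{2\langle z^2\rangle},\qquad
  N^{-1} = \int_{-A}^{\infty} e^{-\beta z^2}\,dz,$$
with $N$ evaluated through the normal CDF (log-scale internally) rather than
raw quadrature, for stability at large $\beta$; tests cross-check the
normalization by adaptive quadrature to $10^{-6}$.

**Two $\beta$ conventions.** Figure-style parameter sets quote one fixed
$\beta$, but the exact $\beta(t)$ is time dependent and infinite at $t=0$.
The default mode (`time_dependent`) evaluates $\beta(t)$ exactly, with $D$
obtained from `map_stationary_beta()` so that a quoted $\beta^\ast$ is the
stationary value; `stationary_beta` holds $\beta$ fixed for direct
figure-style replication. Both are exported and tested.

**Moments are conditional.** The density falls off as
$Ne^{-\beta A^2}/C^2$, so the raw mean diverges logarithmically for any
finite $\beta$. Moment quadrature works in the Gaussian $z$ coordinates on
$[\max(-A + 1/\mathrm{cap},\,-8\sigma),\,8\sigma]$: moments are defined
conditional on $C \le \mathrm{cap}$, with the same default observable-population
cap as the simulator ($10^6 C_*$). For every headline number
($\beta A^2 \gg 1$) the conditioning is numerically invisible; in the
strong-noise limit it realizes the logarithmic divergence of the mean as
$\epsilon \to 0$, which is asserted only qualitatively (sign and
log-linear diagnostic) because the printed strong-noise prefactor in the
source analysis is typographically ambiguous.

**Weak-noise limit.** $\beta\to\infty$ collapses the density onto the
deterministic logistic trajectory $1/A(t)$ and the mean onto the carrying
capacity $C_* = \gamma/\epsilon$; with $\gamma = 1, \epsilon = 0.5$ the
quadrature mean at $\beta^\ast = 500$, $t = 10$ agrees with $C_* = 2$ within
$0.5\%$ (the acceptance check allows 2%).

## 4. Simulating blow-up honestly

When $\epsilon + g_c < 0$ persists, the quadratic term *accelerates* growth
and the population reaches infinity in finite time — the model's unbounded
growth regime must be observable, not an error. Two integrators are
provided:

* `method = "heun"` — predictor–corrector stepping of the population
  equation along the exact noise path, with recursive per-replicate
  sub-stepping when the local error proxy (corrector minus predictor)
  exceeds `tol`, and a configurable cap (default $10^6 C_*$): replicates
  crossing it are flagged diverged, frozen at the cap, reported, and
  excluded from distributional summaries with a count. Self-convergence
  under step halving is tested at the 1% level.
* `method = "inverse"` — an exact second-order update of the linear $y$
  equation. This is the continuation of the flow *through* the blow-up:
  $y$ may cross zero and return, i.e. a colony passes through the
  unbounded-growth episode. Endpoints with $y \le 0$ are recorded as `NA`
  and flagged.

The distinction matters for validation. The analytic density conditions on
a finite population *at time $t$* (truncation of the endpoint Gaussian),
while the capped integrator conditions on *never having blown up* — a
strictly smaller event. In the strongly noisy benchmark regime
($\tau_c=0.01$, $D=100$, $\gamma=1$, $\epsilon=0.5$) about 11% of endpoint
mass lies beyond the blow-up by $t=0.35$, and the capped integrator's KS
distance against the analytic CDF rises to $\approx 0.06$ while the inverse
route stays at $\approx 0.013$ ($n = 10^4$). `validate_model()` therefore
simulates the logistic model through the inverse representation by default —
the same mathematical object the analytic solution describes — and the
Heun route remains available for the capped physical reading. How the
original computational validation handled blow-up replicates is not
recorded; this choice is documented as the package's own resolution.

## 5. Local growth rate $\chi$

$\chi(C,t) = \partial_t \ln P(C,t)$ is evaluated two ways: a closed form
that drops the slow time variation of the normalization (exact for the
white-noise-limit relation $\beta(t) = \beta_\infty/(1-e^{-2\gamma t})$),
and an independent central finite difference of the log-density. Tests
assert agreement of signs and zero-crossing locations — not values, since
the closed form is explicitly approximate. Two qualitative claims inherited
from the source are sharpened by the closed form itself:

* $\chi$ decreases with $C$ on its *positive small-$C$ branch* below
  $C_*$ (the branch growth-variability plots display). Between its zero
  crossings $\chi$ is negative and rises back toward the advancing density
  peak, so monotonicity over the whole interval $C < C_*$ does not hold.
* Stationarity at late times is slower than the headline "zero for
  $t > 4$": in the far left tail the relaxation term
  $-2\beta u (\gamma/C_0-\epsilon)e^{-\gamma t}$ carries a factor
  $2\beta u \approx 950$ at $C = 0.1$ (the $\beta=50$ set), so
  $\max_{[0.1,10]}|\chi(\cdot, 10)| \approx 2\times 10^{-2}$ and the
  $10^{-3}$ bound is reached only for $t \gtrsim 15.5$. The acceptance
  test asserting the bound at $t = 10$ is deliberately left failing, with
  this analysis, rather than weakened.

## 6. Selection layer

Survival of a colony of size $C$ is Bernoulli with probability $f(C)$.
The built-in shapes are one deliberate reading of selection regimes that
are described only pictorially in the source: increasing sigmoid
(directed), Gaussian bump (stabilizing), decreasing sigmoid (therapeutic),
and a decreasing sigmoid in $C^{2/3}$ (toxin uptake proportional to surface
area); all are parameterized and overridable by a tabulated $f$.
Survivability $S = \int f P$ is quadrature against the analytic densities;
dominance ($f_1 \ge f_2 \Rightarrow S_1 \ge S_2$) and closed-form special
cases (step fitness on the log-normal equals its CDF) are tested.

`iterate_selection()` applies selection instantaneously at the end of each
regrowth period (no kill kinetics are specified anywhere) and — critically —
carries both the population state *and the noise state* across rounds, so
cellular memory persists through treatment. This exposes a real trade-off
the tests pin down: long $\tau_c$ keeps treated survivors in their resistant
(slow-growing) state, raising round-2 survival under harsh treatment
centered at the founding size; but memory also makes log-displacement
super-diffusive, so under weak treatment centered above the bulk the extra
spread can dominate and *lower* later-round survival. The packaged test
asserts the persistence effect in the regime where state retention is the
operative mechanism.

`optimize_survivability()` is an exhaustive, deterministic grid search —
survivability surfaces here are cheap closed-form integrals and no
published algorithm exists to reproduce.

## 7. What the synthetic ensembles do and do not establish

The generator *is* the model: ensembles are exact draws from the stated
stochastic processes, so a green validation test establishes that the
simulators, the closed-form densities, and their numerical evaluation are
mutually consistent — to KS $< 0.03$ at $n = 10^4$, with moments within
exact Monte-Carlo standard errors. It does not establish anything about
real populations: there is no demographic (birth–death) noise, no spatial
structure, no interaction between colonies, no heritable parameter change
between selection rounds, and the Gaussian/exponential-correlation noise
family is an assumption, not an inference. Monte-Carlo standard errors for
heavy-tailed log-normal summaries are computed from the known law, not from
the sample, whose tail-moment estimates are biased low by orders of
magnitude at late times.

## 8. Defaults worth knowing

| quantity | default | why |
|---|---|---|
| integration step | $\min(\tau_c/10,\ 0.01\min(1/\gamma,1))$ | resolve noise memory and the fastest deterministic scale |
| divergence cap | $10^6 C_*$ ($10^6$ if $\epsilon=0$) | far beyond any biologically meaningful size; makes blow-up observable |
| Heun sub-step tolerance | $10^{-3}$ relative | balances cost against the 1% self-convergence test |
| KS threshold | 0.03 | calibrated internally: false-failure rate $<1\%$ at $n=10^4$ under the null (tested) |
| quadrature truncation | $\pm 8$ SD in $z$ | Gaussian weight $\sim 10^{-15}$ at the boundary |
| moment cap | simulator's cap | moments of the logistic law are conditional by necessity (Section 3) |

## 9. Known limitations

* The Heun route under strong noise spends most of its time refining
  blow-up replicates; use the inverse route for distributional work.
* Conditional moments depend (logarithmically weakly) on the cap in the
  strong-noise regime; report the cap alongside any strong-noise mean.
* The closed-form $\chi$ is an approximation by construction; only its
  qualitative structure is guaranteed.
* No closed form exists for the coupled system's density; it is simulation
  only.
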