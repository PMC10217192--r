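---
title: "A self-regulated Landau model of stem cell differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A self-regulated Landau model of stem cell differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landaucell)
library(dplyr)
```

## The model

`landaucell` treats differentiation of a stem cell population as spontaneous
symmetry breaking in a Landau free-energy landscape. A single order parameter
$m$ summarizes the population's average cell state — $m = 0$ is the
pluripotent (disordered, high-symmetry) state, $m \neq 0$ a differentiated
(ordered) state — and the strength of intrinsic gene-expression noise $\xi$
plays the role temperature plays in a thermal phase transition. The free
energy is the polynomial

$$V(m, \xi) = -\tfrac{1-\xi}{2} m^2 + \tfrac{\alpha}{3} m^3 +
  \tfrac{\beta}{4} m^4 + \tfrac{\gamma}{6} m^6,$$

and the order parameter descends its gradient, perturbed by finite-size
fluctuations of the population:

$$dm_t = \left[(1-\xi_t) m_t - \alpha m_t^2 - \beta m_t^3 - \gamma m_t^5\right] dt
  + \sigma\, dW_t .$$

What makes the system *self-regulated* is that $\xi$ is not a dial but a
dynamical variable under negative feedback,

$$d\xi_t = G\,(m_t^2 - M^2)\,dt,$$

with gain $G > 0$ and set-point $M \ge 0$: whenever the population is less
differentiated than the set-point prescribes, noise is removed, pushing the
system through its own critical point; overshooting raises noise and pulls
it back. The feedback is the mechanism by which a population can *navigate
itself* through a symmetry-breaking transition instead of requiring an
external schedule of noise reduction.

Three coefficient presets cover the standard phenomenologies
(`landau_model("model1")`, `"model2"`, `"model3"`):

| preset | $(\alpha, \beta, \gamma)$ | fixed-noise behaviour |
|---|---|---|
| model 1 | $(0, 1, 0)$ | supercritical pitchfork at $\xi_c = 1$; second-order transition; reversible |
| model 2 | $(0, -1, 1)$ | double saddle-node at $\xi_{c3} = 1.25$; first-order transition at $19/16$; hysteresis |
| model 3 | $(-1, 1, 0)$ | single saddle-node at $1.25$ plus transcritical at $\xi_c$; first-order transition at $11/9$; one-sided hysteresis |

Arbitrary real coefficients are accepted as long as the potential is bounded
below ($\gamma > 0$, or $\gamma = 0$ with $\beta > 0$). We deliberately do
not restrict coefficients to $\{0, \pm 1\}$: the third preset itself needs
$\alpha = -1$, so the constructor validates boundedness, not membership in a
discrete set.

## Fixed-noise analysis: bifurcations versus phase transitions

With the feedback off, `equilibrium_branches()` returns every real root of
the drift with a stability flag, `critical_noise()` the skeleton of critical
noise levels, `ground_state()` the global minimizer(s), and
`hysteresis_sweep()` the path-dependence of the occupied branch under a slow
noise schedule.

```{r critical, eval = FALSE}
tidy(critical_noise(landau_model("model2")))
#>   model   xi_c  xi_transition  xi_saddle  transition_order
#>   model2     1         1.1875       1.25  first
```

Two distinct diagrams coexist and the package keeps them apart.
*Bifurcations* are changes in the root structure of the drift: the
destabilization of $m = 0$ at $\xi_c$ (the zero of
$\partial \dot m/\partial m$ at the origin, which is $1 - \xi$ and hence
$\xi_c = 1$ for every coefficient set) and the fold where non-zero branches
appear as double roots, found from the shared root of the non-trivial drift
factor and its derivative. *Phase transitions* are shifts of the global
minimum: `critical_noise()` eliminates the stationarity condition from
$V = 0$, leaving the cubic
$-\alpha/6 - (\beta/4)\, m - (\gamma/3)\, m^3 = 0$ whose admissible roots
give the noise level at which a non-zero minimum degenerates with $V(0) = 0$.
For model 2 this yields $m^2 = 3/4$, $\xi = 19/16$; for model 3 $m = 2/3$,
$\xi = 11/9$ — matching the two-decimal values usually quoted (1.18, 1.22) —
and the transition is first order. When the cubic has no admissible root the
ground state leaves $m = 0$ continuously and the transition is second order,
located at $\xi_c$ itself.

The hysteresis sweep relaxes the order parameter by damped gradient flow at
each schedule point, starting from the previously settled value nudged by
`eps = 1e-3` to both sides (nearest settled branch wins; a symmetric tie at
$m = 0$ breaks toward $+$). The nudge size matters: it must induce a drift
larger than the relaxation tolerance on a *freshly destabilized* branch, or
departure from it is artificially delayed past the true branch termination.
The default jump threshold (`0.1` in $m$) is chosen to clear the steep
$\sqrt{1-\xi}$ growth of a pitchfork branch at the default schedule step
(0.005) while being far below a genuine saddle-node jump (order 1).

## Stability of the coupled system

`equilibria()` returns the closed-form fixed points
$E_\pm = (\pm M, \xi^*_\pm)$ with
$\xi^*_\pm = 1 \mp \alpha M - \beta M^2 - \gamma M^4$; `admissible_M_max()`
bounds $M$ by positivity of $\xi^*$ (1, $\approx 1.272$, $\approx 0.618$ for
the presets). `jacobian()` carries the exact linearization
$$J = \begin{pmatrix} \partial \dot m/\partial m & -m \\ 2 G m & 0 \end{pmatrix},$$
whose trace at $E_\pm$ reduces to $-\alpha m - 2\beta m^2 - 4\gamma m^4$
(with $m = \pm M$) and determinant to $2 G M^2$. `classify_stability()`
implements the trace–determinant plane with a sign tolerance of $10^{-10}$;
boundary cases return the degenerate label (`stable_degenerate_node`,
`center_candidate`, `nonhyperbolic`) rather than an arbitrary side. For
model 1 this reproduces the spiral/node boundary $G = M^2/2$ exactly.

`hopf_point()` finds zeros of the equilibrium trace over the admissible
range by sign-scanning plus bisection ($\sqrt 2/2$ for model 2; $1/2$ on the
$E_+$ branch for model 3; none for model 1, whose trace $-2M^2$ is negative
throughout), verifying $\det > 0$ at the root. The eigenvalue formula used
everywhere is the standard $\lambda_{1,2} = [T \pm \sqrt{T^2 - 4\Delta}]/2$;
it is the only form consistent with the trace/determinant classification
above.

Whether the Hopf bifurcation is super- or subcritical is *not* derived from
a first Lyapunov coefficient. With `detect_character = TRUE` the package
simulates deterministically on both sides of $M_c$ (offset 0.02, starting
0.05 away from the equilibrium): a small bounded orbit below $M_c$ together
with convergence to the equilibrium above it is the supercritical signature,
and is what both models 2 and 3 display. We chose the empirical probe
because it tests the property that actually matters downstream (a small
stable cycle exists) and is robust to algebra slips in a normal-form
reduction.

## Simulation

`simulate_path()` and `simulate_ensemble()` integrate the coupled system
with the Euler–Maruyama scheme at fixed step `dt = 1e-3` (the compiled core
is in C++; the R-level `step_em()` documents the elementary update and the
two agree to machine precision). Defaults mirror the canonical experiment:
start at the pluripotent state in the high-noise regime
($m(0) = 0$ or $10^{-3}$, $\xi(0) = 1.5$), weak finite-size forcing
$\sigma = 10^{-4}$, recording every 0.1 time units.

Numerical choices worth knowing:

* **The line $m = 0$ is invariant** under the deterministic flow, so
  deterministic runs default to $m(0) = 10^{-3}$; with $\sigma > 0$ the
  noise itself breaks the symmetry and $m(0) = 0$ is the honest start.
* **$\xi < 0$ is not clamped by default.** The drift remains well defined
  and the deterministic analyses never reach it from admissible parameters;
  a `clamp` floor policy is available (and recorded in output metadata)
  because $\xi$ is physically a noise strength.
* **Seeding.** Ensembles draw one sub-seed per trajectory from the master
  seed; every trajectory can be reproduced in isolation from its recorded
  seed, and the whole ensemble is bitwise reproducible.
* **$\sigma$ versus population size.** The finite-size scaling is exposed as
  `sigma_finite_size(N, c) = c/sqrt(N)`: an average over $N$ weakly
  correlated cells fluctuates with standard deviation $\propto N^{-1/2}$.
  The constant (and thereby the effective exponent) is configurable because
  the mapping from real populations to $\sigma$ is a modelling choice, not a
  derived quantity.
* **First-order convergence** of the deterministic endpoint in `dt` is
  verified by Richardson ratios in the tests, and $\sigma = 0$ paths agree
  with an adaptive ODE solution (`deSolve::lsoda`, tolerances
  $10^{-10}/10^{-12}$) to better than $10^{-4}$ at $t = 10$.

## Ensemble observables

`pdf_over_time()` histograms the order parameter across trajectories (201
uniform bins on $[-1.5, 1.5]$ by default), normalized at every time node.
`quasi_potential()` reconstructs the Waddington-style landscape
$\Phi = -\ln P$, masking never-visited bins rather than imputing them —
flooring empty bins would fabricate landscape features where the ensemble
has simply never been. `fate_fractions()` reports the share of trajectories
within a capture radius of each attractor.

`limit_cycle_summary()` declares a sustained cycle when, after discarding a
transient (default: first half of the horizon), the oscillation amplitude
exceeds $10^{-3}$ in $m$, successive maxima are regular (period CV < 5%),
*and* the amplitude in the second half of the analysis window holds at least
90% of the first half's. The last condition is what separates a genuine
cycle from a slowly converging spiral just above the Hopf point, whose
decaying oscillation also has regular peaks. Orientation is the sign of the
shoelace area of the $(m, \xi)$ loop; flipping the initial $m$ sign flips
the orientation in the symmetric models.

`switching_report()` assigns basins with hysteretic (Schmitt-trigger)
labeling — the label changes only on *entering* a new interval, whose
half-width defaults to 0.3 times the attractor spacing — so boundary
chatter does not inflate transition counts. Dwell times per visit quantify,
for example, that the large-amplitude model 3 cycle lingers far longer near
the pluripotent state than near $m_+$.

## What the simulations do and do not emulate

The stochastic term stands in for finite-population fluctuations only; it is
additive, white and scalar. Real stem cell populations have state-dependent
(multiplicative) noise, cell division and death, spatial structure, and many
interacting order parameters — none of which the mean-field model carries.
Passing tests therefore certify the mathematics of the reduced model (its
bifurcation skeleton, attractor taxonomy and noise-induced kinetics), not
biological realism of any particular gene network.

Two quantitative caveats found while validating, both documented in the
tests rather than hidden:

* **Square-root cycle growth is asymptotic.** The Hopf normal-form law
  (amplitude $\propto \sqrt{M_c - M}$) is verified with a log–log slope of
  $0.5 \pm 0.1$ for $M_c - M \in [10^{-3}, 10^{-2}]$, where
  amplitude$/\sqrt{M_c - M}$ is constant at $\approx 1.22$. Farther from
  onset ($M_c - M \gtrsim 0.02$) higher-order terms inflate the apparent
  slope to $\approx 0.7$; the law should not be extrapolated there.
* **Switching needs noise of order $10^{-3}$.** The hybrid three-state
  occupancy of model 2 at $M = 0.5$ and the cycle-to-cycle transitions at
  $M = 0.65$ are demonstrated at $\sigma = 10^{-3}$ and $10^{-2}$
  respectively: at $\sigma = 2\times 10^{-4}$ the cycle's closest approach
  to $m = 0$ sits 6–10 noise standard deviations away and no transition
  occurs within $10^4$ time units at the horizons we integrate. Likewise,
  capture of the model 3 oscillation by the asymmetric sink $E_-$ — which is
  inevitable in principle, since $E_-$ is the only asymptotically stable
  point — is complete within $t = 1500$ at $\sigma = 10^{-3}$ but remains
  partial at $2\times 10^{-4}$.

## Problem sizes

The test-suite simulations use the sizes a laptop analysis would: single
deterministic trajectories of $10^5$–$2\times 10^7$ steps, and the
symmetry-breaking ensemble at 80–200 trajectories of $1.5\times 10^5$ steps
each, enough to put three binomial standard deviations of the fate split at
about $\pm 10\%$. Larger ensembles sharpen the densities but change no
conclusion; the full analysis suite runs in well under a minute.
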