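---
title: "Modelling the subdiffusive-to-Brownian crossover of lateral membrane diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the subdiffusive-to-Brownian crossover of lateral membrane diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(gleml)
```

## The model

A protein diffusing laterally in a lipid bilayer passes through three
dynamical regimes: ballistic at sub-picosecond lags, subdiffusive at
intermediate lags where it moves concertedly with its lipid shell, and
Brownian once the shell has relaxed.  `gleml` describes all three with a
single generalized Langevin equation (GLE) for the center-of-mass velocity
$\mathbf{U}(t) \in \mathbb{R}^2$,
$$
M\,\dot{\mathbf{U}}(t) = -\int_0^t \zeta(t-u)\, \mathbf{U}(u)\, du +
\boldsymbol{\Xi}(t),
$$
with Gaussian colored noise tied to the memory kernel $\zeta$ by the
fluctuation-dissipation theorem.  The kernel combines an instantaneous
viscous response and a retarded elastic response of the membrane,
$$
\zeta(t) = M\left[\omega_s^2\,\delta(t/\tau_s) + \omega_0^2\,
(t/\tau)^{\nu-1} E^{\delta}_{\lambda,\nu}\!\left(-(t/\tau)^\lambda\right)
\right],
$$
where $E^{\delta}_{\lambda,\nu}$ is the three-parameter Mittag-Leffler
(Prabhakar) function.  In the Laplace domain the kernel is algebraic,
$$
\hat\zeta(s) = \xi_s + \xi_p \frac{(\tau s)^{\delta\lambda-\nu}}
{(1+(\tau s)^\lambda)^\delta},
\qquad \xi_s = M\omega_s,\quad \xi_p = M\omega_p,\quad
\omega_p = \omega_0^2 \tau ,
$$
and every observable follows from the resolvent
$\hat g(s) = 1/(Ms + \hat\zeta(s))$: the velocity autocorrelation function
$C_v(t) = 2k_BT\,g(t)$, the time-dependent diffusion coefficient
$D(t) = k_BT \int_0^t g$, and the mean-square displacement
$\langle\Delta X^2\rangle = 2d\,k_BT\,I(t)$ with $\hat I = \hat g/s^2$.

Two structural constraints carry the physics:

* **Complete monotonicity** ($0 < \lambda \le 1$,
  $0 < \lambda\delta \le \nu \le 1$) makes the elastic kernel a
  non-negative mixture of exponential relaxation modes with rate density
  $p_{\lambda\nu\delta,\tau}(f)$ — `rate_spectrum()` — peaked near
  $1/\tau$.  Physically: monotone energy decay and a genuine spectrum of
  shell-relaxation times.
* **The Brownian constraint** $\nu = \delta\lambda$ makes $D(t)$ approach a
  finite $D_\infty = k_BT/(\xi_s+\xi_p)$, so normal diffusion is recovered
  at long lags; the VACF then has a negative power-law tail
  $\propto -t^{-1-\lambda}$.

The parameters, with units and their physical role:

| parameter | units | role | default origin |
|---|---|---|---|
| $M$ | g/mol | particle mass | fixed input |
| $T$ | K | temperature | fixed input |
| $\omega_s$ | ps$^{-1}$ | inverse ballistic timescale ($\tau_s = 1/\omega_s$) | fitted |
| $\omega_p$ | ps$^{-1}$ | elastic friction scale $\omega_0^2\tau$ | fitted |
| $\tau$ | ps | membrane shell relaxation timescale | fitted |
| $\lambda, \nu, \delta$ | — | shape of the subdiffusive-to-Brownian crossover | fitted / constrained |

Internally the package works in MD-native units (g/mol, nm, ps, K;
$k_B = 0.00831446$ kJ mol$^{-1}$K$^{-1}$, so kJ/mol $\equiv$ amu nm$^2$/ps$^2$);
frictions are reported in Pa s $\mu$m and diffusion coefficients in
$\mu$m$^2$/s only at the API boundary (`derive_parameters()`,
`d_infinity()`).

```{r example}
p <- gle_params(mass = 41697, temperature = 310, omega_s = 0.98,
                omega_p = 447, tau = 13.4e3, lam = 0.715)
derive_parameters(p)
```

```{r msdplot}
t <- 10^seq(-2, 6.5, length.out = 200)
msd <- gle_observable(p, t, "msd")
plot(msd$time, msd$value, log = "xy", type = "l", lwd = 2,
     xlab = "lag (ps)", ylab = "MSD (nm^2)")
lines(t, gle_short_time(p, t, "msd"), lty = 2)
lines(t, gle_long_time(p, t, "msd"), lty = 3)
legend("topleft", c("model", "ballistic law", "Brownian line"),
       lty = 1:3, bty = "n")
```

## Numerical choices

**Prabhakar evaluation.**  No single representation of
$E^\delta_{\lambda,\nu}(-x)$ is accurate on all scales.  The package uses
the power series for $x \le 3$ (where alternating-series cancellation is
still benign in double precision), the optimally truncated algebraic
asymptotic expansion for $x \ge 40$ when its own error estimate reaches
$10^{-10}$, and otherwise trapezoidal quadrature of the spectrum integral
$\int_0^\infty p(f)e^{-ft}df$ on a log rate grid (step $h \le 0.04$,
refined as $\lambda \to 1$ where the spectrum narrows).  The switch points
were chosen by cross-validating the three routes against each other and
against an arbitrary-precision series; accuracy is $\lesssim 10^{-10}$
relative across $x \in [0, 10^6]$ in the completely monotone region.  At
$\lambda = 1$ the function reduces to a confluent hypergeometric form and is
summed with positive terms after a Kummer transformation.  $1/\Gamma$ at
non-positive arguments is evaluated by reflection, so $1/\Gamma(0) = 0$
exactly — this is what kills the leading asymptotic term under the Brownian
constraint.

**Inverse Laplace transform.**  All model transforms are analytic for
$\mathrm{Re}\,s > 0$ with singularities on the closed negative axis.  The
default engine is the fixed Talbot contour; the cross-check engine is the
de Hoog quotient-difference accelerated Fourier series, evaluated per
decade of $t$.  Each inversion carries a two-sided error estimate
(deviation from node counts $\pm 4$, inflated Richardson-style when
convergence is slow) and escalates its node count until the requested goal
is met; in fixed precision the practical floor is $\sim 10^{-11}$ relative
for monotone targets and $\sim 10^{-7}$ deep in decayed tails, which is why
the VACF-tail diagnostics request a $10^{-6}$ goal.  The two methods agree
to $10^{-6}$ on the model transforms over eight decades of lag; the
property suite draws its random parameter sets in the overdamped regime
($\omega_0 \le \omega_s/2$, as in lateral membrane diffusion) — an
underdamped kernel makes the VACF ring, a configuration covered separately
by the damped-oscillation battery pair rather than by the deep-tail
agreement contract.

**Bayesian fitting.**  `gle_fit()` fits the Laplace-domain MSD model (under
$\nu = \delta\lambda$) with a flat prior inside wide bounds (defaults:
$\omega_s \in [0.05, 20]$ ps$^{-1}$, $\omega_p \in [10, 5000]$ ps$^{-1}$,
$\tau \in [0.5, 200]$ ns, $\lambda \in [0.35, 0.99]$, and for variant M1
$\delta \in [0.3, 1.4]$ restricted to the completely monotone region).  The
noise model is independent Gaussian with $\sigma_i = \sigma_{rel}\,y_i$
($\sigma_{rel} = 0.02$ by default); fitted lags are thinned to at most 40
log-spaced points per decade (capped at 300) so no regime dominates the
residual.  The posterior of this model is extremely narrow and strongly
correlated relative to the prior box, which defeats a bare tensor grid: the
reference method therefore first locates the mode (coarse scan plus
Nelder-Mead), measures the local Hessian, and lays the tensor grid over
mode $\pm 5$ standard deviations *in the Hessian eigenbasis* — an
axis-aligned grid aliases the thin probability ridge and underestimates the
marginal widths by a factor of about two.  Credible intervals are
equal-tailed, interpolated between grid points to avoid half-cell quantile
bias.  The alternative `method = "mcmc"` runs an affine-invariant stretch
sampler started in a Hessian-scaled ball around the mode and reports a
split-chain convergence statistic (warning above 1.05).  The reported point
estimate is the posterior mean; the mode is also stored.

**Kernel-consistent simulation.**  `kernel_modes()` discretizes the rate
spectrum into $K$ exponential modes: a two-point Gaussian rule per log-bin
(from centered spectral moments, which avoids catastrophic cancellation in
the raw-moment Hankel system), followed by a non-negative least-squares
refinement of the weights on the relative kernel error over the target
window; modes faster than the window keep their quadrature weights, since
they carry genuine short-time spectral mass but do not project onto the
fitting grid.  With $K = 48$ the kernel is reproduced to better than 1%
over the window 0.1 ps to 10 $\mu$s at the published best-fit parameters.
`simulate_gle()` integrates the equivalent Markovian system — one
Ornstein-Uhlenbeck force variable per mode, coupled so that the
fluctuation-dissipation theorem holds mode by mode — with exact OU updates
of the auxiliary variables and of the velocity drag between half-step
position/force updates; the stationary velocity variance is $k_BT/M$ per
component by construction, and the time step must satisfy
$dt \cdot \max(\omega_s, f_k) \le 0.1$.

## What the synthetic data do and do not show

The generator produces (i) GLE trajectories whose kernel is the
$K$-mode approximation of the Prabhakar kernel, (ii) noisy model MSD
curves with independent multiplicative Gaussian noise
($\sigma_{rel} = 2\%$ by default, the level used in the recovery
exercises), and (iii) plain 2D Brownian references.  These emulate the
*statistics* of the model — they are the correct self-consistency targets
for the estimators, the fitting machinery and the asymptotic laws.  They do
not emulate molecular-dynamics data: real MD MSD curves have correlated
sampling noise across lags (overlapping time origins), finite-size
(periodic-boundary) suppression of $D_\infty$, and possible non-Gaussian
lipid dynamics at high cholesterol content.  Passing the recovery and
coverage tests therefore validates the machinery, not the model's adequacy
for any particular membrane.

Problem sizes used in the packaged checks (chosen as the smallest that
leave the stochastic assertions comfortable margins): 300 log-spaced lags
over 0.1 ps to 5 $\mu$s for the headline recovery fit; 20 replicate
80-point datasets for the coverage property; ensembles of 100-200
trajectories of $6\,000$-15,000 steps for the simulator checks, with
timescale-compressed parameters ($\tau = 50$ ps) so the Brownian regime is
reached within the run.

## Degenerate inputs, tie-breaks, edge cases

* `ml_kernel(0, ...)` is refused for $\nu < 1$ (genuinely singular) and
  returns the finite limit otherwise.
* Outside the completely monotone region the rate spectrum may be negative;
  it is evaluated with a warning, and the crossover band of the Prabhakar
  function (where only the spectrum route is available) raises an error
  naming the range.
* `select_near()` breaks residence-time ties in favor of the lower
  particle index; `displacement_cdf()` uses overlapping origins and flags
  this in its metadata.
* MSD curves are clipped non-negative after inversion; `noisy_msd()` clips
  its multiplicative noise to keep curves positive.
* With uninformative data the posterior reverts to the flat prior (checked
  by a property test); if the model cannot reach the data at all inside the
  bounds, `gle_fit()` raises a diagnostic error rather than returning a
  spurious posterior.

## Open choices made by this package

* The fitted-lag range includes the sub-ps ballistic lags by default; the
  range is exposed as `fit_range` and recorded in the fit object, since the
  choice is not dictated by the model.
* Credible intervals are equal-tailed (not highest-density), flagged in the
  output.
* The long-time MSD line uses the exact
  $D_\infty = k_BT/(\xi_s + \xi_p)$ rather than its $\xi_p$-dominated
  approximation, which is only the $\varphi = \xi_p/\xi_s \gg 1$ limit.
* The VACF tail prefactor exists in two algebraically equivalent forms
  (friction-ratio and frequency-ratio); both are computed and asserted
  equal at run time rather than choosing one.
* The $\delta(t/\tau_s)$ term contributes its full mass $\xi_s$ to
  $\hat\zeta$ (no half-mass boundary convention), consistent with the
  algebraic form of $\hat\zeta$ above.

## Known limitations

* The Prabhakar quadrature route degrades for $\lambda > 0.995$ (the
  spectrum approaches a point mass); $\lambda = 1$ exactly is handled by
  the confluent reduction.
* Double-precision contour inversion cannot certify better than
  $\sim 10^{-7}$ relative accuracy deep in decayed oscillatory tails; the
  error estimate reports this honestly instead of silently returning noise.
* No finite-size (periodic-boundary) correction of $D_\infty$ is applied;
  literature estimates for comparable simulation boxes put it near 40%,
  which is why absolute comparisons with experiment need care.
* Fits assume independent Gaussian noise across lags; MSD curves estimated
  from a single trajectory with overlapping origins violate independence,
  and the resulting intervals are then optimistic.
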