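---
title: "Invasion fronts and extinction in scalar neural fields: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invasion fronts and extinction in scalar neural fields: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofront)
```

## The model

`neurofront` studies the activity-based scalar neural field

$$\tau \,\partial_t a(x,t) = -a(x,t) + F\!\left(\int w(x-x')\,J(x')\,a(x',t)\,dx'\right),$$

with $a(x,t)\ge 0$ the population firing rate, $w$ a Gaussian synaptic
footprint of mass $W_0=\int w$ and range $\sigma$, $J$ an optional spatial
modulation of the weights, and $F$ a non-negative, bounded, monotone firing
rate. The package centres on the regime in which the zero-activity state is
*linearly unstable* ($W_0 > 1$ with $F'(0)=1$), which produces two linked
phenomena:

* localized activity invades the quiescent state as a **pulled front**
  whose speed is fixed by the linear dynamics in its leading edge, and
* once multiplicative noise vanishing at $a=0$ is added, the quiescent
  state becomes **absorbing**, and rare fluctuations can extinguish all
  activity.

Three firing rates are provided. The piecewise-linear rate
($F(a)=\min(\max(a,0),\kappa)$) is the workhorse: it has exactly the two
homogeneous states $a^*=0$ (unstable) and $a^*=\kappa$ (stable) when
$W_0>1$, and its unit slope at the origin makes the leading-edge
linearisation exact. `tanh` is the smooth analogue used by the extinction
module, where a differentiable rate is needed. The sigmoid of the classical
bistable neural-field literature has $F(0)>0$; it is accepted for
fixed-point analysis but rejected by the stochastic and extinction modules,
which require an absorbing zero state.

## Pulled-front dispersion

Substituting an exponential edge $a \sim e^{-\lambda(x-ct)}$ into the
linearised equation gives the dispersion relation

$$c(\lambda) = \frac{W(\lambda)-1}{\lambda}, \qquad
W(\lambda) = \int w(y)e^{-\lambda y}dy = W_0 e^{\lambda^2\sigma^2/2},$$

a positive unimodal curve for $W_0>1$ whose minimum $(\lambda_0, c_0)$ is
the selected front: `minimal_speed()` brackets the minimum on a logarithmic
grid, minimises with Brent's method, and then polishes $\lambda_0$ on the
stationarity condition $\lambda W'(\lambda)-W(\lambda)+1=0$, because a
bracketed minimiser alone is only accurate to the square root of machine
precision in $\lambda$. The result stores the residuals of the implicit
minimiser equation and of the equivalent quadratic relation between
$\lambda_0$ and $c_0$; both are checked to $10^{-8}$ in the tests. For the
reference parameters $W_0=1.2$, $\sigma=1$ this gives
$\lambda_0 = 0.52249$, $c_0 = 0.71868$. Scaling holds exactly:
$c_0\propto\sigma$, $\lambda_0\propto\sigma^{-1}$ at fixed $W_0$.

### Pulsating fronts in periodic media

With a periodic weight modulation $1+K(x/\varepsilon)$ of period
$2\pi\varepsilon$, the leading edge supports pulsating fronts whose mean
speed follows from a nonlocal Hill equation. Fourier-expanding the periodic
amplitude and truncating at $|m|\le M$ yields the eigenproblem

$$(1+c\lambda)P_m = W(\lambda - im/\varepsilon)\Big[P_m + \sum_l K_l P_{m-l}\Big].$$

`pulsating_dispersion()` builds the $(2M{+}1)$-dimensional matrix exactly
as written (the transform argument uses the row index $m$) and selects the
eigenvalue of largest real part. This selection rule is a package decision:
it is the branch that connects continuously to the homogeneous transform
$W(\lambda)$ as the modulation amplitude goes to zero (verified in the
tests by an amplitude-continuation check), and the chosen eigenvalue must
be real to within $10^{-8}$ relative tolerance or an error is raised, as is
a tie between two distinct leading eigenvalues. Fourier coefficients are
supplied directly rather than computed from a callable so that
trigonometric modulations are represented exactly. `pulsating_minimal_speed()`
re-solves at twice the truncation and requires the minimal speed to move by
less than $10^{-6}$; for $K=\cos$ at the reference parameters, $M=8$ is
already converged to that tolerance, and the minimal mean speed rises from
$0.7635$ at $\varepsilon=0.5$ to $0.8709$ at $\varepsilon=0.8$ — the
direct simulation in the test suite reproduces the $\varepsilon=0.5$ value
to within its relaxation-limited accuracy.

## Direct simulation

`simulate_field()` uses forward Euler (the discretisation the sharp-interface
and stochastic analyses are calibrated against; Heun is available and
flagged in the trajectory metadata) with the default preset discretisation
$dx = 0.1\sigma$, $dt = 0.01\tau$. "Free" boundaries truncate the nonlocal
integral at the domain edge — for a nonlocal operator this is the only
consistent reading of free boundary conditions — and Dirichlet boundaries
additionally pin the two edge nodes to zero.

The nonlocal drive is evaluated by a compiled **banded direct sum** over
the kernel support $|x-x'|\le 8\sigma$ (truncated mass below
$2\times10^{-15}W_0$). This choice, rather than an FFT, is deliberate: a
spectral convolution deposits roundoff-level values ($\sim 10^{-16}$)
everywhere in the domain, and ahead of an invasion front any positive floor
grows at the bulk rate $(W_0-1)/\tau$. At the reference parameters that
floor ignites the entire domain by $t\approx\ln(10^{16})/0.2\approx 190$,
which silently destroys long-horizon stochastic statistics and the
absorbing property. The banded sum returns exact zeros beyond the band, so
compact support — and with it the absorbing state — is preserved to
arbitrary times. An FFT path (zero-padded or circular) is retained as an
option, and a dense $O(N^2)$ sum serves as the test oracle; the three agree
to $10^{-10}$ on random fields.

Front positions are read off level sets: $X_z(t)$ is the rightmost
downward crossing of level $z$, linearly interpolated between nodes, with
uncrossed levels flagged missing. Speeds are least-squares slopes of the
level-averaged position over a user window.

### The slow approach to the minimal speed

Pulled fronts relax to $c_0$ only algebraically: the front position carries
a universal logarithmic shift, $X(t) \simeq c_0 t - \tfrac{3}{2\lambda_0}\ln t
+ \mathrm{const}$, so the instantaneous speed is
$c(t)\simeq c_0 - 3/(2\lambda_0 t)$, an $\sim 8\%$ deficit at $t=50$ for the
reference parameters. The test suite fits the homogeneous front over
$t\in[40,50]$ and finds the plain linear fit a few percent below $c_0$
(the run prints both numbers); refitting with the $-\tfrac{3}{2\lambda_0}\ln t$
term included recovers $c_0$ to about one percent. This is physics, not a
solver artefact: no choice of level or window at $t\le 50$ brings the plain
fitted speed within five percent of $c_0$, and the package reports the
deficit rather than extending the horizon to mask it.

## Sharp-interface (Hamilton-Jacobi) limit for slow heterogeneity

For a slow modulation $J$, rescaling $x\to x/\epsilon$, $t\to t/\epsilon$
turns the front into the zero level set of an action $G(x,t)$ obeying
$\partial_t G + H(\partial_x G, x)=0$ with

$$H(p, x) = -1 + W(p)\,J(x).$$

`solve_hamilton_bvp()` solves the characteristic equations
$\dot X = J(X)W'(P)$, $\dot P = -J'(X)W(P)$ by shooting on $P(0)$ with an
adaptive Runge–Kutta integrator. Because $\dot X$ increases with $P$, the
boundary residual is monotone in $P(0)$: the solver brackets locally around
the homogeneous solution of $W'(p)=x/t$ and expands geometrically, instead
of scanning momenta where $W'$ is astronomically large and the
characteristics become needlessly stiff. Energy $E=H(P,X)$ is conserved
along every returned path to $10^{-8}$ (checked per solve), and
$G = -Et + \int P\,dX$ matches the homogeneous closed form
$t - W(\lambda)t + \lambda x$ to $10^{-8}$.

For weak modulations $J = 1+\beta f$, first-order perturbation theory gives
the front position

$$x(t) = l + c_0 t + \beta\,\frac{W(\lambda_0)}{c_0\lambda_0}
\int_0^{c_0 t} f(y)\,dy,$$

implemented by adaptive quadrature for arbitrary profiles and in closed
form for the linear profile $f(y)=y-l$, where it is the parabola
$x(t) = l + \big(c_0 - \epsilon^2 l(c_0\lambda_0+1)/\lambda_0\big)t +
\epsilon^2 c_0 (c_0\lambda_0+1)/(2\lambda_0)\,t^2$. The bookkeeping of the
small parameters deserves a note: the hyperbolic rescaling puts the
*squared* small parameter on the unscaled modulation slope, so the
`fig6`/`fig7` presets simulate $J(x) = 1+\epsilon^2(x-l)$ with
$\epsilon^2 = 0.005$ and $0.01$; this is the only reading under which the
closed parabola above follows from the perturbative position formula, and
the package treats that parabola as normative. The test suite verifies the
perturbative momentum against the shooting solution with the expected
$O(\beta^2)$ error (log–log slope 2 over $\beta\in\{10^{-1},10^{-2},10^{-3}\}$).

Two caveats bound the parabola's validity, both reported by the tests: at
early times the simulated front lags by the logarithmic relaxation shift
described above (up to $\sim$8% relative position error at $t=10$), and at
late times $t = O(1/\epsilon^2)$ the first-order theory breaks down — for
$\epsilon^2=0.01$ the position error grows past 100% by $t=40$, the
documented failure mode.

## Stochastic simulation and front wandering

`simulate_langevin()` integrates the Ito Langevin extension

$$dA = \big[-A + F(w*A)\big]dt + \epsilon\, g(A)\, dW(x,t)$$

by Euler–Maruyama. The discrete noise convention is explicit and recorded
in every output: increments have covariance
$2\,dt\,C_d(i-j)$ with the correlation matrix row-normalised so
$\sum_j C_d\,dx = 1$; in the white limit this gives independent per-node
increments of variance $2\,dt/dx$. The amplitude convention folds any
system-size factor into $\epsilon$ via $g(A)=A$; only the scaling exponent
of the wandering variance, not its prefactor, is treated as a reproducible
quantity. The zero state is exactly invariant ($g(0)=0$ and the banded
convolution of an exactly-zero region is exactly zero); negative
excursions are clamped to zero to preserve absorption in discrete time,
with the clamp count logged and a warning if it exceeds 0.1% of
node-steps. With $\epsilon=0$ the stochastic stepper takes the identical
arithmetic path as the deterministic one, so the reduction is bitwise.

`ensemble_front_statistics()` implements the level-set wandering protocol:
track $X_z(t)$ for a set of levels, average over levels first, then take
mean and variance across independent trials (per-trial RNG streams are
split from the master seed with L'Ecuyer-CMRG, so ensembles are
reproducible and trials independent). The wandering preset uses eight
levels in $(0.5\kappa,\,0.95\kappa)$: levels at or above the saturation
ceiling $\kappa$ are not crossed by the front under the piecewise-linear
rate — the bulk sits exactly at $\kappa$ — and when noise does push the
bulk across them the "crossings" are bulk fluctuations anywhere in the
invaded region, not front positions, which inflates the variance estimate.

The variance exponent is the least-squares slope of $\log\sigma_X^2$
against $\log t$ over the last half-decade of the run (after a transient
of $0.2T$), with a confidence interval obtained by bootstrap over whole
trials. The bootstrap is essential: variance estimates at nearby times are
strongly correlated, so the OLS slope standard error would be misleadingly
small. The wandering experiment runs at a reduced scale chosen once — 96
trials, $T=200$, domain $[0,250]$, $dx=0.2$, $dt=0.02$ — sized so the fit
window probes the late-time scaling while the full ensemble completes in a
few minutes on one CPU; at this scale the bootstrap CI reliably contains
the subdiffusive exponent $1/2$ and excludes diffusive wandering (exponent
1).

## Extinction as a Hamiltonian optimal path

In the weak-noise limit the probability of reaching the absorbing state is
dominated by the extremal path of the stochastic action, a trajectory of
the Hamiltonian system with

$$\frac{\mathcal H[q,p]}{L} \;(\text{uniform fields})\; =
p\Big[-q + F(W_0 q) + \tfrac12 p\, g^2(q)\Big], \qquad g(q)=\beta q^s .$$

`reduced_rhs()` implements the *canonical* equations $\dot q = \partial_p H$,
$\dot p = -\partial_q H$. The canonical sign on the momentum equation is
what makes $E=H$ a constant of motion and the metastable state
$Q_+=(q_0,0)$ a saddle of the $(q,p)$ flow — both structural facts the
phase portrait depends on; a finite-difference gradient check of the
Hamiltonian and an energy-drift bound of $10^{-8}$ along generic
trajectories pin this down in the tests.

The phase plane has zero-energy lines $p=0$ (deterministic dynamics) and
$q=0$ (absorbing line, carrying $Q_-=(0,0)$ and the fluctuational fixed
point $P=(0,p_e)$), plus the nontrivial branch obtained by dividing
$H=0$ by its trivial root:

$$p(q) = \frac{2\,[\,q - F(W_0 q)\,]}{g^2(q)},$$

which vanishes at $q_0$ and tends to
$p_e = -2(W_0-1)\lim_{q\to0} q/g^2(q)$: magnitude $2(W_0-1)/\beta^2$ for
$s=1/2$, zero for $s<1/2$, divergent (an error) for $s>1/2$. The branch is
derived from the Hamiltonian itself rather than from the instanton formula
as printed elsewhere, because only this form is consistent with the
$p_e$ limit; the branch momentum is negative for $W_0>1$ and the package
reports magnitudes with the sign convention recorded in the result object.

The action per unit length $S_0/L = |\int p\,dq|$ along the optimal path
($Q_+\to P$ for $s=1/2$, $Q_+\to Q_-$ for $s<1/2$) is computed by two
independent routes that must agree to $10^{-6}$: adaptive quadrature of the
branch formula (with the analytic $q\to0$ endpoint limit supplied), and
time-integration of the Hamilton equations along the heteroclinic
accumulating $\int p\,\dot q\,dt$, started $10^{-8}q_0$ off the saddle and
terminated by an event at $10^{-10}q_0$ (the endpoint tails are bounded
analytically and are far below the tolerance). For the tanh rate at
$W_0=1.2$, $\beta=1$ this yields $S_0/L = 0.16770$ for $s=1/2$ and
$0.07648$ for $s=1/4$ — the corresponding two- and one-significant-figure
values are what the phase-portrait analysis is usually quoted at, and the
acceptance script reports the computed values at full precision. The mean
extinction time follows as $\ln\tau_e = \epsilon^{-2} S_0/L$ (the intensive
reading of the action; pre-exponential factors are out of scope), so
$S_0/L = 0.15$ at $\epsilon = 0.1$ would give $\ln\tau_e = 15$. The barrier
grows monotonically with $W_0$ and vanishes as $W_0\to 1^+$, where invasion
is marginal.

For spatially structured fields, `field_hamilton_rhs()` provides the full
functional Hamilton right-hand sides (with the transposed kernel in the
momentum equation, equal to the forward kernel for even footprints) and
`integrate_field_hamilton()` verifies conservation of $\mathcal H[q,p]$ to
$10^{-6}$ along initial-value runs; heteroclinic boundary-value problems in
the infinite-dimensional phase space (needed for $x$-dependent steady
states) are out of scope.

## What the presets emulate — and what they do not

The bundled presets reproduce the reference setups: dispersion-curve
families; Dirichlet steady states with boundary layers; pulsating fronts at
$\varepsilon=0.5, 0.8$; the homogeneous invasion front (domain
$[-100,100]$, steep sigmoid initial front at $l=10$, whose printed form is
implemented mirrored so that high activity lies to the *left* of $l$ and
the front invades rightward, the only orientation consistent with the
rightward-moving predictions); the linear slow heterogeneity at
$\epsilon^2\in\{0.005, 0.01\}$; the wandering ensemble
($\epsilon=0.005$, $g(A)=A$, $\kappa=0.8$); and the extinction phase planes
($s=1/2, 1/4$).

Synthetic trajectories generated by these presets probe the *model's* own
predictions under exactly known conditions. They do not emulate features of
real cortical recordings — measurement noise, adaptation and refractory
dynamics, multiple populations, two-dimensional geometry, or inputs — so
passing tests certify the numerics and the asymptotic theory, not the
biological applicability of the scalar model.

## Numerical choices and degenerate inputs

* Fixed points: dense sign-change scan on $[0, \max(2\kappa, 2)]$ plus
  bisection to $10^{-12}$; at piecewise-linear kinks stability uses
  one-sided derivatives and reports `"marginal"` when they disagree; the
  origin is classified by its right derivative since $a \ge 0$.
* Steady states: damped fixed-point iteration (damping 0.5) from the
  uniform nontrivial state to a sup-norm residual of $10^{-10}$.
* Level tracking: linear interpolation; multiple crossings resolve to the
  rightmost (invasion moves rightward); levels never crossed are missing,
  and trials that lose the front are excluded from ensembles with a count.
* Quadrature endpoints: the $s=1/2$ action integrand is finite at zero
  (limit $2(W_0-1)/\beta^2$) and supplied explicitly; for $s<1/2$ it
  vanishes.
* Tabulated heterogeneity profiles interpolate linearly and extend flat
  beyond the table, with a warning.
* Serialisation: model and experiment configs round-trip exactly through
  YAML; unknown keys are rejected; outputs carry a provenance header
  (config hash, seed, package version), and repeated runs with the same
  seed are byte-identical.

## Known limitations

* Plain late-time speed fits sit several percent below $c_0$ at feasible
  horizons; use the logarithmic-shift-corrected fit when an accurate
  $c_0$ estimate from simulation is needed.
* The sharp-interface predictions assume slow, weak modulation; the
  package documents (and the tests exercise) the breakdown at
  $t=O(1/\epsilon^2)$.
* The wandering variance prefactor depends on the noise-amplitude
  convention and is not a portable quantity; only the exponent is.
* Finite-cutoff dispersion corrections, pushed-front selection,
  Stratonovich speed shifts, and pre-exponential factors in the extinction
  time are all out of scope.
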