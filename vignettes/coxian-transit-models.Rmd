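---
title: "Transit compartment tumor models with Erlang and Coxian delay kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transit compartment tumor models with Erlang and Coxian delay kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxtcm)
```

## The model

Drug-induced tumor cell death is not instantaneous: cells hit by a cytotoxic
agent pass through a cascade of damaged states before they die. Transit
compartment models (TCMs) represent that cascade as a chain of ordinary
differential equations. `coxtcm` implements two members of this family and
the machinery around them.

The state is a proliferating mass $u(t)$ and damaged masses
$y_1, \dots, y_n$, with total burden $w = u + \sum_i y_i$. Proliferation
follows one of two laws:

* **dual-regime (Simeoni-type)**:
  $k_{in}(u, w) = \lambda_0 u \, / \, (1 + ((\lambda_0/\lambda_1) w)^\phi)^{1/\phi}$ —
  exponential at rate $\lambda_0$ below the threshold mass
  $w_{th} = \lambda_1/\lambda_0$ and linear ($\lambda_1 u / w$) above it,
  with $\phi$ controlling the sharpness of the switch;
* **logistic**: $k_{in} = \lambda_0 (1 - w/u_{max}) u$ with carrying
  capacity $u_{max}$.

Drug kill moves mass out of the proliferating pool at rate
$k_{out}(C, u) = \eta \, C \, u$, where $C(t)$ is the drug concentration
(from a two-compartment PK model with bolus dosing, a constant infusion, or
any user function).

The two chains differ in what happens at each transit. The **Erlang TCM**
(the classical Simeoni chain) passes every damaged cell down the full
cascade:
$$\dot y_1 = k_{out} - k_1 y_1, \qquad \dot y_i = k_1 (y_{i-1} - y_i),$$
so the residence time in the damaged state is Erlang with mean $n/k_1$. The
**Coxian TCM** additionally lets a fraction of cells die *immediately* at
each transition: with continuation probability $p$,
$$\dot y_1 = k_{out} - k_1 y_1, \qquad \dot y_i = p\, k_1 y_{i-1} - k_1 y_i,$$
which is the chain induced by a Coxian phase-type residence-time law under
the equal-instant-death-rate assumption $(1-p_i)k_i$ constant across
phases, with the phase-wise $p_i$ and $k_i$ replaced by their means. At
$p = 1$ the Coxian chain *is* the Erlang chain; the package treats this as
a hard identity and tests it to $10^{-8}$ pointwise on the full dosing
regimen.

Both chains are exact reductions of one distributed-delay master equation,
$$\dot y = k_{out}(C, u) - (k_{out} * f)(t),$$
where $f$ is the residence-time density (the age-structured survival
formulation; the survival function is taken as
$S(a) = \exp(-\int_0^a \mu(\alpha)\,d\alpha)$ — the sign and upper limit
follow from $dS/da = -\mu S$, and the implementation uses this form
throughout). `convolution_oracle()` integrates this equation directly and
serves as an independent oracle for the chain reduction (the linear chain
trick): the acceptance suite demands agreement within $10^{-3}$ relative
with at least first-order improvement under grid halving, and a
near-degenerate kernel (Erlang with $n = 200$) is checked against the
pure-delay (DDE) limit.

## Phase-type kernels

`phase_type_spec(alpha, S)` holds an absorption-time law
$f(t) = \alpha e^{St} S^0$ with $S^0 = -S\mathbf{1}$. Erlang and Coxian
kernels are constructed by `erlang_spec()` / `coxian_spec()` +
`coxian_generator()`. Densities and CDFs are evaluated with a
scaling-and-squaring matrix exponential (`Matrix::expm`; the Erlang
sub-generator is a single Jordan block, i.e. maximally defective, so
eigendecomposition-based exponentials are inaccurate — this drove the
choice of backend). Means come from $-\alpha S^{-1}\mathbf{1}$ and are
cross-checked by Monte-Carlo simulation of the embedded jump chain.
Degenerate hypoexponential specifications (all $p_i = 1$ with unequal
$k_i$) are representable but sit outside the mean-reduction assumption
used by the Coxian chain; they are supported at the phase-type level only.

## Parameters, units and defaults

The bundled `mouse150` configuration carries the xenograft study
conditions: implant at day 0 with $w_0 = 0.0121$ g; Simeoni growth
$\lambda_0 = 0.25\,\mathrm{day^{-1}}$, $\lambda_1 = 0.4603\,\mathrm{g\,day^{-1}}$,
$\phi = 20$; chain $n = 4$, $k_1 = 0.2859\,\mathrm{day^{-1}}$ (total mean
residence time $n/k_1 \approx 14$ days), fitted $p = 0.44268$; PK
$k_{01} = 1.6$, $k_{21} = 0.2353$, $k_{12} = 0.1699\,\mathrm{day^{-1}}$,
$V = 1028$ ml; ten daily boluses of $4.5 \times 10^7\,\mathrm{ng\,kg^{-1}}$
from day 13.

**Concentration-unit reconciliation.** The nominal kill potency
$\eta = 0.7816$ is quoted without a concentration unit. Taken per ng/ml it
puts the critical infusion concentration $\lambda_0/\eta$ at
$0.32$ ng/ml — four orders of magnitude below every simulated plasma
concentration (post-bolus peak $\approx 4.4\times 10^4$ ng/ml), so under
constant infusion anywhere near the simulated exposure the tumor would be
eradicated instantly and the threshold analysis would be vacuous. The
infusion analysis, however, places the threshold at $4032.3$ on the same
scale as the PK output. The package therefore adopts
$\eta = \lambda_0 / 4032.3 = 6.19994\times 10^{-5}\,\mathrm{ml\,ng^{-1}\,day^{-1}}$
for the `mouse150` scenario — the unique value consistent with both the PK
model and the threshold — and records the nominal 0.7816 in the fixture
metadata. With this convention the simulated drug-effect phase (deepest
divergence between the $p=1$ and fitted-$p$ trajectories) falls in days
13–30, and concentrations cross the threshold about two weeks after the
last dose.

The bundled `spheroid` configuration holds the constant-concentration
assay constants: logistic $\lambda_0 = 0.12\,\mathrm{h^{-1}}$,
$u_{max} = 0.0066\,\mathrm{mm^3}$, $\eta = 0.0035\,\mathrm{\mu M^{-1} h^{-1}}$,
$k_1 = 0.1682\,\mathrm{h^{-1}}$, Erlang $n = 4$ / Coxian $n = 5$ with
$p = 0.9$, sampling at 0, 1, 2, 3, 6, 24, 48, 72 h. The initial spheroid
volume is not reported; the fixture fixes $w_0 = 5\times10^{-4}$ mm$^3$,
small enough that the control series traverses the full logistic rise
within the 72 h window (which is what makes $\lambda_0$ and $u_{max}$
jointly identifiable from the control arm). That value is a documented
synthetic-design choice, not an assay fact.

## Dosing and solver choices

Bolus events **add** the dose to the central compartment (standard
superposition); a literal reset interpretation is available as
`bolus_mode = "reset"`. The residual from the previous day is small
($k_{01} = 1.6\,\mathrm{day^{-1}}$) but not zero, so the two conventions
are distinguishable and both are exposed. Integration never steps across a
dose: the PK integrator restarts at each event, and the tumor simulation
co-integrates the PK amounts with solver events rather than interpolating
a precomputed concentration.

The default integrator is `lsoda` at `rtol = 1e-8`, `atol = 1e-10`. With
the reconciled potency the kill rate reaches $\eta C \approx 3\,\mathrm{day^{-1}}$
at peak — mildly stiff against the growth scale — and `lsoda` switches
methods automatically; a fixed explicit Runge–Kutta pair is available via
`method = "ode45"` for users who want the classical choice. Trajectory
states below $-10^{-9}$ abort the run rather than being clipped, so a
mis-specified model cannot silently produce negative masses; drug-free
compartments stay at exactly zero because the initial damaged state is
exactly zero ($\phi(a, 0) = 0$: before treatment the whole tumor is
proliferating).

The dual-regime growth law is evaluated in log-domain: at $\phi = 20$ the
bracket $((\lambda_0/\lambda_1) w)^\phi$ overflows double precision already
at $w \sim 10^{16} w_{th}$, and the log-sum-exp form is exact for all
masses.

The convolution oracle uses a fixed uniform grid (default
$\Delta t = 0.005$; acceptance runs use 0.01 against 0.005), a Heun
predictor–corrector for the coupled $(u, y)$ system and trapezoidal
quadrature of the age convolution that keeps one-sided limits of $k_{out}$
at bolus instants, preserving second-order accuracy between events. A
Richardson self-check (`check_refinement = TRUE`) warns when the grid is
too coarse.

## Equilibria under constant infusion

For constant $\bar C$ the fate of the tumor is decided by the single ratio
$\lambda_0/\eta$: above it only the zero equilibrium exists and it is
locally (and in simulation, globally) attracting; below it a nonzero
equilibrium appears and zero destabilizes; exactly at the threshold a
continuum of equilibria arises (reported only under a $10^{-12}$ relative
collision test, and stability classification is refused there because the
Jacobian is structurally singular along the manifold).

The nonzero equilibrium is computed by **direct algebraic solve** of the
chain: $\bar y_i = (\eta \bar C \bar u / k_1)\, p^{i-1}$, total factor
$1 + (\eta \bar C / k_1) \sum_{i=0}^{n-1} p^i$ (the geometric factor, with
an explicit $p = 1$ branch), and $\bar w$ from inverting the growth law —
for the dual-regime law
$\bar w = w_{th}\,((\lambda_0/\eta\bar C)^\phi - 1)^{1/\phi}$ exactly, which
tends to $\lambda_1/(\eta \bar C)$ in the sharp-switch limit; for the
logistic law $\bar w = u_{max}(1 - \eta\bar C/\lambda_0)$. Two commonly
quoted closed forms are reported alongside in `$printed` but never
asserted: the sharp-switch limiting $\bar u$ (indistinguishable from the
exact solve away from the threshold, badly wrong near it), and a logistic
variant whose last damaged compartment lacks its $p^{n-1}$ attenuation
and is not a steady state of the chain (the direct solve zeroes the
right-hand side to machine precision; that printed form does not).

Two structural monotonicities are tested: $\bar u$ is strictly decreasing
in $p$ at fixed $\bar C$ below threshold (the geometric factor is strictly
increasing in $p$), and in a single-dose logistic scenario the time of the
post-dose tumor nadir is non-decreasing in the Erlang chain length $n$.
The nadir scenario ($\lambda_0 = 0.08\,\mathrm{day^{-1}}$, $u_{max} = 2$ g,
$w_0 = 1$ g, one bolus at day 2, horizon 150 days) is a package design:
regrowth must be slow enough that every chain length $n = 1..8$ produces a
genuine post-dose minimum, otherwise the longer chains hold mass in the
damaged compartments and the burden never dips below baseline. Note that
the *total* equilibrium burden $\bar w$ in the sharp-switch regime is
$p$-independent — only its split between $u$ and the chain moves with $p$
— so the $p$-monotonicity is asserted for $\bar u$, never for $\bar w$.

Stability is classified from a numerical Jacobian (central differences on
a smooth extension of the right-hand side, so boundary equilibria are
differentiated correctly) with eigenvalue tolerance $10^{-10}$. Global
statements are probed, not proved: long-run simulation to $t = 2000$ from
the implant mass must land on the predicted attractor within $10^{-4}$
relative for every stable case in $n \in \{2,3,4\}$,
$p \in \{0, 0.5, 1\}$, under both growth laws.

## Estimation

`fit_least_squares()` is bounded Levenberg–Marquardt (via `minpack.lm`) on
stacked, unweighted natural-scale residuals of total burden — the direct
analogue of `lsqnonlin` least squares. The optimizer accepts only
loss-decreasing steps, so a refit started from a previous solution can
never end worse (tested). Residual weighting and the optimizer tolerances
are package defaults, not study facts. Five Latin-hypercube starting
points (seeded, RNG-state preserving) guard against local minima; fitting
$p$ and $k_1$ jointly from a single series triggers an identifiability
warning because the two delay parameters trade off along the mean
residence time $n/k_1$ and the chain leak $(1-p)k_1$.

Goodness of fit is the range-normalized RMSE
$\sqrt{\tfrac1n\sum (y_i - \hat y_i)^2} \,/\, (y_{max} - y_{min})$ with the
range taken from the *observed* series; it is dimensionless, scale
invariant, and recomputable from the stored residuals to $10^{-12}$.

`staged_spheroid_fit()` implements the three-stage constant-concentration
protocol: $(\lambda_0, u_{max})$ from the control arm under pure logistic
growth; $(k_1, \eta)$ from the treated arms under the Erlang logistic TCM
with stage-1 values fixed; $p$ alone under the Coxian TCM with everything
else fixed. For the recovery benchmark each stage's synthetic data is
generated from the model that stage fits (control from drug-free logistic
growth, stage 2 from the Erlang chain, stage 3 from the Coxian chain with
$p = 0.9$): a single generating model cannot make all five constants
jointly identifiable across stages, because stage 2 would then be fitting
an Erlang chain to Coxian-generated curves and absorb the mismatch into
biased $(k_1, \eta)$. With stage-matched data the whole quintuple
$(0.12, 0.0066, 0.1682, 0.0035, 0.9)$ is recovered to better than
$10^{-3}$ relative from noise-free series.

## What the synthetic data does and does not emulate

`generate_xenograft_dataset()` reproduces the *design* of the mouse
experiment — implant mass, ten daily boluses from day 13, ten samples —
with sampling days placed uniformly over days 13–40 because the actual
measurement days are not reported. `generate_spheroid_dataset()`
reproduces the assay design: constant concentration per arm, the eight
sampling times, optionally 30 replicates per group. Volumes are generated
directly in model units; the ellipsoid formula
$0.5 \cdot \ell \cdot s^2$ used to derive assay volumes from diameters is
noted but raw diameters are not simulated. The noise model is a package
choice (the study reports none): proportional lognormal with
$\sigma = 0.05$ by default, additive Gaussian (zero-truncated) as an
alternative, bit-reproducible given the seed. Passing recovery tests on
these datasets therefore demonstrates correctness of the estimation
machinery under the stated designs — not robustness to assay artifacts
(edge effects, measurement floors, correlated replicates), which are out
of scope.

Problem sizes used by the test and acceptance runs — 10 (xenograft) and 8
(spheroid) observations per series, 20 Monte-Carlo noise replicates,
$10^5$ phase-type draws, convolution grids of $4000$–$8000$ steps,
long-run horizons of $t = 2000$ — mirror the study designs where stated
and otherwise keep each check comfortably converged at the asserted
tolerance.

## Known limitations

* The Coxian chain uses the mean-$p$, mean-$k$ reduction; phase-wise
  $(p_i, k_i)$ are supported in the phase-type layer but not in the ODE
  chain, whose identifiability from a single series would be poor anyway.
* No saturating drug-effect model is included: the kill term is strictly
  bilinear in $C$ and $u$, so extrapolation far above the calibrated
  concentration range over-predicts inhibition.
* Infusion dosing in the tumor co-integration path is supported through a
  concentration function or a constant; the PK event machinery handles
  zero-order infusion for the PK model itself.
* Stability verdicts are local (spectral); "global" behavior is checked by
  simulation probes only.
* Mixed-effects (population) estimation, Bayesian inference, and
  Mittag-Leffler/fractional kernels are out of scope.
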