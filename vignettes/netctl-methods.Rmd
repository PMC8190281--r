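---
title: "netctl: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netctl: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`netctl` treats task-related brain activity as the state of a linear
time-invariant system evolving on a structural connectome,

$$\dot{x}(t) = A\,x(t) + B\,u(t),$$

where $x(t)$ is a length-$n$ vector of region-wise activation, $A$ is
derived from a weighted, symmetric, FA-like structural connectivity matrix,
$B$ selects the regions allowed to inject control input (the identity by
default, so every region is an independent controller), and $u(t)$ is the
control signal. Transitions between two empirically defined states
$x_0 \to x_T$ (e.g., an attention-control and a working-memory activation
pattern) are modeled as the solution of the finite-horizon optimal control
problem with Hamiltonian cost

$$\min\; H(p, x, u, t) = x^\top x + \rho\, u^\top u + p^\top(Ax + Bu).$$

The first-order conditions give $u^* = -B^\top p / (2\rho)$ and a linear
two-point boundary value problem in the augmented state $(x, p)$ with block
matrix $\bigl[\begin{smallmatrix} A & -BB^\top/2\rho \\ -2I & -A^\top
\end{smallmatrix}\bigr]$. `optimal_control()` exponentiates this matrix
once over the horizon, solves a dense linear system for the initial costate
$p(0)$ such that $x(T) = x_T$, and then propagates the augmented state on a
uniform grid by repeated multiplication with the one-step exponential. From
the optimal input, the per-node control energy is

$$E_{k} = \int_0^{T} \lVert u^*_{k}(t)\rVert^2\, dt,$$

integrated by composite trapezoid on the grid; the total energy $E$ is the
sum over control nodes, and analyses use $\log_{10} E$. The stability of a
state is the inverse log-energy of its self-maintenance,
$S = 1 / \log_{10}(E_{x_0 = x_T})$. The control impact of region $i$ is the
change in total transition energy when row/column $i$ of $A$, entry $i$ of
both states, and region $i$'s control channel are removed and the problem
re-solved.

### Assumptions worth stating

* The linear model is a local approximation: states are stationary spatial
  patterns (GLM beta maps in the emulated study), not time-resolved
  activity, and intermediate trajectory points are virtual.
* The cost is quadratic and the dynamics noiseless; "energy" is the control
  effort of the linear-systems framework, not a metabolic quantity.
* $A$ must be strictly stable for the boundary solve and the discretization
  to be well posed; raw nonnegative connectome weights are not, which
  motivates the stabilization step below.

## Stabilization of the connectome

The source analyses never state how the raw FA-weighted matrix is made
stable; some transformation is implied because a nonnegative symmetric
matrix has a positive leading eigenvalue. `stabilize()` defaults to the
convention of the continuous-time network-control literature,

$$A = \frac{W}{\lambda_{\max}(W) + 1} - I,$$

which is strictly stable for every nonnegative symmetric $W$ and keeps the
relative weight structure intact. The scheme is recorded in the returned
object's `normalization` tag, and a `"scaled"` variant (divide by
$\lambda_{\max}+1$, subtract a configurable $c\,I$) is available. Asymmetry
below $10^{-8}$ in loaded files is treated as file-precision noise and
symmetrized; anything larger is an error. Diagonals are zeroed (FA of a
region with itself is undefined).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `horizon` (T) | 1 | arbitrary time | convention of the cited literature; all cohort comparisons use one fixed T |
| `rho` | 1 | dimensionless | no a priori preference between input cost and trajectory deviation |
| `nsteps` | 1001 | grid points | trapezoid quadrature error well below 0.5% on test instances, cheap at n = 374 |
| `boundary_tol` | 1e-4 | relative | endpoint miss above this aborts with the boundary-block condition number |
| `sigma` | 0.05 | fraction of RMS(u\*) | a "subtle" perturbation relative to the optimal input |
| `n_iter`, `n_repeat` | 200, 10 | counts | 10 x 200 = 2000 suboptimal trajectories per subject |

Stability is undefined or sign-flipped when the maintenance energy is at or
below 1 ($\log_{10} E \le 0$). Empirical maintenance energies of
beta-pattern-scale states are far above 1; rather than return sign-flipped
values, such results are flagged `valid = FALSE` with `stability = NA`, and
cohort statistics drop them listwise with a logged count.

Control impact is reported as $E_{\text{removed}} - E_{\text{baseline}}$
(positive: the region's presence lowers the energy demand). Ranking uses
absolute impact, descending, ties broken by node index; the top
$\lceil f\,n\rceil$ regions are returned (at $f = 0.2$ and $n = 374$, 75
regions).

## Discretization and suboptimal trajectories

For the perturbation analysis the system is discretized by zero-order hold:
$\bar A = e^{A T_s}$, $\bar B = \bigl(\int_0^{T_s} e^{A s} ds\bigr) B$,
with the sampling time tied to the system's own timescale,
$T_s = \mathrm{RT}/10$, where $\mathrm{RT} = \ln 9 / \max_i
|\mathrm{Re}\,\lambda_i(A)|$ is the 10-to-90% rise time of the fastest
first-order mode (complex modes contribute through their real part).

Perturbations are applied to the control input, not the states: a state
perturbed directly would violate the dynamics, whereas a perturbed input
yields a lawful, dynamics-consistent suboptimal trajectory through
$\bar x(t+1) = \bar A \bar x(t) + \bar B \bar u(t)$. Each of the
`n_iter` iterations adds i.i.d. Gaussian noise to every input sample. One
subtlety: with a per-sample standard deviation fixed at
$\sigma\,\mathrm{RMS}(u^*)$, the induced trajectory dispersion would scale
as $\sqrt{T_s}$ and the summary would depend on the (heuristic) sampling
step. The noise is therefore parameterized as discretization-invariant
input white noise: the per-sample sd is $\sigma\,\mathrm{RMS}(u^*)$
*exactly at the canonical step* $T_s = \mathrm{RT}/10$ and scales as
$1/\sqrt{T_s}$ away from it, so halving $T_s$ leaves the deviation summary
unchanged to first order.

At each discrete timestep, PCA is applied to the cloud of perturbed state
points; the first component carries the summary (its variance fraction is
reported per timestep). The deviation statistic is the maximum absolute
distance between the projections of the perturbed points and of the optimal
point on PC1, normalized per timestep by $\lVert x^*(t)\rVert_2$ and
averaged over timesteps, times 100 — a scale-free percentage. The
normalization denominator and the average-over-timesteps choice are design
decisions (the source description leaves both open); the per-timestep trace
is exposed so either convention can be recovered. Degenerate clouds (all
points identical) have deviation 0 and PC1 fraction 1 by convention; the
all-share-$x_0$ first timestep is excluded from the degeneracy log.

## The synthetic cohort generator

No imaging or genetic data are deposited with the source study, so
`make_cohort()` generates cohorts with the statistical structure the
analysis assumes:

* **Connectomes** — modular graphs over 374 regions by default (8 modules,
  density 0.25), weights drawn from Beta distributions bounded in $[0,1]$
  like FA, within-module mean 0.5 versus 0.2 between.
* **State pairs** — the 0-back state is focal (10% of nodes, essentially
  one module) with amplitude 1; the 2-back state is nested, more
  distributed (40% of nodes across several modules) with amplitude 2, plus
  i.i.d. Gaussian noise (sd 0.05 at cohort level). All subjects in a
  cohort share a spatial template (support ordering and loadings) and
  differ by noise and by subject-level dispersion.
* **Patient degradation** — weight-preserving rewiring relocates a
  fraction of edge weights to random node pairs, preserving the exact
  weight multiset and total strength, so group differences arise from
  topology rather than weight loss; `rewire_fraction` is
  `0.25 * energy_d` (a fixed conversion, capped at 1 with a warning
  reporting that the achieved effect will fall short).
* **Stability effect** — the requested group deficit `stability_d` (in
  Cohen's d units) is injected by shifting the patients' 2-back
  *dispersion* latent: each subject's 2-back pattern is rescaled around
  its own mean by a lognormal factor (sd `sigma_amp` = 0.35 on the log
  scale), and patients' log dispersion is shifted by
  `stability_d * sigma_amp`. The scaling is mean-preserving by
  construction, which matters: the statistics covary mean activity, and an
  effect injected through raw amplitude would be absorbed by that
  adjustment. `sigma_amp` = 0.35 makes the dispersion latent the dominant
  between-subject variance source in log maintenance energy (the
  connectome and pattern-noise contributions are smaller), so the realized
  group d tracks the requested one; the value is in the range of typical
  between-subject variability of fMRI effect amplitudes.
* **Gene scores** — standardized scalars correlated with the latents:
  `d1_score` anti-correlated with the 2-back dispersion latent (so it
  predicts stability positively), `d2_score` anti-correlated with the
  dispersion-difference latent (so it predicts transition energy
  negatively). They are linear proxies only; no SNP structure is modeled,
  and the "first 5 genetic PCA components" covariates of the original
  analyses have no synthetic counterpart.
* **Covariates** — age ~ N(33, 11) truncated to 18–65, sex ~ Bernoulli(1/2),
  tSNR ~ N(5.52, 0.49) for controls and N(5.26, 0.49) for patients,
  matching the reported sample characteristics.

What the generator does **not** emulate: BOLD time series, HRF or GLM
estimation, tractography and its biases, spatial autocorrelation of
activation maps, site or motion artifacts, and genuine genetic population
structure. A green pipeline test therefore establishes that the estimators
and tests behave correctly on data with the assumed structure — not that
the neurobiological claims of the emulated study are reproduced.

## Statistics

The two-level within-subject factor (condition) is implemented as ANCOVA on
per-subject difference scores, which is numerically identical to the
repeated-measures ANOVA condition effect for two levels and avoids
sphericity machinery the design cannot use. Covariates are mean-centered so
the intercept is the adjusted mean difference; with a between-subject
group, the group term of the difference model is the condition-by-group
interaction and the group term of the subject-mean model is the group main
effect. Covariate-by-condition interactions are not included (the source
description is silent; the simpler model is recorded in the output
metadata). Stability analyses covary the mean activity of the maintained
state; energy analyses covary the absolute 0-back/2-back mean-activity
difference. All tests are two-sided; no multiple-testing correction is
applied. Regressions report standardized coefficients.

## Numerical conventions and degenerate inputs

* Boundary solves report the condition number of the $E_{12}$ block;
  endpoint misses above `boundary_tol` are errors, not silent results.
* Node removals that make the boundary problem unsolvable yield `NA`
  impact with a log entry.
* Identical outcome columns in the difference-score ANCOVA produce the
  exact-null convention F = 0, p = 1.
* Perfect fits in regressions return $|b| = 1$ with infinite t.
* Deviation timesteps with $\lVert x^*(t)\rVert = 0$ and zero spread
  contribute 0; a nonzero spread over a zero-norm reference uses a floor
  denominator of $10^{-12}$.
* `ceiling(fraction * n)` governs the top-impact count everywhere.

## Known limitations

* The matrix-exponential boundary solve is dense ($2n \times 2n$); it is
  comfortable at $n = 374$ but not intended for parcellations an order of
  magnitude larger.
* Energies depend on the stabilization convention; comparisons are only
  meaningful within one scheme (the tag is carried on every system
  matrix).
* The generator's effect-injection calibration is first-order: requested
  and realized group effect sizes agree to within sampling noise at the
  default settings, and the achieved effect shrinks when `energy_d`
  requires capping the rewiring fraction.
* Under isotropic i.i.d. input perturbations with `B = I`, the
  per-timestep suboptimal cloud is close to isotropic and PC1 typically
  explains well under half of the variance — far from the "more than 90%"
  the emulated study reports for its (unspecified) perturbation scheme.
  The PC1-based summary is retained for fidelity to the described
  procedure, and the per-timestep variance-fraction trace is reported so
  users can judge how much of the cloud the summary captures.
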