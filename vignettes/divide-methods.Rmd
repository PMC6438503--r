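---
title: "Diffusional variance decomposition: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusional variance decomposition: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dividemri)
```

## The problem and the signal model

Conventional diffusion MRI encodes along a single direction per shot, which
confounds three distinct tissue properties: microscopic anisotropy of the
cellular structures, their orientation dispersion across the voxel, and
heterogeneity of isotropic diffusivities. Tensor-valued encoding separates
them by varying the *shape* of the encoding: each signal sample carries a
3×3 symmetric positive-semidefinite b-tensor $\mathbf{B}$ with b-value
$b = \mathrm{Tr}(\mathbf{B})$ and shape
$b_\Delta = (\lambda_{ax} - \lambda_{rad})/b$, where $b_\Delta = 1$ is
linear (LTE), $0$ spherical (STE) and $-0.5$ planar (PTE) encoding.

Diffusional variance decomposition (DIVIDE) assumes the voxel signal is a
mixture of Gaussian diffusion tensors. After powder averaging — the
arithmetic mean over encoding directions at fixed $(b, b_\Delta)$ — the
apparent diffusivity distribution is summarised by its mean MD and a
variance that splits into an isotropic part $V_I$ (spread of compartment
mean diffusivities) and an anisotropic part $V_A$ (orientational variance
from microscopic anisotropy). Approximating that distribution by a gamma
distribution gives the closed-form powder signal

$$\bar S(b, b_\Delta) \;=\;
  S_0\left(1 + b\,\frac{V_I + b_\Delta^2 V_A}{\mathrm{MD}}\right)
  ^{-\mathrm{MD}^2 / (V_I + b_\Delta^2 V_A)} ,$$

so a *joint* fit of LTE ($b_\Delta = 1$, sensitive to $V_I + V_A$) and STE
($b_\Delta = 0$, sensitive to $V_I$ alone) shells separates the two
variance components. Derived maps are the kurtosis-style normalisations
$MK_x = 3 V_x / \mathrm{MD}^2$ and the microscopic fractional anisotropy

$$\mu FA \;=\; \sqrt{\tfrac{3}{2}}
  \left(1 + \frac{\mathrm{MD}^2 + V_I}{\tfrac{5}{2} V_A}\right)^{-1/2},$$

the Westin-style definition that retains the $V_I$ contribution; it reads
as the FA the voxel would show if all its microscopic structures were
co-aligned. Units are fixed package-wide: $b$ in ms/μm², diffusivity in
μm²/ms (so $bD$ is dimensionless), gradients in mT/m, time in ms; the ¹H
gyromagnetic ratio is $2.6751\times10^8$ rad s⁻¹ T⁻¹.

The gamma form is a *representation*, not the generating model: when the
true diffusivity distribution has a different shape (e.g. a discrete
two-compartment mixture), the noise-free fit carries a representation bias —
a few percent on MD, but substantial on $V_A$ for stick-like mixtures at
$b$ up to 2 ms/μm², whose powder signal is much heavier-tailed than any
gamma distribution. The accuracy sweep therefore always reports noise bias
relative to the noise-free *fit*, not to the mixture moments.

## Sampling protocol

`build_divide_protocol()` reproduces the whole-brain scheme used at
clinical field strengths: shells at $b$ = 0.1, 0.7, 1.4 and 2 ms/μm² for
both LTE and STE, with 6, 6, 12 and 16 LTE directions and equally many STE
repeats — 80 samples in total, $T_{tot} = n \cdot TR$. STE is not rotated
(it is rotation invariant by construction); LTE directions come from
electrostatic-repulsion point sets. The ordering is volume-interleaved
round-robin across (shell, shape) groups, ascending in $b$ with LTE before
STE, to spread gradient duty evenly; any interleaving that breaks up
same-shell runs would do, and the exact permutation does not affect any
estimate. TE and TR are user inputs: minimising them is a scanner-hardware
problem outside the package's scope.

Direction sets for $n \le 32$ are shipped as plain text, each the best of
50 seeded restarts of a Coulomb-energy minimisation over antipodal pairs
(`repulsion_directions()`); they reproduce the known optima (orthogonal
triplet at $n=3$, icosahedral set at $n=6$). Larger sets are optimised on
demand. Reported $n_{min}$ values are meaningful only relative to a stated
scheme, which is why the scheme ships with the package.

## Gradient waveforms

`btensor_from_waveform()` integrates
$\mathbf{B} = \int q(t) q(t)^\top dt$ with
$q(t) = \gamma \int_0^t g\,dt'$ by trapezoidal quadrature (default grid
0.01 ms; halving the step moves $b$ by well under $10^{-6}$ relative).
Waveforms are stored as *effective* gradients — the sign flip after the
refocusing pulse already applied — so the refocusing condition is simply a
vanishing zeroth moment per channel, enforced at $10^{-9}$ of
$\max|g|\cdot$duration.

`make_bipolar_lte_waveform()` synthesises the LTE waveform as a bipolar
effective-gradient pair: a $+G$ trapezoid filling the pre-refocusing window
$\delta_1$, the refocusing pause $\delta_P$, and a $-G$ trapezoid filling
$\delta_2$, ramps at the slew limit, amplitude found by root-finding
against the numerically integrated b-value (and the second lobe rescaled
to refocus exactly on the sampling grid). A layout in which each half is
itself a zero-area bipolar pair was considered and rejected: with
representative timings ($\delta_1=\delta_2=26$ ms) it cannot reach
$b = 2$ ms/μm² within 80 mT/m, whereas the implemented layout does at
about 41 mT/m. Spherical waveforms are not synthesised — STE b-tensors are
constructed ideally, or integrated from user-supplied waveform files —
because efficient STE design is a numerical-optimisation problem in its
own right.

## The fit

`divide_fit()` minimises the weighted residual
$\sqrt{n_s}\,(\bar S_s - \hat S_s)$ over shells $s$ by
Levenberg–Marquardt, where $n_s$ is the number of samples averaged into
shell $s$ (shell means are heteroscedastic with variance $\propto 1/n_s$).
Choices that matter:

* **Parameterisation** $(\log S_0, \log \mathrm{MD}, V_I, V_A)$: positivity
  of $S_0$ and MD is structural, while the variances stay sign-free.
  Negative variance estimates are deliberately allowed — clipping at zero
  would bias small values upward — and negative $MK$ maps are emitted
  as-is.
* **Starting points**: five seeded uniform draws
  ($\mathrm{MD} \in [0.1, 3]$, $V \in [-0.2, 1.5]$) plus one deterministic
  cumulant start from a weighted quadratic regression of $\log \bar S$ on
  $b$; lowest weighted SSE wins. The cumulant start makes noise-free
  recovery reliable to $10^{-5}$ relative across the parameter space.
* **Degenerate inputs**: as $\mu_2 = V_I + b_\Delta^2 V_A \to 0$ the
  power law tends to $S_0 e^{-b\,\mathrm{MD}}$; below
  $|b\,\mu_2/\mathrm{MD}| < 10^{-5}$ a fourth-order series in $\log \bar S$
  is used, continuous with the exact branch to better than $10^{-9}$.
  Parameter points where $1 + b\,\mu_2/\mathrm{MD} \le 0$ (possible for
  negative variances at high $b$) are rejected with penalty residuals.
* **$\mu FA$ convention**: the expression is undefined for $V_A \le 0$;
  the package returns 0 there and flags the result
  (`uFA_defined = FALSE`). A single stick compartment gives exactly 1.
* **Tolerances**: relative function tolerance $10^{-10}$, at most 500
  iterations per start; a fit is non-converged only if every start fails,
  in which case parameters are NaN and flagged.

Voxel masks (e.g. MD < 1.5 μm²/ms) are never applied inside the fit; they
belong to the downstream quality statistics.

## Synthetic data: what it emulates and what it does not

No acquired data ship with the package. The forward model generates
per-sample signals $S/S_0 = \sum_i f_i \exp(-\mathbf{B}\!:\!\mathbf{D}_i)$
for mixtures of Gaussian compartments; three presets span the relevant
regimes — `wm_mimic` (high $MK_A$, low $MK_I$), `iso_hetero` (isotropic
with high $MK_I$) and `mki_zero` (anisotropic and isotropic compartments
with matched mean diffusivity, so the true $V_I$ is exactly zero).
Magnitude noise is Rician: $\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$ with
independent Gaussian $\epsilon$ of standard deviation $S_0/\mathrm{SNR}$,
applied per sample *before* powder averaging, independently across volumes
and voxels.

This emulates the signal and noise statistics the estimator sees. It does
**not** emulate: subject motion and eddy currents (no registration is
performed anywhere), spatially correlated reconstruction noise, partial
volume at tissue interfaces, relaxation-time contrast ($S_0$ is a free
map), diffusion-time dependence, exchange, or intra-compartment kurtosis —
the multi-Gaussian assumption is exact in simulation by construction.
Passing simulation tests therefore validates the estimator and its noise
behaviour, not the biophysical completeness of the model on real tissue.

The accuracy sweep defaults to 2000 noise realisations per (tissue, SNR)
cell over SNR ∈ {10, 20, 30, 50, 100} — enough that Monte-Carlo error
(∝ $1/\sqrt{n}$) is a few percent of the parameter SD while a full
three-tissue sweep runs in minutes on one core; `n_reps` raises it (e.g.
to $10^4$) when tighter summaries are wanted. The sweep records the
noise-free reference fit, per-cell means and SDs, and the incidence of
negative variance estimates.

Two behaviours of the sweep are worth knowing when reading its output.
First, $MK_I$ is consistently less precise than $MK_A$: isotropic variance
is read from the curvature common to both encoding shapes, anisotropic
variance from their *difference*, and the common-mode channel also absorbs
the Rician floor. Second, and for the same reason, the low-SNR floor bias
loads onto $MK_I$; a parameter whose true value is zero and whose sign is
free — such as $V_A$ in an isotropic-but-heterogeneous tissue — shows no
detectable mean bias even at SNR 10, while its realisations scatter into
negative values. Clipping variances at zero would turn exactly that
scatter into positive bias, which is why the fit never clips.

## Rotation invariance and $n_{min}$

A powder average over finitely many directions is only approximately
rotation invariant. `powder_cv()` quantifies the residual: a single
prolate axisymmetric tensor substrate is built from (MD, FA) by inverting
the FA formula (the minimal substrate consistent with a scalar anisotropy
level), rotated 1000 times under a seeded uniform quaternion sampling, and
the CV of the $n$-direction powder mean across rotations is reported.
`find_nmin()` scans $n$ upward on a shared rotation sample and returns the
first $n$ with CV < 1% (no hysteresis). Doubling the rotation count moves
CV estimates by under 10%, and the scan is deterministic under a fixed
seed. With the shipped direction sets, a substrate with MD = 1.8 μm²/ms
and FA = 0.1 at $b = 1.3$ ms/μm² — diffusivities typical of tumour tissue —
needs only $n_{min} = 3$ directions, against 16 at $b = 2$ for
healthy-brain anisotropy; near band boundaries other direction schemes can
shift $n_{min}$ by ±1.

## Quality statistics

`snr_map()` estimates per-voxel SNR at each b-value as mean/SD across the
repeated STE samples, on *unregistered* data (registration would align the
noise and overestimate SNR — not an issue for the phantom generator, which
never moves). $Q_3$ and $Q_6$ are the masked fractions with SNR above 3
and 6 at the highest b-value; the mask keeps MD < 1.5 μm²/ms, and
zero-variance voxels are flagged infinite and excluded (SD floor
$10^{-12}\cdot$mean). $Q_6 \le Q_3$ holds by construction.

`repeatability()` summarises test–retest differences
$\Delta X = X_1 - X_2$ by their mask-restricted mean (bias) and SD
(precision), plus Bland–Altman points with mean and ±2 SD lines. The
default mask keeps μFA > 0.7 *and* MD < 1.5 μm²/ms — a
coherent-white-matter mask that avoids the misregistered periphery and CSF
partial volume. Both thresholds are arguments: studies targeting
low-anisotropy tissue should lower or invert the μFA criterion, and
published descriptions of this mask are not fully consistent across
sources, so the package treats it as configurable rather than canonical.

## Worked example

```{r example, eval = FALSE}
protocol <- build_divide_protocol(TR = 5000, TE = 115)
tissue <- tissue_preset("wm_mimic")
signal <- add_rice_noise(dwi_signal(tissue, protocol$btensors),
                         snr = 50, seed = 1)
fit <- divide_fit(powder_average(signal, protocol))
summary(fit)
plot(fit)
```

## Known limitations

* The gamma representation biases parameters when the true diffusivity
  distribution departs strongly from it; the noise-free reference fit in
  `run_accuracy_sweep()` makes that bias visible but does not remove it.
* Only axisymmetric b-tensors enter the fit ($b_\Delta$ well defined);
  general asymmetric encodings are rejected by `btensor_shape()` beyond a
  1% radial-eigenvalue spread.
* The voxel-wise image fit is a plain R loop — adequate for phantoms and
  ROIs; whole-brain volumes at full resolution would want coarse
  parallelisation around `divide_fit_image()`.
* No registration, brain extraction or artifact correction is provided;
  inputs to the quality statistics are assumed co-registered.
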