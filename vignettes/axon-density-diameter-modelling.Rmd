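---
title: "Modelling axonal density and diameter with time-dependent extra-axonal diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling axonal density and diameter with time-dependent extra-axonal diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`axontime` implements a two-pool model of the diffusion-weighted STEAM
signal in coherently oriented white matter. A measurement is described by
its unit gradient direction, pulse duration $\delta$, pulse spacing
$\Delta$, mixing time $TM$ and gradient amplitude $g$ (equivalently the
b-value $b = (\gamma\delta g)^2(\Delta-\delta/3)$ under the
rectangular-pulse convention, or the reciprocal wavevector
$q = \gamma\delta g/2\pi$). The signal is

$$S(\mathbf q, \Delta) = e^{-TM/T_1}\, S_0 \left[(1-f_r)\,S_h(\mathbf q,\Delta) + f_r\,S_r(\mathbf q,\Delta)\right],$$

where $f_r$ is the restricted (intra-axonal) signal fraction — the axonal
density index — and the $e^{-TM/T_1}$ factor is the longitudinal decay a
stimulated echo accumulates over its mixing time, which changes with
$\Delta$ and must therefore be modelled whenever several diffusion times are
combined.

Because displacements parallel and perpendicular to the fiber are
statistically independent, both compartment signals factor into parallel
and perpendicular parts.

**Restricted pool.** Parallel to the fiber the intra-axonal water is free,
$S_{r,\parallel} = \exp(-4\pi^2 q_\parallel^2(\Delta-\delta/3) D_{r,\parallel})$.
Perpendicular, the water is confined in impermeable cylinders and follows
the classical eigenmode series for finite-width gradient pulses: the
log-signal is $-8\pi^2 q_\perp^2$ times a sum over modes $\alpha_m$
given by the roots of $J_1'(\alpha_m R)=0$. The series is truncated at
`m_max = 30` terms; terms decay as $\alpha_m^{-6}$, and the suite verifies
that 20- and 50-term evaluations agree to $10^{-9}$ over the regimes of
interest (radii up to 5 µm, b up to 4000 s/mm²) and that the truncated
value matches an independent 200-term evaluation to $10^{-10}$. Signals
from a distribution of radii mix with *area* weights
$w_i \propto P(r_i)\,r_i^2$, because a cylinder contributes signal in
proportion to its water content.

**Hindered pool.** The extra-axonal signal is Gaussian,
$S_h = \exp(-4\pi^2(\Delta-\delta/3)\,\mathbf q^\top D_h \mathbf q)$, with
an axially symmetric tensor. Three variants of its perpendicular component
are implemented:

* *free tensor* — $D_{h,\perp}$ is an independent fitted parameter per
  diffusion time;
* *tortuosity* — $D_{h,\perp} = D_{h,\parallel}(1-f_r)$, the constraint
  used by NODDI/ActiveAx-style models;
* *time-dependent* —
  $D_{h,\perp}(\Delta) = D_\infty + A\,\frac{\ln(\Delta/\delta)+3/2}{\Delta-\delta/3}$,
  the long-time behaviour of diffusion transverse to a short-range
  disordered fiber packing. $D_\infty$ (µm²/ms) is the bulk diffusivity and
  $A$ (µm²) scales with the squared correlation length of the packing
  disorder. The logarithmic form is a long-$\Delta$ approximation; the
  package evaluates it at any $\Delta > \delta$ and warns below
  $\Delta/\delta = 2$ (the nine-diffusion-time protocol modelled here
  starts at $\Delta/\delta \approx 2.8$).

Throughout, a single diffusivity ties $D_{r,\parallel}$,
$D_{h,\parallel}$ and the intrinsic perpendicular diffusivity $D_f$ of the
restricted cylinders, which is the parsimony the fitting protocols assume.

### Units

Internally everything is ms / µm / µm²/ms (1 µm²/ms = $10^{-3}$ mm²/s);
b-values are accepted and reported in s/mm² and gradient amplitudes in
mT/m. The gyromagnetic ratio is fixed at the proton value
$2.6752218744\times10^8$ rad s⁻¹ T⁻¹. This keeps optimiser gradients at
order one instead of $10^{-9}$.

## The acquisition

`steam_scheme()` builds the nine-diffusion-time STEAM protocol the
simulations emulate: $\delta = 17$ ms, $\Delta = 48 \ldots 195$ ms, four
b-values (500–4000 s/mm²) on five directions (two in-plane diagonals, the
two in-plane axes, and the fiber axis), plus two b = 0 images per
diffusion time — 198 rows in total. The mixing time tracks the diffusion
time with a constant offset, $TM = \Delta - 33.6$ ms, inferred from the
protocol's $TM$ and $\Delta$ lists and exposed as
`STEAM_TM_OFFSET`. A reported in vivo protocol size of 216 measurements
does not decompose into this direction/b/b0 grid
($9\times(5\times4+2) = 198$); the builder produces the reconstructable
198-measurement reading. In-plane diagonal directions are realised by two
simultaneous gradient axes, which appears here simply as a larger
effective amplitude on a unit direction (up to $70\sqrt2 \approx 99$
mT/m); the per-axis demand never exceeds 70 mT/m.

## The Monte Carlo substrate simulator

The substrate is a periodic square box of parallel, non-overlapping,
impermeable cylinders (axes along x). Because the geometry is invariant
along x, walkers perform a 2D equal-step random walk in the transverse
plane (step $\sqrt{4 D dt}$, specular reflection with exact circle–segment
intersection, periodic wrap) plus an independent free 1D walk axially —
exact for this geometry and three times cheaper than a 3D walk. Phases are
accumulated per measurement from running position integrals under the
effective pulsed-gradient pair (+g over $[0,\delta]$, −g over
$[\Delta, \Delta+\delta]$); the mixing-time $T_1$ factor is applied
analytically. The simulator is validated against closed forms (free MSD
slopes, the uniform-disk displacement variance) and against the analytic
cylinder signal on a single-radius substrate, and every walk audits that
no walker changes compartment.

Radii are gamma-distributed. No specific gamma fit accompanies the target
mean axonal diameters of 1.26–1.94 µm, so the package uses shape $k = 3$ (a moderately broad, right-skewed shape typical
of fiber-calibre histograms) with the scale calibrated so the *truncated*
distribution hits the target mean diameter. Radii are floored at 0.25 µm —
the smallest calibre histology reports — which also bounds the walker step
length needed to resolve the smallest cylinder.

Two numerical contracts matter here:

* the transverse step must not exceed half the smallest radius, or
  reflections are too coarse; `mc_config(n_steps = NULL)` picks the
  smallest adequate step count automatically (with a 2000-step floor), and
  an explicit too-coarse `n_steps` is refused;
* disordered packings are built by random seeding followed by pairwise
  overlap relaxation, keeping a surface-to-surface clearance of 0.02 µm
  between cylinders. Plain sequential insertion jams far below the 0.6
  area fraction the substrates target (an `"rsa"` method is provided for
  lower-density Poisson-like media), and relaxation without a clearance
  leaves exact contacts that disconnect the 2D pore space outright; the
  0.02 µm default is the scale of real extra-cellular sheets and leaves
  the packing strongly disordered — its transverse diffusivity falls with
  diffusion time exactly as the time-dependent extra-axonal model
  describes, which is the behaviour the recovery experiments rely on.

The restricted fraction of the *signal* is set by seeding 60% of walkers
uniformly inside cylinders (cylinder chosen in proportion to its area) and
40% outside, independently of the geometric area fraction; both numbers
are recorded. Ordered-reference substrates are exact periodic hexagonal
lattices at the same area fraction.

Desk-scale defaults ($10^4$ walkers, 5 repetitions from different walker
seeds on a common substrate, 30–40 µm boxes) keep a full recovery
condition within minutes on one CPU; they are an order of magnitude below
the original study's $10^5\times10^4\times30$, which widens Monte Carlo
error bars but leaves every qualitative contrast intact.

## Fitting protocols

All fits are bounded Levenberg–Marquardt least squares (via
**minpack.lm**), with bounds $f_r\in[0,1]$, diffusivities $\in[0,3.5]$
µm²/ms, radius $\in[0.05,5]$ µm, $A\in[0,20]$ µm², and by default five
starts (the nominal start plus four perturbed ±30%, clipped to bounds);
repeated fits under a fixed RNG seed are bit-identical. Standard errors
come from the final Jacobian. The fiber orientation is always supplied,
never fitted.

* `fit_t1()` — $S_0 e^{-TM/T_1}$ on the b = 0 images across mixing times;
  the estimate is fixed in subsequent diameter fits.
* `fit_density()` — one diffusion time at a time, normalised to that
  group's b = 0 mean (removing $S_0$ and $T_1$), with the diameter
  distribution assumed (CHARMED-style prior; delta at 1 µm by default and
  configurable, since no specific histological prior is mandated). Free: $f_r, D_\parallel$ (+ $D_\perp$ for the free-tensor
  variant).
* `fit_diameter()` — all diffusion times jointly; continuous-Poisson
  radius distribution $P(r;\lambda) = \lambda^r e^{-\lambda}/\Gamma(r+1)$
  on a 0.05–5 µm grid (0.05 µm steps), one parameter for both mean and
  width; with or without the time-dependent extra-axonal term. The
  reported mean axonal diameter is twice the count-weighted mean radius of
  the fitted distribution.

### The accuracy study and its initialisation

`run_accuracy_experiment()` reproduces the signal-simulation accuracy
protocol: signals generated from the full time-dependent model over the
$f_r \in \{0.3, 0.5\}$ × radius $\in \{0.25, 1.5\}$ µm ×
$D_0 \in \{1, 2\}$ µm²/ms grid at SNR 30 (Rician, referenced to the
largest-$\Delta$ b = 0 image), refit with the radius distribution assumed
and $f_r, D_\parallel, D_\infty, A$ free, accuracy
$= 100(1-\overline{|\hat\theta - \theta|/\theta})$. Two protocol choices
deserve emphasis. First, the radius is assumed rather than fitted: at
these gradient strengths a 0.25 µm radius attenuates the signal by ~0.03%
against 3.3% noise, so a freed radius parameter just measures the
optimiser's bounds, and *no* protocol that frees it can report uniformly
high accuracy. Second, starts are perturbed ±30% around the generating
truth — a local-accuracy convention chosen a priori; with parameters this
weakly identified a fixed remote start would measure the start, not the
data. The disorder coefficient $A$ is the hardest parameter in this
ensemble by a wide margin, and configurations with the faster $D_0$ make
it harder still.

### Trend classification

`bic_trend_select()` fits constant/linear/quadratic by least squares and
ranks them with $BIC = n\ln(RSS/n) + k\ln n$, $k$ counting the intercept.
With nine points and this penalty, a truly flat noisy series is classified
constant in roughly two-thirds of draws (about 0.8 in a pairwise race
against the linear model alone) — the package asserts those honest rates.
Trend direction is the sign of the winner's net fitted change, floored at
machine noise.

## What the generators do and do not emulate

The analytic generator produces exactly the model's signals plus Rician
noise: passing round-trip and bias tests shows the estimators are correct
*given the model*. The Monte Carlo substrates add what the analytic model
omits — genuine restricted geometry, extra-axonal time dependence arising
from packing disorder rather than from an imposed formula, and
non-Gaussian extra-axonal diffusion — so recovery there is a real
cross-validation. Neither emulates orientation dispersion, membrane
permeability, compartmental $T_1/T_2$ differences, undulation, or any
in vivo confound (motion, distortion, partial volume); agreement on these
simulations therefore says nothing about those effects, and the original
study's in vivo values are not reproducible targets for this package.

## Numerical choices and degenerate inputs

* Bessel-root cache: the universal scaled roots of $J_1'$ are found once
  by bracketed root refinement and rescaled per radius.
* $D_f = 0$ or $q_\perp = 0$ short-circuit to unit restricted signal; the
  series denominators never vanish because $x_m^2 > 1$ for every root.
* A derived negative $D_{h,\perp}$ (impossible for the implemented
  variants, but reachable through hand-built specs) raises an error naming
  the parameters rather than synthesising a non-physical tensor.
* Degenerate trend inputs (all equal) classify as constant without
  touching `lm`.
* The T1 pre-fit flags non-decaying b = 0 data by its upper bound.
* Scheme files are written at 17 significant digits, so round-trips are
  bit-faithful at double precision.

## Known limitations

* The walker step contract (step ≤ half the smallest radius) makes run
  time scale as $D_f/r_\mathrm{min}^2$; very fine substrates are
  expensive.
* The continuous-Poisson family cannot represent very narrow or fat-tailed
  calibre distributions.
* The relaxed packing with clearance is more homogeneous than a Poisson
  (sequentially inserted) medium, so its disorder coefficient $A$ is at
  the low end of what real fiber packings may show; the ordered/disordered
  contrast experiments use the substrate pair to bracket the behaviour.
* Least-squares fitting of Rician magnitudes is used as-is (no Rician
  likelihood), matching the protocols the package reproduces; at SNR 25-30
  this contributes a small floor bias to weakly attenuating signals.
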