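# axontime

Multi-compartment modelling of diffusion-weighted STEAM MRI for estimating
**axonal density** and **axonal diameter** in coherently oriented white
matter, with an extra-axonal compartment whose perpendicular diffusivity
depends on the diffusion time.

## The problem

Two-pool models (CHARMED/AxCaliber/ActiveAx-style) decompose the
diffusion-weighted signal into a restricted intra-axonal pool and a
hindered extra-axonal pool:

```
S(q, Δ) = exp(-TM/T1) · S0 · [ (1 - f_r) · S_h(q, Δ) + f_r · S_r(q, Δ) ]
```

`f_r` is the restricted signal fraction (axonal density);
`S_r` factors into free diffusion along the fiber and the Van Gelderen
eigenmode series for water confined in impermeable cylinders of radius R
perpendicular to it, mixed over a diameter distribution with area weights
`w_i ∝ P(r_i) r_i²`; `S_h` is Gaussian with an axially symmetric tensor.
Classically the extra-axonal perpendicular diffusivity is either fitted
freely or tied by the tortuosity constraint `D_h⊥ = D_h∥ (1 - f_r)` — and
assumed independent of the diffusion time Δ. In disordered fiber packings
it is not:

```
D_h⊥(Δ) = D_∞ + A · (ln(Δ/δ) + 3/2) / (Δ - δ/3)
```

with bulk diffusivity `D_∞` and a disorder coefficient `A` (µm²) scaling
with the squared correlation length of the packing. Ignoring this time
dependence biases density estimates up or down depending on diffusion time
and inflates diameter estimates; modelling it removes both biases. This
package implements the forward model (all three extra-axonal variants),
STEAM acquisition schemes with mixing-time T1 decay, Rician noise, a Monte
Carlo random-walk simulator for substrates of parallel cylinders with
gamma-distributed radii, the bounded nonlinear least-squares fits (density
per diffusion time; diameter over all diffusion times, with a
continuous-Poisson diameter distribution and a T1 pre-fit), and the
simulation experiments that quantify the biases.

## Worked example

Synthesise the nine-diffusion-time STEAM protocol from a known tissue,
add Rician noise, and refit the diameter model:

```r
library(axontime)
set.seed(1)

sch <- steam_scheme()            # δ=17 ms, Δ=48…195 ms, b=500…4000 s/mm², 198 rows
tis <- tissue_params(
  f_r = 0.45,
  hindered = hindered_spec("time_dependent", D_hpar = 1.3, D_inf = 0.6, A = 1.5),
  distribution = axon_distribution("delta", radius = 1.2),
  D_rpar = 1.3, D_f = 1.3, T1 = 800
)
sig <- steam_signal(sch, tis, S0 = 1.4)
fit <- fit_diameter(sig, time_dependent = TRUE, family = "delta")
round(coef(fit), 4)
#>           f_r         D_par             R         D_inf             A mean_diameter
#>          0.45          1.30          1.20          0.60          1.50          2.40
```

The noiseless round trip recovers every generating parameter (0.45, 1.3
µm²/ms, 1.2 µm, 0.6 µm²/ms, 1.5 µm²) and reports the mean axonal diameter
2R = 2.4 µm; `tidy(fit)` / `glance(fit)` give broom-style summaries, and
`autoplot()` methods exist for fits, substrates and experiment reports.

A Monte Carlo recovery on a packed substrate:

```r
radii <- substrate_radii(1.26, 5000, seed = 1)     # gamma radii, mean diameter 1.26 µm
sub   <- pack_cylinders(radii, target_icvf = 0.6, box = 40, seed = 2)
cfg   <- mc_config(n_walkers = 1e4, duration = 212, D_f = 1.5, intra_fraction = 0.6)
sig   <- mc_signal(sub, sch, cfg, T1 = 800, snr = 40, seed = 3)
fit   <- fit_diameter(sig, time_dependent = TRUE)   # Poisson diameter distribution
```

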