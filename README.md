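# ridmefit

Simulation and quantitative fitting of RIDME (relaxation induced dipolar
modulation enhancement) time traces for spin pairs in which one partner is a
strongly g-anisotropic spin-1/2 center — the low-spin Fe³⁺ of a bis-imidazole
heme is the motivating case — and the other is an isotropic organic radical
(nitroxide, trityl). It is aimed at EPR spectroscopists extracting distance
and orientation constraints from metalloprotein PDS data.

## The science in one paragraph

For spins with g ≈ g_e the dipolar coupling is the Pake form
ν₀(r)·(1 − 3cos²θ) with ν₀ = μ₀β_e²g_e²/(4πh r³) ≈ 52.04/r³ MHz (r in nm).
A low-spin ferric center with principal g-values (1.56, 2.28, 2.91) instead
couples as

    ν_dd = (μ₀β_e²/4πh) · (g_eff·g_e / r³) · [1 − 3 (w·n̂)(b̂·n̂)],
    w = (g_x²b_x, g_y²b_y, g_z²b_z)/g_eff²,   g_eff = √(Σ g_i² b_i²),

so the spectrum depends on the orientation (polar ξ, azimuth φ) of the
inter-spin vector in the g-frame. Powder spectra show three singularities
(e.g. 2.91, 0.78 and 1.14 ν₀ when the inter-spin vector lies on the g_zz
axis) instead of the two Pake horns. The package:

* simulates RIDME traces V(t)/V₀ = 1 − (λ/N)Σ(1 − cos 2πν_i t) by
  Monte-Carlo powder averaging over Gaussian distributions of r, ξ, φ;
* generates synthetic datasets (background, noise, optional ESEEM peak) with
  full ground-truth manifests;
* preprocesses traces (cubic background fit and division, modulation depth,
  FFT to the RIDME spectrum);
* fits the six Gaussian parameters with a staged, seeded global search and
  reports 110%-RMSD confidence intervals from 2-D error surfaces;
* quantifies the artifact of ignoring g-anisotropy: an isotropic-kernel
  Tikhonov inversion of an anisotropic trace displaces each distance r to
  r′ = r(g_e/g_eff)^(1/3).

## Worked example

```r
library(ridmefit)

g  <- principal_g(1.56, 2.28, 2.91)        # low-spin ferric heme
m  <- geometric_model(2.48, 0.05, 69, 24, 27, 20)   # r(nm), xi, phi (deg)

## simulate a measurement-like dataset and preprocess it
ds  <- generate_dataset(m, g, lam = 0.30, noise_sd = 0.005,
                        n_mc = 2e5, seed = 11)
pre <- preprocess_trace(ds$trace)
pre$lam
#> [1] 0.3030032

## fit the six-parameter model (reduced budgets for the example)
fit <- fit_time_trace(pre$corrected, g,
                      fit_options(n_mc = 5e3, n_mc_final = 2e4,
                                  n_mc_refine = 0, n_pop = 24, n_gen = 40,
                                  seed = 1))
fit
#> RIDME time-domain fit (RMSD 0.0058177, lambda 0.303, budget exhausted)
#> Gaussian spin-pair geometry:
#>   r   = 2.483 +/- 0.020 nm
#>   xi  = 72.6 +/- 26.2 deg
#>   phi = 6.9 +/- 51.1 deg
#> Symmetry-equivalent (xi, phi) solutions: 8
#> (2-D RMSD surfaces give a lower bound for parameters' uncertainty)

## what an isotropic analysis would have reported
dist <- tikhonov_invert(pre$corrected, lam = pre$lam)
dist$mode
#> [1] 2.32
artificial_distance_bars(2.48, g)
#> [1] 2.189427 2.374924 2.695172
```

The estimated modulation depth (0.303) and the fitted distance distribution
(2.483 ± 0.020 nm against a generating 2.48 ± 0.05 nm) recover the ground
truth at this reduced search budget; the polar angle matches within its
broad uncertainty and the azimuth lands on a symmetry-degenerate solution
(the φ block is the weakly identified one — see the vignette). The
isotropic inversion of the same trace puts the most probable distance at
2.32 nm, 0.16 nm short of the truth, between the artificial distances of
the g_zz (2.19 nm) and g_yy (2.37 nm) axes — the characteristic error of
neglecting g-anisotropy (0.23 nm at the full 10⁶-sample, noiseless
conditions of `scripts/acceptance.R`).

A thin command-line interface covers the same pipeline
(`exec/ridmefit simulate|synth|preprocess|fit|errsurf|invert-iso|singularities`).

## Package layout

* `R/spin_geometry.R` — g-frame conventions, orientation sampling, symmetry
  orbits
* `R/dipolar.R` — anisotropic/isotropic coupling frequencies, powder
  spectra, singularity positions
* `R/trace_model.R` — forward trace model and the synthetic-data generator
* `R/preprocess.R` — background fit/division, modulation depth, FFT
* `R/fitting.R`, `R/optim_de.R` — staged global fit, RMSD surfaces,
  110%-RMSD confidence intervals
* `R/inversion.R` — Pake kernel, NNLS/Tikhonov inversion, artificial
  distances
* `R/io.R`, `R/cli.R` — ASCII/BES3T readers, configs, command line
* `src/` — compiled cosine-sum kernels
* `vignettes/anisotropic-ridme-analysis.Rmd` — models, assumptions, design
  decisions, limitations
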