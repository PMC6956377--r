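# microrelease

Release-kinetics modelling for drug-loaded polymeric microspheres.

Controlled-release formulations — for example PLGA/PLA microspheres
carrying an osteogenic protein or a steroid, embedded in a hydrogel
scaffold — are characterised in vitro by cumulative release curves. When
the drug is molecularly dissolved in the matrix, release is governed by
Fickian diffusion inside the sphere plus a mass-transfer resistance at
its surface. `microrelease` implements that model and the estimation
machinery around it for formulation scientists who need effective
transport constants, not just empirical release percentages.

The forward model for a sphere of radius $R$ is

$$\frac{M_t}{M_\infty} = 1 - \sum_{n\ge1}
  \frac{6L^2}{\beta_n^2(\beta_n^2+L^2-L)}
  \exp\!\left(-\beta_n^2 \frac{D_{eff} t}{R^2}\right),
  \qquad \beta_n\cot\beta_n + L - 1 = 0,$$

with $L = hR/D_{eff}$ the mass-transfer Biot number; for large $L$ the
eigenvalues become multiples of $\pi$ and the series reduces to the
diffusion-controlled limit. `fit_release()` estimates $(D_{eff}, h)$ per
curve by residual-sum-of-squares minimisation with a seeded genetic
algorithm plus Nelder–Mead refinement, searching in log10 space, and
diagnoses weakly identified $h$ (inevitable for diffusion-controlled
data). The package also provides gravimetric mass-loss / water-uptake
formulas, burst-fraction and phase-rate descriptors, a synthetic-data
generator for validation, a Crank–Nicolson finite-difference
cross-check of the series, and strict CSV I/O with a small CLI
(`inst/cli/microrelease.R`).

## Worked example

Simulate one noiseless curve from the slow aqueous medium regime
($D_{eff} = 5.58\times10^{-16}$ m²/s, $h = 4.01\times10^{-10}$ m/s,
$R = 50.7$ µm) and refit it:

```r
library(microrelease)

sc <- builtin_scenarios(noise_sd = 0, n_replicates = 1)$sls_aqueous
curve <- simulate_release_curves(sc)[[1]]
fit <- fit_release(curve, radius = 50.7e-6, config = fit_config(seed = 1))
fit
```

```
Sphere release model fit
  D_eff    : 5.58e-16 m^2/s
  h        : 4.01e-10 m/s
  Biot L   : 36.43
  R        : 5.07e-05 m (fixed)
  RSS      : 4.49e-19 on 12 points
  R^2      : 100.00 %
```

The estimator recovers the generating constants to nine significant
digits: $D_{eff}$ is the matrix diffusivity in m²/s, $h$ the
boundary-layer mass-transfer coefficient in m/s, and their combination
$L \approx 36$ says internal diffusion dominates but the boundary layer
is not negligible. On noisy replicate sets, `fit_replicates()` reports
mean ± SD per condition:

```r
scs <- builtin_scenarios(noise_sd = 0.02, n_replicates = 3)
rs <- fit_replicates(simulate_release_curves(scs$meoh_water),
                     radius = 50.7e-6)
rs
```

```
Replicate release fits (n = 3)
  D_eff : 2.408e-15 +/- 1.15e-16 m^2/s
  h     : 7.385e-10 +/- 1.62e-11 m/s
  R^2   : 99.74 +/- 0.0822 %
```

Each replicate sees its own noise and its own optimizer seed; the ~5%
spread around the generating value 2.28e-15 m²/s is what 2% additive
measurement noise propagates to.

Gravimetric and profile descriptors work on plain containers:

```r
mass_loss_percent(gravimetric_sample(w0 = 100, ww = 80, wd = 70.81))
#> [1] 29.19
cv <- cumulative_release(c(1, 7, 28) * 86400, c(270, 630, 1890), dose = 6000)
burst_fraction(cv)        # fraction of dose in the first 24 h
#> [1] 0.045
phase_rate(cv, 86400, 28 * 86400)  # sustained-phase slope, ng/day
#> [1] 60
```

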