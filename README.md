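# springdamp

Quantitative phenotyping of animal stress responses with a spring–damper
model.

## The problem

When animals face an acute environmental challenge — a confinement, a
transport, a sudden diet change — their physiological and behavioural
measures (cortisol release, oxygen consumption, group activity and
dispersion, feed intake, milk composition, …) deviate from baseline and
then relax back. Robustness language borrowed from physics — *resistance*,
*elasticity*, *recovery* — is common in animal ecology and production
science, but usually stays qualitative. `springdamp` makes it quantitative
for researchers who have sparse longitudinal measurements taken before,
during and after a challenge and want comparable, unit-free phenotypes of
resistance and recovery per individual and per measure.

## The model

A spring of stiffness *K* and a damper of friction *C* in parallel (a
Kelvin–Voigt element), pulled during the challenge window [τ₁, τ₂) by a
constant perturbation force F_pert scaled by a perception coefficient
perc. With x(t) the deformation (the measure on a fold-change scale) and
m = perc·F_pert:

- outside the challenge:  dx/dt = −(K/C)·x
- during the challenge:   m·x″ = m − K·x − C·x′

Three derived phenotypes summarize a fit:

| quantity | formula | meaning |
|---|---|---|
| x_inf | perc·F_pert / K | asymptotic deformation under a sustained challenge (small = stiff) |
| x_max | x(τ₂⁻) | realized response peak of the finite challenge |
| T | C / K | recovery decay constant (time to shrink by a factor e) |

Fits are scored with the modelling efficiency
MEF = 1 − Σ(Yᵢ − Ŷᵢ)² / Σ(Yᵢ − Ȳ)² (1 = perfect, 0 = no better than the
mean, negative = worse).

The package provides: exact closed-form simulation plus an independent
stiff ODE integrator cross-check; fold-change preprocessing and 0–100 time
rescaling; multi-start least-squares estimation of (K, C) per series;
one-at-a-time sensitivity sweeps and the K×C interplay grid; a synthetic
cohort generator with known ground truth emulating a two-line,
two-replicate aquarium design; and group-level analysis (±1.5·IQR outlier
exclusion, per-line summaries, line contrasts on log parameters, Pearson
correlation matrix between fitted parameters).

## Worked example

```r
library(springdamp)

## a slow, high-amplitude physiological response
p <- kv_params(K = 0.028, C = 0.384, F_pert = 0.1)
p
#> Spring-damper parameters
#>   K = 0.028, C = 0.384, F_pert = 0.1, perc = 1
#>   challenge window: [20, 60)
#>   derived: T = 13.7143, x_inf = 3.57143, x_max = 3.38531
```

T ≈ 13.7 means the post-challenge response shrinks by a factor e every
13.7 time units (on the 0–100 scale where the challenge spans 20–60);
x_inf ≈ 3.6 says a sustained challenge would push the measure to 3.6 times
its baseline spread.

Fit the model back from a sparse noisy series sampled at a realistic
observation design:

```r
tt <- c(0, 8, 16, 22, 30, 40, 50, 58, 62, 70, 80, 90, 100)
set.seed(42)
y <- simulate_closed_form(p, tt)$x * (1 + rnorm(13, 0, 0.05))
fit_series(tt, y)
#> Spring-damper fit
#>   K = 0.02689, C = 0.3767  (n_obs = 13, starts = 9)
#>   T = 14.01, x_inf = 3.719, x_max = 3.513
#>   SSR = 0.08731, MEF = 0.9962, converged = TRUE
```

Both parameters come back within a few percent of truth at 5% observation
noise, with MEF ≈ 0.996.

A full cohort run — generate a synthetic two-line study, preprocess,
fit every individual × measure, exclude Tukey-fence outliers, summarize
and test the line contrast:

```r
spec <- cohort_spec()                    # 2 lines x 2 replicates x 4 aquaria
co   <- generate_cohort(spec, seed = 1)
pp   <- preprocess_cohort(co$data)
fits <- exclude_outliers(fit_cohort(pp))
summ <- summarize_by_line(fits)
summ[summ$measure == "cortisol_release", ]
#>  line          measure      K     C    T x_inf n
#>     A cortisol_release 0.0471 0.664 15.3  2.24 8
#>     R cortisol_release 0.0976 1.193 13.1  1.10 7

line_effect_test(fits, "cortisol_release", "K")
#> Line effect on K (cortisol_release), model y ~ line
#>      A      R
#> 0.0457 0.0942
#>   line p-value = 0.0001616
```

The generator built line R twice as stiff as line A in cortisol stiffness;
the pipeline recovers that ordering (mean K of 0.098 vs 0.047, p ≈ 2e-4;
one of R's 8 aquaria was excluded by the fence rule). Absolute fitted K
here is inflated relative to the generating medians by the grand-mean
fold-change normalization — a common factor per measure that cancels in
between-line comparisons; see the methods vignette
(`vignettes/spring-damper-methods.Rmd`).

## Command line

```sh
Rscript inst/cli/springdamp.R synth --seed 9 --out-dir run1
Rscript inst/cli/springdamp.R fit   --input run1/synthetic_data.csv --out-dir run1
Rscript inst/cli/springdamp.R cohort --input run1/fits.csv --out-dir run1
Rscript inst/cli/springdamp.R simulate K=0.1 C=2 F_pert=1 --out-dir run1
Rscript inst/cli/springdamp.R sweep --out-dir run1
```

Every command writes CSV outputs plus a `run_config_<command>.yaml`
recording the resolved settings and seed, so runs are exactly replayable.

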