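# behavtype

Quantifies animal personality — consistent between-individual differences
in behavior — from automated 2-D tracking data. The package takes
per-second detections from standardized behavioral tests (novel object,
mirror stimulus, conspecific separation, predator stimulus, open field),
turns them into trait metrics and principal-component scores, and
decomposes trait variance with Bayesian linear mixed models fitted by its
own Gibbs sampler. It is aimed at behavioral ecologists who want a
reproducible repeatability/syndrome analysis, validated end-to-end on
synthetic data with known ground truth.

## The statistics at the core

For a trait score $y_{ij}$ of individual $i$ in trial $j$, the model is a
Gaussian random-intercept LMM

$$y_{ij} = \mathbf{x}_{ij}^\top\boldsymbol\beta + u_i + e_{ij},\qquad
u_i \sim N(0, V_{ind}),\quad e_{ij} \sim N(0, V_e),$$

with trial number, body length, and sample origin as fixed effects. The
**adjusted repeatability** is computed per posterior draw:

$$R = \frac{V_{ind}}{V_{ind} + V_e},$$

reported as posterior mean with a 95% credibility interval, and called
significant when removing the random intercept raises the DIC by more
than 2. For trait pairs, a bivariate LMM with between-individual and
residual covariance matrices $G$ and $R$ decomposes the phenotypic
correlation into levels:

$$r_{ind} = \frac{G_{12}}{\sqrt{G_{11}G_{22}}},\qquad
r_e = \frac{R_{12}}{\sqrt{R_{11}R_{22}}},\qquad
r_p = \frac{G_{12}+R_{12}}{\sqrt{(G_{11}+R_{11})(G_{22}+R_{22})}},$$

a significant $r_{ind}$ (ΔDIC > 2 against a covariance-constrained refit)
being the operational definition of a behavioral syndrome.

The Gibbs sampler (C++, conjugate blocks, inverse-Wishart covariance
updates) is deterministic under a seed. Trajectory metrics include Von
Mises turning-angle fits and kernel utilization-distribution areas; the
metric-to-score step is a correlation-matrix PCA per behavioral axis. See
the vignette `vignettes/behavioral-types.Rmd` for models, priors, and
design choices.

## Worked example

Simulate a repeated-measures trait with known truth
($V_{ind} = 0.4$, $V_e = 0.6$, so $R = 0.4$) and fit it:

```r
library(behavtype)

cfg <- trait_sim_config(n_individuals = 40, n_trials = 4,
                        v_ind = 0.4, v_e = 0.6, beta = c(0, 0.05, 0.3, 0),
                        seed = 42)
d <- simulate_trait_data(cfg)
fit <- bt_lmm(value ~ trial_c + length_c + sample, d,
              mcmc = bt_mcmc(5000, 1000, 5, seed = 1))
summary(fit)
#> Fixed effects:
#>             post.mean  l.BCI u.BCI pMCMC
#> (Intercept)     0.382  0.020 0.716 0.045
#> trial_c         0.061 -0.035 0.161 0.228
#> length_c       -0.015 -0.211 0.197 0.882
#> samplewild     -0.454 -0.937 0.046 0.078
#>
#> Variance components:
#>       post.mean l.BCI u.BCI
#> V_ind     0.458 0.235 0.806
#> V_e       0.526 0.410 0.682
#>
#> Adjusted repeatability: 0.46 [0.29, 0.62]
#>
#> DIC: 382.40 (pD = 33.30)
```

The interval [0.29, 0.62] covers the true repeatability 0.4; the pMCMC
column gives two-sided MCMC tail probabilities for each fixed effect.
A trait pair with a built-in syndrome ($r_{ind} = 0.6$, $r_e = 0.2$,
70 individuals):

```r
cfgp <- trait_sim_config(n_individuals = 70, v_ind = 0.4, v_e = 0.6,
                         trait_pair_corr = c(0.6, 0.2), seed = 42)
w <- traits_to_wide(simulate_trait_pair(cfgp))
bt_syndrome(cbind(trait1, trait2) ~ trial_c, w,
            mcmc = bt_mcmc(20000, 2000, 20, seed = 1))
#> Syndrome decomposition: trait1 -- trait2
#>   r_ind  0.49 [ 0.21,  0.71]
#>   r_e    0.14 [-0.00,  0.26]
#>   r_p    0.27 [ 0.15,  0.40]
#>   dDIC (constrained - full): 9.47 -> significant
```

The between-individual correlation is detected (ΔDIC = 9.5 > 2) with the
point estimate shrunk slightly toward zero by the near-flat
inverse-Wishart prior, as discussed in the vignette.

The full simulate → metrics → score → fit → syndromes → report chain runs
from one call (or the CLI wrapper in `inst/cli/btpipeline.R`):

```r
cfg <- pipeline_config(system.file("extdata", "demo_config.yaml",
                                   package = "behavtype"))
run_pipeline(cfg, out_dir = "bt_demo", seed = 7)
```

which writes trajectory/metric/score CSVs, repeatability and
syndrome-decomposition tables, a log, and a manifest of seeds and file
hashes into `bt_demo/`.

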