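---
title: "Quantifying behavioral types: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral types: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(behavtype)
```

## The scientific problem

Animal personality research asks whether individuals differ *consistently*
in behavior: is a fish that explores a novel object more than its tank
mates today still the more exploratory fish tomorrow? The quantity of
interest is the **repeatability** of a behavioral trait,

$$R = \frac{V_{ind}}{V_{ind} + V_e},$$

the fraction of phenotypic variance attributable to stable
between-individual differences ($V_{ind}$) rather than within-individual
noise ($V_e$). The *adjusted* repeatability controls confounding fixed
effects (trial number, body length, sample origin) before decomposing the
variance. A second question is whether traits travel together as
**behavioral syndromes**: a between-individual correlation $r_{ind}$
between, say, exploration and activity means the same individuals sit high
on both axes. The phenotypic correlation decomposes over the two levels,

$$r_p = \frac{G_{12} + R_{12}}
             {\sqrt{(G_{11}+R_{11})(G_{22}+R_{22})}},\qquad
  r_{ind} = \frac{G_{12}}{\sqrt{G_{11}G_{22}}},\qquad
  r_e = \frac{R_{12}}{\sqrt{R_{11}R_{22}}},$$

where $G$ and $R$ are the between-individual and residual covariance
matrices of a bivariate mixed model.

The package implements the full path from per-second 2-D tracking
detections to these quantities: trajectory metrics, principal-component
trait scores, and Bayesian mixed models fitted by a purpose-built Gibbs
sampler, together with a synthetic-data generator so that every stage can
be validated against known ground truth.

## From trajectories to metrics

A `bt_track` holds 1 Hz detections for one individual in one test; a
second with no detection means the animal was in the refuge. The metrics
follow the standardized-test protocol:

* **Time outside the refuge** is the number of detected seconds.
* **Minimum distance** to a stimulus centroid (novel object or
  conspecific). When an individual was never detected in a test it never
  left the refuge, and the average refuge-to-stimulus distance is imputed:
  250 px for the novel object, 350 px for the conspecific. The imputation
  is applied per test (a track with *some* detections uses its observed
  minimum); an alternative per-second imputation is available behind the
  `per_second` flag.
* **Interaction time** counts detected seconds within 100 px (~6 cm) of
  the stimulus, with a closed comparison (`<=`).
* **Travelled distance** sums Euclidean steps between consecutive
  detections. Detections separated by undetected seconds still form one
  pair — no interpolation is attempted; `split_gaps = TRUE` breaks paths
  at gaps instead.
* **Turning angles** are signed differences of successive headings in
  $(-\pi, \pi]$; zero-length displacements carry no direction and are
  skipped. The Von Mises fit returns the circular mean direction $\mu$ and
  the ML concentration $\kappa$, obtained by inverting
  $A_1(\kappa) = \bar r$ (Fisher's closed-form approximation refined by
  Newton steps on the Bessel-function ratio). The MLE diverges as
  $\bar r \to 1$, so $\kappa$ is capped at 500 and flagged.
* **Utilization areas** are highest-density regions of a kernel density
  estimate: the smallest region containing 95% (area used) or 50% (core
  area) of the estimated positional mass. Bandwidth is Silverman's rule
  per axis, the grid is 256 x 256 over the arena, and all three choices
  are configurable because no single convention is canonical. Activity
  metrics require at least 20 positions; sparser tracks are flagged
  insufficient and omitted, since a handful of detections cannot support a
  density estimate.

Spatial metrics are computed in pixels and reported alongside a
centimetre conversion with the arena calibration 1 cm = 16.7 px
(`px_to_cm()`).

## Collapsing metrics into trait scores

Each behavioral axis is measured by several correlated metrics
(exploration: 4; sociability: 3; boldness: 3 latencies; activity: 6).
`pc1_score()` standardizes the columns and takes the first principal
component as the axis score. Two choices deserve comment:

* **Correlation-matrix PCA.** The metrics mix units spanning orders of
  magnitude (seconds, pixels, squared pixels), so covariance PCA would be
  dominated by whichever metric has the largest numeric scale.
  Standardization is the defensible default and is configurable.
* **Sign orientation.** A principal component's sign is arbitrary, so each
  axis names an orientation metric (e.g. interaction time) whose loading
  is forced positive; minimum-distance and latency metrics are negated
  beforehand. Positive scores therefore always mean *more* of the trait.

Exploration and sociability scores are log-transformed before model
fitting to normalize residuals. PC scores are signed, so a positivity
shift is required first; the package uses $y' = \log(y - \min(y) + 1)$ and
records the shift. This is an implementation choice — no published
procedure specifies how signed scores were made log-transformable.

Aggressiveness is a single metric (approach counts per hour) and is used
directly, without PCA.

## The Bayesian mixed model

`bt_lmm()` fits the Gaussian random-intercept model

$$y_{ij} = \mathbf{x}_{ij}^\top\boldsymbol\beta + u_i + e_{ij},\qquad
  u_i \sim N(0, V_{ind}),\quad e_{ij} \sim N(0, V_e),$$

by Gibbs sampling with fully conjugate blocks: fixed effects (Gaussian),
random intercepts (Gaussian), and variances (scaled inverse-chi-square).
A two-column `cbind()` response switches to the bivariate model with 2x2
between-individual ($G$) and residual ($R$) covariance matrices updated by
inverse-Wishart draws. The samplers are written in C++ for speed but draw
all randomness through R's RNG, so a chain is bit-reproducible from
`bt_mcmc(seed = )`.

Defaults follow the analysis conventions of the field:

* **MCMC settings**: 13,000 iterations, 3,000 burn-in, thinning 10 for
  univariate models; 100,000 / 10,000 / 100 for bivariate syndrome models,
  whose correlation parameters mix more slowly.
* **Priors**: fixed effects $N(0, 10^{10})$; univariate variances
  $\mathrm{IG}(\nu/2, \nu V/2)$ with $\nu = 0.002$, $V = 1$ (the standard
  near-flat choice); bivariate covariance matrices
  $\mathrm{IW}(\mathbf{I}, \dim - 1 + 0.002)$. All are configurable via
  `bt_prior()`; with 70 individuals and 4 trials the likelihood dominates
  and results are insensitive to these choices, except that the
  inverse-Wishart identity scale mildly shrinks bivariate correlations
  toward zero at small sample sizes (visible as a downward bias of
  $\hat r_{ind}$ of roughly 0.05–0.1 at 70 individuals).
* **Convergence**: a single chain, checked by a Geweke diagnostic
  (warning-only at $|z| > 2$) and trace plots via `plot()`.

`adjusted_repeatability()` computes $R$ per posterior draw and reports the
posterior mean with 2.5%/97.5% credibility intervals; because the mean of
a ratio is not the ratio of means, the plug-in ratio of posterior-mean
variances is reported alongside.

`pmcmc()` is the two-sided MCMC tail probability
$2\min(\Pr(\theta > 0), \Pr(\theta < 0))$, floored at $1/n_{draws}$.

## DIC, significance, and model reduction

Model comparison uses the deviance information criterion
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$. A
repeatability is called significant when removing the random intercept
raises the DIC by more than 2; a syndrome correlation when constraining
the $G$ and $R$ off-diagonals to zero does the same.

The deviance can be focused at two levels, and the package exposes both
(`dic(fit, focus = )`):

* **Conditional** on the random intercepts (the default, and the
  convention of MCMC mixed-model software). This is the focus used for the
  repeatability and syndrome comparisons, where the random structure
  itself is under test.
* **Marginal**, with the intercepts integrated out analytically (the
  per-individual Woodbury factorisation of
  $V_e\mathbf{I} + V_{ind}\mathbf{J}$).

The distinction matters for fixed-effect selection. Under the conditional
focus a covariate that is constant within individuals (body length, sample
origin) can be absorbed entirely by the random intercepts, so removing it
barely moves the DIC — conditional DIC is structurally blind to
between-individual fixed effects. `backward_reduce()` therefore uses the
marginal focus by default when eliminating fixed terms (the intercept and
the random term are never candidates; DIC ties within 0.01 are broken
deterministically toward the later-listed term).

`variance_f_test()` compares the spread of per-individual mean trait
values between two samples: $F$ is the larger-to-smaller variance ratio
with a two-sided p-value. Which trait summary enters the test is the
caller's choice; per-individual means are the default input convention.

## The synthetic-data generator

The generator defines the conditions under which the machinery is
validated.

**Trajectories** (`simulate_trajectory()`) emulate 1 Hz tracker output: a
two-state Markov chain switches between refuge (no detection) and open
arena; outside, the animal performs a correlated random walk with Von
Mises turning angles and exponential step lengths, reflective walls, and
positions pushed off the refuge rectangle. The exponential step-length law
is a modelling choice — turning angles, not step lengths, are the
documented movement quantity — selected for having a single parameter.
Likewise the geometric within-refuge dwell time implied by the Markov
chain is an assumption, not an inference about real fish.

**Traits** (`simulate_trait_data()`, `simulate_trait_pair()`) draw
repeated measures from exactly the mixed model above, with configurable
$V_{ind}$, $V_e$, fixed effects, and (for pairs) between- and
within-individual correlations. True repeatability and correlations are
therefore known, and the estimators can be checked for bias, interval
coverage, and false-positive rates.

What the generator does *not* emulate: detector noise and identity
switches, spatially structured behavior near stimuli (approach bouts,
thigmotaxis), non-Gaussian trait distributions, and any individual-by-trial
interaction beyond the linear trial effect. Passing tests therefore
demonstrate that the estimators recover the truth when the model holds;
they do not certify robustness to misspecified real data.

## Problem sizes and numerical choices

The validation suite uses the study-scale design of 70 individuals by 4
trials. Repeatability recovery runs 50 simulations at the univariate MCMC
settings; syndrome recovery and null calibration run 20 simulations each
at 20,000-iteration bivariate chains, a scaled-down setting whose
posterior means agree with the 100,000-iteration convention to well within
Monte-Carlo error (both are single-second fits; the long setting remains
the default for analyses). Degenerate inputs are handled explicitly:
constant metric columns abort the PCA with the column named, collinear
fixed-effect designs abort the sampler with the columns named, tracks with
fewer than 20 positions or fewer than 3 detections raise typed
insufficient-data conditions, and a zero-variance response is rejected.

## The pipeline

`run_pipeline()` chains simulate, metrics, score, fit, syndromes, and
report into a reproducible run directory: long-format CSVs as the
interchange, a YAML config, a log, and a `manifest.json` with per-stage
seeds and input/output MD5 hashes. Reruns with the same config and seed
are byte-identical. A thin command-line wrapper ships in
`inst/cli/btpipeline.R`.

```{r, eval = FALSE}
cfg <- pipeline_config(system.file("extdata", "demo_config.yaml",
                                   package = "behavtype"))
run_pipeline(cfg, out_dir = "bt_demo", seed = 7)
```

## A small worked example

```{r example}
cfg <- trait_sim_config(n_individuals = 40, n_trials = 4,
                        v_ind = 0.4, v_e = 0.6, beta = c(0, 0.05, 0.3, 0),
                        seed = 42)
d <- simulate_trait_data(cfg)
fit <- bt_lmm(value ~ trial_c + length_c + sample, d,
              mcmc = bt_mcmc(5000, 1000, 5, seed = 1))
summary(fit)
```

The true repeatability here is $0.4/(0.4+0.6) = 0.4$; the credibility
interval above is computed from 800 retained draws on 160 observations.

## Known limitations

* Gaussian responses only; count-valued aggressiveness scores are modelled
  on the (transformed) observed scale, not with a GLMM family.
* Random intercepts only — no random slopes, no individual-by-environment
  interaction.
* Single-chain inference; the Geweke check flags gross non-stationarity
  but is no substitute for multi-chain diagnostics when priors are made
  informative.
* Bivariate models are limited to trait pairs, matching the pairwise
  syndrome-decomposition design.
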