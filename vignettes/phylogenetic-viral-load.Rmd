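---
title: "Phylogenetic mixed models for cross-species viral load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic mixed models for cross-species viral load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a virus is inoculated into a panel of host species spanning a phylogeny,
how much of the variation in infection outcome is structured by host
evolutionary history, and how similar are the patterns for related viruses?
`virophylo` addresses this for viral-load data: the change in viral RNA
between day 0 and day 2 post-infection, measured by qRT-PCR relative to a
housekeeping gene (RpL32) and expressed as a log2 fold change. The motivating
design is a panel of 45 *Drosophilidae* species each inoculated with four
*Cripavirus* isolates (three closely related DCV isolates and the more
divergent CrPV), with about three biological replicates per species-virus
combination.

## From Ct values to log2 fold changes

Each biological replicate contributes day-0 and day-2 samples, each measured
for the viral and housekeeping amplicons in two technical replicates.
Processing follows four steps:

1. **Exclusion filters** (`apply_exclusion_filters()`): a biological
   replicate is removed entirely when either day's samples show repeated
   amplification failure, a flagged contaminant, or a melt-curve peak more
   than 1.5 °C (viral) or 3 °C (housekeeping) from the reference peak of
   positive samples. Filters change membership only, never values.
2. **Plate correction** (`correct_plate_effects()`): per amplicon, an
   additive two-factor linear model of Ct on plate and biological-replicate
   block, with sum-to-zero contrasts on the plate factor; the fitted plate
   effects are subtracted. A single plate is returned unchanged; a design in
   which plate and block are completely confounded triggers a warning and
   the identity correction, since the two effects are then inseparable. The
   correction is fitted per amplicon because the two amplicons need not
   share plate-level efficiency artefacts; this is a package choice where
   the factor-correction literature leaves the parameterization open.
3. **Normalization and contrast** (`compute_fold_change()`): technical
   replicates are averaged, `dCt = Ct_viral - Ct_housekeeping` per day, and
   `y = dCt_day0 - dCt_day2`. Fold change in viral load is `2^y`, so viral
   growth gives y > 0 and, e.g., `dCt_day0 = 10, dCt_day2 = 0` is a
   1024-fold increase. The sign convention is chosen so that replication
   yields fold changes above 1; the alternative reading of the exponent
   notation would make growing infections appear as declines, contradicting
   the orders-of-magnitude increases such experiments report.
4. Downstream modelling stays on the log2 scale; back-transformation to
   fold units happens only in reporting (`mean_fold_change()`).

Because `y` is a within-replicate double difference, any per-plate or global
additive Ct shift that is shared by a replicate's four measurements cancels
exactly; the plate correction matters when a replicate's measurements are
split across plates.

## The model

For species $h$, biological replicate $i$, virus $v$:

$$y_{hiv} = \beta_{1:v} + \mu_{p:hv} + \mu_{s:hv} + e_{hiv} \quad (1)$$
$$y_{hiv} = \beta_{1:v} + \mu_{p:hv} + e_{hiv} \quad (2)$$

with $\mathrm{vec}(\mu_p) \sim N(0, V_p \otimes A)$,
$\mathrm{vec}(\mu_s) \sim N(0, V_s \otimes I)$, and independent residuals
with virus-specific variances $v_{e:v}$. $A$ is the phylogenetic relatedness
matrix: entry $(g,h)$ is the shared root-to-MRCA path length divided by tree
height on an ultrametric tree, the Brownian-motion trait correlation. $V_p$
and $V_s$ are virus-by-virus covariance matrices of the species-level
effects. Residual covariances between viruses are fixed at zero: each
biological replicate is tested with a single virus, so those covariances are
not estimable — which is also why missing responses can simply be absent
from the long-format likelihood rather than imputed.

Derived quantities (`heritability()`, `repeatability()`,
`interspecific_correlations()`):

* phylogenetic heritability $v_p/(v_p+v_s)$ from model (1) — the analogue of
  Pagel's lambda;
* repeatability $v_p/(v_p+v_e)$ from model (2);
* interspecific correlation $r_{xy} = \mathrm{cov}_{xy}/\sqrt{v_x v_y}$ from
  the model (2) $V_p$. The package defaults to this standard form; the
  variant dividing by $\sqrt{v_x + v_y}$ is available via
  `denominator = "sum"` but is not a correlation (it equals $1/\sqrt 2$ for
  identical responses) and is provided only for comparison with analyses
  that print that expression.

Summaries are posterior means with 95% highest-posterior-density intervals
(`hpd_interval()`: the shortest interval containing `ceiling(0.95 n)` sorted
draws). Differences between correlations come with a two-sided pMCMC
(`correlation_difference()`): twice the smaller tail fraction of draws at or
beyond zero, floored at 1/n.

## Sampling scheme and priors

`vpmm()` runs a Gibbs sampler written in C++ (RcppArmadillo), drawing all
randomness from R's RNG so a seed reproduces the chain exactly:

1. Fixed effects and all random effects are updated jointly from their
   Gaussian full conditional via the mixed-model equations (a single sparse
   normal-equations system, factorized by Cholesky).
2. Covariances use a parameter-expanded ("working parameter")
   representation: $\mu_p = W_p\,\mathrm{diag}(\alpha_p)$ with
   $\mathrm{vec}(W_p) \sim N(0, \tilde V_p \otimes A)$ and
   $\alpha_v \sim N(0, 1000)$. The inner $\tilde V$ gets an inverse-Wishart
   conditional update; $\alpha$ is a small per-virus Gaussian regression.
   The implied marginal prior on $V = \mathrm{diag}(\alpha)\,\tilde V\,
   \mathrm{diag}(\alpha)$ is a heavy-tailed multivariate-F-type distribution
   with variance marginals scaled by 1000 — much less informative near zero
   than a bare inverse-Wishart, which matters for variance components that
   may be small. The inner degrees of freedom default to the number of
   responses $d$; this hyperparameter is not pinned down by the motivating
   analyses (which report robustness to flat and inverse-Wishart
   alternatives), so it is exposed in `vpmm_prior()` as a documented
   default rather than an inference of intent.
3. Residual variances get conjugate inverse-gamma updates with prior shape
   and scale 0.002.
4. Fixed effects have an improper flat prior. In prior-only mode
   (`sample_prior = TRUE`) the fixed effects are therefore held at zero and
   only variance components are sampled; a test compares these draws to
   direct Monte Carlo from the expansion prior.

Numerical choices: Cholesky factorizations first attempt the exact matrix,
then escalate a diagonal jitter from 1e-10 by factors of 10 up to 1e-6
before raising an error. The relatedness matrix is accepted when tip depths
agree to a relative 1e-6 (consensus trees are ultrametric only up to
rounding); `force = TRUE` extends terminal branches and logs a warning.
Semidefinite $V_p$ (perfectly correlated viruses) is handled throughout via
eigenvalue square roots, and the exact marginal likelihood
(`vpmm_loglik()`) uses the factored Woodbury identity so it remains valid
for singular covariance components.

### Chain lengths

The default `vpmm_mcmc()` settings run 130,000 iterations, burn-in 30,000,
thinned every 50 (2,000 retained draws) — a 1:100 scale-down of the
13-million-generation analyses the design mirrors — and warn when any
reported parameter's effective sample size (Geyer initial-positive-sequence
estimator, `effective_sample_size()`) falls below 200. On the 45 x 4 x 3
design this takes on the order of one to four minutes per fit. The
simulation study in the test suite uses 7,000 iterations (burn-in 2,000,
thin 5), chosen from pilot runs of the reduced model at this design where
minimum ESS exceeded 400; `scale = "paper"` switches to the full-length
settings.

## What the synthetic generator emulates — and what it does not

`simulate_host_tree()` draws a pure-birth tree rescaled to unit height: any
ultrametric tree satisfies the model's requirement, and after unit-diagonal
scaling of $A$ all variance-ratio estimands are invariant to the tree's time
units. `simulate_viral_load()` draws species effects from exactly the
model's Kronecker covariances, so parameter-recovery tests are
well-specified by construction. Defaults reproduce the study conditions: 45
species, 4 viruses, per-virus intercepts (13.5, 14.2, 13.6, 10.7) on the
log2 scale (about 11,600-, 19,000-, 12,400- and 1,700-fold mean increases),
$V_p$ correlations of 0.97 within the DCV-like trio and 0.55 to the
outgroup virus with variances (25, 25, 25, 12), no free species effect, and
residual variances set so repeatability is (0.96, 0.96, 0.92, 0.66). Three
replicates per combination are targeted; with probability 19/180 a
combination is hit by attrition, losing one replicate (or two with
conditional probability 1/19) — qualitatively mirroring a 161/18/1 pattern
of combinations with 3/2/1 replicates. Each biological replicate is one
observation, matching the analysis scale rather than individual flies.

`simulate_ct_experiment()` adds the measurement layer: housekeeping Ct
level, day-0 delta Ct, per-plate additive offsets, and technical-replicate
noise. All four measurements of a biological replicate share a plate, and
plates rotate across combinations, so plate and block factors cross (the
correction is estimable) while the noise-free round trip through the qPCR
module is exact.

What passing tests on these data do **not** show: real Ct data have
amplification-efficiency differences between amplicons and species-specific
housekeeping primers, melt-curve artefacts, replicate vials of varying fly
counts, and a tree estimated with error rather than known — none of which
the generator emulates. Recovery results here validate the estimator under
its own assumptions, not robustness to those violations.

## Design notes

* **One fitting function, classed result.** The package follows the classic
  R modelling idiom: `vpmm()` returns an S3 object with `print`, `summary`,
  `coef`, `vcov`, `fitted`, `residuals`, `logLik` and `plot` methods, and
  the derived-quantity functions consume either the fit or bare draw
  arrays. File-based stages (`pipeline_*()`, plus the `exec/virophylo`
  script) wrap these functions thinly so deposited data can replace any
  synthetic stage.
* **Independent cross-checks.** The exact marginal likelihood doubles as an
  oracle: tests compare it against a dense brute-force multivariate-normal
  evaluation, and `vpmm_ml()` maximizes it numerically to confirm the
  posterior concentrates near the MLE on large simulated data. These paths
  share no code with the sampler.
* **Scale of reporting.** Fold changes are reported as $2^\beta$; if a
  data set's working scale were log10 rather than log2, all ratio and
  correlation estimands would be unchanged and only the back-transformed
  means would need reinterpreting.

## Known limitations

Responses are Gaussian on the log2 scale; no non-Gaussian links, no
ancestral-state reconstruction, no model comparison criteria, and no
integration over a posterior sample of trees (a single fixed tree is
assumed known). The wing-size covariate enters as per-virus fixed-effect
slopes only.

## A minimal run

```{r, eval = FALSE}
library(virophylo)

tree <- simulate_host_tree(45, seed = 1)
obs  <- simulate_viral_load(tree, sim_config(seed = 1))

fit2 <- vpmm(obs, tree = tree, species_effect = FALSE, seed = 2)  # model (2)
fit1 <- vpmm(obs, tree = tree, species_effect = TRUE,  seed = 3)  # model (1)

report <- viral_load_report(fit1, fit2)
print(report)
plot(report)
```
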