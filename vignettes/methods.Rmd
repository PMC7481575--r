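---
title: "Models and methods behind metqg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metqg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metqg` implements the quantitative-genetic machinery used to judge how
well a small set of managed selection environments (SEs) screens breeding
lines for a large, heterogeneous target population of environments (TPEs):
lattice-trial adjustment, marker-based heritabilities and genetic
correlations, correlated-response ratios, site clustering, and
reaction-norm genotype-by-environment (GxE) genomic prediction. This
vignette documents the models, the defaults, and the numerical choices; it
states no empirical result beyond what the package's tests and
`scripts/acceptance.R` compute.

## The synthetic cohort generator

Every downstream method is exercised against simulated cohorts with known
truth, because real multi-environment trial (MET) archives ship without
their generating parameters. `simulate_met()` produces:

* **Genotypes** — `n_lines x n_markers` biallelic calls coded 0/1/2
  (minor-allele count). Per-marker minor allele frequencies are uniform on
  `maf_range` (default 0.05–0.5); the heterozygote frequency is capped at
  `het_rate` (default 5%, the residual heterozygosity of advanced selfing
  generations); missingness is independent at `marker_missing_rate`
  (default 10%, typical of genotyping-by-sequencing). The pre-masking
  matrix is retained so true breeding values are computable.
* **Breeding values** — marker effects are drawn i.i.d. per marker and
  mixed across environments through the spectral square root of
  `diag(sd_g) %*% GC %*% diag(sd_g)`, so the line x environment additive
  values have expected per-environment variance `sigma_g2` and
  cross-environment correlation `GC`. Effects are scaled by the summed
  *observed* variance of the centred genotype codes rather than the
  Hardy-Weinberg expression `2*sum(p*q)`: for a near-homozygous panel the
  HW formula under-scales by roughly a factor of two and the realized
  breeding-value variance would miss its target.
* **Phenotypes** — one plot record per line x environment x replicate:
  environment mean (plus an optional random environment main effect with
  variance `env_variance`), trial, replicate-within-trial and
  block-within-replicate effects, breeding value, and a plot error whose
  variance derives from the per-plot heritability,
  `sigma_eps2 = sigma_g2 (1 - h2_plot) / h2_plot`. The alpha-lattice is
  approximated by randomized incomplete blocks of near-equal size: the
  adjustment model treats blocks as exchangeable random effects, so the
  exact alpha arrangement never enters the likelihood. Lines are
  partitioned into trials of 50 entries (a typical international-trial
  size), optionally with a pair of check lines replicated in every trial
  to connect them.

Defaults for the design-effect standard deviations (trial 0.2, replicate
0.1, block 0.15 t/ha) are of the order seen in irrigated wheat trials with
means of 4–6 t/ha. The generator emulates means, variances and genetic
correlations only; it has no physiological model of drought or heat, no
selection over cycles, and no dominance or epistasis — so passing tests
show that the estimators recover the *statistical* structure of MET data,
not that they are robust to biology the generator does not contain.

For the recovery studies in the test suite the design-effect SDs are set
to zero, which is what makes the stated line-mean heritability the exact
truth of the simulation (with nonzero design effects the truth would be
the heritability *after* lattice adjustment, confounding two stages in one
check; the adjustment stage is tested separately against a GLS oracle).

## Lattice adjustment (BLUEs)

Within one environment, plot yield is modelled as

`y = genotype (fixed) + trial + rep(trial) + block(trial:rep) + error`,

all design terms independent random effects with identity kernels, fitted
by REML. Best linear unbiased estimates of the genotypes are re-centred so
their mean equals the grand plot mean, keeping BLUEs on the t/ha scale and
comparable across environments. Environments are fitted separately — the
adjustment model has no environment term, and cross-environment analyses
start from the per-environment BLUE tables. Checks replicated across
trials are ordinary genotype levels; they are what makes multi-trial
adjustment identifiable. Note one consequence of the re-centring: adding a
constant to every plot of one replicate shifts all BLUEs by `c/n_reps`
through the grand mean while leaving every line *contrast* unchanged;
invariance holds for the contrasts, not the absolute values.

## The REML engine

All fits go through one engine for Gaussian mixed models with arbitrary
PSD covariance kernels. Variance components are maximized by
average-information (AI) updates with step-halving; any step that fails to
improve the restricted likelihood (or proposes an inadmissible component)
falls back to the monotone EM-REML update, and components pinned at the
floor (1e-10) are frozen out of the AI system so they cannot distort the
search direction of the rest. Convergence is a score-norm tolerance of
1e-6 (components at the floor with downhill gradients excluded).
Fixed effects and BLUPs come from Henderson's equations at the converged
components; a zero-variance term has exactly-zero BLUPs.

The Gibbs counterpart (`gibbs_multikernel()`) samples each kernel's
effects in the kernel's eigenbasis — with fully observed responses the
conditional posterior there is diagonal, so a whole term updates in one
pass — with scaled-inverse-chi-square priors (df 5, scales set by
splitting half the response variance equally across terms). Missing
responses are data-augmented, which is why masked records can never inform
the fit. Sampler settings (12,000 iterations, 2,000 burn-in, thinning 5)
are configuration, not constants.

## Heritability

Line-mean narrow-sense heritability uses the marker kinship:
`y = mu + g + eps` on line means with `g ~ N(0, sigma_g2 K)`, and

`h2 = sigma_g2 / (sigma_g2 + sigma_eps2 / n_reps)`,

where `sigma_eps2` is the *plot-level* error variance, recovered as
`n_reps` times the residual variance of the line-mean fit. (Plugging the
line-mean residual into the formula together with `n_reps` would discount
replication twice.) The kinship is rescaled to unit mean diagonal before
fitting: VanRaden method 1 keeps its textbook `2*sum(p*q)` scaling in
`compute_grm()`, but on nearly homozygous panels that scaling puts the
diagonal near 2, and without the rescale the genetic variance component
would be on an arbitrary kernel scale rather than the scale of a line.

## Genetic correlations and their significance

The additive covariance of one trait across two environments is fitted as
a bivariate Gaussian mixed model, `(g1, g2) ~ N(0, G2 (x) K)` with
independent per-environment residuals (per-environment BLUEs from separate
trials share no plot error). The fit is an expectation-maximisation in the
eigenbasis of `K`, where the model decouples into independent
2-dimensional observations; the per-environment means are re-estimated by
GLS each iteration and their sampling uncertainty enters both the E-step
moments and the reported likelihood (a restricted-likelihood EM).
Convergence is a relative log-likelihood change of 1e-8. The genetic
correlation is `r_A = cov / sqrt(var_x var_y)`, clamped to [-1, 1] when
small-sample REML estimates overshoot (clamping is flagged).

Significance is a likelihood-ratio test of the zero-covariance null
(chi-square, 1 df). A Fisher-z test on `r_A` with n-based scaling is
available (`method = "fisher"`) but is **not** the default: a
REML-estimated genetic correlation is far noisier than a raw Pearson
correlation on the same number of lines, so the z scaling overstates
precision — in the package's own null simulations (h2 0.5, n = 100) the
Fisher test rejected at roughly four times the nominal 5% while the LRT
sits at nominal size. Calibration of the chosen test is enforced by a
200-replicate null simulation in the test suite.

Indirect-selection efficiency is the textbook correlated-response ratio
`CR/R = r_A * h_sel / h_target` at equal selection intensity; site
clustering is complete-linkage hierarchical clustering on Euclidean
distances between rows of the GC matrix (the defaults of the usual heatmap
workflow), cut to five branches by default.

## Reaction-norm GxE prediction

For a selection environment SE and a target environment TPE, the stacked
records carry three kernels: environment (`Z_y Z_y'`), genomic main effect
(`Z_g G Z_g'`), and their cell-wise (Hadamard) product for GxE — PSD by
the Schur product theorem. The baseline "EL" model replaces the genomic
kernels with i.i.d. line effects and uses no markers. Per pair, the model
is trained on the SE records only with the TPE fully masked; the masked
environment's intercept is unidentifiable and set to zero, which is
harmless because Pearson prediction accuracy is shift-invariant. With a
single observed environment the env and GxE kernels are confounded with
the intercept and the genomic kernel respectively (their training blocks
coincide), so the fit honestly reduces to GBLUP — under either backend the
arbitrary main/interaction split would otherwise leak into the masked
cross-covariances. Predictions use the posterior-mean (Gibbs) or BLUP
cross-covariance (REML) path; the two backends agree to correlation
> 0.98 on the suite's fixtures. The GRM is rescaled to unit mean diagonal
here too, so the reported variance components are line-scale.

`partition_variance()` fits the same three-kernel model on a fully
observed two-environment stack and reports the four components, the ratio
string normalised to the genetic variance (one decimal per component,
computed from unrounded components), and an across-environment
heritability. Two formula choices exist because the line-mean convention
is not universal: the default
`s2g / (s2g + s2gxe/n_env + s2eps/(n_env n_reps))` and the plot-basis
`s2g / (s2g + s2gxe + s2eps)` (`h2_formula = "plot"`). With only two
environment levels the environment component is estimated with ~1 degree
of freedom; recovery in the test suite is therefore judged against the
*realized* component variances of each simulated dataset (e.g. the
variance of the two drawn environment effects), not the population
parameters — the estimator tracks what actually happened in the data,
which is all a 2-level design can support.

## Problem sizes and reproducibility

The test suite and acceptance script use cohorts of 100–500 lines and
400–2,000 markers: large enough that recovery bands (heritability within
0.05, GC within 0.1, null size within 0.035 of nominal over 200 nulls)
are comfortably inside sampling noise, small enough that the whole stack
re-runs in minutes on one core. All randomness flows from explicit seeds;
`run_pipeline()` derives per-stage seeds from one global seed by fixed
offsets and reproduces its numeric outputs bit-for-bit in REML mode.

## Known limitations

* The bivariate GC fit handles one environment pair at a time (the usual
  reporting unit); a joint fit across many environments would share
  information but is less stable at the cohort sizes involved.
* KNN imputation defines linkage disequilibrium genome-wide (squared
  Pearson correlation over shared lines), not within physical windows; at
  GBS marker densities the nearest correlated neighbours are effectively
  local, but the package records no genetic map to enforce that.
* Spatial field trends (row-column, AR1) are out of scope; the lattice
  model absorbs only block-structured heterogeneity.
* Prediction pairs train on a single selection environment; multi-SE
  training sets would change the accuracy ceiling.
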