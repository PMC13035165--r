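# vppca

Variational probabilistic principal component analysis (VPPCA) for
multimodal disease-progression modelling.

## What problem this solves

Cohort studies of Alzheimer's disease and related disorders measure many
channels at once — CSF proteins (ABETA, TAU, PTAU), PET uptake (FDG, AV45),
six regional MRI volumes, eleven cognitive/functional scales, and
demographics — with substantial, structured missingness. This package
compresses such a 25-feature panel into a single latent **disease-progression
score** (the first latent component of a fully Bayesian PPCA), with a
calibrated per-observation uncertainty, and interprets the score over time
with a Bayesian hierarchical trajectory model. It is aimed at biostatisticians
and imaging/biomarker researchers who want a one-dimensional, uncertainty-aware
pseudotime for staging, classification audits and longitudinal prediction.

## The model

Each standardized observation $x_n \in \mathbb{R}^d$ follows

$$x_n = W z_n + \mu + \varepsilon_n,\qquad z_n \sim \mathcal N(0, I_q),\qquad
\varepsilon_n \sim \mathcal N(0, \tau^{-1} I_d),$$

with ARD priors $w_{\cdot i} \sim \mathcal N(0, \alpha_i^{-1} I)$,
$\alpha_i \sim \Gamma(a_\alpha, b_\alpha)$, $\mu \sim \mathcal N(0,
\beta^{-1} I)$ and $\tau \sim \Gamma(a_\tau, b_\tau)$. A fully factorized
variational posterior is fitted by exact coordinate-ascent fixed-point
updates (ELBO provably non-decreasing); missing entries drop out of every
sum, so no pre-imputation is needed. The progression score of a row is the
severity-anchored first latent posterior mean; its sd comes from
$M_n^{-1}$ with $M_n = I + \tau W_{\mathrm{obs}}^\top W_{\mathrm{obs}}$, so
uncertainty grows as data go missing. Missing biomarkers are imputed as
$W_{\mathrm{mis}} \mathbb E[z\mid x_{\mathrm{obs}}] + \mu_{\mathrm{mis}}$.

Longitudinally, per-visit scores follow
$\mathrm{score}_n \sim \mathcal N(\alpha_{p} + \beta_{p} t_n, \sigma)$ with
correlated patient-level random intercepts/slopes (LKJ prior on the
correlation), fitted by MCMC (JAGS; 4 chains, 3000 warmup + 3000 sampling by
default) with split-R-hat and ESS diagnostics.

The evaluation layer provides depth-1 Gini-stump classification, bootstrap
ROC/PR AUCs, modality-block ablation with importance scores, classical PPCA /
mean z-score / Fisher-LDA baselines, and uncertainty diagnostics with
quartile risk stratification. A synthetic cohort generator with known ground
truth (modelled on published cohort statistics) makes the whole pipeline
testable without any data download; see the methods vignette
(`vignettes/vppca-methods.Rmd`) for the science and all design choices.

## Worked example

```r
library(vppca)
# 1. simulate a multimodal cohort with known ground truth
gen <- generate_cohort(cohort_spec(n_patients = 300, seed = 1))
# 2. split at patient level, adjust volumes, z-score, fit, score
sp  <- patient_level_split(gen$table, seed = 1)
adj <- adjust_mri_volumes(sp$train)
test_adj <- adjust_mri_volumes(sp$test, adj$params)$table
pl  <- score_pipeline(adj$table, test_adj, control = vppca_control(q = 5))
print(pl$fit)
#> Variational PPCA fit
#>   n = 600 observations, d = 25 features, q = 5 components
#>   <tau> = 4.807 (noise sd 0.4561)
#>   loading norms: 3.996 0.976 0.895 0.816 0.801
#>   ELBO: -12329 after 33 sweeps
```

One dominant component carries the progression signal (loading norm 4.0 vs
&lt; 1 for the ARD-suppressed rest). The score separates diagnoses on the
held-out test set:

```r
base <- subset(pl$test_scores, visit_time == 0 & diagnosis %in% c("CN", "Dementia"))
auc  <- auc_bootstrap(base$score1, base$diagnosis, n_boot = 1000, seed = 1,
                      positive = "Dementia")
#> CN vs Dementia ROC-AUC 1.000 (95% CI 1.000-1.000)
rep <- uncertainty_report(pl$test_scores)
#> sigma range 0.113-0.141, mean 95% interval width 0.469
```

(The clean one-factor synthetic regime separates CN from dementia
perfectly; on real registry data the same pipeline operates at lower AUCs.
Here per-score uncertainty varies only through which features are missing,
so sigma tracks the per-row missing count rather than reconstruction
error.) The trajectory model then recovers the planted progression
structure from the scores alone:

```r
fit_l <- fit_hierarchical(pl$test_scores,
                          hier_model_spec(warmup = 1000, sampling = 1000, seed = 1))
print(fit_l)
#>               mean     sd   rhat
#> beta         0.2173 0.0122 1.0015   # planted population slope: 0.25/yr
#> rho          0.2235 0.0848 1.0015   # planted intercept-slope corr: 0.3
#> max split-R-hat over all parameters: 1.0028
predict_trajectory(fit_l, pl$test_scores$patient_id[1], times = c(0, 2, 5))
#>   patient_id time   mean   lo95  hi95
#> 1      P0002    0 -0.747 -1.037 -0.463
#> 2      P0002    2  0.104 -0.153  0.352
#> 3      P0002    5  1.381  0.959  1.800
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/vppca-cli.R` (subcommands `simulate`, `preprocess`, `fit`,
`score`, `impute`, `classify`, `ablate`, `longitudinal`, `report`).

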