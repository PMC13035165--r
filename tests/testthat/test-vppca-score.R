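# fixture: a fitted model on a standardized synthetic cohort
fit_cohort <- local({
  gen <- generate_cohort(cohort_spec(n_patients = 120, seed = 21))
  tab <- zscore_apply(gen$table, zscore_fit(gen$table))
  X <- feature_matrix(tab)
  fit <- fit_vppca(X, vppca_control(q = 5, max_iter = 120))
  fit <- order_and_sign_components(fit)
  list(gen = gen, tab = tab, X = X, fit = fit)
})

test_that("latent inference follows the observed-dimension formulas", {
  fit <- fit_cohort$fit
  # all-missing row falls back to the latent prior
  lp <- infer_latents(fit, rep(NA_real_, fit$d))
  expect_equal(lp$mean[1, ], rep(0, fit$q))
  expect_equal(lp$cov[[1]], diag(fit$q))

  # q = 1 scalar check: mean = tau w'(x - mu) / (1 + tau ||w||^2)
  pl <- planted_lowrank(N = 100, d = 5, sv = 2, noise = 0.3, seed = 31)
  f1 <- fit_vppca(pl$X, vppca_control(q = 1, max_iter = 200))
  x <- pl$X[7, ]
  got <- infer_latents(f1, x)
  w <- f1$m_W[, 1]; tau <- f1$tau_mean
  expect_equal(got$mean[1, 1],
               unname(tau * sum(w * (x - f1$m_mu)) / (1 + tau * sum(w^2))),
               tolerance = 1e-12)
  expect_equal(got$cov[[1]][1, 1], unname(1 / (1 + tau * sum(w^2))),
               tolerance = 1e-12)

  # removing observed dimensions inflates the posterior covariance (Loewner)
  full <- infer_latents(fit, fit_cohort$X[1, ])$cov[[1]]
  part_row <- fit_cohort$X[1, ]
  part_row[1:15] <- NA
  part <- infer_latents(fit, part_row)$cov[[1]]
  expect_true(all(eigen(part - full, symmetric = TRUE)$values > -1e-12))
})

test_that("posterior imputation reconstructs and beats column means", {
  fit <- fit_cohort$fit
  # complete rows come back bit-identical
  complete <- fit_cohort$X[rowSums(is.na(fit_cohort$X)) == 0, , drop = FALSE]
  expect_identical(impute_missing(fit, complete), complete)

  # noisy rank-2 data with 20% MCAR: VPPCA imputation beats column-mean
  wins <- 0
  for (seed in 1:20) {
    pl <- planted_lowrank(N = 120, d = 10, sv = c(3, 1.5), noise = 0.3,
                          seed = seed)
    set.seed(seed + 500)
    mask <- matrix(runif(length(pl$X)) < 0.2, nrow(pl$X))
    Xm <- pl$X; Xm[mask] <- NA
    f <- fit_vppca(Xm, vppca_control(q = 4, max_iter = 100))
    imp <- impute_missing(f, Xm)
    cm <- impute_column_mean(Xm)
    rmse <- sqrt(mean((imp[mask] - pl$X[mask])^2))
    rmse_cm <- sqrt(mean((cm[mask] - pl$X[mask])^2))
    wins <- wins + (rmse < rmse_cm)
  }
  expect_equal(wins, 20)
})

test_that("component ordering and signing is anchored and invariant", {
  fit <- fit_cohort$fit
  wsq <- colSums(fit$m_W^2) +
    vapply(seq_len(fit$q), function(i) sum(fit$Sigma_w[i, i, ]), numeric(1))
  expect_equal(fit$component_order, order(-wsq))
  # after signing, score1 correlates non-negatively with the anchor
  sc <- progression_scores(fit, fit_cohort$X)
  cdrsb <- fit_cohort$X[, "CDRSB"]
  expect_gte(cor(sc$score1, cdrsb, use = "complete.obs"), 0)

  # sign equivariance: negating the data (which also reverses what "high
  # anchor" means) and flipping the anchor direction leaves scores invariant
  fneg <- fit_vppca(-fit_cohort$X, fit$control)
  fneg <- order_and_sign_components(fneg, anchor_direction = -1)
  sneg <- progression_scores(fneg, -fit_cohort$X)
  expect_gt(cor(sneg$score1, sc$score1), 0.999)

  # fallback anchor engages when CDRSB is absent
  feats <- setdiff(fit$features, "CDRSB")
  Xs <- fit_cohort$X[, feats]
  fs <- fit_vppca(Xs, vppca_control(q = 4, max_iter = 80))
  fs <- order_and_sign_components(fs)
  expect_identical(fs$anchor$feature, "Hippocampus")
  expect_error(order_and_sign_components(fs, anchor_feature = "nope",
                                         fallback_feature = "nada"),
               "anchor feature")
})

test_that("progression scores quantify information loss and track truth", {
  fit <- fit_cohort$fit
  # a fully observed row equal to mu scores exactly zero
  sc0 <- progression_scores(fit, fit$m_mu)
  expect_equal(sc0$score1, 0, tolerance = 1e-12)
  # sigma1 grows when observations are removed
  row <- impute_missing(fit, fit_cohort$X[2, , drop = FALSE])
  sparse <- row; sparse[, -(1:3)] <- NA
  s_full <- progression_scores(fit, row)$sigma1
  s_sparse <- progression_scores(fit, sparse)$sigma1
  expect_gt(s_sparse, s_full)
  # ci95 is the +/- 1.96 sigma interval
  sc <- progression_scores(fit, fit_cohort$X)
  expect_equal(sc$ci_high - sc$score1, 1.96 * sc$sigma1)
  # sigma1 increases with the number of missing dimensions (calibration)
  nmiss <- rowSums(is.na(fit_cohort$X))
  ct <- suppressWarnings(cor.test(sc$sigma1, nmiss, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # scores track the planted latent
  expect_gt(cor(sc$score1, fit_cohort$gen$truth$latent), 0.95)
})

test_that("rescoring after 10% extra masking barely moves the scores", {
  fit <- fit_cohort$fit
  sc <- progression_scores(fit, fit_cohort$X)
  set.seed(77)
  Xm <- fit_cohort$X
  obs <- which(!is.na(Xm))
  drop <- sample(obs, round(0.1 * length(obs)))
  Xm[drop] <- NA
  keep <- rowSums(!is.na(Xm)) > 0
  sc2 <- progression_scores(fit, Xm[keep, ])
  expect_lt(mean(abs(sc2$score1 - sc$score1[keep])), 0.1)
})

test_that("VPPCA and classical PPCA first components agree on complete data", {
  gen <- generate_cohort(cohort_spec(n_patients = 150, seed = 41),
                         missingness = FALSE)
  tab <- zscore_apply(gen$table, zscore_fit(gen$table))
  X <- feature_matrix(tab)
  fv <- order_and_sign_components(fit_vppca(X, vppca_control(q = 5, max_iter = 150)))
  sv <- progression_scores(fv, X)$score1
  fp <- baseline_ppca(X, q = 5)
  sp <- ppca_scores(fp)
  expect_gt(abs(cor(sv, sp)), 0.99)
})
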