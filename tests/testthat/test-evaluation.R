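# brute-force oracles
stump_oracle <- function(scores, labels) {
  us <- sort(unique(scores))
  mids <- (us[-1] + us[-length(us)]) / 2
  cls <- sort(unique(labels))
  best_t <- NA; best_imp <- Inf
  for (t in mids) {
    for (side in list(scores <= t)) {
      p1 <- mean(labels[side] == cls[2]); p2 <- mean(labels[!side] == cls[2])
      imp <- (sum(side) * 2 * p1 * (1 - p1) +
                sum(!side) * 2 * p2 * (1 - p2)) / length(scores)
      if (imp < best_imp - 1e-15) { best_imp <- imp; best_t <- t }
    }
  }
  list(threshold = best_t, impurity = best_imp)
}

auc_pairs_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

test_that("stump threshold equals exhaustive midpoint search", {
  # pure split returns the midpoint and zero impurity
  clf <- fit_stump(c(-1, -0.5, 0.5, 1), c("a", "a", "b", "b"))
  expect_equal(clf$threshold, 0)
  expect_equal(clf$impurity, 0)
  expect_identical(predict(clf, c(-2, 2)), c("a", "b"))

  # Gini closed form: pure node 0, 50/50 node 0.5
  clf2 <- fit_stump(c(1, 2, 3, 4), c("a", "b", "a", "b"))
  expect_equal(stump_oracle(c(1, 2, 3, 4), c("a", "b", "a", "b"))$impurity,
               clf2$impurity)

  set.seed(12)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    sc <- round(rnorm(n), 2) # rounding induces ties
    lb <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(lb)) < 2 || length(unique(sc)) < 2) next
    clf <- fit_stump(sc, lb)
    orc <- stump_oracle(sc, lb)
    expect_equal(clf$threshold, orc$threshold)
    expect_equal(clf$impurity, orc$impurity)
  }
  expect_error(fit_stump(1:4, rep("a", 4)), "two classes")
})

test_that("classification metrics follow the macro-averaged definitions", {
  clf <- structure(list(threshold = 0, left_class = "neg", right_class = "pos",
                        classes = c("neg", "pos")), class = "stump")
  # perfect predictions
  m <- evaluate_classification(clf, c(-1, -2, 1, 2), c("neg", "neg", "pos", "pos"))
  expect_equal(unlist(m[c("accuracy", "f1", "precision", "recall")]),
               c(accuracy = 1, f1 = 1, precision = 1, recall = 1))
  # all-one-class predictions on balanced labels
  m2 <- evaluate_classification(clf, c(1, 2, 3, 4), c("neg", "pos", "neg", "pos"))
  expect_equal(m2$accuracy, 0.5)
  # hand-computed confusion: TP=8 FP=2 FN=1 TN=9 for class "pos"
  scores <- c(rep(1, 10), rep(-1, 10))
  labels <- c(rep("pos", 8), rep("neg", 2), "pos", rep("neg", 9))
  m3 <- evaluate_classification(clf, scores, labels)
  pc <- m3$per_class[m3$per_class$class == "pos", ]
  expect_equal(pc$precision, 0.8)
  expect_equal(pc$recall, 8 / 9)
  expect_equal(m3$accuracy, 17 / 20)
})

test_that("ROC AUC equals the all-pairs concordance count", {
  expect_equal(roc_auc(rep(1, 10), rep(c("a", "b"), 5)), 0.5) # pure ties
  expect_equal(roc_auc(1:10, rep(c("a", "b"), each = 5), positive = "b"), 1)
  expect_equal(pr_auc(1:10, rep(c("a", "b"), each = 5), positive = "b"), 1)

  set.seed(3)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    sc <- round(rnorm(n), 1)
    lb <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb, positive = "b"),
                 auc_pairs_oracle(sc, lb, "b"))
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  sc <- rnorm(80)
  lb <- ifelse(rnorm(80, sc) > 0, "pos", "neg")
  if (length(unique(lb)) == 2) {
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("neg", "pos"),
                                                           direction = "<"))))
    expect_equal(roc_auc(sc, lb, positive = "pos"), ref, tolerance = 1e-12)
  }
})

test_that("PR AUC integrates the precision envelope", {
  # small hand case: scores 4>3>2>1 with labels +,-,+,-
  sc <- c(4, 3, 2, 1); lb <- c("p", "n", "p", "n")
  # operating points: r=1/2 pr=1 ; r=1/2 pr=1/2 ; r=1 pr=2/3 ; r=1 pr=1/2
  # envelope: pr(r<=1/2)=1, pr(1/2<r<=1)=2/3 -> area = .5*1 + .5*2/3
  expect_equal(pr_auc(sc, lb, positive = "p"), 0.5 + 0.5 * 2 / 3)
})

test_that("bootstrap CIs are deterministic, ordered and cover the estimate", {
  set.seed(5)
  sc <- rnorm(60)
  lb <- ifelse(sc + rnorm(60, 0, 0.8) > 0, "p", "n")
  b1 <- auc_bootstrap(sc, lb, n_boot = 200, seed = 11, positive = "p")
  b2 <- auc_bootstrap(sc, lb, n_boot = 200, seed = 11, positive = "p")
  expect_identical(b1, b2)
  expect_lte(b1$roc_ci[1], b1$roc_auc)
  expect_gte(b1$roc_ci[2], b1$roc_auc)
  expect_lte(b1$pr_ci[1], b1$pr_auc)
})

test_that("association reproduces closed-form correlations", {
  x <- c(1.2, -0.4, 2.2, 0.3, -1.5)
  y <- c(0.5, 0.1, 1.9, -0.2, -0.9)
  a <- association(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(a$pearson_r, r_manual, tolerance = 1e-12)
  expect_equal(association(x, x)$pearson_r, 1)
  expect_equal(association(x, x)$spearman_rho, 1)
  a3 <- association(x, -x^3)
  expect_equal(a3$spearman_rho, -1)
  expect_lt(abs(a3$pearson_r), 1)
  expect_error(association(x, rep(1, 5)), "zero variance")
})

test_that("uncertainty report stratifies by sigma quartiles", {
  set.seed(6)
  n <- 48
  sig <- runif(n, 0.05, 0.2) # untied
  sc <- data.frame(score1 = rnorm(n), sigma1 = sig,
                   reconstruction_error = 3 * sig) # perfectly coupled
  rep <- uncertainty_report(sc)
  expect_equal(rep$sigma_error_cor, 1, tolerance = 1e-12)
  expect_equal(rep$strata_proportions, c(0.25, 0.5, 0.25))
  expect_equal(rep$mean_ci_width, mean(2 * 1.96 * sig))
  # strata match a sort-and-slice oracle
  o <- order(sig)
  expect_setequal(rep$strata_members$low, o[1:(n / 4)])
  expect_setequal(rep$strata_members$high, o[(3 * n / 4 + 1):n])
  # constant sigma is a sentinel
  scc <- sc; scc$sigma1 <- 0.1
  expect_warning(rc <- uncertainty_report(scc), "constant")
  expect_true(is.na(rc$sigma_error_cor))
})

test_that("mean z-score baseline averages severity-signed values", {
  X <- cbind(CDRSB = c(1, NA), Hippocampus = c(-0.5, 2), ABETA = c(0.2, NA))
  s <- baseline_mean_zscore(X)
  # directions: CDRSB +1, Hippocampus -1, ABETA -1
  expect_equal(s[1], mean(c(1, 0.5, -0.2)))
  expect_equal(s[2], -2) # single observed feature
  expect_error(baseline_mean_zscore(rbind(c(NA, NA, NA)), c(1, 1, 1)),
               "zero observed")
})

test_that("classical PPCA matches its closed-form solution", {
  pl <- planted_lowrank(N = 250, d = 8, sv = c(4, 2), noise = 0.5, seed = 7)
  f <- baseline_ppca(pl$X, q = 2)
  S <- crossprod(sweep(pl$X, 2, colMeans(pl$X))) / nrow(pl$X)
  e <- eigen(S)
  # subspace equality with the top-q eigenspace
  cosines <- svd(crossprod(qr.Q(qr(f$W)), e$vectors[, 1:2]))$d
  expect_lt(max(acos(pmin(cosines, 1))), 1e-6)
  # noise variance equals the mean of the discarded eigenvalues
  expect_equal(f$sigma2, mean(e$values[3:8]), tolerance = 1e-6)
})

test_that("Fisher projection matches oracles and handles missing values", {
  set.seed(8)
  n <- 400
  X <- rbind(matrix(rnorm(n * 3, 0), n), matrix(rnorm(n * 3, 3), n))
  lb <- rep(c("A", "B"), each = n)
  proj <- baseline_lda_projection(X, lb)
  # direction parallels the class-mean difference for spherical classes
  dirv <- colMeans(X[lb == "B", ]) - colMeans(X[lb == "A", ])
  w_est <- coef(lm(proj ~ X))[-1]
  cosine <- abs(sum(w_est * dirv)) / sqrt(sum(w_est^2) * sum(dirv^2))
  expect_gt(cosine, 0.99)
  # agrees with an independent LDA implementation on clean data
  ml <- MASS::lda(X, grouping = lb)
  ref <- drop(X %*% ml$scaling[, 1])
  expect_gt(abs(cor(proj, ref)), 0.999)
  # missing values are zero-filled
  Xm <- X; Xm[1, 1] <- NA
  expect_silent(pm <- baseline_lda_projection(Xm, lb))
  expect_length(pm, 2 * n)

  # permuted labels carry (almost) no signal: at d = 25 the whitened
  # discriminant direction is essentially random, so its projection barely
  # correlates with the true class axis
  set.seed(9)
  d <- 25; n2 <- 300
  X2 <- rbind(matrix(rnorm(n2 * d), n2), matrix(rnorm(n2 * d), n2))
  X2[, 1] <- X2[, 1] + rep(c(0, 3), each = n2)
  lb2 <- rep(c("A", "B"), each = n2)
  proj_true <- baseline_lda_projection(X2, lb2)
  proj_perm <- baseline_lda_projection(X2, sample(lb2))
  expect_gt(abs(cor(proj_true, X2[, 1])), 0.95)
  expect_lt(abs(cor(proj_perm, X2[, 1])), 0.5)
})

test_that("block ablation isolates the signal-bearing block", {
  panel <- feature_panel()
  zero_load <- setNames(rep(0, 25), panel$feature)
  cog <- panel$feature[panel$block == "cognitive"]
  plant <- zero_load
  plant[cog] <- panel$direction[match(cog, panel$feature)] * 0.9
  spec <- cohort_spec(n_patients = 600, visit_times = 0:1, loadings = plant,
                      mcar_rates = zero_load, block_miss_prob = c(CSF = 0),
                      seed = 17)
  gen <- generate_cohort(spec)
  rep <- block_ablation(gen$table, tasks = list(c("CN", "Dementia")),
                        control = vppca_control(q = 4, max_iter = 80),
                        n_boot = 100, seed = 2)
  res <- rep$results
  expect_identical(res$config[1], "full")
  full_auc <- res$roc_auc[res$config == "full"]
  # removing a zero-signal block barely moves the AUC
  expect_lt(abs(res$roc_auc[res$config == "w/o CSF"] - full_auc), 0.02)
  # removing the only signal-bearing block collapses to chance
  expect_lt(abs(res$roc_auc[res$config == "w/o cognitive"] - 0.5), 0.05)
  # importance ranks the cognitive block first
  expect_identical(names(rep$importance)[1], "w/o cognitive")
})
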