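# Depth-1 Gini stump classification, threshold-free ROC/PR evaluation with
# bootstrap confidence intervals, correlation reporting, and uncertainty
# diagnostics.

#' Fit a depth-1 decision stump by exhaustive Gini search
#'
#' Candidate thresholds are the midpoints of consecutive distinct sorted
#' training scores; the chosen threshold minimizes the size-weighted sum of
#' the two children's Gini impurities `sum_k p_k (1 - p_k)` (K = 2). Ties are
#' broken towards the smaller threshold. Each side predicts its majority
#' class.
#'
#' @param scores Numeric training scores.
#' @param labels Binary labels (two distinct values).
#' @return Object of class `stump`: `threshold`, `left_class` (predicted for
#'   scores <= threshold), `right_class`, `impurity` (weighted training Gini),
#'   `classes`.
#' @export
fit_stump <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.character(labels[ok])
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("need exactly two classes present")
  us <- sort(unique(scores))
  if (length(us) < 2) stop("need at least 2 distinct scores")
  mids <- (us[-1] + us[-length(us)]) / 2
  y <- as.integer(labels == cls[2])
  n <- length(y)
  gini <- function(p) 2 * p * (1 - p) # sum_k p_k(1-p_k) for K = 2
  best <- NULL
  for (t in mids) {
    left <- scores <= t
    nl <- sum(left); nr <- n - nl
    pl <- mean(y[left]); pr <- mean(y[!left])
    imp <- (nl * gini(pl) + nr * gini(pr)) / n
    if (is.null(best) || imp < best$impurity - 1e-15) {
      best <- list(threshold = t, impurity = imp, pl = pl, pr = pr)
    }
  }
  left_class <- if (best$pl <= 0.5) cls[1] else cls[2]
  right_class <- if (best$pr <= 0.5) cls[1] else cls[2]
  structure(list(threshold = best$threshold, left_class = left_class,
                 right_class = right_class, impurity = best$impurity,
                 classes = cls), class = "stump")
}

#' @export
predict.stump <- function(object, newdata, ...) {
  ifelse(newdata <= object$threshold, object$left_class, object$right_class)
}

#' Classification metrics for a fitted stump
#'
#' Accuracy plus macro-averaged F1, precision and recall (the mean of the
#' per-class one-vs-rest values), alongside the per-class values.
#'
#' @param clf A `stump`.
#' @param scores,labels Evaluation scores and binary labels.
#' @return List with `accuracy`, `f1`, `precision`, `recall` (macro) and
#'   `per_class` (data.frame).
#' @export
evaluate_classification <- function(clf, scores, labels) {
  stopifnot(length(scores) > 0)
  labels <- as.character(labels)
  pred <- predict(clf, scores)
  acc <- mean(pred == labels)
  per <- lapply(clf$classes, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  list(accuracy = acc,
       f1 = mean(per$f1), precision = mean(per$precision),
       recall = mean(per$recall), per_class = per)
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' Equals the probability that a random positive outranks a random negative,
#' with ties credited 0.5.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels Binary; `positive` names the positive class.
#' @param positive Positive class value (default: the larger/lexically last).
#' @return Scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  stopifnot(length(cls) == 2)
  if (is.null(positive)) positive <- cls[2]
  y <- labels == positive
  n1 <- sum(y); n0 <- sum(!y)
  r <- rank(scores) # midranks handle ties with 0.5 credit
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC by precision-envelope integration
#'
#' Computes the (recall, precision) operating points over all distinct score
#' thresholds, replaces the precision at each recall by the maximum precision
#' achievable at any recall at least as large (the monotone envelope), and
#' integrates the envelope over recall from 0 to 1.
#'
#' @inheritParams roc_auc
#' @return Scalar PR-AUC.
#' @export
pr_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  stopifnot(length(cls) == 2)
  if (is.null(positive)) positive <- cls[2]
  y <- labels == positive
  np <- sum(y)
  stopifnot(np > 0)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys)
  pred_pos <- seq_along(ys)
  last_of_tie <- c(ss[-1] != ss[-length(ss)], TRUE)
  rec <- tp[last_of_tie] / np
  prec <- (tp / pred_pos)[last_of_tie]
  # monotone precision envelope from high recall downwards
  env <- rev(cummax(rev(prec)))
  r <- c(0, rec)
  sum(diff(r) * env)
}

#' ROC and PR AUC with percentile bootstrap confidence intervals
#'
#' Observations are resampled with replacement; replicates degenerating to a
#' single class are redrawn. Deterministic given `seed`.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return List with `roc_auc`, `pr_auc`, `roc_ci`, `pr_ci` (2-vectors) and
#'   `n_boot`.
#' @export
auc_bootstrap <- function(scores, labels, n_boot = 1000L, seed = 1L,
                          positive = NULL, conf = 0.95) {
  stopifnot(n_boot >= 100)
  labels <- as.character(labels)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(scores)
  roc_b <- pr_b <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2) break
    }
    roc_b[b] <- roc_auc(scores[idx], labels[idx], positive)
    pr_b[b] <- pr_auc(scores[idx], labels[idx], positive)
  }
  a <- (1 - conf) / 2
  list(roc_auc = roc_auc(scores, labels, positive),
       pr_auc = pr_auc(scores, labels, positive),
       roc_ci = unname(stats::quantile(roc_b, c(a, 1 - a))),
       pr_ci = unname(stats::quantile(pr_b, c(a, 1 - a))),
       n_boot = n_boot)
}

#' Pearson and Spearman association with two-sided p-values
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @return List with `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`.
#' @export
association <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance input")
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}

#' Uncertainty diagnostics and quartile risk stratification
#'
#' Reports (a) the Pearson correlation between the per-observation posterior
#' sd and the reconstruction error, (b) the mean 95% interval width
#' `mean(2 * 1.96 * sigma1)`, and (c) risk strata by sigma1 quartiles: low
#' (below Q1), medium (Q1 to Q3 inclusive), high (above Q3) — 25/50/25% by
#' construction for untied sigma1 with n divisible by 4.
#'
#' @param scores A progression-score `data.frame` (see
#'   [progression_scores()]) with >= 8 rows of finite `sigma1`.
#' @return List with `sigma_error_cor` (with p-value), `mean_ci_width`,
#'   `sigma_range`, `strata` (factor per row), `strata_proportions`,
#'   `strata_members`.
#' @export
uncertainty_report <- function(scores) {
  s <- scores$sigma1
  stopifnot(sum(is.finite(s)) >= 8)
  if (stats::var(s) == 0) {
    warning("constant sigma1: strata undefined")
    return(list(sigma_error_cor = NA_real_, sigma_error_p = NA_real_,
                mean_ci_width = mean(2 * 1.96 * s), sigma_range = range(s),
                strata = NULL, strata_proportions = NULL, strata_members = NULL))
  }
  q13 <- stats::quantile(s, c(0.25, 0.75))
  strata <- factor(ifelse(s < q13[1], "low", ifelse(s <= q13[2], "medium", "high")),
                   levels = c("low", "medium", "high"))
  assoc <- association(s, scores$reconstruction_error)
  list(sigma_error_cor = assoc$pearson_r, sigma_error_p = assoc$pearson_p,
       mean_ci_width = mean(2 * 1.96 * s),
       sigma_range = range(s),
       strata = strata,
       strata_proportions = as.numeric(table(strata)) / length(s),
       strata_members = split(seq_along(s), strata))
}
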