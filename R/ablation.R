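# Train/score pipeline and modality-block ablation.

.severity_rank <- c(CN = 1, MCI = 2, Dementia = 3)

#' Train-and-score pipeline on a patient-level split
#'
#' Normalizes both splits with training z-score parameters, fits the
#' variational PPCA model on the training rows, orders and signs its
#' components, and scores both splits.
#'
#' @param train,test Cohort tables (already volume-adjusted if desired).
#' @param features Feature columns to model.
#' @param control A [vppca_control()].
#' @return List with `fit`, `params`, `train_scores`, `test_scores` (score
#'   data frames carrying `diagnosis` as an extra column).
#' @export
score_pipeline <- function(train, test, features = NULL,
                           control = vppca_control()) {
  feats <- .table_features(train, features)
  nz <- zscore_fit_apply(train, test, feats)
  fit <- fit_vppca(feature_matrix(nz$train, feats), control)
  fit <- order_and_sign_components(fit)
  sc_tr <- progression_scores(fit, feature_matrix(nz$train, feats),
                              nz$train$patient_id, nz$train$visit_time)
  sc_te <- progression_scores(fit, feature_matrix(nz$test, feats),
                              nz$test$patient_id, nz$test$visit_time)
  sc_tr$diagnosis <- nz$train$diagnosis
  sc_te$diagnosis <- nz$test$diagnosis
  list(fit = fit, params = nz$params, train_scores = sc_tr, test_scores = sc_te)
}

# stump + threshold-free metrics for one binary task on baseline rows
.task_metrics <- function(train_scores, test_scores, task, n_boot, seed) {
  pos <- task[which.max(.severity_rank[task])] # more impaired class
  tr <- train_scores[train_scores$diagnosis %in% task &
                       train_scores$visit_time == 0, ]
  te <- test_scores[test_scores$diagnosis %in% task &
                      test_scores$visit_time == 0, ]
  clf <- fit_stump(tr$score1, tr$diagnosis)
  cls <- evaluate_classification(clf, te$score1, te$diagnosis)
  auc <- auc_bootstrap(te$score1, te$diagnosis, n_boot = n_boot, seed = seed,
                       positive = pos)
  data.frame(task = paste(task, collapse = "/"),
             accuracy = cls$accuracy, f1 = cls$f1,
             precision = cls$precision, recall = cls$recall,
             roc_auc = auc$roc_auc, pr_auc = auc$pr_auc,
             roc_lo = auc$roc_ci[1], roc_hi = auc$roc_ci[2],
             pr_lo = auc$pr_ci[1], pr_hi = auc$pr_ci[2],
             stringsAsFactors = FALSE)
}

#' Modality-block ablation
#'
#' Refits the model from scratch on the training split for the full feature
#' set and for each leave-one-block-out configuration, rescores the test
#' split, and evaluates every binary diagnostic task (stump metrics plus
#' bootstrap ROC/PR AUC) on baseline test rows. A block's importance is the
#' mean ROC-AUC drop relative to the full model across tasks.
#'
#' @param table Cohort table (raw scales; normalization happens inside per
#'   configuration).
#' @param tasks List of 2-vectors of diagnosis labels, e.g.
#'   `list(c("CN","Dementia"), c("CN","MCI"), c("MCI","Dementia"))`.
#' @param control A [vppca_control()].
#' @param n_boot Bootstrap replicates per task.
#' @param seed Seed for the patient split and the bootstrap.
#' @param features Feature panel to start from (default: all panel features
#'   present in `table`).
#' @return Object of class `ablation_report`: `results` (data.frame, full
#'   configuration first) and `importance` (named mean AUC drop per block,
#'   decreasing).
#' @export
block_ablation <- function(table,
                           tasks = list(c("CN", "Dementia"), c("CN", "MCI"),
                                        c("MCI", "Dementia")),
                           control = vppca_control(), n_boot = 1000L,
                           seed = 1L, features = NULL) {
  panel <- feature_panel()
  feats <- .table_features(table, features)
  blocks <- stats::setNames(panel$block, panel$feature)[feats]
  sp <- patient_level_split(table, seed)
  configs <- c(list(full = feats),
               lapply(stats::setNames(modality_blocks(),
                                      paste0("w/o ", modality_blocks())),
                      function(b) feats[blocks != b]))
  configs <- configs[vapply(configs, length, 1L) != length(feats) |
                       names(configs) == "full"]
  res <- list()
  for (cf in names(configs)) {
    f <- configs[[cf]]
    if (length(f) < 2) stop("configuration ", cf, " leaves fewer than 2 features")
    pl <- score_pipeline(sp$train, sp$test, f, control)
    for (ti in seq_along(tasks)) {
      m <- .task_metrics(pl$train_scores, pl$test_scores, tasks[[ti]],
                         n_boot, seed)
      m$config <- cf
      res[[length(res) + 1]] <- m
    }
  }
  res <- do.call(rbind, res)
  res <- res[, c("config", setdiff(names(res), "config"))]
  full <- res[res$config == "full", c("task", "roc_auc", "pr_auc")]
  res$delta_auc <- full$roc_auc[match(res$task, full$task)] - res$roc_auc
  res$delta_pr <- full$pr_auc[match(res$task, full$task)] - res$pr_auc
  abl <- res[res$config != "full", ]
  importance <- sort(tapply(abl$delta_auc, abl$config, mean), decreasing = TRUE)
  structure(list(results = res, importance = importance),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("Block ablation report\n")
  print(x$results[, c("config", "task", "roc_auc", "pr_auc",
                      "delta_auc", "delta_pr")], row.names = FALSE, digits = 3)
  cat("\nBlock importance (mean ROC-AUC drop across tasks):\n")
  print(round(x$importance, 4))
  invisible(x)
}
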