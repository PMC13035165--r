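# Latent inference, posterior imputation, component ordering/signing, and
# progression scores with calibrated uncertainty.

# observed-dimension latent posterior for one row: mean and covariance of
# z | x_obs using the posterior-mean loadings and noise precision
# (M_i = I + tau * W_obs' W_obs)
.latent_posterior <- function(fit, x) {
  q <- fit$q
  ok <- which(!is.na(x))
  if (!length(ok)) {
    return(list(mean = rep(0, q), cov = diag(q)))
  }
  W <- fit$m_W[ok, , drop = FALSE]
  Mi <- diag(q) + fit$tau_mean * crossprod(W)
  cv <- chol2inv(chol(Mi))
  mn <- fit$tau_mean * drop(cv %*% crossprod(W, x[ok] - fit$m_mu[ok]))
  list(mean = mn, cov = cv)
}

#' Infer latent coordinates for (partially observed) rows
#'
#' For each row the posterior of the latent coordinates restricted to the
#' observed dimensions is Gaussian with covariance `M_i^-1`,
#' `M_i = I + tau * W_obs' W_obs`, and mean
#' `tau * M_i^-1 W_obs' (x_obs - mu_obs)`. Rows with no observed entries fall
#' back to the prior (zero mean, identity covariance).
#'
#' @param fit A `vppca_fit`.
#' @param rows Numeric matrix (or vector for one row) on the same
#'   standardized feature scale the model was fitted on; `NA` = missing.
#' @return List with `mean` (n x q matrix) and `cov` (list of q x q matrices).
#' @export
infer_latents <- function(fit, rows) {
  stopifnot(inherits(fit, "vppca_fit"))
  rows <- .as_row_matrix(rows, fit$d)
  out_m <- matrix(0, nrow(rows), fit$q)
  out_c <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    lp <- .latent_posterior(fit, rows[i, ])
    out_m[i, ] <- lp$mean
    out_c[[i]] <- lp$cov
  }
  list(mean = out_m, cov = out_c)
}

#' Impute missing entries by posterior-mean reconstruction
#'
#' Observed entries are returned unchanged; each missing entry is filled with
#' `W_mis %*% E[z | x_obs] + mu_mis`.
#'
#' @inheritParams infer_latents
#' @return Matrix of the same shape as `rows` with missing entries filled.
#' @export
impute_missing <- function(fit, rows) {
  stopifnot(inherits(fit, "vppca_fit"))
  rows <- .as_row_matrix(rows, fit$d)
  for (i in seq_len(nrow(rows))) {
    mis <- which(is.na(rows[i, ]))
    if (!length(mis)) next
    lp <- .latent_posterior(fit, rows[i, ])
    rows[i, mis] <- fit$m_W[mis, , drop = FALSE] %*% lp$mean + fit$m_mu[mis]
  }
  rows
}

#' Order components by explained signal and fix their signs
#'
#' Components are ordered by descending expected squared loading norm
#' (equivalently ascending ARD precision); exact ties keep the original
#' index order. Each component's sign is then flipped so that the loading of
#' the anchor feature, multiplied by `anchor_direction`, is non-negative. The
#' default anchor is CDRSB (higher = more impaired, direction +1) with
#' hippocampal volume (direction -1) as fallback, which points the first
#' component towards advancing disease.
#'
#' @param fit A `vppca_fit`.
#' @param anchor_feature Feature name anchoring the sign convention.
#' @param anchor_direction +1 or -1.
#' @param fallback_feature,fallback_direction Used when the anchor is absent
#'   from the fitted columns.
#' @return The fit with `component_order` and `component_signs` set.
#' @export
order_and_sign_components <- function(fit, anchor_feature = "CDRSB",
                                      anchor_direction = 1,
                                      fallback_feature = "Hippocampus",
                                      fallback_direction = -1) {
  stopifnot(inherits(fit, "vppca_fit"))
  if (!(anchor_feature %in% fit$features)) {
    anchor_feature <- fallback_feature
    anchor_direction <- fallback_direction
  }
  if (!(anchor_feature %in% fit$features)) {
    stop("anchor feature not among fitted columns and no fallback available")
  }
  w_sq <- colSums(fit$m_W^2) +
    vapply(seq_len(fit$q), function(i) sum(fit$Sigma_w[i, i, ]), numeric(1))
  fit$component_order <- order(-w_sq) # stable: ties keep original index order
  a <- fit$m_W[match(anchor_feature, fit$features), fit$component_order]
  sg <- ifelse(a * anchor_direction >= 0, 1, -1)
  fit$component_signs <- sg
  fit$anchor <- list(feature = anchor_feature, direction = anchor_direction)
  fit
}

#' Progression scores with per-observation uncertainty
#'
#' The progression score of a row is the signed first ordered latent
#' coordinate of its posterior mean; its uncertainty `sigma1` is the square
#' root of the corresponding diagonal element of the per-row latent posterior
#' covariance `M_i^-1`, which grows as observed dimensions are removed. The
#' 95% interval is `score1 +/- 1.96 * sigma1`. The per-row reconstruction
#' error is the mean squared residual over observed dimensions.
#'
#' @param fit A `vppca_fit` with components ordered and signed (see
#'   [order_and_sign_components()]).
#' @param rows Matrix of standardized feature rows (`NA` = missing).
#' @param patient_id,visit_time Optional identifiers carried into the output.
#' @return A `data.frame` with columns `patient_id`, `visit_time`, `score1`,
#'   `sigma1`, `ci_low`, `ci_high`, `reconstruction_error`.
#' @export
progression_scores <- function(fit, rows, patient_id = NULL, visit_time = NULL) {
  stopifnot(inherits(fit, "vppca_fit"))
  rows <- .as_row_matrix(rows, fit$d)
  n <- nrow(rows)
  if (is.null(patient_id)) patient_id <- as.character(seq_len(n))
  if (is.null(visit_time)) visit_time <- rep(NA_real_, n)
  first <- fit$component_order[1]
  s1 <- fit$component_signs[1]
  score1 <- sigma1 <- rec <- numeric(n)
  for (i in seq_len(n)) {
    lp <- .latent_posterior(fit, rows[i, ])
    score1[i] <- s1 * lp$mean[first]
    sigma1[i] <- sqrt(lp$cov[first, first])
    ok <- which(!is.na(rows[i, ]))
    if (length(ok)) {
      xhat <- fit$m_W[ok, , drop = FALSE] %*% lp$mean + fit$m_mu[ok]
      rec[i] <- mean((rows[i, ok] - xhat)^2)
    } else {
      rec[i] <- NA_real_
    }
  }
  data.frame(patient_id = patient_id, visit_time = visit_time,
             score1 = score1, sigma1 = sigma1,
             ci_low = score1 - 1.96 * sigma1, ci_high = score1 + 1.96 * sigma1,
             reconstruction_error = rec, stringsAsFactors = FALSE)
}

.as_row_matrix <- function(rows, d) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1)
  rows <- as.matrix(rows)
  storage.mode(rows) <- "double"
  stopifnot(ncol(rows) == d)
  rows
}

#' Extract the standardized feature matrix from a cohort table
#'
#' @param table Cohort table (normalized).
#' @param features Feature columns to use, in order.
#' @return Numeric matrix with one row per table row.
#' @export
feature_matrix <- function(table, features = NULL) {
  feats <- .table_features(table, features)
  as.matrix(table[, feats, drop = FALSE])
}

# ---- serialization ---------------------------------------------------------

#' Serialize a fitted model (and normalization parameters) to JSON
#'
#' Round-trip loading reproduces scores to numerical precision.
#'
#' @param fit A `vppca_fit`.
#' @param path File path to write.
#' @param norm_params Optional `norm_params` to embed.
#' @return `path`, invisibly.
#' @export
vppca_save <- function(fit, path, norm_params = NULL) {
  stopifnot(inherits(fit, "vppca_fit"))
  obj <- list(
    m_W = fit$m_W, Sigma_w = fit$Sigma_w,
    m_mu = fit$m_mu, sigma2_mu = fit$sigma2_mu,
    alpha_shape = fit$alpha_shape, alpha_rate = fit$alpha_rate,
    alpha_mean = fit$alpha_mean,
    tau_shape = fit$tau_shape, tau_rate = fit$tau_rate, tau_mean = fit$tau_mean,
    elbo_trace = fit$elbo_trace,
    component_order = fit$component_order, component_signs = fit$component_signs,
    features = fit$features, n = fit$n, d = fit$d, q = fit$q,
    control = unclass(fit$control),
    anchor = fit$anchor,
    norm_params = if (!is.null(norm_params)) unclass(norm_params)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a fitted model saved by [vppca_save()]
#'
#' @param path JSON file path.
#' @return List with `fit` (a `vppca_fit` usable for scoring and imputation)
#'   and `norm_params` (or `NULL`).
#' @export
vppca_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  q <- obj$q; d <- obj$d
  fit <- list(
    m_W = matrix(unlist(obj$m_W), d, q, dimnames = list(obj$features, NULL)),
    Sigma_w = array(unlist(obj$Sigma_w), dim = c(q, q, d)),
    m_mu = stats::setNames(as.numeric(obj$m_mu), obj$features),
    sigma2_mu = as.numeric(obj$sigma2_mu),
    alpha_shape = obj$alpha_shape, alpha_rate = as.numeric(obj$alpha_rate),
    alpha_mean = as.numeric(obj$alpha_mean),
    tau_shape = obj$tau_shape, tau_rate = obj$tau_rate, tau_mean = obj$tau_mean,
    elbo_trace = as.numeric(obj$elbo_trace),
    component_order = as.integer(obj$component_order),
    component_signs = as.numeric(obj$component_signs),
    features = obj$features, n = obj$n, d = d, q = q,
    control = do.call(vppca_control, obj$control[setdiff(names(obj$control), "q")]),
    anchor = obj$anchor
  )
  fit$control$q <- obj$control$q
  class(fit) <- "vppca_fit"
  np <- NULL
  if (!is.null(obj$norm_params)) {
    np <- structure(list(
      mean = stats::setNames(as.numeric(obj$norm_params$mean),
                             obj$norm_params$features),
      sd = stats::setNames(as.numeric(obj$norm_params$sd),
                           obj$norm_params$features),
      features = obj$norm_params$features,
      sd_type = obj$norm_params$sd_type
    ), class = "norm_params")
  }
  list(fit = fit, norm_params = np)
}
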