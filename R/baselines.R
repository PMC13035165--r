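# Comparator progression scores: classical maximum-likelihood PPCA (EM),
# severity-signed mean z-score, and a deliberately label-overfit 1-D Fisher
# discriminant projection.

#' Classical probabilistic PCA by EM
#'
#' Maximum-likelihood PPCA (isotropic-noise linear-Gaussian factor model, no
#' ARD, no priors): at the ML solution the loading span equals the top-`q`
#' subspace of the sample covariance and the noise variance equals the mean
#' of the discarded eigenvalues.
#'
#' @param X Complete (or pre-imputed) numeric matrix.
#' @param q Number of components.
#' @param max_iter,tol EM iteration controls (convergence in relative
#'   log-likelihood-surrogate change of the parameters).
#' @return Object of class `ppca_fit`: `W` (d x q), `mu`, `sigma2`,
#'   `latent_means` (n x q posterior means), ordering/sign fields as in
#'   `vppca_fit`.
#' @export
baseline_ppca <- function(X, q = NULL, max_iter = 1000L, tol = 1e-10) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("baseline_ppca requires complete data; impute first")
  N <- nrow(X); d <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(d))
  if (is.null(q)) q <- min(d - 1L, 10L)
  stopifnot(q >= 1, q < d)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / N
  # init from scaled SVD; EM then converges to the ML solution
  sv <- svd(Xc, nu = 0, nv = q)
  W <- sv$v %*% diag(sv$d[seq_len(q)] / sqrt(N), q, q)
  sigma2 <- max(mean(diag(S)) / 10, 1e-8)
  for (it in seq_len(max_iter)) {
    M <- crossprod(W) + diag(sigma2, q)
    Minv <- chol2inv(chol(M))
    SW <- S %*% W
    W_new <- SW %*% chol2inv(chol(diag(sigma2, q) + Minv %*% crossprod(W, SW)))
    sigma2_new <- mean(diag(S - SW %*% Minv %*% t(W_new)))
    sigma2_new <- max(sigma2_new, 1e-12)
    delta <- max(abs(W_new - W)) + abs(sigma2_new - sigma2)
    W <- W_new; sigma2 <- sigma2_new
    if (delta < tol) break
  }
  M <- crossprod(W) + diag(sigma2, q)
  Z <- Xc %*% W %*% chol2inv(chol(M))
  structure(list(W = W, mu = mu, sigma2 = sigma2, latent_means = Z,
                 features = colnames(X), n = N, d = d, q = q,
                 component_order = seq_len(q), component_signs = rep(1, q)),
            class = "ppca_fit")
}

#' First-component PPCA scores with the shared anchor sign rule
#'
#' @param fit A `ppca_fit`.
#' @param rows Complete matrix of rows to score (defaults to training rows).
#' @param anchor_feature,anchor_direction Sign convention as in
#'   [order_and_sign_components()].
#' @return Numeric vector of signed first-component posterior-mean scores.
#' @export
ppca_scores <- function(fit, rows = NULL, anchor_feature = "CDRSB",
                        anchor_direction = 1) {
  stopifnot(inherits(fit, "ppca_fit"))
  ord <- order(-colSums(fit$W^2))
  first <- ord[1]
  if (!(anchor_feature %in% fit$features)) {
    anchor_feature <- "Hippocampus"; anchor_direction <- -1
  }
  ai <- match(anchor_feature, fit$features)
  if (is.na(ai)) stop("anchor feature not among fitted columns")
  sg <- ifelse(fit$W[ai, first] * anchor_direction >= 0, 1, -1)
  if (is.null(rows)) {
    z <- fit$latent_means[, first]
  } else {
    rows <- as.matrix(rows)
    M <- crossprod(fit$W) + diag(fit$sigma2, fit$q)
    Z <- sweep(rows, 2, fit$mu) %*% fit$W %*% chol2inv(chol(M))
    z <- Z[, first]
  }
  sg * z
}

#' Column-mean imputation
#'
#' @param X Matrix with `NA`s.
#' @param means Optional column means to use (e.g. from training data).
#' @return Completed matrix.
#' @export
impute_column_mean <- function(X, means = NULL) {
  X <- as.matrix(X)
  if (is.null(means)) means <- colMeans(X, na.rm = TRUE)
  for (k in seq_len(ncol(X))) X[is.na(X[, k]), k] <- means[k]
  X
}

#' Severity-signed mean z-score baseline
#'
#' The score of a row is the mean over its observed features of the
#' severity-direction-signed standardized value, so that larger scores always
#' mean more advanced disease.
#'
#' @param X Standardized matrix (`NA` = missing).
#' @param directions Named (+1/-1) severity direction per feature; defaults
#'   to the panel directions for matching column names.
#' @return Numeric score vector.
#' @export
baseline_mean_zscore <- function(X, directions = NULL) {
  X <- as.matrix(X)
  if (is.null(directions)) {
    p <- feature_panel()
    directions <- stats::setNames(p$direction, p$feature)[colnames(X)]
    if (anyNA(directions)) stop("no severity direction for: ",
                                paste(colnames(X)[is.na(directions)], collapse = ", "))
  }
  if (any(rowSums(!is.na(X)) == 0)) stop("row with zero observed features")
  Xs <- sweep(X, 2, directions, `*`)
  rowMeans(Xs, na.rm = TRUE)
}

#' One-dimensional Fisher discriminant projection (deliberately overfit)
#'
#' Missing entries are replaced by 0 (the post-normalization mean) because
#' the discriminant cannot handle them natively; the within/between scatter
#' matrices are computed on the supplied rows and labels themselves, so the
#' projection is intentionally overfit to those labels — it serves as a
#' label-aware reference axis, not a classifier. A fixed ridge (1e-6 on the
#' diagonal) regularizes a singular within-class scatter.
#'
#' @param X Standardized matrix (`NA` allowed, replaced by `fill_value`).
#' @param labels Class labels (>= 2 classes present).
#' @param fill_value Replacement for missing entries.
#' @return Numeric vector: projection of each row on the first discriminant.
#' @export
baseline_lda_projection <- function(X, labels, fill_value = 0) {
  X <- as.matrix(X)
  X[is.na(X)] <- fill_value
  labels <- as.character(labels)
  cls <- unique(labels)
  stopifnot(length(cls) >= 2)
  d <- ncol(X)
  gm <- colMeans(X)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (g in cls) {
    Xg <- X[labels == g, , drop = FALSE]
    mg <- colMeans(Xg)
    Sw <- Sw + crossprod(sweep(Xg, 2, mg))
    Sb <- Sb + nrow(Xg) * tcrossprod(mg - gm)
  }
  if (rcond(Sw) < 1e-12) {
    message("singular within-class scatter; adding ridge 1e-6")
    Sw <- Sw + diag(1e-6, d)
  }
  ev <- eigen(solve(Sw, Sb))
  w <- Re(ev$vectors[, 1])
  drop(X %*% w)
}
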