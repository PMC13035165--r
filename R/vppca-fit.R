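# Variational Bayesian probabilistic PCA with automatic relevance
# determination, fitted by coordinate-ascent fixed-point updates on
# (partially) observed data.
#
# Model, per observation x_n (d-vector, possibly partially observed):
#   x_n = W z_n + mu + eps_n,   z_n ~ N(0, I_q),  eps_n ~ N(0, tau^-1 I)
#   W[, i] ~ N(0, alpha_i^-1 I_d)   (ARD column precisions)
#   mu ~ N(0, beta^-1 I_d),  alpha_i ~ Gamma(a_alpha, b_alpha),
#   tau ~ Gamma(a_tau, b_tau)
# The variational family factorizes over Z rows, W rows, mu, alpha, tau, all
# Gaussian/Gamma; missing entries simply drop out of every sum, so each row n
# contributes only through its observed coordinate set and each feature k only
# through the rows that observe it.

#' Hyperparameters and fitting controls for the variational PPCA fit
#'
#' @param q Latent dimension (default `min(d - 1, 10)` chosen at fit time
#'   when `NULL`); redundant components are pruned automatically by the ARD
#'   prior, so `q` is an upper bound rather than a model-selection knob.
#' @param beta Prior precision of the mean vector `mu`.
#' @param a_alpha,b_alpha Shape/rate of the Gamma prior on each ARD precision.
#' @param a_tau,b_tau Shape/rate of the Gamma prior on the noise precision.
#' @param max_iter Maximum number of full update sweeps.
#' @param elbo_rel_tol Relative ELBO change declaring convergence.
#' @param seed Integer seed (used only to break exactly degenerate
#'   initializations; the updates themselves are deterministic).
#' @return An object of class `vppca_control`.
#' @export
vppca_control <- function(q = NULL, beta = 1e-3,
                          a_alpha = 1e-3, b_alpha = 1e-3,
                          a_tau = 1e-3, b_tau = 1e-3,
                          max_iter = 500L, elbo_rel_tol = 1e-6,
                          seed = 1L) {
  stopifnot(beta > 0, a_alpha > 0, b_alpha > 0, a_tau > 0, b_tau > 0,
            max_iter >= 1, elbo_rel_tol > 0)
  structure(list(q = q, beta = beta, a_alpha = a_alpha, b_alpha = b_alpha,
                 a_tau = a_tau, b_tau = b_tau, max_iter = as.integer(max_iter),
                 elbo_rel_tol = elbo_rel_tol, seed = as.integer(seed)),
            class = "vppca_control")
}

# group rows by missingness pattern; returns list(pattern_id per row,
# list of observed-index vectors, list of row-index vectors)
.obs_patterns <- function(obs) {
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  uk <- unique(key)
  pid <- match(key, uk)
  list(
    pid = pid,
    obs_idx = lapply(uk, function(k) which(strsplit(k, "")[[1]] == "1")),
    rows = lapply(seq_along(uk), function(i) which(pid == i))
  )
}

#' Fit variational Bayesian PPCA to a (partially observed) data matrix
#'
#' Cycles exact coordinate-ascent updates for the latent rows, the mean, the
#' loading rows, the ARD precisions and the noise precision until the
#' evidence lower bound (ELBO) stabilizes. Missing entries are handled inside
#' the fit: every sum restricts to observed coordinates, and rows sharing a
#' missingness pattern share a latent posterior covariance. The ELBO is
#' evaluated after every full sweep and is guaranteed non-decreasing; a
#' decrease beyond numerical slack aborts with diagnostics.
#'
#' @param X Numeric matrix (rows = observations, columns = standardized
#'   features) with `NA` marking missing entries. Every row needs at least
#'   one observed entry and every column at least two.
#' @param control A [vppca_control()].
#' @return An object of class `vppca_fit` with elements `m_W` (d x q loading
#'   posterior means), `Sigma_w` (q x q x d per-feature-row loading
#'   covariances), `m_mu`, `sigma2_mu`, Gamma posteriors for the ARD
#'   precisions (`alpha_shape`, `alpha_rate`, `alpha_mean`) and the noise
#'   precision (`tau_shape`, `tau_rate`, `tau_mean`), the fitted latent
#'   posterior (`latent_means`, per-pattern `Sigma_x`), `elbo_trace`,
#'   `component_order`, `component_signs` and the control used.
#' @export
fit_vppca <- function(X, control = vppca_control()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  N <- nrow(X); d <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(d))
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0)) stop("every row needs at least one observed entry")
  if (any(colSums(obs) < 2)) stop("every column needs at least two observed entries")
  q <- control$q
  if (is.null(q)) q <- min(d - 1L, 10L)
  q <- as.integer(q)
  stopifnot(q >= 1, q <= d)

  pat <- .obs_patterns(obs)
  n_pat <- length(pat$obs_idx)
  rows_k <- lapply(seq_len(d), function(k) which(obs[, k]))
  N_k <- colSums(obs)
  N_obs <- sum(obs)

  # --- initialization -------------------------------------------------------
  m_mu <- colMeans(X, na.rm = TRUE)
  Ximp <- X
  for (k in seq_len(d)) Ximp[!obs[, k], k] <- m_mu[k]
  Xc <- sweep(Ximp, 2, m_mu)
  sv <- svd(Xc, nu = 0, nv = min(q, min(N, d)))
  svals <- c(sv$d, rep(0, q))[seq_len(q)]
  V <- cbind(sv$v, matrix(0, d, q))[, seq_len(q), drop = FALSE]
  m_W <- V %*% diag(svals / sqrt(N), q, q)
  if (all(abs(m_W) < .Machine$double.eps)) m_W <- matrix(0, d, q)
  dimnames(m_W) <- list(colnames(X), NULL)
  Sigma_w <- array(rep(diag(1e-2, q), d), dim = c(q, q, d))
  sigma2_mu <- rep(1 / (control$beta + N * 1), d)
  # initial q(alpha), q(tau) = their priors (so every CAVI step below is exact)
  a_al <- control$a_alpha; b_al <- rep(control$b_alpha, q)
  alpha_mean <- rep(a_al / control$b_alpha, q)
  a_ta <- control$a_tau; b_ta <- control$b_tau
  tau_mean <- 1

  M <- matrix(0, N, q)
  Sigma_x <- vector("list", n_pat)

  elbo_trace <- numeric(0)
  prev_elbo <- -Inf

  for (iter in seq_len(control$max_iter)) {
    # --- latent update (per missingness pattern) ---------------------------
    for (p in seq_len(n_pat)) {
      ok <- pat$obs_idx[[p]]
      G <- crossprod(m_W[ok, , drop = FALSE]) +
        apply(Sigma_w[, , ok, drop = FALSE], c(1, 2), sum)
      Sx <- chol2inv(chol(diag(q) + tau_mean * G))
      Sigma_x[[p]] <- Sx
      rws <- pat$rows[[p]]
      Xn <- sweep(X[rws, ok, drop = FALSE], 2, m_mu[ok])
      M[rws, ] <- tau_mean * (Xn %*% m_W[ok, , drop = FALSE]) %*% Sx
    }

    # --- mean update --------------------------------------------------------
    pred <- M %*% t(m_W)
    sigma2_mu <- 1 / (control$beta + N_k * tau_mean)
    for (k in seq_len(d)) {
      r <- rows_k[[k]]
      m_mu[k] <- tau_mean * sigma2_mu[k] * sum(X[r, k] - pred[r, k])
    }

    # --- loading-row updates ------------------------------------------------
    # per-pattern counts of rows observing each feature
    cnt <- matrix(0, n_pat, d)
    for (p in seq_len(n_pat)) {
      cnt[p, pat$obs_idx[[p]]] <- length(pat$rows[[p]])
    }
    for (k in seq_len(d)) {
      r <- rows_k[[k]]
      Mk <- M[r, , drop = FALSE]
      A <- crossprod(Mk)
      for (p in which(cnt[, k] > 0)) A <- A + cnt[p, k] * Sigma_x[[p]]
      Sw <- chol2inv(chol(diag(alpha_mean, q) + tau_mean * A))
      Sigma_w[, , k] <- Sw
      m_W[k, ] <- tau_mean * (Sw %*% crossprod(Mk, X[r, k] - m_mu[k]))
    }

    # --- ARD precision update ----------------------------------------------
    w_sq <- colSums(m_W^2) +
      vapply(seq_len(q), function(i) sum(Sigma_w[i, i, ]), numeric(1))
    a_al <- control$a_alpha + d / 2
    b_al <- control$b_alpha + w_sq / 2
    alpha_mean <- a_al / b_al

    # --- expected squared residuals over observed entries -------------------
    ss <- .expected_sq_resid(X, obs, M, Sigma_x, pat, cnt, m_W, Sigma_w,
                             m_mu, sigma2_mu, rows_k)

    # --- noise precision update ---------------------------------------------
    a_ta <- control$a_tau + N_obs / 2
    b_ta <- control$b_tau + ss$total / 2
    tau_mean <- a_ta / b_ta

    # --- ELBO ---------------------------------------------------------------
    elbo <- .vppca_elbo(control, N, d, q, N_obs, ss$total, M, Sigma_x, pat,
                        m_W, Sigma_w, w_sq, m_mu, sigma2_mu,
                        a_al, b_al, alpha_mean, a_ta, b_ta, tau_mean)
    if (!is.finite(elbo)) stop("non-finite ELBO at iteration ", iter)
    slack <- 1e-8 * max(1, abs(elbo))
    if (elbo < prev_elbo - slack) {
      stop(sprintf("ELBO decreased at iteration %d (%.10g -> %.10g)",
                   iter, prev_elbo, elbo))
    }
    elbo_trace <- c(elbo_trace, elbo)
    if (is.finite(prev_elbo) &&
        abs(elbo - prev_elbo) < control$elbo_rel_tol * abs(elbo)) {
      prev_elbo <- elbo
      break
    }
    prev_elbo <- elbo
  }

  structure(list(
    m_W = m_W, Sigma_w = Sigma_w,
    m_mu = stats::setNames(m_mu, colnames(X)), sigma2_mu = sigma2_mu,
    alpha_shape = a_al, alpha_rate = b_al, alpha_mean = alpha_mean,
    tau_shape = a_ta, tau_rate = b_ta, tau_mean = tau_mean,
    latent_means = M, Sigma_x = Sigma_x, pattern_id = pat$pid,
    pattern_obs = pat$obs_idx,
    elbo_trace = elbo_trace,
    component_order = seq_len(q), component_signs = rep(1, q),
    features = colnames(X), n = N, d = d, q = q,
    control = control
  ), class = "vppca_fit")
}

# E_q[(x_nk - w_k' z_n - mu_k)^2] summed over observed entries, plus the
# same quantity per feature (used by the ELBO and the tau update)
.expected_sq_resid <- function(X, obs, M, Sigma_x, pat, cnt, m_W, Sigma_w,
                               m_mu, sigma2_mu, rows_k) {
  d <- ncol(X)
  total <- 0
  for (k in seq_len(d)) {
    r <- rows_k[[k]]
    Mk <- M[r, , drop = FALSE]
    w <- m_W[k, ]
    q <- ncol(M)
    Sw <- matrix(Sigma_w[, , k], q, q)
    resid <- X[r, k] - Mk %*% w - m_mu[k]
    s <- sum(resid^2) + sum((Mk %*% Sw) * Mk) + length(r) * sigma2_mu[k]
    for (p in which(cnt[, k] > 0)) {
      Sx <- Sigma_x[[p]]
      s <- s + cnt[p, k] * (drop(w %*% Sx %*% w) + sum(Sw * Sx))
    }
    total <- total + s
  }
  list(total = total)
}

.vppca_elbo <- function(control, N, d, q, N_obs, ss_total, M, Sigma_x, pat,
                        m_W, Sigma_w, w_sq, m_mu, sigma2_mu,
                        a_al, b_al, alpha_mean, a_ta, b_ta, tau_mean) {
  elog_tau <- digamma(a_ta) - log(b_ta)
  elog_alpha <- digamma(a_al) - log(b_al)

  # expected data log-likelihood over observed entries
  ll <- N_obs / 2 * (elog_tau - log(2 * pi)) - tau_mean / 2 * ss_total

  # latent prior + entropy
  tr_Ezz <- sum(M^2)
  logdet_x <- 0
  for (p in seq_along(Sigma_x)) {
    npat <- length(pat$rows[[p]])
    tr_Ezz <- tr_Ezz + npat * sum(diag(Sigma_x[[p]]))
    logdet_x <- logdet_x + npat * determinant(Sigma_x[[p]])$modulus
  }
  lz <- -N * q / 2 * log(2 * pi) - tr_Ezz / 2
  hz <- N * q / 2 * (1 + log(2 * pi)) + logdet_x / 2

  # loadings prior + entropy
  lw <- d / 2 * sum(elog_alpha) - d * q / 2 * log(2 * pi) -
    sum(alpha_mean * w_sq) / 2
  logdet_w <- sum(vapply(seq_len(d), function(k)
    as.numeric(determinant(matrix(Sigma_w[, , k], q, q))$modulus), numeric(1)))
  hw <- d * q / 2 * (1 + log(2 * pi)) + logdet_w / 2

  # mean prior + entropy
  lmu <- d / 2 * (log(control$beta) - log(2 * pi)) -
    control$beta / 2 * sum(m_mu^2 + sigma2_mu)
  hmu <- sum(log(2 * pi * exp(1) * sigma2_mu)) / 2

  # Gamma priors + entropies
  lalpha <- sum(control$a_alpha * log(control$b_alpha) - lgamma(control$a_alpha) +
                  (control$a_alpha - 1) * elog_alpha - control$b_alpha * alpha_mean)
  halpha <- sum(a_al - log(b_al) + lgamma(a_al) + (1 - a_al) * digamma(a_al))
  ltau <- control$a_tau * log(control$b_tau) - lgamma(control$a_tau) +
    (control$a_tau - 1) * elog_tau - control$b_tau * tau_mean
  htau <- a_ta - log(b_ta) + lgamma(a_ta) + (1 - a_ta) * digamma(a_ta)

  as.numeric(ll + lz + hz + lw + hw + lmu + hmu + lalpha + halpha + ltau + htau)
}

#' Evidence lower bound of a fitted variational posterior
#'
#' Recomputes the ELBO of `fit` on `X` (the matrix it was fitted to), summing
#' the expected complete-data log-likelihood over observed entries, the prior
#' expectations and the variational entropies.
#'
#' @param X The data matrix the posterior was fitted to.
#' @param fit A `vppca_fit`.
#' @return Scalar ELBO.
#' @export
compute_elbo <- function(X, fit) {
  stopifnot(inherits(fit, "vppca_fit"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == fit$n, ncol(X) == fit$d)
  obs <- !is.na(X)
  pat <- list(pid = fit$pattern_id, obs_idx = fit$pattern_obs,
              rows = lapply(seq_along(fit$pattern_obs),
                            function(i) which(fit$pattern_id == i)))
  rows_k <- lapply(seq_len(fit$d), function(k) which(obs[, k]))
  cnt <- matrix(0, length(pat$obs_idx), fit$d)
  for (p in seq_along(pat$obs_idx)) {
    cnt[p, pat$obs_idx[[p]]] <- length(pat$rows[[p]])
  }
  w_sq <- colSums(fit$m_W^2) +
    vapply(seq_len(fit$q), function(i) sum(fit$Sigma_w[i, i, ]), numeric(1))
  ss <- .expected_sq_resid(X, obs, fit$latent_means, fit$Sigma_x, pat, cnt,
                           fit$m_W, fit$Sigma_w, fit$m_mu, fit$sigma2_mu,
                           rows_k)
  elbo <- .vppca_elbo(fit$control, fit$n, fit$d, fit$q, sum(obs), ss$total,
                      fit$latent_means, fit$Sigma_x, pat,
                      fit$m_W, fit$Sigma_w, w_sq, fit$m_mu, fit$sigma2_mu,
                      fit$alpha_shape, fit$alpha_rate, fit$alpha_mean,
                      fit$tau_shape, fit$tau_rate, fit$tau_mean)
  if (!is.finite(elbo)) stop("non-finite ELBO")
  elbo
}

#' @export
print.vppca_fit <- function(x, ...) {
  cat("Variational PPCA fit\n")
  cat(sprintf("  n = %d observations, d = %d features, q = %d components\n",
              x$n, x$d, x$q))
  cat(sprintf("  <tau> = %.4g (noise sd %.4g)\n", x$tau_mean, 1 / sqrt(x$tau_mean)))
  norms <- sqrt(colSums(x$m_W^2))
  cat("  loading norms:", paste(sprintf("%.3f", norms[x$component_order]),
                                collapse = " "), "\n")
  cat(sprintf("  ELBO: %.6g after %d sweeps\n",
              utils::tail(x$elbo_trace, 1), length(x$elbo_trace)))
  invisible(x)
}
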