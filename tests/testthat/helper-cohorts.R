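# Shared fixture builders (all fixtures are generated in code).

# tiny long-format cohort with controllable missingness in one feature
toy_table <- function(n_patients = 10, miss_feature = NULL, n_miss = 0) {
  tab <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n_patients)),
    visit_time = 0,
    diagnosis = rep(c("CN", "MCI"), length.out = n_patients),
    CDRSB = seq(0, 4, length.out = n_patients),
    ADAS13 = seq(5, 30, length.out = n_patients),
    Hippocampus = seq(7500, 5500, length.out = n_patients),
    AGE = seq(60, 85, length.out = n_patients),
    ICV = seq(1.3e6, 1.7e6, length.out = n_patients),
    stringsAsFactors = FALSE
  )
  if (!is.null(miss_feature) && n_miss > 0) {
    tab[[miss_feature]][seq_len(n_miss)] <- NA_real_
  }
  tab
}

# scores from a planted hierarchical trajectory model
simulate_hier_scores <- function(P = 100, times = 0:3, alpha = 0, beta = 0.5,
                                 sigma_alpha = 0.5, sigma_beta = 0.2,
                                 rho = 0.3, sigma = 0.1, seed = 1) {
  set.seed(seed)
  Sig <- diag(c(sigma_alpha, sigma_beta)) %*%
    matrix(c(1, rho, rho, 1), 2) %*% diag(c(sigma_alpha, sigma_beta))
  re <- MASS::mvrnorm(P, c(alpha, beta), Sig)
  sc <- do.call(rbind, lapply(seq_len(P), function(p) {
    data.frame(patient_id = sprintf("P%03d", p), visit_time = times,
               score1 = re[p, 1] + re[p, 2] * times +
                 stats::rnorm(length(times), 0, sigma),
               stringsAsFactors = FALSE)
  }))
  list(scores = sc, alpha_p = re[, 1], beta_p = re[, 2])
}

# complete low-rank matrix with planted loadings
planted_lowrank <- function(N = 200, d = 10, sv = c(3, 1.5), noise = 0,
                            seed = 1) {
  set.seed(seed)
  r <- length(sv)
  Z <- matrix(stats::rnorm(N * r), N) %*% diag(sv, r, r)
  W <- matrix(stats::rnorm(d * r), d, r)
  X <- Z %*% t(W)
  if (noise > 0) X <- X + matrix(stats::rnorm(N * d, 0, noise), N)
  list(X = X, Z = Z, W = W)
}
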