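# Bayesian hierarchical random-intercept/random-slope model of progression
# scores over time, fitted by MCMC (Gibbs/slice sampling via JAGS), with
# convergence diagnostics and per-patient trajectory prediction.
#
# Model: score_n ~ Normal(alpha_{p(n)} + beta_{p(n)} * t_n, sigma)
#        (alpha_p, beta_p) ~ MVN((alpha, beta), S L L' S),
#        S = diag(sigma_alpha, sigma_beta), L = Cholesky factor of the
#        intercept-slope correlation matrix with an LKJ prior.
# Priors: alpha, beta ~ Normal(0, sd 2); sigma_alpha, sigma_beta, sigma ~
# Exponential(1); correlation ~ LKJ(eta). For a 2x2 correlation matrix the
# LKJ density is proportional to (1 - rho^2)^(eta - 1), so eta = 1 (the
# default) is uniform on rho.

#' Specification of the hierarchical longitudinal model
#'
#' @param mean_prior_sd Prior sd of the population mean intercept and slope.
#' @param scale_prior_rate Rate of the exponential priors on the random-effect
#'   scales `sigma_alpha`, `sigma_beta`.
#' @param resid_prior_rate Rate of the exponential prior on the residual sd.
#' @param lkj_eta LKJ shape for the intercept-slope correlation (1 = uniform).
#' @param chains Number of MCMC chains (>= 2 for R-hat).
#' @param warmup,sampling Iterations per chain discarded / retained.
#' @param seed Integer seed (drives per-chain RNGs).
#' @return Object of class `hier_spec`.
#' @export
hier_model_spec <- function(mean_prior_sd = 2, scale_prior_rate = 1,
                            resid_prior_rate = 1, lkj_eta = 1,
                            chains = 4L, warmup = 3000L, sampling = 3000L,
                            seed = 1L) {
  stopifnot(mean_prior_sd > 0, scale_prior_rate > 0, resid_prior_rate > 0,
            lkj_eta > 0, chains >= 2, warmup >= 0, sampling >= 4)
  structure(list(mean_prior_sd = mean_prior_sd,
                 scale_prior_rate = scale_prior_rate,
                 resid_prior_rate = resid_prior_rate, lkj_eta = lkj_eta,
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 sampling = as.integer(sampling), seed = as.integer(seed)),
            class = "hier_spec")
}

.hier_model_string <- function(prior_only = FALSE, lkj_eta = 1) {
  lik <- if (prior_only) "" else "
  for (n in 1:N) {
    y[n] ~ dnorm(ab[pid[n], 1] + ab[pid[n], 2] * t[n], tau_y)
  }"
  lkj <- if (lkj_eta != 1) "
  # LKJ(eta) density on rho via the zeros trick
  zero ~ dpois(phi)
  phi <- -(eta - 1) * log(1 - rho * rho) + 10" else ""
  paste0("model {", lik, "
  for (p in 1:P) { ab[p, 1:2] ~ dmnorm(mu[1:2], Prec[1:2, 1:2]) }
  mu[1] ~ dnorm(0, prec_mean)
  mu[2] ~ dnorm(0, prec_mean)
  sig_a ~ dexp(rate_scale)
  sig_b ~ dexp(rate_scale)
  sigma ~ dexp(rate_resid)
  tau_y <- pow(sigma, -2)
  rho ~ dunif(-1, 1)", lkj, "
  Cov[1, 1] <- sig_a * sig_a
  Cov[2, 2] <- sig_b * sig_b
  Cov[1, 2] <- rho * sig_a * sig_b
  Cov[2, 1] <- Cov[1, 2]
  Prec[1:2, 1:2] <- inverse(Cov[1:2, 1:2])
}")
}

#' Fit the hierarchical longitudinal model by MCMC
#'
#' Observation times are re-expressed as years since each patient's first
#' visit, so the intercept is the patient's baseline score. The model is
#' sampled in the centered parameterization (per-patient effects drawn
#' jointly from the bivariate normal), which mixes well when visits are
#' informative relative to the between-patient scales.
#'
#' @param scores A `data.frame` with `patient_id`, `visit_time`, `score1`
#'   (e.g. from [progression_scores()]).
#' @param spec A [hier_model_spec()].
#' @param prior_only Sample from the priors alone (no likelihood term); used
#'   for prior predictive checks.
#' @param quiet Suppress JAGS progress output.
#' @return Object of class `hier_fit`: `draws` (iterations x chains x
#'   parameters array), `rhat` and `ess` per parameter, `patients`,
#'   `divergent` (NA; the Gibbs sampler has no divergence diagnostic),
#'   `spec`. Population parameters are named `alpha`, `beta`, `sigma_alpha`,
#'   `sigma_beta`, `sigma`, `rho`; per-patient effects `alpha_p[i]`,
#'   `beta_p[i]`.
#' @export
fit_hierarchical <- function(scores, spec = hier_model_spec(),
                             prior_only = FALSE, quiet = TRUE) {
  stopifnot(inherits(spec, "hier_spec"))
  if (!prior_only) {
    stopifnot(all(c("patient_id", "visit_time", "score1") %in% names(scores)))
    scores <- scores[is.finite(scores$score1) & is.finite(scores$visit_time), ]
    pts <- unique(scores$patient_id)
    stopifnot(length(pts) >= 2)
    t0 <- tapply(scores$visit_time, scores$patient_id, min)
    tt <- scores$visit_time - t0[as.character(scores$patient_id)]
    dat <- list(y = scores$score1, t = as.numeric(tt),
                pid = match(scores$patient_id, pts),
                N = nrow(scores), P = length(pts))
  } else {
    pts <- sprintf("prior%03d", 1:50)
    dat <- list(P = length(pts))
  }
  dat$prec_mean <- 1 / spec$mean_prior_sd^2
  dat$rate_scale <- spec$scale_prior_rate
  dat$rate_resid <- spec$resid_prior_rate
  if (spec$lkj_eta != 1) {
    dat$eta <- spec$lkj_eta
    dat$zero <- 0
  }
  inits <- lapply(seq_len(spec$chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = spec$seed * 1000L + i)
  })
  # spend the warmup on sampler adaptation first (up to 1000 iterations),
  # then burn-in; short warmups are used entirely for adaptation
  n_adapt <- min(spec$warmup, 1000L)
  if (n_adapt == 0L) n_adapt <- 100L
  model <- rjags::jags.model(
    textConnection(.hier_model_string(prior_only, spec$lkj_eta)),
    data = dat, inits = inits, n.chains = spec$chains,
    n.adapt = n_adapt, quiet = quiet
  )
  burn <- max(0L, spec$warmup - n_adapt)
  if (burn > 0) update(model, burn, progress.bar = "none")
  monitors <- c("mu", "sig_a", "sig_b", "sigma", "rho", "ab")
  samp <- rjags::coda.samples(model, monitors, n.iter = spec$sampling,
                              progress.bar = "none")
  draws <- .coda_to_array(samp)
  dimnames(draws)[[3]] <- .rename_hier_params(dimnames(draws)[[3]], pts)
  rhat <- apply(draws, 3, compute_rhat)
  ess <- stats::setNames(as.numeric(coda::effectiveSize(samp)),
                         dimnames(draws)[[3]])
  bad <- rhat[is.finite(rhat)] > 1.05
  if (any(bad)) {
    warning(sum(bad), " parameter(s) with split-R-hat > 1.05; ",
            "inspect convergence before use")
  }
  structure(list(draws = draws, rhat = rhat, ess = ess, patients = pts,
                 prior_only = prior_only, spec = spec),
            class = "hier_fit")
}

# coda mcmc.list -> iterations x chains x parameters array
.coda_to_array <- function(samp) {
  p <- ncol(samp[[1]])
  it <- nrow(samp[[1]])
  arr <- array(NA_real_, c(it, length(samp), p),
               dimnames = list(NULL, NULL, colnames(samp[[1]])))
  for (c in seq_along(samp)) arr[, c, ] <- as.matrix(samp[[c]])
  arr
}

.rename_hier_params <- function(nm, pts) {
  nm[nm == "mu[1]"] <- "alpha"
  nm[nm == "mu[2]"] <- "beta"
  nm[nm == "sig_a"] <- "sigma_alpha"
  nm[nm == "sig_b"] <- "sigma_beta"
  ab <- grepl("^ab\\[", nm)
  if (any(ab)) {
    idx <- regmatches(nm[ab], regexec("^ab\\[(\\d+),(\\d+)\\]$", nm[ab]))
    nm[ab] <- vapply(idx, function(m) {
      paste0(if (m[3] == "1") "alpha_p[" else "beta_p[", m[2], "]")
    }, character(1))
  }
  nm
}

#' Posterior draws of a named parameter
#'
#' @param fit A `hier_fit`.
#' @param par Parameter name (see [fit_hierarchical()]).
#' @return Numeric vector of pooled draws (all chains).
#' @export
hier_draws <- function(fit, par) {
  stopifnot(inherits(fit, "hier_fit"), par %in% dimnames(fit$draws)[[3]])
  as.numeric(fit$draws[, , par])
}

#' Cholesky factor of the intercept-slope correlation matrix per draw
#'
#' @param fit A `hier_fit`.
#' @return 2 x 2 x draws array of lower-triangular Cholesky factors with
#'   unit-norm rows.
#' @export
hier_corr_chol <- function(fit) {
  rho <- hier_draws(fit, "rho")
  out <- array(0, c(2, 2, length(rho)))
  out[1, 1, ] <- 1
  out[2, 1, ] <- rho
  out[2, 2, ] <- sqrt(1 - rho^2)
  out
}

#' Predict a patient's score trajectory
#'
#' For each posterior draw the conditional mean is `alpha_p + beta_p * t`;
#' the predictive interval additionally includes the residual noise `sigma`.
#' A patient absent from the fit gets the population-level prediction, with
#' random effects drawn from their posterior-parameterized bivariate normal.
#'
#' @param fit A `hier_fit`.
#' @param patient_id Patient identifier.
#' @param times Numeric vector of years since the patient's first visit.
#' @param include_residual Include residual noise in the interval (default
#'   `TRUE`).
#' @param seed Seed for the predictive noise draws.
#' @return `data.frame` with `patient_id`, `time`, `mean`, `lo95`, `hi95`.
#' @export
predict_trajectory <- function(fit, patient_id, times,
                               include_residual = TRUE, seed = 1L) {
  stopifnot(inherits(fit, "hier_fit"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i <- match(patient_id, fit$patients)
  n_draw <- prod(dim(fit$draws)[1:2])
  if (!is.na(i)) {
    a <- hier_draws(fit, sprintf("alpha_p[%d]", i))
    b <- hier_draws(fit, sprintf("beta_p[%d]", i))
  } else {
    # unseen patient: draw random effects from the population posterior
    mu_a <- hier_draws(fit, "alpha"); mu_b <- hier_draws(fit, "beta")
    sa <- hier_draws(fit, "sigma_alpha"); sb <- hier_draws(fit, "sigma_beta")
    rho <- hier_draws(fit, "rho")
    z1 <- stats::rnorm(n_draw); z2 <- stats::rnorm(n_draw)
    a <- mu_a + sa * z1
    b <- mu_b + sb * (rho * z1 + sqrt(1 - rho^2) * z2)
  }
  sig <- hier_draws(fit, "sigma")
  out <- lapply(times, function(t) {
    m <- a + b * t
    pred <- if (include_residual) m + stats::rnorm(n_draw, 0, sig) else m
    data.frame(patient_id = patient_id, time = t, mean = mean(m),
               lo95 = stats::quantile(pred, 0.025),
               hi95 = stats::quantile(pred, 0.975))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Group-wise posterior summaries of intercepts and slopes
#'
#' Averages the per-patient random effects within each baseline diagnostic
#' group, per posterior draw, and summarizes the group means.
#'
#' @param fit A `hier_fit`.
#' @param baseline_dx Named vector: diagnosis label per patient id (patients
#'   in the fit).
#' @return `data.frame` with one row per group: posterior mean and 95%
#'   interval of the group mean intercept and slope.
#' @export
summarize_group_trajectories <- function(fit, baseline_dx) {
  stopifnot(inherits(fit, "hier_fit"))
  dx <- baseline_dx[fit$patients]
  stopifnot(!anyNA(dx))
  groups <- unique(dx)
  out <- lapply(groups, function(g) {
    idx <- which(dx == g)
    A <- sapply(idx, function(i) hier_draws(fit, sprintf("alpha_p[%d]", i)))
    B <- sapply(idx, function(i) hier_draws(fit, sprintf("beta_p[%d]", i)))
    am <- rowMeans(as.matrix(A)); bm <- rowMeans(as.matrix(B))
    data.frame(group = g, n = length(idx),
               intercept = mean(am),
               intercept_lo = stats::quantile(am, 0.025),
               intercept_hi = stats::quantile(am, 0.975),
               slope = mean(bm),
               slope_lo = stats::quantile(bm, 0.025),
               slope_hi = stats::quantile(bm, 0.975))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("Hierarchical longitudinal fit (", dim(x$draws)[2], " chains x ",
      dim(x$draws)[1], " draws)\n", sep = "")
  pars <- c("alpha", "beta", "sigma_alpha", "sigma_beta", "sigma", "rho")
  sm <- t(vapply(pars, function(p) {
    d <- hier_draws(x, p)
    c(mean = mean(d), sd = stats::sd(d), rhat = unname(x$rhat[p]))
  }, numeric(3)))
  print(round(sm, 4))
  cat("max split-R-hat over all parameters:",
      format(max(x$rhat, na.rm = TRUE), digits = 6), "\n")
  invisible(x)
}
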