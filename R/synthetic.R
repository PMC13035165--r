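# Synthetic longitudinal cohort generator with known ground truth.
#
# Observation model: a single latent progression axis s drives every feature
# block linearly (one-factor linear-Gaussian model); per patient the latent
# follows a random-intercept/slope trajectory s = alpha_p + beta_p * t with
# correlated (alpha_p, beta_p). Features are emitted on their natural raw
# scales, regional brain volumes additionally carry age and intracranial
# volume structure, and missingness combines per-feature MCAR with
# whole-modality block dropout.

#' Specify a synthetic cohort
#'
#' @param n_patients Number of patients.
#' @param visit_times Numeric vector of visit times in years from baseline,
#'   shared by all patients (first element must be 0).
#' @param alpha_mean,beta_mean Population mean baseline score and annual
#'   progression rate on the latent scale.
#' @param alpha_sd,beta_sd Between-patient standard deviations of intercept
#'   and slope.
#' @param ab_cor Intercept-slope correlation in (-1, 1); positive values make
#'   more affected patients progress faster.
#' @param noise_sd Observation noise standard deviation on the standardized
#'   feature scale.
#' @param group_thresholds Two increasing cutpoints on the baseline latent
#'   mapping to CN / MCI / Dementia. Defaults to the 25th/75th percentile of
#'   the baseline latent distribution, giving roughly 25/50/25 group sizes.
#' @param features Feature names to emit (subset of [feature_panel()]).
#' @param loadings Optional named vector overriding the panel's per-feature
#'   latent loading strengths (standardized scale), e.g. to plant signal in
#'   one modality block only.
#' @param mcar_rates Named per-feature MCAR missingness probabilities;
#'   defaults to the panel's `mcar_rate` column.
#' @param block_miss_prob Named per-block probability that a whole modality
#'   block is absent at a visit (e.g. no lumbar puncture performed).
#' @param platform CSF assay platform label stored with the cohort.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 500,
                        visit_times = 0:3,
                        alpha_mean = 0, beta_mean = 0.25,
                        alpha_sd = 1, beta_sd = 0.15,
                        ab_cor = 0.3,
                        noise_sd = 0.3,
                        group_thresholds = NULL,
                        features = feature_panel()$feature,
                        loadings = NULL,
                        mcar_rates = NULL,
                        block_miss_prob = c(CSF = 0.10, PET = 0.08, MRI = 0,
                                            cognitive = 0, demographic = 0),
                        platform = "Elecsys",
                        seed = 1L) {
  stopifnot(n_patients >= 2, visit_times[1] == 0, all(diff(visit_times) > 0))
  stopifnot(abs(ab_cor) < 1, alpha_sd > 0, beta_sd > 0, noise_sd >= 0)
  panel <- feature_panel()
  stopifnot(all(features %in% panel$feature))
  if (is.null(group_thresholds)) {
    group_thresholds <- stats::qnorm(c(0.25, 0.75), alpha_mean, alpha_sd)
  }
  stopifnot(length(group_thresholds) == 2, diff(group_thresholds) > 0)
  if (is.null(mcar_rates)) {
    mcar_rates <- stats::setNames(panel$mcar_rate, panel$feature)[features]
  }
  stopifnot(all(mcar_rates >= 0), all(mcar_rates < 1),
            all(block_miss_prob >= 0), all(block_miss_prob <= 1))
  structure(list(
    n_patients = as.integer(n_patients), visit_times = visit_times,
    alpha_mean = alpha_mean, beta_mean = beta_mean,
    alpha_sd = alpha_sd, beta_sd = beta_sd, ab_cor = ab_cor,
    noise_sd = noise_sd, group_thresholds = group_thresholds,
    features = features, loadings = loadings, mcar_rates = mcar_rates,
    block_miss_prob = block_miss_prob, platform = platform,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic longitudinal cohort with ground truth
#'
#' Draws per-patient random effects from the bivariate normal with the
#' spec's scales and correlation, forms the latent trajectory
#' `s = alpha_p + beta_p * t`, emits every feature as
#' `raw = mean + sd * (loading * s + noise)` (volumes with additional age and
#' ICV terms), assigns the diagnosis from the baseline latent against the
#' group thresholds, and applies the missingness spec.
#'
#' @param spec A [cohort_spec()].
#' @param missingness Apply the spec's missingness (`TRUE`) or return the
#'   complete table (`FALSE`).
#' @return A list with `table` (long-format `data.frame`, one row per
#'   patient-visit) and `truth` (planted parameters: random effects, latent
#'   values per row, loadings, noise sd, missingness mask).
#' @export
generate_cohort <- function(spec, missingness = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  P <- spec$n_patients
  tt <- spec$visit_times
  V <- length(tt)
  panel <- feature_panel()
  rownames(panel) <- panel$feature
  panel <- panel[spec$features, ]
  if (!is.null(spec$loadings)) {
    hit <- intersect(names(spec$loadings), panel$feature)
    panel[hit, "loading"] <- spec$loadings[hit]
  }

  Sigma <- diag(c(spec$alpha_sd, spec$beta_sd)) %*%
    matrix(c(1, spec$ab_cor, spec$ab_cor, 1), 2) %*%
    diag(c(spec$alpha_sd, spec$beta_sd))
  re <- MASS::mvrnorm(P, c(spec$alpha_mean, spec$beta_mean), Sigma)
  alpha_p <- re[, 1]; beta_p <- re[, 2]

  pid <- sprintf("P%04d", seq_len(P))
  age0 <- stats::rnorm(P, 73.4, 7.3)
  icv <- stats::rnorm(P, 1.5e6, 1.5e5)
  educ <- stats::rnorm(P, 16, 2.7)
  apoe <- sample(0:2, P, replace = TRUE, prob = c(0.40, 0.44, 0.16))

  rows_pid <- rep(pid, each = V)
  rows_t <- rep(tt, P)
  s <- rep(alpha_p, each = V) + rep(beta_p, each = V) * rows_t
  n <- length(s)

  X <- matrix(NA_real_, n, nrow(panel),
              dimnames = list(NULL, panel$feature))
  for (j in seq_len(nrow(panel))) {
    f <- panel$feature[j]
    if (f == "AGE") { X[, j] <- rep(age0, each = V); next }
    if (f == "PTEDUCAT") { X[, j] <- rep(educ, each = V); next }
    if (f == "APOE4") { X[, j] <- rep(apoe, each = V); next }
    z <- panel$loading[j] * s + stats::rnorm(n, 0, spec$noise_sd)
    x <- panel$mean[j] + panel$sd[j] * z
    if (panel$block[j] == "MRI") {
      x <- x + panel$age_slope[j] * (rep(age0, each = V) - 73.4) +
        panel$icv_slope[j] * (rep(icv, each = V) - 1.5e6)
    }
    X[, j] <- x
  }

  dx <- cut(alpha_p, c(-Inf, spec$group_thresholds, Inf),
            labels = c("CN", "MCI", "Dementia"))
  table <- data.frame(
    patient_id = rows_pid,
    visit_time = rows_t,
    diagnosis = as.character(rep(dx, each = V)),
    X,
    ICV = rep(icv, each = V),
    platform = spec$platform,
    stringsAsFactors = FALSE
  )

  truth <- list(
    alpha_p = stats::setNames(alpha_p, pid),
    beta_p = stats::setNames(beta_p, pid),
    latent = s,
    loadings = stats::setNames(panel$loading, panel$feature),
    noise_sd = spec$noise_sd,
    group_thresholds = spec$group_thresholds,
    mask = NULL
  )

  if (missingness) {
    masked <- apply_missingness(table, spec)
    table <- masked$table
    truth$mask <- masked$mask
  }
  list(table = table, truth = truth)
}

#' Apply the missingness specification to a complete cohort table
#'
#' Per-feature MCAR Bernoulli masking plus whole-block dropout per
#' (visit, modality block). A row is never left with all features missing:
#' the probability of fully masking a row is computed from the spec and the
#' generator refuses if it reaches 1e-3; the rare realized all-missing row is
#' redrawn.
#'
#' @param table Complete cohort table as emitted by [generate_cohort()].
#' @param spec The [cohort_spec()] carrying `mcar_rates` and
#'   `block_miss_prob`. Masking uses the current RNG stream.
#' @return List with `table` (masked) and `mask` (logical matrix, `TRUE` =
#'   missing) over the feature columns.
#' @export
apply_missingness <- function(table, spec) {
  panel <- feature_panel()
  feats <- .table_features(table, spec$features)
  blocks <- stats::setNames(panel$block, panel$feature)[feats]
  rates <- spec$mcar_rates[feats]
  bprob <- spec$block_miss_prob

  # probability a whole row ends up masked, by block independence
  p_row <- 1
  for (b in unique(blocks)) {
    pb <- if (b %in% names(bprob)) bprob[[b]] else 0
    p_row <- p_row * (pb + (1 - pb) * prod(rates[blocks == b]))
  }
  if (p_row >= 1e-3) {
    stop(sprintf(paste0("missingness spec would mask entire rows with ",
                        "probability %.2g >= 1e-3; lower the rates"), p_row))
  }

  n <- nrow(table)
  draw_mask <- function(nr) {
    m <- matrix(stats::runif(nr * length(feats)), nr) <
      matrix(rates, nr, length(feats), byrow = TRUE)
    for (b in unique(blocks)) {
      pb <- if (b %in% names(bprob)) bprob[[b]] else 0
      if (pb > 0) {
        hit <- stats::runif(nr) < pb
        m[hit, blocks == b] <- TRUE
      }
    }
    m
  }
  mask <- draw_mask(n)
  allmiss <- rowSums(!mask) == 0
  while (any(allmiss)) {
    mask[allmiss, ] <- draw_mask(sum(allmiss))
    allmiss <- rowSums(!mask) == 0
  }
  colnames(mask) <- feats
  for (j in seq_along(feats)) table[[feats[j]]][mask[, j]] <- NA_real_
  list(table = table, mask = mask)
}
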