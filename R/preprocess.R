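# Preprocessing: amyloid gating, missing-rate feature filtering, age/ICV
# adjustment of regional volumes, train-anchored z-scoring, patient-level
# splitting.

#' Classify amyloid status from CSF amyloid-beta 1-42
#'
#' A patient is amyloid positive when CSF Abeta42 is strictly below the
#' platform-specific cutoff: 1100 pg/mL on the Roche Elecsys immunoassay,
#' 192 pg/mL on INNO-BIA AlzBio3.
#'
#' @param ab42 Abeta42 concentration in pg/mL (NA allowed).
#' @param platform `"Elecsys"` or `"AlzBio3"` (vectorized, recycled).
#' @return Logical vector: `TRUE` = positive, `NA` when `ab42` is missing.
#' @export
#' @examples
#' classify_amyloid_status(1000, "Elecsys") # TRUE
#' classify_amyloid_status(1100, "Elecsys") # FALSE (strict inequality)
classify_amyloid_status <- function(ab42, platform) {
  cutoffs <- c(Elecsys = 1100, AlzBio3 = 192)
  bad <- !is.na(platform) & !(platform %in% names(cutoffs))
  if (any(bad)) {
    stop("unknown assay platform: ", paste(unique(platform[bad]), collapse = ", "))
  }
  if (any(!is.na(ab42) & ab42 <= 0)) stop("ab42 must be positive")
  out <- ab42 < cutoffs[platform]
  out[is.na(ab42)] <- NA
  unname(out)
}

#' Restrict a cohort to amyloid-positive patients
#'
#' Positivity is assessed on the baseline (visit_time == 0) ABETA value;
#' patients with missing baseline ABETA have unknown status and are excluded.
#'
#' @param table Long-format cohort table with `ABETA` and `platform` columns.
#' @return The rows of `table` belonging to amyloid-positive patients.
#' @export
filter_amyloid_positive <- function(table) {
  base <- table[table$visit_time == 0, ]
  status <- classify_amyloid_status(base$ABETA, base$platform)
  keep <- base$patient_id[!is.na(status) & status]
  table[table$patient_id %in% keep, , drop = FALSE]
}

#' Drop features whose baseline missing rate reaches a threshold
#'
#' Missing rates are computed over baseline rows (visit_time == 0). A feature
#' is dropped when its missing fraction is greater than or equal to
#' `threshold`; column order is otherwise preserved and the dropped names and
#' rates are reported via `message()` and attached as an attribute.
#'
#' @param table Cohort table.
#' @param threshold Fraction in (0, 1].
#' @param features Feature columns to consider (default: all panel features
#'   present).
#' @return `table` without the dropped feature columns; attribute
#'   `"dropped_features"` holds a named numeric vector of their missing rates.
#' @export
filter_features_by_missing_rate <- function(table, threshold = 0.40,
                                            features = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  feats <- .table_features(table, features)
  base <- table[table$visit_time == 0, feats, drop = FALSE]
  rates <- vapply(base, function(x) mean(is.na(x)), numeric(1))
  drop <- names(rates)[rates >= threshold]
  if (length(drop) == length(feats)) {
    stop("all features exceed the missing-rate threshold")
  }
  if (length(drop)) {
    message("dropping features at missing rate >= ", threshold, ": ",
            paste(sprintf("%s (%.1f%%)", drop, 100 * rates[drop]),
                  collapse = ", "))
    table <- table[, setdiff(names(table), drop), drop = FALSE]
  }
  attr(table, "dropped_features") <- rates[drop]
  table
}

#' Adjust regional MRI volumes for age and intracranial volume
#'
#' For each of the six regional volumes, fits (on baseline training rows) or
#' applies an ordinary least-squares regression
#' `volume ~ intercept + age + ICV` and replaces the volume by its residual,
#' removing non-disease head-size and ageing variation. Coefficients are
#' estimated once on the training set and reused for test data; residuals are
#' formed at every visit. Rows missing age or ICV keep the volume missing.
#'
#' @param table Cohort table with `AGE` and `ICV` columns.
#' @param params Optional coefficients from a previous (training) call; if
#'   `NULL` they are fitted on this table's baseline rows.
#' @return List with `table` (volumes replaced by residuals) and `params`
#'   (named list of coefficient vectors `(intercept, age, icv)` per volume).
#' @export
adjust_mri_volumes <- function(table, params = NULL) {
  vols <- intersect(mri_volume_features(), names(table))
  if (!length(vols)) return(list(table = table, params = params))
  stopifnot(all(c("AGE", "ICV") %in% names(table)))
  fit <- is.null(params)
  if (fit) {
    base <- table[table$visit_time == 0, , drop = FALSE]
    params <- list()
    for (v in vols) {
      ok <- stats::complete.cases(base[, c(v, "AGE", "ICV")])
      if (sum(ok) < 3) stop("fewer than 3 complete baseline rows for ", v)
      if (stats::var(base$AGE[ok]) == 0 && stats::var(base$ICV[ok]) == 0) {
        stop("rank-deficient design: AGE and ICV constant for ", v)
      }
      cf <- stats::coef(stats::lm(base[[v]][ok] ~ base$AGE[ok] + base$ICV[ok]))
      params[[v]] <- stats::setNames(as.numeric(cf), c("intercept", "age", "icv"))
    }
  }
  for (v in vols) {
    cf <- params[[v]]
    pred <- cf["intercept"] + cf["age"] * table$AGE + cf["icv"] * table$ICV
    res <- table[[v]] - pred
    res[is.na(table$AGE) | is.na(table$ICV)] <- NA_real_
    table[[v]] <- res
  }
  list(table = table, params = params)
}

#' Fit z-score normalization on training data
#'
#' Per-feature location/scale estimated on the non-missing training values.
#' The scale convention is the population (divide-by-n) standard deviation by
#' default; the choice is recorded in the returned parameters.
#'
#' @param train Training cohort table.
#' @param features Feature columns (default: all panel features present).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return An object of class `norm_params`: list with `mean`, `sd` (named
#'   vectors), `features`, `sd_type`.
#' @export
zscore_fit <- function(train, features = NULL, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  feats <- .table_features(train, features)
  mu <- sdv <- stats::setNames(numeric(length(feats)), feats)
  for (f in feats) {
    x <- train[[f]][!is.na(train[[f]])]
    if (length(x) < 2) stop("feature ", f, " has fewer than 2 training values")
    mu[f] <- mean(x)
    v <- stats::var(x)
    if (sd_type == "population") v <- v * (length(x) - 1) / length(x)
    if (v == 0) stop("zero-variance feature: ", f)
    sdv[f] <- sqrt(v)
  }
  structure(list(mean = mu, sd = sdv, features = feats, sd_type = sd_type),
            class = "norm_params")
}

#' Apply stored z-score parameters to a cohort table
#'
#' @param table Cohort table.
#' @param params A `norm_params` object from [zscore_fit()].
#' @return `table` with the parameterized features standardized; missing
#'   entries stay missing.
#' @export
zscore_apply <- function(table, params) {
  stopifnot(inherits(params, "norm_params"))
  for (f in intersect(params$features, names(table))) {
    table[[f]] <- (table[[f]] - params$mean[f]) / params$sd[f]
  }
  table
}

#' Fit z-score parameters on training data and normalize both splits
#'
#' @param train,test Cohort tables; parameters come from `train` only.
#' @inheritParams zscore_fit
#' @return List with `train`, `test` (normalized) and `params`.
#' @export
zscore_fit_apply <- function(train, test, features = NULL,
                             sd_type = c("population", "sample")) {
  params <- zscore_fit(train, features, match.arg(sd_type))
  list(train = zscore_apply(train, params),
       test = zscore_apply(test, params),
       params = params)
}

#' Split a cohort into train/test halves at the patient level
#'
#' Patients (not rows) are randomly assigned so that the two sides have sizes
#' `ceiling(P/2)` and `floor(P/2)`; all visits of a patient land on the same
#' side. Deterministic given `seed`.
#'
#' @param table Cohort table.
#' @param seed Integer seed.
#' @return List with `train` and `test` tables.
#' @export
patient_level_split <- function(table, seed = 1L) {
  pts <- unique(table$patient_id)
  stopifnot(length(pts) >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(pts)
  n_train <- ceiling(length(pts) / 2)
  tr <- perm[seq_len(n_train)]
  list(train = table[table$patient_id %in% tr, , drop = FALSE],
       test = table[!(table$patient_id %in% tr), , drop = FALSE])
}

# save/restore global RNG state so helpers that seed internally do not
# disturb a caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
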