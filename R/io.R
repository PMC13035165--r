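# CSV / JSON round-tripping for cohort tables, scores, posterior draws and
# run configuration.

#' Read a long-format cohort CSV
#'
#' One row per patient-visit; mandatory columns `patient_id` and
#' `visit_time`; empty cells become missing values. Unknown columns are kept
#' but reported. Per-feature missing rates are reported via `message()`.
#'
#' @param path CSV file path.
#' @param alias Optional named character vector mapping file column names to
#'   panel feature names (`c(file_name = "panel_name")`).
#' @param quiet Suppress the log messages.
#' @return Cohort `data.frame`.
#' @export
read_cohort_csv <- function(path, alias = NULL, quiet = FALSE) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!is.null(alias)) {
    hit <- names(tab) %in% names(alias)
    names(tab)[hit] <- alias[names(tab)[hit]]
  }
  miss <- setdiff(c("patient_id", "visit_time"), names(tab))
  if (length(miss)) stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  feats <- .table_features(tab)
  for (f in c(feats, "visit_time", "ICV")) {
    if (!(f %in% names(tab))) next
    if (!is.numeric(tab[[f]])) {
      suppressWarnings(num <- as.numeric(tab[[f]]))
      bad <- which(!is.na(tab[[f]]) & is.na(num))
      if (length(bad)) stop("unparseable numeric in column ", f,
                            " at row ", bad[1])
      tab[[f]] <- num
    }
  }
  unknown <- setdiff(names(tab), c(.meta_cols(), feature_panel()$feature))
  if (!quiet) {
    if (length(unknown)) warning("ignoring unknown columns: ",
                                 paste(unknown, collapse = ", "))
    rates <- vapply(tab[feats], function(x) mean(is.na(x)), numeric(1))
    message(sprintf("read %d rows, %d patients; mean feature missing rate %.1f%%",
                    nrow(tab), length(unique(tab$patient_id)),
                    100 * mean(rates)))
  }
  tab
}

#' Write a cohort table to CSV
#'
#' Missing values are written as empty cells so the file round-trips through
#' [read_cohort_csv()].
#'
#' @param table Cohort table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write progression scores to CSV
#' @param scores Score `data.frame` from [progression_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read progression scores written by [write_scores_csv()]
#' @param path CSV path.
#' @return Score `data.frame`.
#' @export
read_scores_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

#' Export hierarchical posterior draws and summaries
#'
#' Writes the pooled draws of the population parameters as a columnar CSV and
#' a JSON summary (posterior mean, sd, split-R-hat and effective sample size
#' for every parameter).
#'
#' @param fit A `hier_fit`.
#' @param draws_path,summary_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the summary list.
#' @export
write_hier_fit <- function(fit, draws_path = NULL, summary_path = NULL) {
  stopifnot(inherits(fit, "hier_fit"))
  pars <- c("alpha", "beta", "sigma_alpha", "sigma_beta", "sigma", "rho")
  if (!is.null(draws_path)) {
    d <- as.data.frame(lapply(stats::setNames(pars, pars),
                              function(p) hier_draws(fit, p)))
    d$chain <- rep(seq_len(dim(fit$draws)[2]), each = dim(fit$draws)[1])
    utils::write.csv(d, draws_path, row.names = FALSE)
  }
  all_pars <- dimnames(fit$draws)[[3]]
  summ <- list(
    parameters = data.frame(
      parameter = all_pars,
      mean = apply(fit$draws, 3, mean),
      sd = apply(fit$draws, 3, stats::sd),
      rhat = as.numeric(fit$rhat[all_pars]),
      ess = as.numeric(fit$ess[all_pars])
    ),
    max_rhat = max(fit$rhat, na.rm = TRUE),
    chains = dim(fit$draws)[2],
    sampling = dim(fit$draws)[1],
    seed = fit$spec$seed
  )
  if (!is.null(summary_path)) {
    jsonlite::write_json(summ, summary_path, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  }
  invisible(summ)
}

# stable hash of a configuration list, for output provenance stamps
.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
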