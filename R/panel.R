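# Feature panel metadata: the 25-measure multimodal panel used throughout the
# package, its modality-block structure, severity directions, and the
# population-scale constants the synthetic generator uses.

#' The default 25-feature multimodal biomarker panel
#'
#' Returns the panel metadata used by the synthetic cohort generator, the
#' preprocessing pipeline and the evaluation layer: one row per feature with
#' its modality block, severity direction, raw-scale location/spread, latent
#' loading strength (for simulation), age/ICV structure for the six regional
#' brain volumes, and a default per-feature MCAR missingness rate.
#'
#' Modality blocks are `CSF` (ABETA, TAU, PTAU), `PET` (FDG, AV45), `MRI`
#' (six regional volumes), `cognitive` (eleven cognitive/functional scales)
#' and `demographic` (AGE, PTEDUCAT, APOE4). The severity `direction` is +1
#' when larger values indicate more advanced disease (e.g. CDRSB, TAU,
#' ventricular volume) and -1 when larger values indicate health (e.g.
#' hippocampal volume, ABETA, delayed recall).
#'
#' The `loading` column is the simulation signal strength on the standardized
#' scale: the per-unit-latent shift of the feature, in within-group standard
#' deviations. Demographic features carry zero loading by default, so a
#' well-behaved progression score should be uncorrelated with age in
#' synthetic cohorts.
#'
#' @return A `data.frame` with columns `feature`, `block`, `direction`,
#'   `mean`, `sd`, `loading`, `age_slope`, `icv_slope`, `mcar_rate`.
#' @export
#' @examples
#' panel <- feature_panel()
#' table(panel$block)
feature_panel <- function() {
  p <- data.frame(
    feature = c(
      "ABETA", "TAU", "PTAU",
      "FDG", "AV45",
      "Ventricles", "Hippocampus", "WholeBrain", "Entorhinal", "Fusiform", "MidTemp",
      "CDRSB", "ADAS13", "ADASQ4", "FAQ",
      "RAVLT_immediate", "RAVLT_learning", "RAVLT_forgetting", "RAVLT_perc_forgetting",
      "LDELTOTAL", "DIGITSCOR", "TRABSCOR",
      "AGE", "PTEDUCAT", "APOE4"
    ),
    block = c(
      rep("CSF", 3), rep("PET", 2), rep("MRI", 6),
      rep("cognitive", 11), rep("demographic", 3)
    ),
    direction = c(
      -1, 1, 1,
      -1, 1,
      1, -1, -1, -1, -1, -1,
      1, 1, 1, 1,
      -1, -1, 1, 1,
      -1, -1, 1,
      1, -1, 1
    ),
    mean = c(
      722, 311, 31,
      1.2, 1.3,
      42183, 6718, 1036920, 3515, 17685, 19630,
      1.6, 17.4, 5.8, 3.6,
      33.0, 4.0, 4.9, 64.2,
      5.5, 35.6, 122.7,
      73.4, 16.0, 0.78
    ),
    sd = c(
      240, 128, 14.1,
      0.1, 0.2,
      22500, 1000, 112000, 705, 2600, 2930,
      0.9, 6.5, 1.9, 3.8,
      9.0, 2.3, 2.3, 27,
      2.8, 10.8, 66,
      7.3, 2.7, 0.7
    ),
    loading = c(
      -0.32, 0.38, 0.38,
      -1.18, 0.39,
      0.23, -0.63, -0.16, -0.58, -0.39, -0.42,
      1.91, 1.30, 1.20, 1.32,
      -0.95, -0.70, 0.09, 0.75,
      -1.61, -0.70, 0.66,
      0, 0, 0
    ),
    age_slope = c(
      0, 0, 0, 0, 0,
      800, -25, -3000, -12, -40, -45,
      rep(0, 11), rep(0, 3)
    ),
    icv_slope = c(
      0, 0, 0, 0, 0,
      0.02, 0.004, 0.6, 0.002, 0.01, 0.012,
      rep(0, 11), rep(0, 3)
    ),
    mcar_rate = c(
      0.094, 0.094, 0.094,
      0.076, 0.345,
      rep(0.08, 6),
      0.02, 0.02, 0.02, 0.02,
      0.02, 0.02, 0.02, 0.02,
      0.035, 0.389, 0.02,
      0, 0, 0.02
    ),
    stringsAsFactors = FALSE
  )
  p
}

#' Names of the five modality blocks
#' @return Character vector of block labels.
#' @export
modality_blocks <- function() c("CSF", "PET", "MRI", "cognitive", "demographic")

#' Feature-subset presets
#'
#' `"full"` is the complete 25-feature panel; `"non_cognitive"` is the
#' 14-feature biological/demographic subset (CSF, PET, MRI volumes and
#' demographics, no cognitive or functional scales) used to show that the
#' progression score tracks cognition without being built from it.
#'
#' @param preset `"full"` or `"non_cognitive"`.
#' @return Character vector of feature names.
#' @export
feature_preset <- function(preset = c("full", "non_cognitive")) {
  preset <- match.arg(preset)
  p <- feature_panel()
  if (preset == "full") p$feature else p$feature[p$block != "cognitive"]
}

#' The six regional MRI volume features
#' @return Character vector.
#' @export
mri_volume_features <- function() {
  p <- feature_panel()
  p$feature[p$block == "MRI"]
}

# columns of a cohort table that are metadata, not features
.meta_cols <- function() c("patient_id", "visit_time", "diagnosis", "ICV", "platform")

# resolve the feature columns present in a cohort table, in panel order
.table_features <- function(table, features = NULL) {
  panel <- feature_panel()
  cand <- if (is.null(features)) panel$feature else features
  cand[cand %in% names(table)]
}
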