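# Patient profiles and their design-matrix encoding.
#
# Reference levels: sex = male, CAD subtype = stable_angina, smoking = never.
# Continuous biomarkers enter linearly, centred at round population values so
# intercepts stay interpretable and the optimiser well conditioned.
# Deprivation enters as the quintile score 1..5 (a common IMD convention).

CAD_SUBTYPES <- c("stable_angina", "unstable_angina", "stemi", "nstemi", "other_chd")
SMOKING_LEVELS <- c("never", "ex", "current")
BINARY_COVARIATES <- c(
  "pci_6m", "cabg_6m", "previous_mi", "nitrates", "hypertension", "diabetes",
  "heart_failure", "pad", "af", "prior_stroke", "ckd", "copd", "cancer",
  "liver_disease", "depression", "anxiety"
)
MODEL_STATES <- c("stable", "post_mi", "post_is", "post_hs",
                  "cvd_death", "noncvd_death")
PRIMARY_ENDPOINTS <- c("mi", "ischaemic_stroke", "haemorrhagic_stroke",
                       "cvd_death", "noncvd_death")
NONFATAL_EVENTS <- c("mi", "ischaemic_stroke", "haemorrhagic_stroke")

# Centring constants for continuous covariates.
.CENTRES <- c(age10 = 6.5, total_chol = 4.8, hdl = 1.37, heart_rate10 = 7.2,
              creatinine100 = 1.0, wcc = 7.5, haemoglobin = 1.36)

#' Design matrix for the primary risk equations
#'
#' Encodes a table of patient profiles as the numeric design matrix used by
#' the five primary survival equations and the cost model. Categorical
#' variables are one-hot against their reference level; fractional indicator
#' values are allowed, so a risk-group mean covariate vector is encoded the
#' same way as an individual patient.
#'
#' @param cohort Data frame of patient profiles (see
#'   \code{\link{generate_cohort}} for the schema).
#' @return Numeric matrix, one row per profile, with an intercept column.
#' @export
profile_model_matrix <- function(cohort) {
  n <- nrow(cohort)
  sub <- subtype_indicators(cohort$cad_subtype)
  smk <- smoking_indicators(cohort$smoking)
  X <- cbind(
    intercept = rep(1, n),
    age10 = cohort$age_entry / 10 - .CENTRES[["age10"]],
    female = sex_indicator(cohort$sex),
    deprivation = as.numeric(cohort$deprived_quintile) - 3,
    sub,
    as.matrix(cohort[BINARY_COVARIATES]),
    smk,
    total_chol = cohort$total_chol - .CENTRES[["total_chol"]],
    hdl = cohort$hdl - .CENTRES[["hdl"]],
    heart_rate10 = cohort$heart_rate / 10 - .CENTRES[["heart_rate10"]],
    creatinine100 = cohort$creatinine / 100 - .CENTRES[["creatinine100"]],
    wcc = cohort$wcc - .CENTRES[["wcc"]],
    haemoglobin = cohort$haemoglobin - .CENTRES[["haemoglobin"]]
  )
  storage.mode(X) <- "double"
  X
}

# Sex/subtype/smoking may arrive as factors/characters (individual patients)
# or as numeric proportions (group-mean profiles).
sex_indicator <- function(sex) {
  if (is.numeric(sex)) return(sex)
  as.numeric(sex == "female")
}

subtype_indicators <- function(subtype) {
  if (is.data.frame(subtype) || is.matrix(subtype)) return(as.matrix(subtype))
  out <- vapply(CAD_SUBTYPES[-1], function(lv) as.numeric(subtype == lv),
                numeric(length(subtype)))
  matrix(out, nrow = length(subtype),
         dimnames = list(NULL, paste0("subtype_", CAD_SUBTYPES[-1])))
}

smoking_indicators <- function(smoking) {
  if (is.data.frame(smoking) || is.matrix(smoking)) return(as.matrix(smoking))
  out <- vapply(SMOKING_LEVELS[-1], function(lv) as.numeric(smoking == lv),
                numeric(length(smoking)))
  matrix(out, nrow = length(smoking),
         dimnames = list(NULL, paste0("smoking_", SMOKING_LEVELS[-1])))
}

# Column names of the primary design matrix, in order.
primary_design_names <- function() {
  c("intercept", "age10", "female", "deprivation",
    paste0("subtype_", CAD_SUBTYPES[-1]),
    BINARY_COVARIATES,
    paste0("smoking_", SMOKING_LEVELS[-1]),
    "total_chol", "hdl", "heart_rate10", "creatinine100", "wcc", "haemoglobin")
}

# Design row(s) for the post-event equations: intercept, female indicator and
# age at the non-fatal event (decades, centred at 70).
post_event_design <- function(female, age_at_event) {
  cbind(intercept = rep(1, length(age_at_event)),
        female = rep_len(sex_indicator(female), length(age_at_event)),
        age_event10 = age_at_event / 10 - 7)
}

#' Group-mean patient profile
#'
#' Column means of the member design-matrix rows; categorical covariates
#' become level proportions, matching how published baseline tables report
#' risk-group characteristics.
#'
#' @param cohort Profile table.
#' @param ids Optional patient ids selecting the group (default: all rows).
#' @return A one-row design matrix (class matrix) usable wherever a profile
#'   design row is accepted.
#' @export
mean_covariate_row <- function(cohort, ids = NULL) {
  X <- profile_model_matrix(cohort)
  if (!is.null(ids)) X <- X[match(ids, cohort$patient_id), , drop = FALSE]
  matrix(colMeans(X), nrow = 1, dimnames = list(NULL, colnames(X)))
}
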