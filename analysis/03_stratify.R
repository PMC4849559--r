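#!/usr/bin/env Rscript
# Stage 3 — stratify the cohort into tenths of baseline 5-year CVD risk.
#
# Scores every patient with the fitted equations, forms ten equal risk
# groups, and writes a baseline-characteristics table (group means, risk at
# the mean covariate vector, representative-patient ids) under results/.

library(stablecad)

cohort <- read.csv("results/cohort.csv", stringsAsFactors = FALSE)
fits <- readRDS("results/fits.rds")
set <- fits$set

risk <- cohort_composite_risk(set, cohort)
groups <- assign_risk_groups(cohort, set, 10, risk = risk)

tab <- do.call(rbind, lapply(groups, function(g) {
  rp <- representative_patient(g, cohort)
  data.frame(group = g$index,
             n = length(g$member_ids),
             mean_risk_pct = 100 * g$mean_risk,
             risk_at_mean_pct = 100 * g$risk_at_mean,
             mean_age = g$mean_age,
             pct_female = 100 * g$mean_female,
             pct_heart_failure = 100 * mean(g$mean_covariates[, "heart_failure"]),
             pct_hypertension = 100 * mean(g$mean_covariates[, "hypertension"]),
             representative_id = rp$patient_id)
}))
write.csv(tab, "results/risk_groups.csv", row.names = FALSE)
saveRDS(groups, "results/groups.rds")

message(sprintf("cohort mean 5-year risk %.2f%%; risk at the mean covariate vector %.2f%%",
                100 * mean(risk),
                100 * predict_5yr_composite_risk(
                  set, mean_covariate_row(cohort),
                  mean(cohort$sex == "female"), mean(cohort$age_entry))))
message("risk by tenth (%):")
message(paste(sprintf("%.1f", tab$mean_risk_pct), collapse = "  "))
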