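#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic stable-CAD cohort.
#
# Generates n patients with the marginal covariate structure of a large
# linked-EHR stable-CAD registry, draws their competing-risk event histories
# from the known ground-truth hazards, and builds the 90-day cost panel.
# Writes cohort.csv, histories.csv, cost_panel.csv under results/.

library(stablecad)

seed <- 20260918L
n <- 20000L
dir.create("results", showWarnings = FALSE)

truth <- default_true_parameters()
cohort <- generate_cohort(n, seed)
histories <- simulate_event_histories(cohort, truth, seed + 1L)
panel <- simulate_cost_panel(cohort, histories, truth, seed + 2L)

write.csv(cohort, "results/cohort.csv", row.names = FALSE)
write.csv(histories, "results/histories.csv", row.names = FALSE)
write.csv(panel, "results/cost_panel.csv", row.names = FALSE)

message(sprintf("simulated %d patients; %.1f%% died, %.1f%% had a non-fatal CVD event, %.1f%% censored",
                n,
                100 * mean(histories$first_event %in% c("cvd_death", "noncvd_death")),
                100 * mean(histories$first_event %in% c("mi", "ischaemic_stroke", "haemorrhagic_stroke")),
                100 * mean(histories$first_event == "censored")))
message(sprintf("cost panel: %d rows (%.1f cycles per patient on average)",
                nrow(panel), nrow(panel) / n))
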