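#!/usr/bin/env Rscript
# Survival analysis: Kaplan-Meier medians with CIs, %ILS against the
# untreated arm, pairwise log-rank tests, and a 200-replicate check that
# the simulated design reproduces the BNCT-vs-untreated significance
# pattern.

suppressPackageStartupMessages(library(bnctquant))

surv <- read.csv("results/inputs/survival_events.csv")
tab <- survival_report(surv, reference = "Untreated")
write.csv(tab, "results/survival_report.csv", row.names = FALSE)
cat("Arm-level survival report:\n")
disp <- tab
disp[c("mst", "mst_lo", "mst_hi")] <-
  lapply(disp[c("mst", "mst_lo", "mst_hi")], round, 1)
disp$p_vs_reference <- signif(disp$p_vs_reference, 3)
print(disp, row.names = FALSE)

power <- logrank_power_experiment(study_config(), n_rep = 200, seed = 42)
cat("\nFraction of 200 simulated experiments with p < 0.05 vs Untreated:\n")
print(round(power, 3))
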