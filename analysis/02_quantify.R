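#!/usr/bin/env Rscript
# Step 2 — quantify the full default study under the published yellow box
# and its +/-5% perturbations.
#
# The default study (486 fish, 972 images at 256x256) is simulated and
# quantified streaming; per-image records and the treatment summary are
# written under results/run/.

library(yellowpix)

dir.create("results/run", recursive = TRUE, showWarnings = FALSE)

base <- yellow_reference_range()
ranges <- list(base = base,
               expand = perturb_range(base, 5, "expand"),
               shrink = perturb_range(base, 5, "shrink"))
print(base)

t0 <- Sys.time()
sim <- simulate_study(ranges = ranges, seed = 1)
cat("Simulated + quantified", nrow(sim$truth), "images in",
    round(as.numeric(Sys.time() - t0, units = "secs")), "s\n")

write.csv(sim$records, "results/run/records.csv", row.names = FALSE)
write.csv(sim$fish, "results/run/fish.csv", row.names = FALSE)
write.csv(sim$truth, "results/run/ground_truth.csv", row.names = FALSE)

features <- fish_feature_table(sim$records[sim$records$range_id == "base", ])
summary_tab <- treatment_summary(features, sim$fish)
write.csv(summary_tab, "results/run/summary.csv", row.names = FALSE)
cat("\nTreatment summary (percent yellow of foreground, mean over fish):\n")
print(summary_tab[, c("treatment", "N", "frontal_pct_mean", "frontal_sdd_mean",
                      "lateral_pct_mean", "lateral_sdd_mean")], digits = 3)

sens <- sensitivity_report(sim$records)
write.csv(sens$rankings, "results/run/sensitivity.csv", row.names = FALSE)
cat("\nTreatment ranking by mean yellow fraction, per colour box:\n")
print(sens$rankings)
cat("\nRanking unchanged under +/-5% perturbation:", sens$unchanged, "\n")
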