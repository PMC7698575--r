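#!/usr/bin/env Rscript
# Step 3 — inferential statistics on the quantified study.
#
# Two-way crossed ANOSIM (treatment x replicate tank) on Manhattan
# distances over the per-fish (frontal, lateral) yellow fractions;
# Bonferroni-corrected pairwise ANOSIM; Mantel test (Spearman, 9999
# permutations) against dietary carotenoid distances; one-way ANOVA with
# Tukey letters on total length and weight.

library(yellowpix)

records <- read.csv("results/run/records.csv", stringsAsFactors = FALSE)
fish <- read.csv("results/run/fish.csv", stringsAsFactors = FALSE)

features <- fish_feature_table(records[records$range_id == "base", ])
st <- pigmentation_stats(features, n_perm_anosim = 999,
                         n_perm_mantel = 9999, seed = 1, pairwise = TRUE)

cat("Two-way crossed ANOSIM on (frontal, lateral) yellow fractions:\n")
print(st$anosim)
cat("\nMantel test, pigmentation distances vs dietary carotenoid:\n")
print(st$mantel)

write.csv(st$pairwise, "results/run/anosim_pairwise.csv", row.names = FALSE)
cat("\nPairwise ANOSIM (first rows, Bonferroni over",
    nrow(st$pairwise), "pairs):\n")
print(head(st$pairwise))

tl <- anova_tukey(fish$TL, fish$treatment)
w <- anova_tukey(fish$W, fish$treatment)
cat("\nTotal length:\n"); print(tl)
cat("\nWeight:\n"); print(w)

out <- list(
  anosim_treatment = list(R = st$anosim$a$R, p = st$anosim$a$p),
  anosim_replicate = list(R = st$anosim$b$R, p = st$anosim$b$p),
  mantel = list(r = st$mantel$r, p = st$mantel$p,
                n_perm = st$mantel$n_perm),
  anova = list(TL = list(F = tl$F, p = tl$p), W = list(F = w$F, p = w$p)),
  settings = st$settings)
jsonlite::write_json(out, "results/run/stats.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("\nWrote results/run/stats.json\n")
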