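#!/usr/bin/env Rscript
# Step 2 — clean and normalize the instance feature tables.
#
# Mirrors the standard descriptor-preprocessing chain: drop features that
# are zero for every ligand, drop near-constant features (dominant value
# in >= 99% of instances), then min-max normalize each survivor into
# [0, 1]. Fingerprints stay binary and are only format-checked.

library(dockselect)

md <- read_feature_csv("results/benchmark/descriptors.csv", kind = "md")
sf <- read_feature_csv("results/benchmark/fingerprints.csv", kind = "sf")

cat("raw descriptor features:", ncol(md), "\n")
step1 <- drop_zero_features(md)
cat("after zero-column removal:", ncol(step1), "\n")
step2 <- drop_near_constant(step1, dominance = 0.99)
cat("after near-constant removal:", ncol(step2), "usable features\n")
if (length(attr(step2, "dropped")))
  cat("dropped:", paste(attr(step2, "dropped"), collapse = ", "), "\n")

norm <- apply_minmax(step2, fit_minmax(step2))
stopifnot(min(unclass(norm)) >= 0, max(unclass(norm)) <= 1)
cat("normalized range: [", min(unclass(norm)), ",", max(unclass(norm)), "]\n")
cat("fingerprint bits:", ncol(sf), "(binary:",
    all(unclass(sf) %in% c(0, 1)), ")\n")

write_feature_csv(norm, "results/benchmark/descriptors_normalized.csv")
cat("written to results/benchmark/descriptors_normalized.csv\n")
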