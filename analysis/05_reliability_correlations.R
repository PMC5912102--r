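#!/usr/bin/env Rscript
# Step 5: context-split prediction reliability and feature-trait
# correlations.
#
# Reliability: for each repetition of the extraversion classifier, the
# stored window-level test predictions are re-voted within context subsets
# (split halves, way I vs way II, shop vs way) and the resulting prediction
# pairs are correlated (ordinal coding, Fisher-averaged across
# repetitions). Correlations: per-participant mean 15 s window features
# against raw trait scores.

suppressPackageStartupMessages(library(gazetraits))

state <- readRDS("results/cache/cohort.rds")
featsets <- readRDS("results/cache/featsets.rds")
sets <- readRDS("results/cache/prediction_sets.rds")

recs <- state$cohort$recordings
durations <- stats::setNames(
  vapply(recs, function(r) r$duration, numeric(1)),
  vapply(recs, function(r) r$participant_id, character(1)))

rel <- reliability_table(sets, durations)
utils::write.csv(rel, "results/reliability.csv", row.names = FALSE)
cat("Context-split reliability (extraversion, Fisher-averaged r):\n")
print(rel, row.names = FALSE)

corr <- feature_trait_correlations(featsets[["15"]], state$cohort$traits)
corr_df <- data.frame(feature = rownames(corr$r), corr$r,
                      flagged = corr$flagged, row.names = NULL)
utils::write.csv(corr_df, "results/feature_trait_correlations.csv",
                 row.names = FALSE)
top <- order(-abs(corr$r[, "extraversion"]))[1:5]
cat("\nStrongest feature correlations with extraversion:\n")
print(data.frame(feature = rownames(corr$r)[top],
                 r = round(corr$r[top, "extraversion"], 3)),
      row.names = FALSE)
cat("Wrote results/reliability.csv, results/feature_trait_correlations.csv.\n")
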