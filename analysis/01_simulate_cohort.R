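#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# 42 participants with Gaussian trait scores; extraversion is wired to four
# oculomotor parameters (fixation duration, saccade amplitude, blink rate,
# pupil baseline) at about one parameter-SD per trait SD, so downstream
# stages have a known signal to recover. Recordings are 150 s at 60 Hz with
# 20% track loss and way1/shop/way2 context segments -- the same regime as
# a ~12.5-minute everyday recording, shortened to keep this workflow quick.
# Rerun with `--duration 750` for full-length recordings.

suppressPackageStartupMessages(library(gazetraits))

args <- commandArgs(trailingOnly = TRUE)
duration <- if ("--duration" %in% args) {
  as.numeric(args[which(args == "--duration") + 1])
} else 150
seed <- 2024

dir.create("results/cache", showWarnings = FALSE, recursive = TRUE)

cat(sprintf("Simulating 42 participants, %g s at 60 Hz, seed %d ...\n",
            duration, seed))
cohort <- generate_cohort(42, strong_effects("extraversion"), seed = seed,
                          duration = duration)

screened <- screen_participants(cohort$recordings)
cat(sprintf("Screening: %d/%d retained (erroneous>0.5: %d, constant-gaze: %d)\n",
            length(screened$retained), nrow(screened$reports),
            sum(screened$reports$reason == "erroneous>0.5"),
            sum(screened$reports$reason == "constant-gaze")))
utils::write.csv(screened$reports, "results/screening_report.csv",
                 row.names = FALSE)
write_trait_scores(cohort$traits, "results/traits.csv")

bins <- bin_traits(cohort$traits)
write_bins(bins, "results/trait_bins.csv", "results/trait_boundaries.csv")
cat("Tertile boundaries (extraversion): ",
    sprintf("%.3f / %.3f\n", bins$extraversion$b_low,
            bins$extraversion$b_high))

cohort$recordings <- screened$retained
saveRDS(list(cohort = cohort, bins = bins, seed = seed),
        "results/cache/cohort.rds")
cat("Wrote results/screening_report.csv, results/traits.csv,",
    "results/trait_bins.csv; cohort cached for the next steps.\n")
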