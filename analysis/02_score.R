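#!/usr/bin/env Rscript
# Stage 2: score trial tables into indicators and apply exclusions.
#
# Signal-detection metrics (d', ln beta, RT variability) from the CPT;
# risky-choice probability, RTs, and cumulative winnings from the WOF
# (anticipatory trials < 200 ms discarded); valence-block accuracy/RT from
# the EFR; indifference points and trapezoidal AUC from the discounting
# choices. Participants with Lie-scale > 6 are excluded wholesale, and the
# retained person-waves are z-standardized into the indicator matrix.

source("analysis/00_config.R")

bundle <- load_bundle(trials = TRUE)
summaries <- score_cohort_bundle(bundle)
excl <- apply_exclusions(bundle$cohort)
indicators <- build_indicator_matrix(summaries, excl$cohort)

write.table(excl$log, file.path(RESULTS_DIR, "exclusions.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
out <- data.frame(indicators$info, indicators$data, check.names = FALSE)
write.csv(out, file.path(RESULTS_DIR, "indicators.csv"), row.names = FALSE)

cat(sprintf("excluded %d participants (Lie > 6); retained %d person-waves\n",
            nrow(excl$log), nrow(indicators$data)))
cat(sprintf("indicator matrix: %d columns, %d masked entries (%.1f%%)\n",
            ncol(indicators$data), sum(indicators$mask),
            100 * mean(indicators$mask)))
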