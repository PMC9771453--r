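#!/usr/bin/env Rscript
# Stage 5: covariate associations and recovery check against ground truth.
#
# Correlates the CMI with anthropometric, questionnaire, and risk covariates
# (repeated-measures caveat: p-values unadjusted), and -- because this cohort
# is simulated -- compares participant-mean CMI with the planted maturity
# offsets from the generator's ground-truth sidecar.

source("analysis/00_config.R")

im <- read_indicators()
cmi_tab <- read.csv(file.path(RESULTS_DIR, "cmi.csv"))
cmi <- compute_cmi(cmi_tab$predicted_age, cmi_tab$observed_age,
                   participant = cmi_tab$participant, wave = cmi_tab$wave)

cov_cols <- c("bmi", "pds", "bas_d", "bas_fs", "bas_rr", "iq", "ses",
              "bis_scale", "dusi_substance", "dusi_health", "dusi_violence")
correlations <- correlate_cmi(cmi, im$info[, cov_cols])
write.table(correlations, file.path(RESULTS_DIR, "cmi_correlations.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("CMI covariate correlations (person-waves, unadjusted):\n")
print(correlations, row.names = FALSE, digits = 3)

# ground truth regenerates deterministically from the master seed (the
# latent stage does not consume the trial-synthesis random stream)
truth <- load_bundle(trials = FALSE)$truth
pd <- tapply(truth$maturity_offset, truth$participant, mean)
pc <- tapply(cmi$cmi, cmi$participant, function(v) mean(v, na.rm = TRUE))
common <- intersect(names(pd), names(pc))
r <- cor(pd[common], pc[common], use = "complete.obs")
cat(sprintf(
  "\nrecovery: corr(planted maturity offset, participant-mean CMI) = %.3f over %d participants\n",
  r, length(common)))
jsonlite::write_json(list(offset_cmi_correlation = r, n = length(common)),
                     file.path(RESULTS_DIR, "recovery.json"),
                     auto_unbox = TRUE, digits = NA)
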