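#!/usr/bin/env Rscript
# Stage 1: simulate the longitudinal cohort.
#
# Generates a three-wave cohort of 141 adolescents (enrolled at ages
# 11.1-14.0, visits ~1.6 y apart) with trial-level task sessions for the
# continuous-performance, wheel-of-fortune, emotional face recognition, and
# delay-discounting tasks, calibrated to a known latent growth model. The
# observable tables and the ground-truth sidecar are written separately.

source("analysis/00_config.R")

bundle <- load_bundle(trials = TRUE)
# trial tables are bulky (4 sessions x ~400 person-waves): park them under
# scratch/; keep the person-wave table and data dictionary with the results
files <- write_cohort_bundle(bundle, file.path("scratch", "cohort"))
file.copy(file.path("scratch", "cohort", c("cohort.csv", "data_dictionary.csv")),
          RESULTS_DIR, overwrite = TRUE)

n_pw <- nrow(bundle$cohort)
n_sessions <- sum(vapply(bundle$trials, function(p) {
  sum(vapply(p, function(w) sum(!vapply(w, is.null, logical(1))), integer(1)))
}, integer(1)))
cat(sprintf("simulated %d participants, %d person-waves, %d task sessions\n",
            length(unique(bundle$cohort$participant)), n_pw, n_sessions))
cat(sprintf("wrote %d files under scratch/cohort\n", length(files)))
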