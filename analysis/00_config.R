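# Shared settings for the analysis drivers. Every stage derives its
# randomness from MASTER_SEED, so the whole workflow is reproducible by
# running the scripts in order from the repository root:
#   Rscript analysis/01_simulate.R && Rscript analysis/02_score.R && ...

library(cogmaturity)

MASTER_SEED <- 20260920L
RESULTS_DIR <- "results"
COHORT_CONFIG <- cohort_config(n_participants = 141, n_waves = 3,
                               seed = MASTER_SEED)
GROWTH <- growth_spec()   # reference growth model: slopes per year of age

dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# regenerate the simulated cohort deterministically for any stage that needs
# the in-memory bundle (trial tables are large; only summaries persist)
load_bundle <- function(trials = TRUE) {
  generate_cohort(COHORT_CONFIG, GROWTH, trials = trials)
}

read_indicators <- function() {
  tab <- utils::read.csv(file.path(RESULTS_DIR, "indicators.csv"),
                         check.names = FALSE)
  info_cols <- c("participant", "wave", "age", "sex", "bmi", "pds", "iq",
                 "ses", "bas_d", "bas_fs", "bas_rr", "bis_scale",
                 "dusi_substance", "dusi_health", "dusi_violence")
  ind_cols <- setdiff(names(tab), info_cols)
  list(data = as.matrix(tab[, ind_cols]), info = tab[, info_cols])
}
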