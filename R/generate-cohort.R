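# Cohort-level simulation: demographics, ground-truth latent growth, indicator
# targets on the standardized latent scale, and calibrated trial-level task
# sessions.

# Natural-unit calibration maps from standardized indicator targets x to task
# parameters. Slopes are wide enough that trial-level sampling noise stays
# well below one latent-scale SD for the high-count metrics.
indicator_natural_maps <- function() {
  list(
    cpt_dprime = function(x) clip(2.2 + 0.8 * x, 0.3, 4.3),
    cpt_lnbeta = function(x) clip(0.55 * x, -2.5, 2.5),
    cpt_hit_rt_sd = function(x) clip(110 + 35 * x, 40, 260),
    cpt_fa_rt_sd = function(x) clip(140 + 40 * x, 40, 300),
    bis = function(x) round(clip(20.3 + 3.5 * x, 7, 28)),
    wof_p_highrisk = function(x) clip(stats::plogis(stats::qlogis(0.35) + 0.7 * x), 0.02, 0.95),
    wof_rt_high = function(x) clip(1100 + 150 * x, 400, 2600),
    wof_rt_low = function(x) clip(1300 + 150 * x, 400, 2800),
    td_auc = function(x) clip(stats::plogis(stats::qlogis(0.55) + 0.8 * x), 0.02, 1),
    efr_neg_acc = function(x) clip(0.80 + 0.08 * x, 0.05, 1),
    efr_neg_rt_mean = function(x) clip(1900 + 250 * x, 600, 4500),
    efr_neg_rt_sd = function(x) clip(450 + 120 * x, 100, 900),
    efr_pos_acc = function(x) clip(0.88 + 0.06 * x, 0.05, 1),
    efr_pos_rt_mean = function(x) clip(1500 + 250 * x, 600, 4500),
    efr_pos_rt_sd = function(x) clip(400 + 120 * x, 100, 900)
  )
}

# Draw demographics and questionnaire scores for every person-wave.
# delta_z is the person's maturity offset in offset-SD units; several
# covariates are coupled to it so that downstream CMI-covariate correlations
# have recoverable signs.
simulate_demographics <- function(config, delta, delta_z) {
  n <- config$n_participants
  waves <- config$n_waves
  pid <- sprintf("P%03d", seq_len(n))
  sex <- ifelse(stats::runif(n) < 0.536, "female", "male")
  age1 <- stats::runif(n, config$wave1_age_range[1], config$wave1_age_range[2])
  gaps <- matrix(pmax(stats::rnorm(n * max(waves - 1, 1),
                                   config$inter_wave_gap_mean_sd[1],
                                   config$inter_wave_gap_mean_sd[2]), 0.5),
                 nrow = n)
  income <- stats::rlnorm(n, log(9e4), 0.6)
  educ1 <- clip(stats::rnorm(n, 16, 2.5), 8, 22)
  educ2 <- clip(stats::rnorm(n, 16, 2.5), 8, 22)
  iq <- round(clip(110 + 14 * (0.3 * delta_z + stats::rnorm(n, 0, sqrt(1 - 0.09))),
                   70, 145))
  lie_flag <- stats::runif(n) < config$lie_gt6_rate
  dusi_lie <- ifelse(lie_flag, sample(7:10, n, replace = TRUE),
                     pmin(stats::rpois(n, 2.2), 6))
  rows <- vector("list", n * waves)
  k <- 0L
  for (i in seq_len(n)) {
    age <- age1[i]
    for (w in seq_len(waves)) {
      if (w > 1) age <- age + gaps[i, w - 1]
      k <- k + 1L
      bmi <- clip(21 + 1.0 * (w - 1) + stats::rnorm(1, 0, 4.2) -
                    1.5 * delta_z[i], 14, 48)
      pds <- clip(1 + 0.45 * (age - 11) + 0.3 * (sex[i] == "female") +
                    stats::rnorm(1, 0, 0.3) - 0.15 * delta_z[i], 1, 4)
      rows[[k]] <- data.frame(
        participant = pid[i], wave = w, age = age, sex = sex[i],
        bmi = bmi, pds = pds,
        income = income[i], educ_years_parent1 = educ1[i],
        educ_years_parent2 = educ2[i],
        iq = iq[i],
        bas_d = round(clip(10.2 + 0.2 * (w - 1) +
                             stats::rnorm(1, 0, 2.3) - 0.8 * delta_z[i], 4, 16)),
        bas_fs = round(clip(stats::rnorm(1, 11.3, 2.3), 4, 16)),
        bas_rr = round(clip(stats::rnorm(1, 17.6, 1.8), 5, 20)),
        dusi_lie = dusi_lie[i],
        dusi_substance = round(clip(1.2 + 0.7 * (w - 1) +
                                      stats::rnorm(1, 0, 1.8) - 0.9 * delta_z[i], 0, 11)),
        dusi_health = round(clip(2.5 + stats::rnorm(1, 0, 2.0) -
                                   0.7 * delta_z[i], 0, 11)),
        dusi_violence = round(clip(2.8 + stats::rnorm(1, 0, 2.0) -
                                     1.1 * delta_z[i], 0, 11)),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Latent factor values per person-wave from the growth model. Structural paths
# from inhibitory control act on its non-age component so that the marginal
# age slope of each factor stays at its configured value.
simulate_latents <- function(cohort, growth, delta) {
  fac <- names(default_factor_indicators())
  pid <- unique(cohort$participant)
  u <- sapply(growth$random_intercept_sd, function(s) {
    stats::rnorm(length(pid), 0, s)
  })
  rownames(u) <- pid
  cog_age <- cohort$age + delta[cohort$participant]
  agec <- cog_age - 13.5
  covz <- list(
    ses = zscore_col(compute_ses(cohort$income, cohort$educ_years_parent1,
                                 cohort$educ_years_parent2)),
    pds = zscore_col(cohort$pds), bmi = zscore_col(cohort$bmi),
    sex = as.numeric(cohort$sex == "female")
  )
  eta <- matrix(0, nrow(cohort), length(fac), dimnames = list(NULL, fac))
  nonage <- matrix(0, nrow(cohort), length(fac), dimnames = list(NULL, fac))
  for (f in fac) {
    nonage[, f] <- u[cohort$participant, f]
    for (ce in growth$covariate_effects) {
      if (ce$factor == f) nonage[, f] <- nonage[, f] + ce$beta * covz[[ce$covariate]]
    }
    eta[, f] <- growth$intercepts[f] + growth$age_slopes[f] * agec + nonage[, f]
  }
  for (f in names(growth$paths)) {
    eta[, f] <- eta[, f] + growth$paths[f] * nonage[, "ICLF"]
  }
  eta
}

# Indicator targets x = loading * factor + correlated residual.
simulate_indicator_targets <- function(eta, growth) {
  ind_map <- default_factor_indicators()
  ind <- unlist(ind_map, use.names = FALSE)
  n <- nrow(eta)
  Theta <- diag(growth$residual_sd[ind]^2)
  dimnames(Theta) <- list(ind, ind)
  for (rc in growth$residual_cor) {
    i <- rc$pair[1]; j <- rc$pair[2]
    Theta[i, j] <- Theta[j, i] <- rc$r * growth$residual_sd[i] * growth$residual_sd[j]
  }
  L <- chol(Theta)
  eps <- matrix(stats::rnorm(n * length(ind)), n) %*% L
  colnames(eps) <- ind
  if (growth$wave_cor > 0) {
    stop("wave_cor > 0 is reserved; residual inter-wave correlation beyond ",
         "the random intercept is not yet implemented")
  }
  x <- eps
  for (f in names(ind_map)) {
    for (j in ind_map[[f]]) x[, j] <- growth$loadings[j] * eta[, f] + eps[, j]
  }
  x
}

#' Generate a synthetic longitudinal cohort with task sessions
#'
#' Produces a full cohort bundle: a long-format cohort table (one row per
#' person-wave, demographics and questionnaires only), per-person-wave
#' trial-level task sessions calibrated to standardized indicator targets
#' drawn from the latent growth model, and a ground-truth sidecar (latent
#' factor values, maturity offsets, and indicator targets) kept separate from
#' the observable tables.
#'
#' @param config a [cohort_config()].
#' @param growth a [growth_spec()].
#' @param trials if `FALSE`, skip trial-level synthesis and instead return the
#'   noiseless indicator targets as observed indicators (fast path for
#'   large-scale recovery simulations).
#' @return list with elements `cohort` (data.frame), `trials` (nested list
#'   `trials[[participant]][[wave]]` of cpt/wof/efr/td tables, `NULL` when a
#'   session is missing), `truth` (data.frame sidecar), `indicator_targets`
#'   (data.frame of standardized targets, only when `trials = FALSE`), and
#'   `config`/`growth`.
#' @export
generate_cohort <- function(config, growth = growth_spec(), trials = TRUE) {
  stopifnot(inherits(config, "cohort_config"), inherits(growth, "growth_spec"))
  set.seed(substream_seed(config$seed, "demographics"))
  delta <- stats::setNames(
    stats::rnorm(config$n_participants, 0, growth$maturity_offset_sd),
    sprintf("P%03d", seq_len(config$n_participants)))
  delta_z <- if (growth$maturity_offset_sd > 0) {
    delta / growth$maturity_offset_sd
  } else delta
  cohort <- simulate_demographics(config, delta, delta_z)

  set.seed(substream_seed(config$seed, "dropout"))
  keep <- rep(TRUE, nrow(cohort))
  for (p in unique(cohort$participant)) {
    idx <- which(cohort$participant == p)
    gone <- FALSE
    for (w in seq_along(idx)[-1]) {
      if (!gone && stats::runif(1) < config$dropout_rate_per_wave) gone <- TRUE
      if (gone) keep[idx[w]] <- FALSE
    }
  }
  cohort <- cohort[keep, , drop = FALSE]
  rownames(cohort) <- NULL

  set.seed(substream_seed(config$seed, "latents"))
  eta <- simulate_latents(cohort, growth, delta)
  x <- simulate_indicator_targets(eta, growth)

  truth <- data.frame(participant = cohort$participant, wave = cohort$wave,
                      maturity_offset = delta[cohort$participant],
                      cognitive_age = cohort$age + delta[cohort$participant],
                      eta, stringsAsFactors = FALSE)
  names(truth)[names(truth) %in% colnames(eta)] <-
    paste0("eta_", colnames(eta))

  maps <- indicator_natural_maps()
  cohort$bis <- maps$bis(x[, "bis"])

  bundle <- list(cohort = cohort, truth = truth, config = config,
                 growth = growth)
  if (!trials) {
    bundle$indicator_targets <- data.frame(
      participant = cohort$participant, wave = cohort$wave, x,
      stringsAsFactors = FALSE)
    return(bundle)
  }

  set.seed(substream_seed(config$seed, "sessions"))
  tasks <- c("cpt", "wof", "efr", "td")
  trial_list <- list()
  for (r in seq_len(nrow(cohort))) {
    p <- cohort$participant[r]; w <- as.character(cohort$wave[r])
    missing_task <- stats::runif(length(tasks)) < config$indicator_missing_rate
    names(missing_task) <- tasks
    sess <- list()
    sess$cpt <- if (missing_task["cpt"]) NULL else generate_cpt_session(
      target_dprime = maps$cpt_dprime(x[r, "cpt_dprime"]),
      target_lnbeta = maps$cpt_lnbeta(x[r, "cpt_lnbeta"]),
      rt_params = list(hit_rt_mean = 380,
                       hit_rt_sd = maps$cpt_hit_rt_sd(x[r, "cpt_hit_rt_sd"]),
                       fa_rt_mean = 350,
                       fa_rt_sd = maps$cpt_fa_rt_sd(x[r, "cpt_fa_rt_sd"])))
    sess$wof <- if (missing_task["wof"]) NULL else generate_wof_session(
      p_high_risk = maps$wof_p_highrisk(x[r, "wof_p_highrisk"]),
      rt_means = list(high = maps$wof_rt_high(x[r, "wof_rt_high"]),
                      low = maps$wof_rt_low(x[r, "wof_rt_low"])))
    sess$efr <- if (missing_task["efr"]) NULL else generate_efr_session(
      neg_acc = maps$efr_neg_acc(x[r, "efr_neg_acc"]),
      pos_acc = maps$efr_pos_acc(x[r, "efr_pos_acc"]),
      rt_params = list(
        neg_mean = maps$efr_neg_rt_mean(x[r, "efr_neg_rt_mean"]),
        neg_sd = maps$efr_neg_rt_sd(x[r, "efr_neg_rt_sd"]),
        pos_mean = maps$efr_pos_rt_mean(x[r, "efr_pos_rt_mean"]),
        pos_sd = maps$efr_pos_rt_sd(x[r, "efr_pos_rt_sd"]),
        other_mean = 1800, other_sd = 450))
    sess$td <- if (missing_task["td"]) NULL else generate_td_session(
      discount_profile_from_auc(maps$td_auc(x[r, "td_auc"])))
    if (is.null(trial_list[[p]])) trial_list[[p]] <- list()
    trial_list[[p]][[w]] <- sess
  }
  bundle$trials <- trial_list
  bundle
}

#' Indicator matrix from noiseless targets (fast simulation path)
#'
#' For recovery simulations that do not need trial-level measurement noise:
#' applies the Lie-scale exclusions and standardizes the generator's
#' indicator targets directly into an `indicator_matrix`, bypassing session
#' synthesis and scoring.
#'
#' @param bundle result of [generate_cohort()] with `trials = FALSE`.
#' @return list with `indicators` (an `indicator_matrix`) and `exclusions`
#'   (the exclusion log).
#' @export
indicators_from_targets <- function(bundle) {
  if (is.null(bundle$indicator_targets)) {
    stop("bundle has no indicator_targets; generate with trials = FALSE")
  }
  excl <- apply_exclusions(bundle$cohort)
  list(indicators = build_indicator_matrix(bundle$indicator_targets,
                                           excl$cohort),
       exclusions = excl$log)
}

#' Write a cohort bundle to disk as plain-text files
#'
#' Cohort as one long-format CSV, each task session as
#' `{participant}_{wave}_{task}.csv`, ground truth as a JSON sidecar, plus a
#' generated data dictionary.
#'
#' @param bundle result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, "cohort.csv")
  utils::write.csv(bundle$cohort, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(bundle$trials)) {
    for (p in names(bundle$trials)) {
      for (w in names(bundle$trials[[p]])) {
        for (task in names(bundle$trials[[p]][[w]])) {
          tab <- bundle$trials[[p]][[w]][[task]]
          if (is.null(tab)) next
          f <- file.path(dir, sprintf("%s_%s_%s.csv", p, w, task))
          utils::write.csv(tab, f, row.names = FALSE)
          files <- c(files, f)
        }
      }
    }
  }
  f <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(bundle$truth, f, digits = NA)
  files <- c(files, f)
  dict <- data.frame(
    column = names(bundle$cohort),
    description = vapply(names(bundle$cohort), cohort_column_description,
                         character(1)),
    stringsAsFactors = FALSE
  )
  f <- file.path(dir, "data_dictionary.csv")
  utils::write.csv(dict, f, row.names = FALSE)
  invisible(c(files, f))
}

cohort_column_description <- function(col) {
  d <- c(
    participant = "participant identifier",
    wave = "assessment wave index (1-based)",
    age = "chronological age at assessment, years",
    sex = "self-reported sex (female/male)",
    bmi = "body-mass index, kg/m^2",
    pds = "pubertal development score (1-4)",
    income = "household income, USD/year",
    educ_years_parent1 = "years of education, parent/guardian 1",
    educ_years_parent2 = "years of education, parent/guardian 2",
    iq = "composite IQ",
    bas_d = "behavioral activation: drive subscale",
    bas_fs = "behavioral activation: fun-seeking subscale",
    bas_rr = "behavioral activation: reward-responsiveness subscale",
    dusi_lie = "DUSI-R Lie validity scale (exclusion if > 6)",
    dusi_substance = "DUSI-R substance-use problem scale",
    dusi_health = "DUSI-R health-risk problem scale",
    dusi_violence = "DUSI-R violence-risk problem scale",
    bis = "behavioral inhibition system scale"
  )
  if (col %in% names(d)) unname(d[col]) else "(undocumented)"
}
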