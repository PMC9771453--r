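#' Configuration for a synthetic longitudinal cohort
#'
#' Defines the sampling design of a simulated adolescent cohort: sample size,
#' number of assessment waves, wave-one age range, inter-wave gap, monotone
#' dropout, session-level missingness, and the rate of invalid questionnaire
#' responders (Lie-scale > 6) planted for the downstream exclusion filter.
#'
#' Defaults emulate a three-wave study of 141 youth enrolled at ages
#' 11.1-14.0 years with visits roughly 1.6 years apart.
#'
#' @param n_participants number of enrolled participants (>= 2).
#' @param n_waves number of assessment waves (>= 1).
#' @param wave1_age_range length-2 numeric, wave-one age range in years.
#' @param inter_wave_gap_mean_sd length-2 numeric, mean and SD (years) of the
#'   gap between consecutive waves.
#' @param dropout_rate_per_wave probability that a participant still enrolled
#'   at wave w-1 is lost before wave w (monotone attrition).
#' @param indicator_missing_rate probability that any one task session of a
#'   retained person-wave is missing (session-level missingness).
#' @param lie_gt6_rate proportion of participants planted with a Lie-scale
#'   score above 6 (their task data are otherwise normal).
#' @param seed integer master seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 141,
                          n_waves = 3,
                          wave1_age_range = c(11.1, 14.0),
                          inter_wave_gap_mean_sd = c(1.6, 0.3),
                          dropout_rate_per_wave = 0.08,
                          indicator_missing_rate = 0.05,
                          lie_gt6_rate = 23 / 141,
                          seed = 1L) {
  stopifnot(length(wave1_age_range) == 2L, length(inter_wave_gap_mean_sd) == 2L)
  if (!is.numeric(n_participants) || n_participants < 2) {
    stop("invalid config: n_participants must be >= 2")
  }
  if (n_waves < 1) stop("invalid config: n_waves must be >= 1")
  if (wave1_age_range[1] >= wave1_age_range[2]) {
    stop("invalid config: wave1 age range lower bound must be below upper")
  }
  for (p in c(dropout_rate_per_wave, indicator_missing_rate, lie_gt6_rate)) {
    if (p < 0 || p > 1) stop("invalid config: probabilities must lie in [0,1]")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_waves = as.integer(n_waves),
    wave1_age_range = as.numeric(wave1_age_range),
    inter_wave_gap_mean_sd = as.numeric(inter_wave_gap_mean_sd),
    dropout_rate_per_wave = dropout_rate_per_wave,
    indicator_missing_rate = indicator_missing_rate,
    lie_gt6_rate = lie_gt6_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Names of the task indicators loading on each latent factor
#'
#' Four latent factors: inhibitory control (ICLF: continuous-performance-task
#' signal-detection metrics plus the behavioral inhibition scale), risk/reward
#' (RRLF: gambling-task metrics plus delay-discounting AUC), and negative /
#' positive emotional face recognition (ENLF / EPLF).
#'
#' @return named list mapping factor name to indicator column names.
#' @export
default_factor_indicators <- function() {
  list(
    ICLF = c("cpt_dprime", "cpt_lnbeta", "cpt_hit_rt_sd", "cpt_fa_rt_sd", "bis"),
    RRLF = c("wof_p_highrisk", "wof_rt_high", "wof_rt_low", "wof_winnings", "td_auc"),
    ENLF = c("efr_neg_acc", "efr_neg_rt_mean", "efr_neg_rt_sd"),
    EPLF = c("efr_pos_acc", "efr_pos_rt_mean", "efr_pos_rt_sd")
  )
}

# Reference loading magnitudes/signs used as generator defaults (standardized
# scale; signs follow the fitted measurement models of the study design this
# generator emulates).
default_loadings <- function() {
  c(cpt_dprime = 0.650, cpt_lnbeta = -0.503, cpt_hit_rt_sd = -0.913,
    cpt_fa_rt_sd = -0.371, bis = 0.193,
    wof_p_highrisk = 0.703, wof_rt_high = 0.158, wof_rt_low = 0.433,
    wof_winnings = -0.899, td_auc = -0.127,
    efr_neg_acc = 0.164, efr_neg_rt_mean = -0.451, efr_neg_rt_sd = -0.302,
    efr_pos_acc = 0.173, efr_pos_rt_mean = 0.310, efr_pos_rt_sd = 0.235)
}

#' Latent growth specification for the synthetic cohort
#'
#' Ground-truth model generating person-wave latent factor values and their
#' indicator targets. Each factor follows a linear growth model in cognitive
#' age (chronological age plus a per-person maturity offset), with a
#' person-level random intercept, cross-factor structural paths from
#' inhibitory control, and covariate effects. Indicators are
#' `loading * factor + residual` on a standardized latent scale, then mapped
#' to natural task units by the session generators.
#'
#' @param intercepts,age_slopes named numeric over factors ICLF, RRLF, ENLF,
#'   EPLF. Slopes are in factor-SD units per year of (cognitive) age.
#' @param random_intercept_sd named numeric, person-level SD per factor.
#' @param maturity_offset_sd SD (years) of the per-person maturity offset
#'   delta; a participant's cognitive age is `age + delta` at every wave.
#' @param loadings named numeric over the 16 indicators (see
#'   [default_factor_indicators()]).
#' @param residual_sd indicator residual SD (single value or named per
#'   indicator) on the standardized latent scale.
#' @param residual_cor named list of indicator pairs and residual correlations,
#'   e.g. `list(list(pair = c("a","b"), r = 0.3))`.
#' @param paths named numeric structural paths from ICLF onto the other
#'   factors, applied to the non-age part of each factor.
#' @param covariate_effects list of lists `(covariate, factor, beta)` adding
#'   `beta * covariate` (z-scaled covariate) to a factor.
#' @param wave_cor extra inter-wave correlation of indicator residuals beyond
#'   the random intercept (0 = none; exposed as a knob, default 0).
#' @return a `growth_spec` list.
#' @export
growth_spec <- function(intercepts = c(ICLF = 0, RRLF = 0, ENLF = 0, EPLF = 0),
                        age_slopes = c(ICLF = 0.72, RRLF = -0.22,
                                       ENLF = 0.35, EPLF = -0.16),
                        random_intercept_sd = c(ICLF = 0.3, RRLF = 0.3,
                                                ENLF = 0.3, EPLF = 0.3),
                        maturity_offset_sd = 0.8,
                        loadings = default_loadings(),
                        residual_sd = 0.5,
                        residual_cor = list(),
                        paths = c(RRLF = -0.22, ENLF = 0.55, EPLF = -0.30),
                        covariate_effects = list(
                          list(covariate = "ses", factor = "ICLF", beta = 0.27),
                          list(covariate = "pds", factor = "EPLF", beta = -0.35),
                          list(covariate = "bmi", factor = "ENLF", beta = 0.15)
                        ),
                        wave_cor = 0) {
  fac <- names(default_factor_indicators())
  stopifnot(all(fac %in% names(intercepts)), all(fac %in% names(age_slopes)),
            all(fac %in% names(random_intercept_sd)))
  ind <- unlist(default_factor_indicators(), use.names = FALSE)
  if (!all(ind %in% names(loadings))) {
    stop("loadings must name every indicator: missing ",
         paste(setdiff(ind, names(loadings)), collapse = ", "))
  }
  if (length(residual_sd) == 1L && is.null(names(residual_sd))) {
    residual_sd <- stats::setNames(rep(residual_sd, length(ind)), ind)
  }
  if (any(residual_sd <= 0)) stop("residual SDs must be positive")
  structure(list(
    intercepts = intercepts[fac], age_slopes = age_slopes[fac],
    random_intercept_sd = random_intercept_sd[fac],
    maturity_offset_sd = maturity_offset_sd,
    loadings = loadings[ind], residual_sd = residual_sd[ind],
    residual_cor = residual_cor, paths = paths,
    covariate_effects = covariate_effects, wave_cor = wave_cor
  ), class = "growth_spec")
}

#' Strong-signal growth preset for recovery studies
#'
#' A well-powered variant of [growth_spec()] used in parameter- and
#' CMI-recovery simulations: reference age slopes per year, indicator residual
#' SD 0.5, loading magnitudes scaled 1.6x (signs unchanged), small person
#' random intercepts, and a 0.8-year maturity-offset SD. Chosen a priori from
#' a power analysis of the recovery design (see the methods vignette).
#'
#' @return a `growth_spec`.
#' @export
strong_signal_growth <- function() {
  growth_spec(
    loadings = default_loadings() * 1.6,
    residual_sd = 0.5,
    random_intercept_sd = c(ICLF = 0.1, RRLF = 0.1, ENLF = 0.1, EPLF = 0.1),
    maturity_offset_sd = 0.8
  )
}
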