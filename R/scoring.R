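# Scoring of trial-level task tables into the indicator variables used for
# latent modeling.

#' Score a continuous-performance-task session
#'
#' Computes signal-detection metrics over target and lure trials:
#' `d' = qnorm(hit_rate) - qnorm(fa_rate)` and
#' `ln(beta) = 0.5 * (qnorm(fa_rate)^2 - qnorm(hit_rate)^2)`.
#' Extreme rates (0 or 1) are replaced by `1/(2N)` and `1 - 1/(2N)`, N the
#' relevant trial count, before taking normal quantiles. RT statistics are
#' computed over responded trials only.
#'
#' @param trials a CPT trial table as produced by [generate_cpt_session()].
#' @return list with `hit_rate`, `fa_rate` (unadjusted), `d_prime`, `ln_beta`,
#'   `hit_rt_mean`, `hit_rt_sd`, `fa_rt_sd` (ms; NA when fewer than two
#'   responded trials of the kind).
#' @export
score_cpt <- function(trials) {
  stopifnot(all(c("stimulus", "responded", "rt_ms") %in% names(trials)))
  targets <- trials$stimulus == "target"
  lures <- trials$stimulus == "lure"
  n_t <- sum(targets); n_l <- sum(lures)
  if (n_t == 0 || n_l == 0) {
    stop("CPT table must contain both targets and lures; rates undefined")
  }
  hit_rate <- sum(trials$responded[targets]) / n_t
  fa_rate <- sum(trials$responded[lures]) / n_l
  adj <- function(p, n) min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  zh <- stats::qnorm(adj(hit_rate, n_t))
  zf <- stats::qnorm(adj(fa_rate, n_l))
  hit_rt <- trials$rt_ms[targets & trials$responded]
  fa_rt <- trials$rt_ms[lures & trials$responded]
  list(
    hit_rate = hit_rate, fa_rate = fa_rate,
    d_prime = zh - zf,
    ln_beta = 0.5 * (zf^2 - zh^2),
    hit_rt_mean = if (length(hit_rt) >= 1) mean(hit_rt) else NA_real_,
    hit_rt_sd = if (length(hit_rt) >= 2) stats::sd(hit_rt) else NA_real_,
    fa_rt_sd = if (length(fa_rt) >= 2) stats::sd(fa_rt) else NA_real_
  )
}

#' Score a wheel-of-fortune gambling session
#'
#' Choice and RT metrics are computed over non-timeout trials with
#' RT >= 200 ms (anticipatory responses are discarded as outliers).
#' Cumulative winnings come from the full payoff ledger, timeouts included:
#' the final balance of each run, summed over runs.
#'
#' @param trials a WOF trial table as produced by [generate_wof_session()].
#' @return list with `p_high_risk`, `rt_high_mean`, `rt_low_mean`,
#'   `cumulative_winnings`, and `n_excluded` (anticipatory + timeout trials).
#' @export
score_wof <- function(trials) {
  stopifnot(all(c("choice", "rt_ms", "payoff", "run") %in% names(trials)))
  valid <- trials$choice != "timeout" & !is.na(trials$rt_ms) &
    trials$rt_ms >= 200
  if (!any(valid)) stop("all WOF trials excluded; choice metrics undefined")
  v <- trials[valid, ]
  hi <- v$choice == "high_risk"
  final_per_run <- tapply(trials$payoff, trials$run, sum)
  list(
    p_high_risk = mean(hi),
    rt_high_mean = if (any(hi)) mean(v$rt_ms[hi]) else NA_real_,
    rt_low_mean = if (any(!hi)) mean(v$rt_ms[!hi]) else NA_real_,
    cumulative_winnings = sum(final_per_run),
    n_excluded = sum(!valid)
  )
}

#' Score an emotional face recognition session
#'
#' The negative block aggregates disgust, anger, sadness and fear; the
#' positive block is happiness only. Accuracy is the proportion of correct
#' labels within a block; RT statistics are computed over all trials of the
#' block, correct and incorrect.
#'
#' @param trials an EFR trial table as produced by [generate_efr_session()].
#' @return list with `neg_accuracy`, `pos_accuracy`, `neg_rt_mean`,
#'   `neg_rt_sd`, `pos_rt_mean`, `pos_rt_sd` (ms).
#' @export
score_efr <- function(trials) {
  stopifnot(all(c("true_emotion", "chosen_emotion", "rt_ms") %in% names(trials)))
  missing_emo <- setdiff(efr_emotions(), unique(trials$true_emotion))
  if (length(missing_emo) > 0) {
    stop("EFR table is missing emotion categories: ",
         paste(missing_emo, collapse = ", "))
  }
  neg <- trials$true_emotion %in% efr_negative_set()
  pos <- trials$true_emotion == "happiness"
  correct <- trials$true_emotion == trials$chosen_emotion
  list(
    neg_accuracy = mean(correct[neg]),
    pos_accuracy = mean(correct[pos]),
    neg_rt_mean = mean(trials$rt_ms[neg]),
    neg_rt_sd = stats::sd(trials$rt_ms[neg]),
    pos_rt_mean = mean(trials$rt_ms[pos]),
    pos_rt_sd = stats::sd(trials$rt_ms[pos])
  )
}

#' Estimate per-delay indifference points from adaptive choices
#'
#' For each delay the indifference point is the midpoint between the largest
#' immediate amount rejected (delayed option chosen) and the smallest
#' immediate amount accepted, clipped to [$0.50, $10]. A delay with no
#' accepted immediate offer yields $10 (subjective value undiminished); one
#' with no rejected offer yields the midpoint between $0.50 and the smallest
#' accepted offer. If the choices admit no separating threshold (an accepted
#' offer below a rejected one), a logistic fit of P(immediate) against the
#' offer provides the 50% midpoint and the delay is flagged.
#'
#' @param choices a TD choice table as produced by [generate_td_session()].
#' @return list with `points` (named numeric, $ per delay label) and
#'   `flagged` (character vector of delays that needed the logistic fallback).
#' @export
estimate_indifference_points <- function(choices) {
  stopifnot(all(c("delay_label", "immediate_amount", "choice") %in%
                  names(choices)))
  labs <- td_delay_grid()$label
  present <- intersect(labs, unique(choices$delay_label))
  if (length(present) == 0) stop("no delays present in choice table")
  points <- stats::setNames(rep(NA_real_, length(present)), present)
  flagged <- character(0)
  for (d in present) {
    sub <- choices[choices$delay_label == d, ]
    acc <- sub$immediate_amount[sub$choice == "immediate"]
    rej <- sub$immediate_amount[sub$choice == "delayed"]
    if (length(acc) == 0) {
      ip <- 10
    } else if (length(rej) == 0) {
      ip <- (0.5 + min(acc)) / 2
    } else if (min(acc) >= max(rej)) {
      ip <- (max(rej) + min(acc)) / 2
    } else {
      fit <- suppressWarnings(stats::glm(
        I(choice == "immediate") ~ immediate_amount,
        family = stats::binomial(), data = sub))
      b <- stats::coef(fit)
      ip <- if (is.finite(b[2]) && abs(b[2]) > 1e-8) -b[1] / b[2]
            else mean(sub$immediate_amount)
      flagged <- c(flagged, d)
    }
    points[d] <- clip(ip, 0.5, 10)
  }
  list(points = points, flagged = flagged)
}

#' Trapezoidal area under the normalized discounting curve
#'
#' Delays are annualized (divided by 365 days; 1 month = 30 d, half year =
#' 182.5 d) and values normalized to the $10 maximum, giving an AUC in
#' `[0, 1]`:
#' `AUC = sum over segments of (d[t+1] - d[t]) * (v[t] + v[t+1]) / 2`.
#' A point at delay 0 anchors the curve; when absent, normalized value 1 at
#' delay 0 is prepended.
#'
#' @param points named numeric of indifference values in $ per delay label of
#'   [td_delay_grid()], or arbitrary $ values when `delay_years` is supplied.
#' @param delay_years optional numeric vector of delays in years matching
#'   `points` (overrides label lookup; must be sorted, strictly increasing).
#' @return AUC in `[0, 1]`.
#' @export
compute_td_auc <- function(points, delay_years = NULL) {
  if (is.null(delay_years)) {
    grid <- td_delay_grid()
    labs <- names(points)
    if (is.null(labs) || !all(labs %in% grid$label)) {
      stop("points must be named by delay labels (",
           paste(grid$label, collapse = ", "), ") or delay_years supplied")
    }
    delay_years <- grid$years[match(labs, grid$label)]
    o <- order(delay_years)
    delay_years <- delay_years[o]
    points <- points[o]
  }
  if (any(duplicated(delay_years))) stop("duplicate delays")
  if (is.unsorted(delay_years, strictly = TRUE)) {
    stop("delays must be sorted strictly ascending")
  }
  v <- as.numeric(points) / 10
  t <- delay_years
  if (t[1] > 0) {
    t <- c(0, t)
    v <- c(1, v)
  }
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Socioeconomic-status composite
#'
#' Household income is z-scored over the cohort; the two parents' years of
#' education are averaged, z-scored over the cohort, and the two z-scores
#' averaged. A missing component drops out of the average; both missing
#' propagates NA.
#'
#' @param income numeric vector, household income.
#' @param educ_years_parent1,educ_years_parent2 numeric vectors, parental
#'   years of education.
#' @return numeric vector of SES z-composites.
#' @export
compute_ses <- function(income, educ_years_parent1, educ_years_parent2) {
  z <- function(x) (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  z_inc <- z(income)
  mean_ed <- rowMeans(cbind(educ_years_parent1, educ_years_parent2),
                      na.rm = TRUE)
  mean_ed[is.nan(mean_ed)] <- NA_real_
  z_ed <- z(mean_ed)
  out <- rowMeans(cbind(z_inc, z_ed), na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Apply validity-scale exclusions
#'
#' Removes every wave of each participant whose DUSI-R Lie score exceeds 6
#' (strict inequality: Lie = 6 is retained).
#'
#' @param cohort long-format cohort data.frame with `participant` and
#'   `dusi_lie` columns.
#' @return list with `cohort` (retained rows) and `log` (data.frame of
#'   excluded participants with their Lie scores and reason).
#' @export
apply_exclusions <- function(cohort) {
  stopifnot("dusi_lie" %in% names(cohort))
  bad <- unique(cohort$participant[cohort$dusi_lie > 6])
  keep <- !(cohort$participant %in% bad)
  log <- data.frame(
    participant = bad,
    max_lie = vapply(bad, function(p) {
      max(cohort$dusi_lie[cohort$participant == p])
    }, numeric(1)),
    reason = if (length(bad)) "DUSI-R Lie > 6" else character(0),
    stringsAsFactors = FALSE
  )
  list(cohort = cohort[keep, , drop = FALSE], log = log)
}

#' Score every task session of a cohort bundle
#'
#' Runs the per-task scorers over all person-wave sessions and assembles the
#' natural-unit indicator summaries (one row per person-wave; missing
#' sessions give NA indicators).
#'
#' @param bundle result of [generate_cohort()] with `trials = TRUE`.
#' @return data.frame with `participant`, `wave`, and the 16 indicator
#'   columns on their natural scales.
#' @export
score_cohort_bundle <- function(bundle) {
  cohort <- bundle$cohort
  rows <- vector("list", nrow(cohort))
  for (r in seq_len(nrow(cohort))) {
    p <- cohort$participant[r]; w <- as.character(cohort$wave[r])
    sess <- bundle$trials[[p]][[w]]
    out <- list(participant = p, wave = cohort$wave[r],
                cpt_dprime = NA_real_, cpt_lnbeta = NA_real_,
                cpt_hit_rt_sd = NA_real_, cpt_fa_rt_sd = NA_real_,
                bis = as.numeric(cohort$bis[r]),
                wof_p_highrisk = NA_real_, wof_rt_high = NA_real_,
                wof_rt_low = NA_real_, wof_winnings = NA_real_,
                td_auc = NA_real_,
                efr_neg_acc = NA_real_, efr_neg_rt_mean = NA_real_,
                efr_neg_rt_sd = NA_real_, efr_pos_acc = NA_real_,
                efr_pos_rt_mean = NA_real_, efr_pos_rt_sd = NA_real_)
    if (!is.null(sess$cpt)) {
      s <- score_cpt(sess$cpt)
      out$cpt_dprime <- s$d_prime; out$cpt_lnbeta <- s$ln_beta
      out$cpt_hit_rt_sd <- s$hit_rt_sd; out$cpt_fa_rt_sd <- s$fa_rt_sd
    }
    if (!is.null(sess$wof)) {
      s <- score_wof(sess$wof)
      out$wof_p_highrisk <- s$p_high_risk; out$wof_rt_high <- s$rt_high_mean
      out$wof_rt_low <- s$rt_low_mean; out$wof_winnings <- s$cumulative_winnings
    }
    if (!is.null(sess$efr)) {
      s <- score_efr(sess$efr)
      out$efr_neg_acc <- s$neg_accuracy; out$efr_neg_rt_mean <- s$neg_rt_mean
      out$efr_neg_rt_sd <- s$neg_rt_sd; out$efr_pos_acc <- s$pos_accuracy
      out$efr_pos_rt_mean <- s$pos_rt_mean; out$efr_pos_rt_sd <- s$pos_rt_sd
    }
    if (!is.null(sess$td)) {
      ip <- estimate_indifference_points(sess$td)
      out$td_auc <- compute_td_auc(ip$points)
    }
    rows[[r]] <- as.data.frame(out, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Assemble the standardized indicator matrix
#'
#' Joins scored summaries to the (exclusion-filtered) cohort, z-standardizes
#' every indicator column over all retained person-waves pooled, and records
#' the missingness mask. Masked entries are never imputed here.
#'
#' @param summaries data.frame from [score_cohort_bundle()] (natural scales).
#' @param cohort exclusion-filtered cohort data.frame (its person-waves
#'   define the retained rows).
#' @return an `indicator_matrix` object: list with `data` (numeric matrix,
#'   rows = person-waves, z-scaled, NA = missing), `mask` (logical matrix,
#'   TRUE = missing), `info` (participant, wave, age and covariates), and
#'   `indicators` (column names).
#' @export
build_indicator_matrix <- function(summaries, cohort) {
  key_s <- paste(summaries$participant, summaries$wave)
  key_c <- paste(cohort$participant, cohort$wave)
  m <- match(key_c, key_s)
  if (anyNA(m)) stop("cohort person-waves missing from summaries")
  ind <- setdiff(names(summaries), c("participant", "wave"))
  raw <- as.matrix(summaries[m, ind, drop = FALSE])
  rownames(raw) <- key_c
  z <- raw
  for (j in ind) z[, j] <- zscore_col(raw[, j], j)
  info <- cohort[, intersect(c("participant", "wave", "age", "sex", "bmi",
                               "pds", "iq", "income", "educ_years_parent1",
                               "educ_years_parent2", "bas_d", "bas_fs",
                               "bas_rr", "bis", "dusi_lie", "dusi_substance",
                               "dusi_health", "dusi_violence"),
                             names(cohort)), drop = FALSE]
  # the BIS total doubles as an indicator column; keep the covariate copy
  # under a distinct name so joined tables have unique columns
  names(info)[names(info) == "bis"] <- "bis_scale"
  info$ses <- compute_ses(cohort$income, cohort$educ_years_parent1,
                          cohort$educ_years_parent2)
  structure(list(data = z, mask = is.na(z), info = info, indicators = ind),
            class = "indicator_matrix")
}
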