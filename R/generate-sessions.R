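# Trial-level session generators. Each generator is calibrated so that the
# scoring module recovers its targets up to trial-level sampling error.

#' Delay grid used by the discounting task
#'
#' Seven delays (0, 1, 2, 10 days, 1 month, half a year, 1 year) with the
#' normalization constants 1 month = 30 days, half year = 182.5 days,
#' 1 year = 365 days.
#'
#' @return data.frame with columns `label`, `days`, `years`.
#' @export
td_delay_grid <- function() {
  data.frame(
    label = c("0d", "1d", "2d", "10d", "1mo", "6mo", "1yr"),
    days = c(0, 1, 2, 10, 30, 182.5, 365),
    years = c(0, 1, 2, 10, 30, 182.5, 365) / 365,
    stringsAsFactors = FALSE
  )
}

# Invert the signal-detection equations: given d' and ln(beta), return the
# normal quantiles of the hit and false-alarm probabilities.
#   d' = zH - zF;  ln(beta) = (zF^2 - zH^2) / 2
# For d' != 0: zH = d'/2 - ln(beta)/d', zF = -d'/2 - ln(beta)/d'.
# d' = 0 forces ln(beta) = 0 (zH = zF = 0).
sdt_invert <- function(d_prime, ln_beta) {
  d_prime <- unname(d_prime)
  ln_beta <- unname(ln_beta)
  if (!is.finite(d_prime) || !is.finite(ln_beta)) {
    stop("d_prime and ln_beta targets must be finite")
  }
  if (abs(d_prime) < 1e-12) {
    if (abs(ln_beta) > 1e-12) {
      stop("ln_beta must be 0 when d_prime is 0 (no solution otherwise)")
    }
    return(c(zH = 0, zF = 0))
  }
  c(zH = d_prime / 2 - ln_beta / d_prime,
    zF = -d_prime / 2 - ln_beta / d_prime)
}

#' Generate one continuous-performance-task session
#'
#' 150 letter trials in 5 blocks of 30; the lure appears 27 times at fixed
#' positions (the lure sequence is the same for every generated session).
#' Response probabilities on target and lure trials are obtained by
#' analytically inverting the signal-detection equations at the requested
#' sensitivity and bias, so the expected scored d-prime equals the target up
#' to binomial sampling error.
#'
#' @param target_dprime,target_lnbeta targets on the signal-detection scale.
#' @param rt_params list with `hit_rt_mean`, `hit_rt_sd`, `fa_rt_mean`,
#'   `fa_rt_sd` in ms (positive).
#' @return data.frame with columns `trial`, `block`, `stimulus`
#'   (`"target"`/`"lure"`), `responded` (logical), `rt_ms` (NA when no
#'   response).
#' @export
generate_cpt_session <- function(target_dprime, target_lnbeta,
                                 rt_params = list(hit_rt_mean = 380,
                                                  hit_rt_sd = 110,
                                                  fa_rt_mean = 350,
                                                  fa_rt_sd = 140)) {
  z <- sdt_invert(target_dprime, target_lnbeta)
  rt_params <- lapply(rt_params, unname)
  stopifnot(rt_params$hit_rt_mean > 0, rt_params$hit_rt_sd > 0,
            rt_params$fa_rt_mean > 0, rt_params$fa_rt_sd > 0)
  n_trials <- 150L
  lure_pos <- round(seq(3, 148, length.out = 27))  # fixed lure sequence
  stimulus <- rep("target", n_trials)
  stimulus[lure_pos] <- "lure"
  p_hit <- stats::pnorm(z["zH"])
  p_fa <- stats::pnorm(z["zF"])
  responded <- logical(n_trials)
  is_lure <- stimulus == "lure"
  responded[!is_lure] <- stats::runif(sum(!is_lure)) < p_hit
  responded[is_lure] <- stats::runif(sum(is_lure)) < p_fa
  rt <- rep(NA_real_, n_trials)
  nh <- sum(responded & !is_lure)
  nf <- sum(responded & is_lure)
  if (nh > 0) {
    rt[responded & !is_lure] <- rt_shifted_lognormal(
      nh, rt_params$hit_rt_mean, rt_params$hit_rt_sd)
  }
  if (nf > 0) {
    rt[responded & is_lure] <- rt_shifted_lognormal(
      nf, rt_params$fa_rt_mean, rt_params$fa_rt_sd)
  }
  data.frame(
    trial = seq_len(n_trials),
    block = rep(1:5, each = 30L),
    stimulus = stimulus,
    responded = responded,
    rt_ms = rt,
    stringsAsFactors = FALSE
  )
}

# Wheel designs implied by the expected-value parity of a winning selection:
# 10:90 wheels pair ($1,$9) or ($2,$18); 30:70 wheels pair ($3,$7) or ($9,$21).
wof_wheels <- function() {
  data.frame(
    split = c("10:90", "10:90", "30:70", "30:70"),
    low_amount = c(1, 2, 3, 9),
    high_amount = c(9, 18, 7, 21),
    p_win_high = c(0.10, 0.10, 0.30, 0.30),
    p_win_low = c(0.90, 0.90, 0.70, 0.70),
    stringsAsFactors = FALSE
  )
}

#' Generate one wheel-of-fortune gambling session
#'
#' 90 trials over 3 runs of 30. The winning-probability split varies
#' pseudo-randomly between 10:90 (32-42 of 90 trials) and 30:70 (48-58
#' trials); dollar pairs keep the expected value of a winning selection equal
#' across risk levels. On a win the selected amount is gained, on a loss it is
#' lost, and a timeout loses the higher amount. Cumulative winnings reset at
#' the start of each run.
#'
#' @param p_high_risk probability a non-timeout choice is the high-risk side.
#' @param rt_means list with `high` and `low` mean RTs (ms); SDs are 25% of
#'   the mean.
#' @param timeout_rate probability a trial times out (no choice in 3000 ms).
#' @return data.frame with one row per trial: `trial`, `run`, `split`,
#'   `low_amount`, `high_amount`, `choice`, `rt_ms`, `win`, `payoff`,
#'   `cumulative`.
#' @export
generate_wof_session <- function(p_high_risk,
                                 rt_means = list(high = 1100, low = 1300),
                                 timeout_rate = 0.02) {
  p_high_risk <- unname(p_high_risk)
  rt_means <- lapply(rt_means, unname)
  stopifnot(p_high_risk >= 0, p_high_risk <= 1,
            timeout_rate >= 0, timeout_rate <= 1)
  n <- 90L
  n_1090 <- sample(32:42, 1L)
  splits <- sample(c(rep("10:90", n_1090), rep("30:70", n - n_1090)))
  wheels <- wof_wheels()
  rows <- vapply(splits, function(s) {
    sample(which(wheels$split == s), 1L)
  }, integer(1))
  w <- wheels[rows, ]
  choice <- ifelse(stats::runif(n) < timeout_rate, "timeout",
                   ifelse(stats::runif(n) < p_high_risk,
                          "high_risk", "low_risk"))
  rt <- rep(NA_real_, n)
  hi <- choice == "high_risk"
  lo <- choice == "low_risk"
  if (any(hi)) rt[hi] <- pmin(rt_shifted_lognormal(
    sum(hi), rt_means$high, 0.25 * rt_means$high), 3000)
  if (any(lo)) rt[lo] <- pmin(rt_shifted_lognormal(
    sum(lo), rt_means$low, 0.25 * rt_means$low), 3000)
  p_win <- ifelse(hi, w$p_win_high, ifelse(lo, w$p_win_low, 0))
  win <- stats::runif(n) < p_win & choice != "timeout"
  amount <- ifelse(hi, w$high_amount, ifelse(lo, w$low_amount, 0))
  payoff <- ifelse(choice == "timeout", -pmax(w$high_amount, w$low_amount),
                   ifelse(win, amount, -amount))
  run <- rep(1:3, each = 30L)
  cumulative <- stats::ave(payoff, run, FUN = cumsum)
  data.frame(
    trial = seq_len(n), run = run, split = w$split,
    low_amount = w$low_amount, high_amount = w$high_amount,
    choice = choice, rt_ms = rt, win = win,
    payoff = payoff, cumulative = cumulative,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

efr_emotions <- function() {
  c("happiness", "surprise", "sadness", "anger", "disgust", "fear", "neutral")
}

efr_negative_set <- function() c("disgust", "anger", "sadness", "fear")

#' Generate one emotional face recognition session
#'
#' 70 labeling trials, 10 per emotion (happiness, surprise, sadness, anger,
#' disgust, fear, neutral) in random order. Accuracy is controlled per block:
#' the four negative emotions share `neg_acc`, happiness uses `pos_acc`, and
#' surprise/neutral use `other_acc`. Errors are spread uniformly over the six
#' incorrect labels.
#'
#' @param neg_acc,pos_acc,other_acc accuracies in `[0,1]`.
#' @param rt_params list with `neg_mean`, `neg_sd`, `pos_mean`, `pos_sd`,
#'   `other_mean`, `other_sd` in ms.
#' @return data.frame with columns `trial`, `true_emotion`, `chosen_emotion`,
#'   `rt_ms`.
#' @export
generate_efr_session <- function(neg_acc, pos_acc, other_acc = 0.8,
                                 rt_params = list(neg_mean = 1900, neg_sd = 450,
                                                  pos_mean = 1500, pos_sd = 400,
                                                  other_mean = 1800,
                                                  other_sd = 450)) {
  neg_acc <- unname(neg_acc); pos_acc <- unname(pos_acc)
  rt_params <- lapply(rt_params, unname)
  stopifnot(neg_acc >= 0, neg_acc <= 1, pos_acc >= 0, pos_acc <= 1,
            other_acc >= 0, other_acc <= 1)
  emos <- efr_emotions()
  true_emotion <- sample(rep(emos, each = 10L))
  n <- length(true_emotion)
  acc <- ifelse(true_emotion %in% efr_negative_set(), neg_acc,
                ifelse(true_emotion == "happiness", pos_acc, other_acc))
  correct <- stats::runif(n) < acc
  chosen <- true_emotion
  wrong <- which(!correct)
  for (i in wrong) {
    chosen[i] <- sample(setdiff(emos, true_emotion[i]), 1L)
  }
  block_mean <- ifelse(true_emotion %in% efr_negative_set(),
                       rt_params$neg_mean,
                       ifelse(true_emotion == "happiness",
                              rt_params$pos_mean, rt_params$other_mean))
  block_sd <- ifelse(true_emotion %in% efr_negative_set(), rt_params$neg_sd,
                     ifelse(true_emotion == "happiness",
                            rt_params$pos_sd, rt_params$other_sd))
  rt <- vapply(seq_len(n), function(i) {
    min(rt_shifted_lognormal(1L, block_mean[i], block_sd[i]), 5000)
  }, numeric(1))
  data.frame(trial = seq_len(n), true_emotion = true_emotion,
             chosen_emotion = chosen, rt_ms = rt, stringsAsFactors = FALSE)
}

#' Hyperbolic discount profile matching a target AUC
#'
#' Solves for the hyperbolic rate k such that subjective values
#' `v(t) = 10 / (1 + k t)` over the task's delay grid give the requested
#' trapezoidal area under the normalized discounting curve.
#'
#' @param target_auc desired AUC in `(0, 1]`.
#' @return named numeric of subjective values ($) per delay label.
#' @export
discount_profile_from_auc <- function(target_auc) {
  target_auc <- unname(target_auc)
  stopifnot(target_auc > 0, target_auc <= 1)
  grid <- td_delay_grid()
  profile_at <- function(k) stats::setNames(10 / (1 + k * grid$years),
                                            grid$label)
  if (target_auc >= 1 - 1e-12) return(profile_at(0))
  f <- function(logk) {
    compute_td_auc(profile_at(exp(logk))) - target_auc
  }
  lo <- -12; hi <- 12
  if (f(lo) < 0) return(profile_at(exp(lo)))  # target above reachable range
  if (f(hi) > 0) return(profile_at(exp(hi)))
  k <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
  profile_at(k)
}

#' Generate one delay-discounting choice session
#'
#' For each delay, an adaptive bisection staircase offers an immediate amount
#' against the fixed $10 delayed reward: the first offer is $5.00 with step
#' $2.50; choosing the immediate option lowers the next offer by the step and
#' choosing the delayed option raises it, with the step halving after every
#' choice (6 choices per delay, offers bounded to [$0.50, $10]). The simulated
#' responder chooses the immediate reward when the offer exceeds the profile's
#' subjective value of $10 at that delay, with optional logistic choice noise.
#'
#' @param true_discount_profile named numeric of subjective values ($, in
#'   (0, 10]) per delay label of [td_delay_grid()].
#' @param noise_scale logistic noise scale in $ (0 = deterministic
#'   thresholding).
#' @param n_steps staircase choices per delay.
#' @return data.frame with columns `trial`, `delay_label`, `delay_days`,
#'   `immediate_amount`, `delayed_amount` (always 10), `choice`.
#' @export
generate_td_session <- function(true_discount_profile, noise_scale = 0.25,
                                n_steps = 6L) {
  grid <- td_delay_grid()
  stopifnot(all(grid$label %in% names(true_discount_profile)))
  v <- true_discount_profile[grid$label]
  if (any(v <= 0 | v > 10)) {
    stop("subjective values must lie in (0, 10]")
  }
  out <- vector("list", nrow(grid))
  trial <- 0L
  for (i in seq_len(nrow(grid))) {
    offer <- 5
    step <- 2.5
    rows <- vector("list", n_steps)
    for (s in seq_len(n_steps)) {
      trial <- trial + 1L
      diff <- offer - v[i]
      p_imm <- if (noise_scale > 0) stats::plogis(diff / noise_scale)
               else as.numeric(diff > 0)
      choice <- if (stats::runif(1) < p_imm) "immediate" else "delayed"
      rows[[s]] <- data.frame(
        trial = trial, delay_label = grid$label[i], delay_days = grid$days[i],
        immediate_amount = offer, delayed_amount = 10, choice = choice,
        stringsAsFactors = FALSE
      )
      offer <- clip(offer + if (choice == "immediate") -step else step,
                    0.5, 10)
      step <- step / 2
    }
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}
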