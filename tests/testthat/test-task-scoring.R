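test_that("CPT scoring matches the recount oracle and handles edge rates", {
  # symmetric half rates: d' = 0, ln beta = 0 exactly
  tab <- data.frame(
    stimulus = c(rep("target", 4), rep("lure", 4)),
    responded = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    rt_ms = c(300, 310, NA, NA, 290, 295, NA, NA)
  )
  s <- score_cpt(tab)
  expect_equal(s$d_prime, 0)
  expect_equal(s$ln_beta, 0)
  expect_error(score_cpt(tab[tab$stimulus == "target", ]), "targets and lures")

  set.seed(1)
  for (i in 1:50) {
    tt <- random_cpt_table()
    got <- score_cpt(tt)
    want <- sdt_oracle(tt)
    expect_equal(got$d_prime, want$d_prime, tolerance = 1e-14)
    expect_equal(got$ln_beta, want$ln_beta, tolerance = 1e-14)
  }
  # purity: same table scores identically
  tt <- random_cpt_table()
  expect_identical(score_cpt(tt), score_cpt(tt))
})

test_that("WOF scoring applies the anticipatory and timeout filters", {
  set.seed(2)
  s <- generate_wof_session(0.6, timeout_rate = 0.05)
  s$rt_ms[1:5] <- 150  # plant anticipatory trials
  got <- score_wof(s)
  valid <- s$choice != "timeout" & !is.na(s$rt_ms) & s$rt_ms >= 200
  expect_identical(got$n_excluded, sum(!valid))
  expect_equal(got$p_high_risk, mean(s$choice[valid] == "high_risk"))
  # winnings use the full ledger including timeouts
  expect_equal(got$cumulative_winnings, sum(s$payoff))
  # filter is idempotent: scoring the pre-filtered table changes nothing
  # except the exclusion count
  got2 <- score_wof(s[valid, ])
  expect_equal(got2$p_high_risk, got$p_high_risk)
  expect_equal(got2$rt_high_mean, got$rt_high_mean)
  expect_identical(got2$n_excluded, 0L)
  s$rt_ms[] <- 100
  s$choice[] <- "timeout"
  expect_error(score_wof(s), "excluded")
})

test_that("EFR scoring aggregates valence blocks correctly", {
  set.seed(3)
  s <- generate_efr_session(0.75, 0.9)
  got <- score_efr(s)
  neg <- s$true_emotion %in% c("disgust", "anger", "sadness", "fear")
  expect_equal(got$neg_accuracy,
               mean((s$true_emotion == s$chosen_emotion)[neg]))
  expect_equal(got$neg_rt_mean, mean(s$rt_ms[neg]))
  expect_equal(got$pos_rt_sd, sd(s$rt_ms[s$true_emotion == "happiness"]))
  # 40 negative trials with 30 correct -> accuracy 0.75
  s2 <- s
  correct_rows <- which(neg)[1:30]
  s2$chosen_emotion[neg] <- "surprise"
  s2$chosen_emotion[correct_rows] <- s2$true_emotion[correct_rows]
  expect_equal(score_efr(s2)$neg_accuracy, 0.75)
  expect_error(score_efr(s[s$true_emotion != "fear", ]), "fear")
})

test_that("indifference points follow the midpoint rule", {
  mk <- function(delay, offers, choices) {
    data.frame(trial = seq_along(offers), delay_label = delay,
               delay_days = 365, immediate_amount = offers,
               delayed_amount = 10, choice = choices)
  }
  # delayed always chosen -> 10
  r <- estimate_indifference_points(mk("1yr", c(5, 7.5, 8.75),
                                       rep("delayed", 3)))
  expect_equal(unname(r$points["1yr"]), 10)
  # rejects the $4 immediate offer, accepts $6 -> midpoint 5
  r2 <- estimate_indifference_points(mk("1yr", c(4, 6),
                                        c("delayed", "immediate")))
  expect_equal(unname(r2$points["1yr"]), 5)
  expect_length(r2$flagged, 0)
  # inconsistent (accepts below a rejection) -> logistic fallback, flagged
  r3 <- estimate_indifference_points(
    mk("1yr", c(2, 4, 6, 8), c("immediate", "delayed", "immediate", "delayed")))
  expect_identical(r3$flagged, "1yr")
  expect_true(r3$points["1yr"] >= 0.5 && r3$points["1yr"] <= 10)
  # zero-noise responder with value $3 at 6mo recovered within grid step
  prof <- setNames(c(10, 10, 10, 10, 10, 3, 3), td_delay_grid()$label)
  s <- generate_td_session(prof, noise_scale = 0)
  r4 <- estimate_indifference_points(s)
  expect_lt(abs(r4$points["6mo"] - 3), 0.35)
})

test_that("trapezoidal AUC matches hand values and the fine-grid oracle", {
  grid <- td_delay_grid()
  expect_equal(compute_td_auc(setNames(rep(10, 7), grid$label)), 1)
  expect_equal(compute_td_auc(c(10, 5), delay_years = c(0, 1)), 0.75)
  expect_error(compute_td_auc(c(10, 5), delay_years = c(1, 0)), "sorted")
  expect_error(compute_td_auc(c(10, 5, 4), delay_years = c(0, 1, 1)),
               "duplicate")
  expect_error(compute_td_auc(setNames(rep(5, 3), c("x", "y", "z"))), "named")

  set.seed(4)
  for (i in 1:50) {
    v <- runif(7, 0.5, 10)
    expect_equal(compute_td_auc(setNames(v, grid$label)),
                 auc_grid_oracle(grid$years, v / 10),
                 tolerance = 1e-10)
  }
})

test_that("AUC is invariant to refining the grid by linear interpolation", {
  grid <- td_delay_grid()
  set.seed(5)
  v <- runif(7, 1, 10)
  base <- compute_td_auc(setNames(v, grid$label))
  t_fine <- sort(unique(c(grid$years, runif(25, 0, 1))))
  v_fine <- approx(grid$years, v, xout = t_fine)$y
  expect_equal(compute_td_auc(v_fine, delay_years = t_fine), base,
               tolerance = 1e-12)
})

test_that("SES composite averages income and education z-scores", {
  inc <- c(50000, 90000, 130000)
  e1 <- c(12, 16, 20); e2 <- c(14, 16, 18)
  got <- compute_ses(inc, e1, e2)
  z <- function(x) (x - mean(x)) / sd(x)
  want <- (z(inc) + z((e1 + e2) / 2)) / 2
  expect_equal(got, want, tolerance = 1e-12)
  # one component missing falls back to the other; both missing -> NA
  got2 <- compute_ses(c(NA, 90000, 130000), c(12, 16, NA), c(14, 16, NA))
  z_inc <- (90000 - 110000) / sd(c(90000, 130000))
  ed <- c(13, 16)
  z_ed <- (13 - 14.5) / sd(ed)
  expect_equal(got2[1], z_ed)              # income missing: education only
  expect_equal(got2[3], (130000 - 110000) / sd(c(90000, 130000)))
  expect_true(is.na(compute_ses(NA, NA, NA)))
})

test_that("Lie-scale exclusion is strict and removes whole participants", {
  cohort <- data.frame(
    participant = rep(c("A", "B", "C"), each = 2), wave = rep(1:2, 3),
    dusi_lie = c(6, 6, 7, 2, 3, 3)
  )
  r <- apply_exclusions(cohort)
  expect_identical(sort(unique(r$cohort$participant)), c("A", "C"))
  expect_identical(r$log$participant, "B")
  # idempotent
  r2 <- apply_exclusions(r$cohort)
  expect_identical(r2$cohort, r$cohort)
  expect_identical(nrow(r2$log), 0L)
})

test_that("planted high-Lie participants are exactly the ones excluded", {
  b <- generate_cohort(cohort_config(n_participants = 60, lie_gt6_rate = 0.2,
                                     seed = 77), growth_spec(), trials = FALSE)
  planted <- unique(b$cohort$participant[b$cohort$dusi_lie > 6])
  r <- apply_exclusions(b$cohort)
  expect_identical(sort(r$log$participant), sort(planted))
})

test_that("indicator matrix standardizes columns and conserves the mask", {
  im <- indicators_from_targets(
    generate_cohort(cohort_config(n_participants = 40, seed = 13,
                                  indicator_missing_rate = 0),
                    growth_spec(), trials = FALSE))$indicators
  for (j in im$indicators) {
    expect_lt(abs(mean(im$data[, j], na.rm = TRUE)), 1e-10)
    expect_lt(abs(sd(im$data[, j], na.rm = TRUE) - 1), 1e-10)
  }
  # constant column -> error naming the column
  b <- generate_cohort(cohort_config(n_participants = 20, seed = 14),
                       growth_spec(), trials = FALSE)
  b$indicator_targets$td_auc <- 0.5
  expect_error(indicators_from_targets(b), "td_auc")
})

test_that("masked entries are preserved, never imputed", {
  set.seed(15)
  b <- make_fixtures("tiny")
  summ <- score_cohort_bundle(b)
  summ$cpt_dprime[c(2, 5, 9)] <- NA
  excl <- apply_exclusions(b$cohort)
  im <- build_indicator_matrix(summ, excl$cohort)
  keys <- paste(summ$participant, summ$wave)
  kept <- keys %in% paste(excl$cohort$participant, excl$cohort$wave)
  expect_identical(sum(im$mask[, "cpt_dprime"]),
                   sum(is.na(summ$cpt_dprime[kept])))
  expect_true(all(is.na(im$data[im$mask])))
})
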