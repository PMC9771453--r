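test_that("cohort config validates its inputs", {
  expect_error(cohort_config(n_participants = 1), "n_participants")
  expect_error(cohort_config(wave1_age_range = c(14, 11)), "age range")
  expect_error(cohort_config(dropout_rate_per_wave = 1.2), "probabilities")
  expect_error(cohort_config(n_waves = 0), "n_waves")
})

test_that("cohort generation is deterministic and respects the design counts", {
  cfg <- cohort_config(n_participants = 15, n_waves = 3,
                       dropout_rate_per_wave = 0, seed = 42)
  b1 <- generate_cohort(cfg, growth_spec(), trials = TRUE)
  b2 <- generate_cohort(cfg, growth_spec(), trials = TRUE)
  expect_identical(b1$cohort, b2$cohort)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$trials[["P003"]][["2"]], b2$trials[["P003"]][["2"]])
  # no dropout: every participant has exactly n_waves records
  expect_true(all(table(b1$cohort$participant) == 3))
  # age strictly increasing within participant
  for (p in unique(b1$cohort$participant)) {
    ages <- b1$cohort$age[b1$cohort$participant == p]
    expect_true(all(diff(ages) > 0))
  }
  # observable tables carry no ground-truth columns
  expect_false(any(grepl("eta_|maturity_offset", names(b1$cohort))))
  cfg2 <- cohort_config(n_participants = 30, dropout_rate_per_wave = 0.3,
                        seed = 9)
  b3 <- generate_cohort(cfg2, growth_spec(), trials = FALSE)
  expect_lte(nrow(b3$cohort), 90)
  # dropout is monotone: wave indices per participant are 1..k
  for (p in unique(b3$cohort$participant)) {
    w <- sort(b3$cohort$wave[b3$cohort$participant == p])
    expect_identical(w, seq_along(w))
  }
})

test_that("positive ICLF age slope induces a positive age correlation", {
  rs <- vapply(1:5, function(s) {
    b <- generate_cohort(cohort_config(n_participants = 141, seed = s),
                         growth_spec(), trials = FALSE)
    cor(b$cohort$age, b$truth$eta_ICLF)
  }, numeric(1))
  expect_true(all(rs > 0))
})

test_that("CPT sessions invert the signal-detection equations", {
  expect_error(generate_cpt_session(NaN, 0), "finite")
  expect_error(generate_cpt_session(0, 0.5), "ln_beta")
  z0 <- cogmaturity:::sdt_invert(0, 0)
  expect_equal(unname(pnorm(z0)), c(0.5, 0.5))
  z2 <- cogmaturity:::sdt_invert(2, 0)
  expect_equal(unname(pnorm(z2)), c(pnorm(1), pnorm(-1)), tolerance = 1e-12)
  # asymmetric target round-trips through the scoring formulas
  z <- cogmaturity:::sdt_invert(1.3, 0.4)
  expect_equal(unname(z["zH"] - z["zF"]), 1.3)
  expect_equal(unname(0.5 * (z["zF"]^2 - z["zH"]^2)), 0.4)

  set.seed(5)
  s <- generate_cpt_session(1.5, 0.2)
  expect_identical(nrow(s), 150L)
  expect_identical(sum(s$stimulus == "lure"), 27L)
  expect_identical(as.integer(table(s$block)), rep(30L, 5))
  expect_true(all(is.na(s$rt_ms[!s$responded])))
})

test_that("mean scored d-prime matches the generator target over many sessions", {
  set.seed(7)
  d <- vapply(1:200, function(i) {
    score_cpt(generate_cpt_session(1, 0))$d_prime
  }, numeric(1))
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 1), 4 * se)
  # RT targets are recovered too
  set.seed(8)
  rts <- vapply(1:100, function(i) {
    score_cpt(generate_cpt_session(2, 0,
      rt_params = list(hit_rt_mean = 400, hit_rt_sd = 120,
                       fa_rt_mean = 350, fa_rt_sd = 140)))$hit_rt_sd
  }, numeric(1))
  expect_lt(abs(mean(rts) - 120), 4 * sd(rts) / sqrt(length(rts)) + 2)
})

test_that("WOF sessions obey the wheel design", {
  set.seed(11)
  s <- generate_wof_session(p_high_risk = 0, timeout_rate = 0)
  expect_identical(nrow(s), 90L)
  expect_true(all(s$choice == "low_risk"))
  n1090 <- sum(s$split == "10:90")
  expect_gte(n1090, 32); expect_lte(n1090, 42)
  expect_gte(90 - n1090, 48); expect_lte(90 - n1090, 58)
  # expected value of a winning selection is equal across risk levels
  w <- cogmaturity:::wof_wheels()
  expect_equal(w$p_win_high * w$high_amount, w$p_win_low * w$low_amount)
  # timeouts lose the higher dollar amount
  set.seed(12)
  s2 <- generate_wof_session(0.5, timeout_rate = 1)
  expect_true(all(s2$choice == "timeout"))
  expect_equal(s2$payoff, -pmax(s2$high_amount, s2$low_amount))
  # cumulative winnings reset per run and accumulate payoffs
  set.seed(13)
  s3 <- generate_wof_session(0.5, timeout_rate = 0.1)
  for (r in 1:3) {
    sub <- s3[s3$run == r, ]
    expect_equal(sub$cumulative, cumsum(sub$payoff))
  }
})

test_that("EFR sessions control block accuracies", {
  set.seed(21)
  s <- generate_efr_session(neg_acc = 0.6, pos_acc = 1)
  expect_identical(nrow(s), 70L)
  expect_true(all(table(s$true_emotion) == 10))
  hap <- s$true_emotion == "happiness"
  expect_true(all(s$chosen_emotion[hap] == "happiness"))
  expect_true(all(s$chosen_emotion != "" & s$chosen_emotion %in%
                    cogmaturity:::efr_emotions()))
  # errors never repeat the true label
  wrong <- s$chosen_emotion != s$true_emotion
  expect_true(all(s$chosen_emotion[wrong] != s$true_emotion[wrong]))
})

test_that("TD sessions follow the responder's discount profile", {
  grid <- td_delay_grid()
  flat <- setNames(rep(10, 7), grid$label)
  s <- generate_td_session(flat, noise_scale = 0)
  expect_true(all(s$choice == "delayed"))
  expect_true(all(s$delayed_amount == 10))
  steep <- setNames(c(10, 9, 8, 6, 4, 2, 1), grid$label)
  s2 <- generate_td_session(steep, noise_scale = 0)
  yr <- s2[s2$delay_label == "1yr", ]
  expect_true(all(yr$choice[yr$immediate_amount > 1] == "immediate"))
  expect_true(all(yr$choice[yr$immediate_amount < 1] == "delayed"))
  expect_error(generate_td_session(setNames(rep(11, 7), grid$label)),
               "subjective values")
})

test_that("discount profiles reproduce a target AUC", {
  for (a in c(0.15, 0.4, 0.75, 0.97, 1)) {
    prof <- discount_profile_from_auc(a)
    expect_equal(compute_td_auc(prof), a, tolerance = 1e-6)
  }
})

test_that("scored TD AUC recovers the generating AUC within staircase resolution", {
  set.seed(31)
  targets <- runif(60, 0.15, 0.95)
  rec <- vapply(targets, function(a) {
    s <- generate_td_session(discount_profile_from_auc(a), noise_scale = 0)
    compute_td_auc(estimate_indifference_points(s)$points)
  }, numeric(1))
  # staircase grid resolution is ~\$0.16 on a \$10 scale per point
  expect_lt(max(abs(rec - targets)), 0.06)
  expect_gt(cor(rec, targets), 0.99)
})
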