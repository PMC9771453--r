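test_that("the unpenalized limit reproduces ordinary least squares", {
  set.seed(201)
  X <- matrix(rnorm(40 * 4), 40)
  colnames(X) <- paste0("F", 1:4)
  y <- drop(X %*% c(1, -0.5, 0.3, 0)) + rnorm(40)
  cf <- ridge_loocv(X, y, 1e-12)$coef(1e-12)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(cf - ols)), 1e-8)
})

test_that("closed-form LOOCV equals explicit refits (row and participant level)", {
  set.seed(202)
  for (i in 1:10) {
    n <- sample(25:40, 1)
    X <- matrix(rnorm(n * 4), n)
    colnames(X) <- paste0("F", 1:4)
    y <- drop(X %*% rnorm(4)) + rnorm(n)
    lam <- 10^runif(3, -3, 0.5)
    expect_lt(max(abs(ridge_loocv(X, y, lam)$cv_mse -
                        ridge_loocv_brute(X, y, lam))), 1e-10)
    grp <- sample(rep(seq_len(ceiling(n / 3)), length.out = n))
    expect_lt(max(abs(ridge_loocv(X, y, lam, groups = grp)$cv_mse -
                        ridge_loocv_brute(X, y, lam, groups = grp))), 1e-10)
  }
})

test_that("training error is non-decreasing in lambda", {
  set.seed(203)
  X <- matrix(rnorm(60 * 4), 60)
  colnames(X) <- paste0("F", 1:4)
  y <- drop(X %*% c(1, -0.5, 0.3, 0.1)) + rnorm(60)
  lam <- 10^seq(-4, 1, length.out = 20)
  fit <- ridge_loocv(X, y, lam)
  train_mse <- vapply(lam, function(l) {
    cf <- fit$coef(l)
    mean((y - cf[1] - drop(X %*% cf[-1]))^2)
  }, numeric(1))
  expect_true(all(diff(train_mse) > -1e-10))
})

test_that("pure-noise predictors give no held-out skill", {
  set.seed(204)
  cfg <- age_model_config(alpha_grid = c(0, 1), n_lambda = 25, seed = 1)
  r2 <- vapply(1:100, function(i) {
    n_p <- 30
    pid <- rep(seq_len(n_p), each = 2)
    age <- rep(runif(n_p, 11, 14), each = 2) + rep(0:1, n_p) * 1.6
    X <- matrix(rnorm(2 * n_p * 4), ncol = 4,
                dimnames = list(NULL, paste0("F", 1:4)))
    cfg$seed <- i
    fit <- fit_regularized_age_model(X, age, pid, cfg)
    fit$test_r2
  }, numeric(1))
  expect_lte(quantile(r2, 0.95), 0.05)
})

test_that("the split respects participant clustering and the selection rule", {
  set.seed(205)
  n_p <- 50
  pid <- rep(sprintf("P%02d", seq_len(n_p)), each = 3)
  age <- rep(runif(n_p, 11, 14), each = 3) + rep(0:2, n_p) * 1.6
  X <- vapply(c(0.72, -0.22, 0.35, -0.16), function(b) {
    as.numeric(scale(b * age + rnorm(length(age), 0, 0.5)))
  }, numeric(length(age)))
  colnames(X) <- c("ICLF", "RRLF", "ENLF", "EPLF")
  fit <- fit_regularized_age_model(X, age, pid)
  expect_length(intersect(fit$train_participants, fit$test_participants), 0)
  expect_setequal(c(fit$train_participants, fit$test_participants),
                  unique(pid))
  # the chosen lambda attains the best CV R2 within its alpha, and no larger
  # lambda does better
  tab <- fit$cv_table
  best_row <- tab[tab$alpha == fit$alpha &
                    abs(tab$lambda - fit$lambda) < 1e-12, ]
  expect_equal(best_row$cv_r2, max(tab$cv_r2), tolerance = 1e-10)
  ties <- tab[tab$cv_r2 >= max(tab$cv_r2) - 1e-12, ]
  expect_lte(fit$lambda, min(ties$lambda) + 1e-12)
  expect_gt(fit$test_r2, 0.5)
})

test_that("predict_age behaves like a linear model in the scores", {
  set.seed(206)
  n_p <- 40
  pid <- rep(seq_len(n_p), each = 3)
  age <- rep(runif(n_p, 11, 14), each = 3) + rep(0:2, n_p) * 1.6
  X <- matrix(rnorm(length(age) * 4), ncol = 4,
              dimnames = list(NULL, paste0("F", 1:4)))
  X <- X + outer(scale(age)[, 1], c(0.8, -0.3, 0.4, -0.2))
  fit_base <- fit_regularized_age_model(X, age, pid,
                                        age_model_config(seed = 206))
  # centered predictors: prediction at zero scores is the training mean age
  tr_c <- as.character(pid) %in% fit_base$train_participants
  Xc <- sweep(X, 2, colMeans(X[tr_c, ]))
  fit_c <- fit_regularized_age_model(Xc, age, pid,
                                     age_model_config(seed = 206))
  stopifnot(identical(fit_c$train_participants, fit_base$train_participants))
  x0 <- matrix(0, 1, 4, dimnames = list(NULL, colnames(X)))
  expect_equal(unname(predict_age(fit_c, x0)), mean(age[tr_c]),
               tolerance = 1e-8)
  # affine equivariance: shifting all ages shifts predictions by the constant
  fit_s <- fit_regularized_age_model(X, age + 5, pid,
                                     age_model_config(seed = 206))
  expect_equal(predict_age(fit_s, X), predict_age(fit_base, X) + 5,
               tolerance = 1e-6)
  # manual dot product on the pinned coefficient vector
  cf <- fit_base$coefficients
  expect_equal(predict_age(fit_base, X[1:5, ]),
               cf[1] + drop(X[1:5, ] %*% cf[-1]), ignore_attr = TRUE)
  expect_error(predict_age(fit_base, X[, c(2, 1, 3, 4)]), "columns")
})

test_that("CMI definition, sign convention, and correlations", {
  expect_error(compute_cmi(1:3, 1:4), "length")
  cm <- compute_cmi(c(12, 13), c(12, 13))
  expect_equal(cm$cmi, c(0, 0))
  a <- compute_cmi(c(12, 14), c(13, 13))
  b <- compute_cmi(c(12, 14), c(13, 13),
                   sign_convention = "observed_minus_predicted")
  expect_equal(a$cmi, -b$cmi)
  expect_equal(a$cmi, c(-1, 1))

  set.seed(207)
  cmi <- compute_cmi(rnorm(80, 13), rnorm(80, 13))
  covs <- data.frame(self = cmi$cmi, noise = rnorm(80), const = rep(1, 80))
  rep_ <- correlate_cmi(cmi, covs)
  expect_equal(rep_$r[rep_$covariate == "self"], 1, tolerance = 1e-12)
  expect_true(is.na(rep_$r[rep_$covariate == "const"]))
  # textbook covariance / sd-ratio oracle
  r_manual <- cov(cmi$cmi, covs$noise) / (sd(cmi$cmi) * sd(covs$noise))
  expect_equal(rep_$r[rep_$covariate == "noise"], r_manual,
               tolerance = 1e-12)
  expect_match(attr(rep_, "clustering_caveat"), "repeated measures")
})

test_that("planted maturity offsets surface in the CMI with the right sign", {
  b <- generate_cohort(cohort_config(n_participants = 141, seed = 301),
                       strong_signal_growth(), trials = FALSE)
  im <- indicators_from_targets(b)$indicators
  fit <- fit_cfa(default_measurement_spec("sem"), im, se = FALSE, factr = 1e9)
  sc <- extract_factor_scores(fit, im)
  af <- fit_regularized_age_model(sc, im$info$age, im$info$participant,
                                  age_model_config(seed = 302))
  cmi <- compute_cmi(predict_age(af, sc), im$info$age,
                     participant = im$info$participant)
  pd <- tapply(b$truth$maturity_offset, b$truth$participant, mean)
  pc <- tapply(cmi$cmi, cmi$participant, function(v) mean(v, na.rm = TRUE))
  common <- intersect(names(pd), names(pc))
  ct <- cor.test(pd[common], pc[common])
  expect_gt(ct$estimate, 0.5)
  expect_lt(ct$p.value, 1e-6)
  # a covariate generated to oppose maturity correlates negatively
  rep_ <- correlate_cmi(cmi, im$info[, "bmi", drop = FALSE])
  expect_lt(rep_$r, 0)
})
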