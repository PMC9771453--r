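table2_loadings <- c(0.650, -0.503, -0.913, -0.371, 0.193)

test_that("exact-fit moment input is a fixed point of the estimator", {
  ind <- paste0("x", 1:5)
  spec <- measurement_spec(list(F1 = ind))
  Sigma <- tcrossprod(table2_loadings) + diag(1 - table2_loadings^2)
  dimnames(Sigma) <- list(ind, ind)
  fit <- fit_cfa(spec, list(cov = Sigma, mean = rep(0, 5), n = 1000),
                 se = FALSE, factr = 10)
  est <- fit$parameters$estimate[fit$parameters$type == "loading"]
  expect_lt(max(abs(est - table2_loadings)), 1e-4)
  expect_lt(fit$fit_indices$chisq, 1e-4)
  expect_equal(fit$fit_indices$cfi, 1)
  expect_equal(fit$fit_indices$rmsea, 0)
})

test_that("loadings are recovered from simulated data within Monte-Carlo error", {
  set.seed(101)
  d <- simulate_factor_data(1500, table2_loadings)
  spec <- measurement_spec(list(F1 = colnames(d$Y)))
  fit <- fit_cfa(spec, d$Y)
  lt <- fit$parameters[fit$parameters$type == "loading", ]
  expect_true(all(sign(lt$estimate) == sign(table2_loadings)))
  expect_true(all(abs(lt$estimate - table2_loadings) < 4 * lt$se))
})

test_that("complete-data FIML equals the ordinary multivariate-normal log-likelihood", {
  set.seed(102)
  d <- simulate_factor_data(200, c(0.7, 0.6, 0.8))
  spec <- measurement_spec(list(F1 = colnames(d$Y)))
  fit <- fit_cfa(spec, d$Y, se = FALSE)
  S <- fit$est$Sigma
  mu <- fit$est$mu
  n <- nrow(d$Y)
  md <- stats::mahalanobis(d$Y, mu, S)
  ll_manual <- -0.5 * sum(md) - n / 2 * (3 * log(2 * pi) +
                                           determinant(S)$modulus[1])
  expect_equal(fit$loglik, ll_manual, tolerance = 1e-8)
})

test_that("FIML under MCAR missingness tracks the complete-data estimates", {
  set.seed(103)
  d <- simulate_factor_data(1200, table2_loadings)
  spec <- measurement_spec(list(F1 = colnames(d$Y)))
  full <- fit_cfa(spec, d$Y, se = FALSE)
  Ym <- d$Y
  Ym[sample(length(Ym), round(0.3 * length(Ym)))] <- NA
  miss <- fit_cfa(spec, Ym)
  lt_f <- full$parameters$estimate[full$parameters$type == "loading"]
  lt_m <- miss$parameters[miss$parameters$type == "loading", ]
  expect_true(all(abs(lt_m$estimate - lt_f) < 4 * lt_m$se))
  # likelihood at the solution is at least that at the generating parameters
  gen <- list(mu = rep(0, 5),
              Lambda = matrix(table2_loadings, 5, 1,
                              dimnames = list(colnames(d$Y), "F1")),
              Psi = matrix(1, 1, 1),
              Theta = diag(1 - table2_loadings^2))
  expect_gte(miss$loglik, latent_model_loglik(gen, Ym))
})

test_that("fit indices match their closed forms on pinned values", {
  # exact fit limit
  f0 <- compute_fit_indices(40, 40, 500, 55, 300)
  expect_equal(f0$rmsea, 0)
  expect_equal(f0$cfi, 1)
  # pinned triple against the formulas computed by hand
  f <- compute_fit_indices(50, 40, 500, 55, 300)
  expect_equal(f$rmsea, sqrt((50 - 40) / (40 * 299)))
  expect_equal(f$cfi, 1 - (50 - 40) / (500 - 55))
  expect_equal(f$tli, ((500 / 55) - (50 / 40)) / ((500 / 55) - 1))
  expect_equal(f$p, pchisq(50, 40, lower.tail = FALSE))
  expect_equal(f$rmsea_pclose,
               pchisq(50, 40, ncp = 0.05^2 * 40 * 299, lower.tail = FALSE))
  # chisq/df < 1 can push TLI above 1
  f2 <- compute_fit_indices(35, 40, 500, 55, 300)
  expect_gt(f2$tli, 1)
  # df = 0 reports indices as undefined
  f3 <- compute_fit_indices(5, 0, 500, 55, 300)
  expect_true(is.na(f3$rmsea) && is.na(f3$cfi))
})

test_that("factor scores: identity limit and the closed-form linear algebra", {
  spec1 <- suppressWarnings(measurement_spec(list(F1 = "x1")))
  fit1 <- list(spec = spec1,
               est = list(mu = c(x1 = 0),
                          Lambda = matrix(1, 1, 1,
                                          dimnames = list("x1", "F1")),
                          Psi = matrix(1, 1, 1),
                          Theta = matrix(1e-10, 1, 1,
                                         dimnames = list("x1", "x1"))))
  y <- matrix(c(-1.3, 0.2, 2.1), 3, 1, dimnames = list(NULL, "x1"))
  sc <- extract_factor_scores(fit1, y, standardize = FALSE)
  expect_equal(drop(sc), drop(y), tolerance = 1e-6, ignore_attr = TRUE)

  set.seed(104)
  d <- simulate_factor_data(300, c(0.7, 0.6, 0.8, 0.5))
  spec <- measurement_spec(list(F1 = colnames(d$Y)))
  fit <- fit_cfa(spec, d$Y, se = FALSE)
  sc2 <- extract_factor_scores(fit, d$Y, standardize = FALSE)
  A <- fit$est$Psi %*% t(fit$est$Lambda) %*% solve(fit$est$Sigma)
  manual <- sweep(d$Y, 2, fit$est$mu) %*% t(A)
  expect_equal(drop(sc2), drop(manual), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("factor scores recover the true factor", {
  set.seed(105)
  d <- simulate_factor_data(1000, table2_loadings)
  spec <- measurement_spec(list(F1 = colnames(d$Y)))
  fit <- fit_cfa(spec, d$Y, se = FALSE)
  sc <- extract_factor_scores(fit, d$Y)
  expect_gte(cor(d$eta, sc[, "F1"]), 0.8)
  # Bartlett scores agree up to scaling on complete data
  scb <- extract_factor_scores(fit, d$Y, method = "bartlett")
  expect_gt(cor(sc[, 1], scb[, 1]), 0.999)
  # all-missing rows get NA scores
  Ym <- d$Y[1:50, ]
  Ym[1, ] <- NA
  scm <- extract_factor_scores(fit, Ym, standardize = FALSE)
  expect_true(is.na(scm[1, "F1"]))
  expect_identical(unname(attr(scm, "n_unscored")["F1"]), 1)
})

test_that("a SEM with a single path reproduces the CFA factor covariance", {
  set.seed(106)
  n <- 400
  f1 <- rnorm(n); f2 <- 0.4 * f1 + rnorm(n, 0, sqrt(1 - 0.16))
  lam <- c(0.7, 0.6, 0.8)
  Y <- cbind(
    vapply(lam, function(l) l * f1 + rnorm(n, 0, sqrt(1 - l^2)), numeric(n)),
    vapply(lam, function(l) l * f2 + rnorm(n, 0, sqrt(1 - l^2)), numeric(n)))
  colnames(Y) <- c(paste0("a", 1:3), paste0("b", 1:3))
  factors <- list(F1 = paste0("a", 1:3), F2 = paste0("b", 1:3))
  cfa <- fit_cfa(measurement_spec(factors), Y, se = FALSE, factr = 1e2)
  sem <- fit_sem(measurement_spec(factors), Y, se = FALSE,
                 paths = data.frame(from = "F1", to = "F2"))
  # implied standardized factor correlation agrees
  Psi_sem <- sem$est$Psi
  r_sem <- Psi_sem[1, 2] / sqrt(Psi_sem[1, 1] * Psi_sem[2, 2])
  expect_equal(r_sem, cfa$est$Psi[1, 2], tolerance = 0.01)
  expect_equal(sem$loglik, cfa$loglik, tolerance = 1e-3)
})

test_that("path recovery: a planted structural coefficient is estimated", {
  set.seed(107)
  n <- 2000
  f1 <- rnorm(n); f2 <- -0.22 * f1 + rnorm(n)
  lam <- c(0.7, 0.6, 0.8, 0.5)
  Y <- cbind(
    vapply(lam, function(l) l * f1 + rnorm(n, 0, sqrt(1 - l^2)), numeric(n)),
    vapply(lam, function(l) l * f2 + rnorm(n, 0, sqrt(1 - l^2)), numeric(n)))
  colnames(Y) <- c(paste0("a", 1:4), paste0("b", 1:4))
  sem <- fit_sem(measurement_spec(list(F1 = paste0("a", 1:4),
                                       F2 = paste0("b", 1:4))), Y,
                 se = FALSE, paths = data.frame(from = "F1", to = "F2"))
  path <- sem$parameters$estimate[sem$parameters$type == "path"]
  # disturbance variance is 1, so the standardized path is attenuated:
  # std path = -0.22 / sd(f2-model scale); compare on the standardized scale
  std_path <- sem$parameters$std_estimate[sem$parameters$type == "path"]
  expect_lt(abs(std_path - (-0.22 / sqrt(0.22^2 + 1))), 0.06)
})

test_that("the standardized solution is invariant to affine rescaling of an indicator", {
  set.seed(108)
  d <- simulate_factor_data(800, c(0.7, 0.6, 0.8, 0.5))
  spec <- measurement_spec(list(F1 = colnames(d$Y)))
  f1 <- fit_cfa(spec, d$Y, se = FALSE, factr = 1e2)
  Y2 <- d$Y
  Y2[, 2] <- 7 * Y2[, 2] - 3
  f2 <- fit_cfa(spec, Y2, se = FALSE, factr = 1e2)
  expect_equal(f2$parameters$std_estimate[1:4],
               f1$parameters$std_estimate[1:4], tolerance = 1e-4)
  expect_equal(f2$fit_indices$chisq, f1$fit_indices$chisq, tolerance = 1e-3)
})

test_that("measurement specs validate and serialize", {
  expect_error(measurement_spec(list(A = c("x", "y"), B = c("y", "z"))),
               "exactly one factor")
  expect_warning(measurement_spec(list(A = "x")), "under-identified")
  expect_error(
    measurement_spec(list(A = c("x", "y"), B = c("z", "w")),
                     paths = data.frame(from = "B", to = "A")),
    "acyclic")
  spec <- default_measurement_spec("sem")
  path <- tempfile(fileext = ".json")
  write_measurement_spec(spec, path)
  spec2 <- read_measurement_spec(path)
  expect_identical(spec2$factors, spec$factors)
  expect_identical(spec2$residual_cov, spec$residual_cov)
  expect_identical(spec2$paths$from, spec$paths$from)
  expect_identical(spec2$disturbance_cov, spec$disturbance_cov)
  unlink(path)
})
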