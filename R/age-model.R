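# Regularized age prediction from latent factor scores: exact ridge with
# closed-form (block) leave-one-out cross-validation, glmnet for the
# elastic-net/lasso mixing values, participant-clustered splitting and folds.

#' Age-model configuration
#'
#' @param alpha_grid elastic-net mixing values to search (0 = ridge,
#'   0.5 = elastic net, 1 = lasso).
#' @param n_lambda points on the regularization path.
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @param split_fraction fraction of participants assigned to the training
#'   split (all waves of a participant stay together).
#' @param loocv_unit `"participant"` (leave all waves of one training
#'   participant out per fold; avoids within-person leakage) or `"row"`.
#' @param seed integer seed for the split.
#' @return an `age_model_config` list.
#' @export
age_model_config <- function(alpha_grid = c(0, 0.5, 1), n_lambda = 100,
                             lambda_min_ratio = 1e-4, split_fraction = 0.5,
                             loocv_unit = c("participant", "row"), seed = 1L) {
  loocv_unit <- match.arg(loocv_unit)
  stopifnot(all(alpha_grid >= 0 & alpha_grid <= 1),
            split_fraction > 0, split_fraction < 1)
  structure(list(alpha_grid = alpha_grid, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 split_fraction = split_fraction, loocv_unit = loocv_unit,
                 seed = as.integer(seed)),
            class = "age_model_config")
}

# Exact ridge on the augmented design [1, X] with fixed penalty
# kappa * diag(0, 1, ..., 1): beta = (Z'Z + kappa D)^{-1} Z'y. The design is
# standardized once (columns of X to mean 0, SD 1); keeping the design fixed
# is what makes the hat-matrix LOOCV identity exact.
ridge_solve <- function(Z, y, kappa) {
  k <- ncol(Z)
  D <- diag(c(0, rep(1, k - 1)), k)
  solve(crossprod(Z) + kappa * D, crossprod(Z, y))
}

#' Exact ridge regression with closed-form grouped LOOCV
#'
#' Fits ridge regression (intercept unpenalized, predictors standardized once
#' on the input data) for each `lambda`, and computes the leave-one-group-out
#' cross-validation error by the hat-matrix identity
#' `e_S = (I - H_SS)^{-1} r_S` -- algebraically identical to refitting without
#' each group on the same standardized design. The penalty is
#' `kappa = n * lambda` on the squared-error objective `RSS + kappa ||beta||^2`.
#'
#' @param X numeric predictor matrix (no missing values).
#' @param y numeric response.
#' @param lambda numeric vector of penalties (on the mean-squared-error
#'   scale; internally scaled by `n`).
#' @param groups grouping vector for grouped LOOCV (default: each row its own
#'   group).
#' @return list with `lambda`, `cv_mse` (per lambda), `coef(lambda)` function
#'   returning named coefficients (intercept first, original predictor scale),
#'   and the standardization (`center`, `scale`).
#' @export
ridge_loocv <- function(X, y, lambda, groups = seq_len(nrow(X))) {
  X <- as.matrix(X)
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("constant predictor column")
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Z <- cbind(1, Xs)
  g <- split(seq_len(n), groups)
  cv_mse <- numeric(length(lambda))
  betas <- matrix(0, ncol(Z), length(lambda))
  for (li in seq_along(lambda)) {
    kappa <- n * lambda[li]
    k <- ncol(Z)
    D <- diag(c(0, rep(1, k - 1)), k)
    A_inv <- solve(crossprod(Z) + kappa * D)
    beta <- A_inv %*% crossprod(Z, y)
    betas[, li] <- beta
    r <- y - drop(Z %*% beta)
    ZAi <- Z %*% A_inv
    err2 <- 0
    for (idx in g) {
      Hss <- ZAi[idx, , drop = FALSE] %*% t(Z[idx, , drop = FALSE])
      e <- solve(diag(length(idx)) - Hss, r[idx])
      err2 <- err2 + sum(e^2)
    }
    cv_mse[li] <- err2 / n
  }
  coef_fun <- function(l) {
    li <- which.min(abs(lambda - l))
    b <- betas[, li]
    bx <- b[-1] / scl
    c(intercept = b[1] - sum(bx * ctr),
      stats::setNames(bx, colnames(X)))
  }
  list(lambda = lambda, cv_mse = cv_mse, coef = coef_fun,
       center = ctr, scale = scl)
}

#' Brute-force grouped LOOCV for ridge (oracle)
#'
#' Explicitly refits the ridge solution without each group (same standardized
#' design and same fixed penalty `kappa = n * lambda`) and averages squared
#' held-out errors. Used as the independent check of [ridge_loocv()].
#'
#' @inheritParams ridge_loocv
#' @return numeric vector of CV MSEs, one per lambda.
#' @export
ridge_loocv_brute <- function(X, y, lambda, groups = seq_len(nrow(X))) {
  X <- as.matrix(X)
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Z <- cbind(1, Xs)
  g <- split(seq_len(n), groups)
  vapply(lambda, function(l) {
    kappa <- n * l
    err2 <- 0
    for (idx in g) {
      beta <- ridge_solve(Z[-idx, , drop = FALSE], y[-idx], kappa)
      e <- y[idx] - drop(Z[idx, , drop = FALSE] %*% beta)
      err2 <- err2 + sum(e^2)
    }
    err2 / n
  }, numeric(1))
}

lambda_path <- function(X, y, alpha, n_lambda, lambda_min_ratio) {
  n <- nrow(X)
  Xs <- scale(X)
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(Xs, yc))) / (n * max(alpha, 0.001))
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Fit the regularized age-prediction model
#'
#' Splits participants into training and test halves (all waves of a
#' participant stay together), searches the (alpha, lambda) grid by
#' leave-one-participant-out cross-validation on the training split --
#' closed-form hat-matrix LOOCV for ridge (alpha = 0), explicit glmnet refits
#' otherwise -- selects the smallest lambda attaining the highest
#' cross-validated R-squared (`1 - cvMSE / Var(age)`), refits on the full
#' training split, and evaluates on the held-out split.
#'
#' @param scores matrix/data.frame of factor scores (columns = factors).
#' @param ages numeric chronological ages (years), aligned with `scores`.
#' @param participants participant id per row (clustering unit).
#' @param config an [age_model_config()].
#' @return an `age_model_fit`: `alpha`, `lambda`, `coefficients` (intercept +
#'   per-score, original score scale), `cv_table` (alpha, lambda, cv R2),
#'   `test_r2`, `test_mae_months`, `train_participants`, `test_participants`,
#'   `score_columns`.
#' @export
fit_regularized_age_model <- function(scores, ages, participants,
                                      config = age_model_config()) {
  X <- as.matrix(scores)
  stopifnot(nrow(X) == length(ages), length(participants) == length(ages))
  ok <- stats::complete.cases(X) & is.finite(ages)
  X <- X[ok, , drop = FALSE]
  y <- ages[ok]
  pid <- as.character(participants)[ok]

  set.seed(config$seed)
  ids <- unique(pid)
  n_train <- max(2, round(length(ids) * config$split_fraction))
  train_ids <- sort(sample(ids, n_train))
  test_ids <- setdiff(ids, train_ids)
  tr <- pid %in% train_ids
  if (sum(tr) < 20) stop("fewer than 20 person-waves in the training split")
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
  if (stats::var(ytr) == 0 || stats::var(yte) == 0) {
    stop("degenerate age variance in a split")
  }
  folds <- if (config$loocv_unit == "participant") pid[tr] else seq_len(sum(tr))

  cv_rows <- list()
  best <- list(r2 = -Inf)
  for (a in config$alpha_grid) {
    lam <- lambda_path(Xtr, ytr, a, config$n_lambda, config$lambda_min_ratio)
    if (a == 0) {
      cv <- ridge_loocv(Xtr, ytr, lam, groups = folds)
      mse <- cv$cv_mse
    } else {
      fold_ids <- unique(folds)
      pred <- matrix(NA_real_, sum(tr), length(lam))
      for (f in fold_ids) {
        hold <- folds == f
        gfit <- glmnet::glmnet(Xtr[!hold, , drop = FALSE], ytr[!hold],
                               alpha = a, lambda = lam)
        pred[hold, ] <- stats::predict(gfit, Xtr[hold, , drop = FALSE],
                                       s = lam)
      }
      mse <- colMeans((pred - ytr)^2)
    }
    r2 <- 1 - mse / mean((ytr - mean(ytr))^2)
    cv_rows[[length(cv_rows) + 1]] <-
      data.frame(alpha = a, lambda = lam, cv_mse = mse, cv_r2 = r2)
    # highest R2; ties broken by the smallest lambda
    cand <- which(r2 >= max(r2) - 1e-12)
    pick <- cand[which.min(lam[cand])]
    if (r2[pick] > best$r2 + 1e-12) {
      best <- list(r2 = r2[pick], alpha = a, lambda = lam[pick])
    }
  }
  cv_table <- do.call(rbind, cv_rows)

  if (best$alpha == 0) {
    fit <- ridge_loocv(Xtr, ytr, best$lambda, groups = folds)
    coefs <- fit$coef(best$lambda)
  } else {
    gfit <- glmnet::glmnet(Xtr, ytr, alpha = best$alpha, lambda = best$lambda)
    cf <- as.numeric(stats::coef(gfit, s = best$lambda))
    coefs <- c(intercept = cf[1], stats::setNames(cf[-1], colnames(X)))
  }
  pred_te <- coefs[1] + drop(Xte %*% coefs[-1])
  test_r2 <- 1 - mean((yte - pred_te)^2) / mean((yte - mean(yte))^2)
  test_mae_months <- mean(abs(yte - pred_te)) * 12

  structure(list(
    alpha = best$alpha, lambda = best$lambda, cv_r2 = best$r2,
    coefficients = coefs, cv_table = cv_table,
    test_r2 = test_r2, test_mae_months = test_mae_months,
    train_participants = train_ids, test_participants = test_ids,
    score_columns = colnames(X), train_mean_age = mean(ytr),
    config = config
  ), class = "age_model_fit")
}

#' Predict chronological age from factor scores
#'
#' @param fit an `age_model_fit`.
#' @param scores matrix/data.frame whose columns match the training score
#'   columns.
#' @return numeric vector of predicted ages in years.
#' @export
predict_age <- function(fit, scores) {
  X <- as.matrix(scores)
  if (is.null(colnames(X)) || !identical(colnames(X), fit$score_columns)) {
    stop("score columns do not match the training columns: expected ",
         paste(fit$score_columns, collapse = ", "))
  }
  drop(fit$coefficients[1] + X %*% fit$coefficients[-1])
}
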