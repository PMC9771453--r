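# Full-information maximum likelihood machinery: missingness-pattern
# sufficient statistics, the casewise multivariate-normal log-likelihood, the
# EM-fitted saturated model, and the independence (null) baseline.

# Group rows of Y (numeric matrix, NA = missing) by missingness pattern and
# return per-pattern sufficient statistics: observed column indices, count,
# mean vector, and the ML (divide-by-n) covariance of observed columns.
pattern_stats <- function(Y) {
  stopifnot(is.matrix(Y))
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  out <- lapply(split(seq_len(nrow(Y)), key), function(idx) {
    o <- which(obs[idx[1], ])
    Yo <- Y[idx, o, drop = FALSE]
    n_g <- length(idx)
    ybar <- colMeans(Yo)
    Yc <- sweep(Yo, 2, ybar)
    list(obs = o, n = n_g, mean = ybar, S = crossprod(Yc) / n_g, rows = idx)
  })
  attr(out, "n_total") <- nrow(Y)
  attr(out, "p") <- ncol(Y)
  out
}

# -2-free log-likelihood of (mu, Sigma) given pattern stats. Returns -Inf
# replacement (large penalty) if any observed submatrix is not PD.
fiml_loglik <- function(mu, Sigma, stats) {
  ll <- 0
  for (g in stats) {
    o <- g$obs
    k <- length(o)
    So <- Sigma[o, o, drop = FALSE]
    R <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    logdet <- 2 * sum(log(diag(R)))
    Sinv_S <- chol2inv(R)
    m <- g$mean - mu[o]
    quad <- sum(Sinv_S * g$S) + drop(t(m) %*% Sinv_S %*% m)
    ll <- ll - g$n / 2 * (k * log(2 * pi) + logdet + quad)
  }
  ll
}

# Saturated (unstructured) MVN model under missing data, fitted by EM.
# Complete data reduces to the closed-form MLE in one step.
fit_saturated_mvn <- function(stats, max_iter = 500, tol = 1e-10) {
  p <- attr(stats, "p")
  n <- attr(stats, "n_total")
  # initial values from available-case moments
  mu <- numeric(p); v <- numeric(p); cnt <- numeric(p)
  for (g in stats) {
    mu[g$obs] <- mu[g$obs] + g$n * g$mean
    v[g$obs] <- v[g$obs] + g$n * (diag(g$S) + g$mean^2)
    cnt[g$obs] <- cnt[g$obs] + g$n
  }
  if (any(cnt == 0)) stop("a variable is missing in every case")
  mu <- mu / cnt
  Sigma <- diag(pmax(v / cnt - mu^2, 1e-8), p)
  complete <- length(stats) == 1 && length(stats[[1]]$obs) == p
  if (complete) {
    mu <- stats[[1]]$mean
    Sigma <- stats[[1]]$S
    return(list(mu = mu, Sigma = Sigma,
                loglik = fiml_loglik(mu, Sigma, stats), iterations = 0L))
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (g in stats) {
      o <- g$obs
      m <- setdiff(seq_len(p), o)
      Soo_inv <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
      Eo <- g$mean                     # observed block expectation
      CPoo <- g$n * (g$S + tcrossprod(g$mean))  # sum of y_o y_o'
      T1[o] <- T1[o] + g$n * Eo
      T2[o, o] <- T2[o, o] + CPoo
      if (length(m)) {
        B <- Sigma[m, o, drop = FALSE] %*% Soo_inv   # regression of mis on obs
        mm <- mu[m] + B %*% (g$mean - mu[o])         # E[y_m] at pattern mean
        Cv <- Sigma[m, m, drop = FALSE] -
          B %*% Sigma[o, m, drop = FALSE]            # conditional covariance
        # sum over cases of E[y_m]: mu_m + B (y_o - mu_o)
        T1[m] <- T1[m] + g$n * drop(mm)
        # cross moments: sum E[y_m y_o'] = B * sum(y_o y_o') + (mu_m - B mu_o) sum(y_o)'
        a <- mu[m] - B %*% mu[o]
        Smo <- B %*% CPoo + a %*% t(g$n * Eo)
        T2[m, o] <- T2[m, o] + Smo
        T2[o, m] <- T2[o, m] + t(Smo)
        # sum E[y_m y_m'] = B sum(y_o y_o') B' + B sum(y_o) a' + a sum(y_o)' B' + n a a' + n Cv
        so <- g$n * Eo
        T2[m, m] <- T2[m, m] + B %*% CPoo %*% t(B) +
          B %*% so %*% t(a) + a %*% t(so) %*% t(B) +
          g$n * (a %*% t(a) + Cv)
      }
    }
    mu <- T1 / n
    Sigma <- T2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- fiml_loglik(mu, Sigma, stats)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      return(list(mu = mu, Sigma = Sigma, loglik = ll, iterations = it))
    }
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll_old, iterations = max_iter)
}

# Independence baseline: zero loadings / covariances, free means and
# variances. With a diagonal covariance the FIML likelihood decouples per
# column, so the MLE is the per-column observed-case mean and ML variance.
fit_null_mvn <- function(stats) {
  p <- attr(stats, "p")
  mu <- numeric(p); ssq <- numeric(p); cnt <- numeric(p)
  for (g in stats) {
    mu[g$obs] <- mu[g$obs] + g$n * g$mean
    cnt[g$obs] <- cnt[g$obs] + g$n
  }
  mu <- mu / cnt
  for (g in stats) {
    o <- g$obs
    ssq[o] <- ssq[o] + g$n * (diag(g$S) + (g$mean - mu[o])^2)
  }
  v <- ssq / cnt
  Sigma <- diag(v, p)
  list(mu = mu, Sigma = Sigma, loglik = fiml_loglik(mu, Sigma, stats),
       n_free = 2 * p)
}
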