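# Confirmatory factor / structural equation models estimated by FIML with
# unit-variance latent identification, fit indices against the independence
# baseline, and regression factor scores.

# ---- parameter layout ------------------------------------------------------

par_layout <- function(spec) {
  ind <- spec$indicators
  fac <- names(spec$factors)
  p <- length(ind); m <- length(fac)
  n_lambda <- length(ind)
  lambda_map <- do.call(rbind, lapply(seq_along(fac), function(fi) {
    data.frame(ind = match(spec$factors[[fi]], ind), fac = fi)
  }))
  has_paths <- !is.null(spec$paths)
  n_beta <- if (has_paths) nrow(spec$paths) else 0L
  n_dcov <- length(spec$disturbance_cov)
  n_psi <- if (!has_paths && spec$factor_cov == "free" && m > 1) {
    m * (m - 1) / 2
  } else 0L
  n_rcov <- length(spec$residual_cov)
  sizes <- c(mu = p, lambda = n_lambda, logsd = p, rcov = n_rcov,
             beta = n_beta, dcov = n_dcov, psi = n_psi)
  offs <- cumsum(c(0, sizes))[seq_along(sizes)]
  names(offs) <- names(sizes)
  idx <- lapply(names(sizes), function(b) {
    if (sizes[b] == 0) integer(0) else offs[b] + seq_len(sizes[b])
  })
  names(idx) <- names(sizes)
  rcov_ij <- lapply(spec$residual_cov, function(rc) match(rc, ind))
  dcov_ij <- lapply(spec$disturbance_cov, function(dc) match(dc, fac))
  beta_ij <- if (has_paths) {
    cbind(to = match(spec$paths$to, fac), from = match(spec$paths$from, fac))
  } else NULL
  list(spec = spec, p = p, m = m, n_par = sum(sizes), idx = idx,
       lambda_map = lambda_map, rcov_ij = rcov_ij, dcov_ij = dcov_ij,
       beta_ij = beta_ij, has_paths = has_paths,
       psi_free = n_psi > 0)
}

# Row-normalized Cholesky parameterization of a correlation matrix: z fills
# the strict lower triangle row by row; each row (z_i1..z_i,i-1, 1) is scaled
# to unit length.
corr_from_z <- function(z, m) {
  L <- diag(m)
  k <- 0L
  for (i in seq_len(m)[-1]) {
    w <- c(z[k + seq_len(i - 1)], 1)
    k <- k + i - 1L
    L[i, seq_len(i)] <- w / sqrt(sum(w^2))
  }
  tcrossprod(L)
}

z_from_corr <- function(R) {
  m <- nrow(R)
  L <- t(chol(R))
  z <- numeric(0)
  for (i in seq_len(m)[-1]) {
    z <- c(z, L[i, seq_len(i - 1)] / L[i, i])
  }
  z
}

# Build model matrices from a parameter vector.
build_model <- function(theta, layout) {
  p <- layout$p; m <- layout$m
  mu <- theta[layout$idx$mu]
  Lambda <- matrix(0, p, m,
                   dimnames = list(layout$spec$indicators,
                                   names(layout$spec$factors)))
  lam <- theta[layout$idx$lambda]
  Lambda[cbind(layout$lambda_map$ind, layout$lambda_map$fac)] <- lam
  sds <- exp(theta[layout$idx$logsd])
  Theta <- diag(sds^2, p)
  dimnames(Theta) <- list(layout$spec$indicators, layout$spec$indicators)
  if (length(layout$idx$rcov)) {
    zz <- theta[layout$idx$rcov]
    for (k in seq_along(layout$rcov_ij)) {
      ij <- layout$rcov_ij[[k]]
      Theta[ij[1], ij[2]] <- Theta[ij[2], ij[1]] <-
        tanh(zz[k]) * sds[ij[1]] * sds[ij[2]]
    }
  }
  B <- matrix(0, m, m, dimnames = list(names(layout$spec$factors),
                                       names(layout$spec$factors)))
  Pz <- diag(m)
  dimnames(Pz) <- dimnames(B)
  if (layout$has_paths) {
    B[layout$beta_ij] <- theta[layout$idx$beta]
    if (length(layout$idx$dcov)) {
      zz <- theta[layout$idx$dcov]
      for (k in seq_along(layout$dcov_ij)) {
        ij <- layout$dcov_ij[[k]]
        Pz[ij[1], ij[2]] <- Pz[ij[2], ij[1]] <- tanh(zz[k])
      }
    }
    IB <- solve(diag(m) - B)
    Psi <- IB %*% Pz %*% t(IB)
  } else if (layout$psi_free) {
    Psi <- corr_from_z(theta[layout$idx$psi], m)
    dimnames(Psi) <- dimnames(B)
  } else {
    Psi <- Pz
  }
  Sigma <- Lambda %*% Psi %*% t(Lambda) + Theta
  names(mu) <- layout$spec$indicators
  list(mu = mu, Lambda = Lambda, Theta = Theta, Psi = Psi, B = B, Pz = Pz,
       Sigma = (Sigma + t(Sigma)) / 2)
}

# Inverse of build_model for the canonical-sign transform.
theta_from_model <- function(model, layout) {
  theta <- numeric(layout$n_par)
  theta[layout$idx$mu] <- model$mu
  theta[layout$idx$lambda] <-
    model$Lambda[cbind(layout$lambda_map$ind, layout$lambda_map$fac)]
  sds <- sqrt(diag(model$Theta))
  theta[layout$idx$logsd] <- log(sds)
  if (length(layout$idx$rcov)) {
    theta[layout$idx$rcov] <- vapply(layout$rcov_ij, function(ij) {
      atanh(model$Theta[ij[1], ij[2]] / (sds[ij[1]] * sds[ij[2]]))
    }, numeric(1))
  }
  if (layout$has_paths) {
    theta[layout$idx$beta] <- model$B[layout$beta_ij]
    if (length(layout$idx$dcov)) {
      theta[layout$idx$dcov] <- vapply(layout$dcov_ij, function(ij) {
        atanh(model$Pz[ij[1], ij[2]])
      }, numeric(1))
    }
  } else if (layout$psi_free) {
    theta[layout$idx$psi] <- z_from_corr(model$Psi)
  }
  theta
}

neg_loglik <- function(theta, layout, stats) {
  model <- tryCatch(build_model(theta, layout), error = function(e) NULL)
  if (is.null(model) || any(!is.finite(model$Sigma))) return(1e10)
  ll <- fiml_loglik(model$mu, model$Sigma, stats)
  if (!is.finite(ll)) return(1e10)
  -ll
}

# ---- input coercion --------------------------------------------------------

as_pattern_stats <- function(data, spec) {
  ind <- spec$indicators
  if (inherits(data, "indicator_matrix")) {
    Y <- data$data[, ind, drop = FALSE]
  } else if (is.list(data) && !is.data.frame(data) &&
             all(c("cov", "n") %in% names(data))) {
    S <- as.matrix(data$cov)
    if (!is.null(colnames(S))) S <- S[ind, ind, drop = FALSE]
    mn <- if (!is.null(data$mean)) {
      if (!is.null(names(data$mean))) data$mean[ind] else data$mean
    } else rep(0, length(ind))
    if (identical(data$cov_type, "unbiased")) S <- S * (data$n - 1) / data$n
    st <- list(list(obs = seq_along(ind), n = data$n, mean = as.numeric(mn),
                    S = S, rows = integer(0)))
    attr(st, "n_total") <- data$n
    attr(st, "p") <- length(ind)
    return(st)
  } else {
    Y <- as.matrix(as.data.frame(data)[, ind, drop = FALSE])
  }
  pattern_stats(Y)
}

# data-driven starting values: loading signs from pairwise covariance with
# each factor's first indicator.
start_values <- function(layout, stats) {
  p <- layout$p
  # pooled available-case means and variances
  mu <- numeric(p); v <- rep(1, p); cnt <- numeric(p)
  C <- matrix(0, p, p); Ccnt <- matrix(0, p, p)
  for (g in stats) {
    o <- g$obs
    mu[o] <- mu[o] + g$n * g$mean
    cnt[o] <- cnt[o] + g$n
    C[o, o] <- C[o, o] + g$n * g$S
    Ccnt[o, o] <- Ccnt[o, o] + g$n
  }
  mu <- ifelse(cnt > 0, mu / cnt, 0)
  Cav <- ifelse(Ccnt > 0, C / pmax(Ccnt, 1), 0)
  v <- pmax(diag(Cav), 1e-4)
  theta <- numeric(layout$n_par)
  theta[layout$idx$mu] <- mu
  theta[layout$idx$logsd] <- log(sqrt(v) * 0.75)
  lam <- numeric(nrow(layout$lambda_map))
  for (fi in seq_along(layout$spec$factors)) {
    rows <- which(layout$lambda_map$fac == fi)
    first <- layout$lambda_map$ind[rows[1]]
    for (r in rows) {
      j <- layout$lambda_map$ind[r]
      s <- if (j == first) 1 else sign(Cav[j, first])
      if (s == 0) s <- 1
      lam[r] <- 0.5 * s * sqrt(v[j])
    }
  }
  theta[layout$idx$lambda] <- lam
  theta
}

# Warm start for multi-factor models: fit each factor's measurement block
# separately (small, fast) and seed the joint model with those loadings,
# residual parameters, and means.
warm_start_values <- function(spec, data, layout, theta0) {
  ind <- spec$indicators
  for (f in names(spec$factors)) {
    sub_ind <- spec$factors[[f]]
    # plain congeneric sub-model: residual covariances excluded so short
    # factors stay identified
    sub_spec <- suppressWarnings(
      measurement_spec(stats::setNames(list(sub_ind), f)))
    sub_fit <- suppressWarnings(
      fit_cfa(sub_spec, data, se = FALSE, warm_start = FALSE, factr = 1e9))
    fi <- match(f, names(spec$factors))
    rows <- which(layout$lambda_map$fac == fi)
    jj <- layout$lambda_map$ind[rows]
    sub_jj <- match(ind[jj], sub_ind)
    theta0[layout$idx$lambda[rows]] <- sub_fit$est$Lambda[sub_jj, 1]
    theta0[layout$idx$mu[jj]] <- sub_fit$est$mu[sub_jj]
    theta0[layout$idx$logsd[jj]] <-
      log(sqrt(diag(sub_fit$est$Theta)[sub_jj]))
    if (length(layout$idx$rcov)) {
      for (k in seq_along(layout$rcov_ij)) {
        pair <- ind[layout$rcov_ij[[k]]]
        if (all(pair %in% sub_ind)) {
          si <- match(pair, sub_ind)
          sds <- sqrt(diag(sub_fit$est$Theta))
          theta0[layout$idx$rcov[k]] <- atanh(clip(
            sub_fit$est$Theta[si[1], si[2]] / (sds[si[1]] * sds[si[2]]),
            -0.99, 0.99))
        }
      }
    }
  }
  theta0
}

# canonical sign: the first indicator of every factor loads positively
canonicalize_signs <- function(model, layout) {
  flips <- rep(1, layout$m)
  for (fi in seq_len(layout$m)) {
    first <- layout$lambda_map$ind[which(layout$lambda_map$fac == fi)[1]]
    if (model$Lambda[first, fi] < 0) flips[fi] <- -1
  }
  if (all(flips == 1)) return(model)
  Fm <- diag(flips, layout$m)
  model$Lambda <- model$Lambda %*% Fm
  model$Psi <- Fm %*% model$Psi %*% Fm
  model$B <- Fm %*% model$B %*% Fm
  model$Pz <- Fm %*% model$Pz %*% Fm
  model
}

numeric_hessian <- function(fn, x, h_rel = 1e-4) {
  k <- length(x)
  h <- h_rel * (1 + abs(x))
  H <- matrix(0, k, k)
  f0 <- fn(x)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h[i]
    H[i, i] <- (fn(x + 2 * ei) - 2 * f0 + fn(x - 2 * ei)) / (4 * h[i]^2)
    if (i < k) for (j in seq((i + 1), k)) {
      ej <- numeric(k); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) -
           fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

numeric_jacobian <- function(fn, x, h_rel = 1e-6) {
  f0 <- fn(x)
  k <- length(x)
  J <- matrix(0, length(f0), k)
  for (i in seq_len(k)) {
    h <- h_rel * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

# Reported (raw-scale) parameter vector with labels: loadings, residual
# variances/covariances, structural paths, factor/disturbance correlations.
report_vector <- function(theta, layout, standardized = FALSE) {
  model <- build_model(theta, layout)
  ind <- layout$spec$indicators
  fac <- names(layout$spec$factors)
  D <- sqrt(diag(model$Sigma))
  Fs <- sqrt(diag(model$Psi))
  vals <- c(); labs <- c(); type <- c()
  for (r in seq_len(nrow(layout$lambda_map))) {
    j <- layout$lambda_map$ind[r]; fi <- layout$lambda_map$fac[r]
    v <- model$Lambda[j, fi]
    if (standardized) v <- v * Fs[fi] / D[j]
    vals <- c(vals, v)
    labs <- c(labs, paste0(fac[fi], "=~", ind[j]))
    type <- c(type, "loading")
  }
  th <- diag(model$Theta)
  if (standardized) th <- th / D^2
  vals <- c(vals, th)
  labs <- c(labs, paste0(ind, "~~", ind))
  type <- c(type, rep("residual_variance", length(ind)))
  for (k in seq_along(layout$rcov_ij)) {
    ij <- layout$rcov_ij[[k]]
    v <- model$Theta[ij[1], ij[2]]
    if (standardized) v <- v / (D[ij[1]] * D[ij[2]])
    vals <- c(vals, v)
    labs <- c(labs, paste0(ind[ij[1]], "~~", ind[ij[2]]))
    type <- c(type, "residual_covariance")
  }
  if (layout$has_paths) {
    for (k in seq_len(nrow(layout$beta_ij))) {
      toi <- layout$beta_ij[k, "to"]; fri <- layout$beta_ij[k, "from"]
      v <- model$B[toi, fri]
      if (standardized) v <- v * Fs[fri] / Fs[toi]
      vals <- c(vals, v)
      labs <- c(labs, paste0(fac[toi], "~", fac[fri]))
      type <- c(type, "path")
    }
    for (k in seq_along(layout$dcov_ij)) {
      ij <- layout$dcov_ij[[k]]
      vals <- c(vals, model$Pz[ij[1], ij[2]])
      labs <- c(labs, paste0(fac[ij[1]], "~~", fac[ij[2]]))
      type <- c(type, "disturbance_correlation")
    }
  } else if (layout$psi_free) {
    for (i in seq_len(layout$m - 1)) for (j in seq(i + 1, layout$m)) {
      v <- model$Psi[i, j]
      if (standardized) v <- v / (Fs[i] * Fs[j])
      vals <- c(vals, v)
      labs <- c(labs, paste0(fac[i], "~~", fac[j]))
      type <- c(type, "factor_covariance")
    }
  }
  list(values = vals, labels = labs, type = type)
}

# ---- fit indices -----------------------------------------------------------

#' Fit indices relative to the zero-loading baseline
#'
#' `RMSEA = sqrt(max(chisq - df, 0) / (df (n - 1)))` with a close-fit p-value
#' (epsilon0 = 0.05) from the noncentral chi-square;
#' `CFI = 1 - max(chisq - df, 0) / max(chisq0 - df0, chisq - df, 0)`;
#' `TLI = ((chisq0/df0) - (chisq/df)) / ((chisq0/df0) - 1)` (may exceed 1 when
#' chisq/df < 1).
#'
#' @param chisq,df likelihood-ratio statistic and degrees of freedom of the
#'   fitted model.
#' @param null_chisq,null_df the same for the independence baseline.
#' @param n number of person-waves.
#' @return list with `chisq`, `df`, `p`, `rmsea`, `rmsea_pclose`, `cfi`,
#'   `tli` (all NA with a note when `df == 0`).
#' @export
compute_fit_indices <- function(chisq, df, null_chisq, null_df, n) {
  if (df == 0) {
    return(list(chisq = chisq, df = 0L, p = NA_real_, rmsea = NA_real_,
                rmsea_pclose = NA_real_, cfi = NA_real_, tli = NA_real_,
                note = "df = 0: fit indices undefined"))
  }
  p_val <- stats::pchisq(chisq, df, lower.tail = FALSE)
  rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
  ncp_close <- 0.05^2 * df * (n - 1)
  pclose <- stats::pchisq(chisq, df, ncp = ncp_close, lower.tail = FALSE)
  denom <- max(null_chisq - null_df, chisq - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chisq - df, 0) / denom
  r0 <- null_chisq / null_df
  tli <- if (abs(r0 - 1) < 1e-12) NA_real_ else (r0 - chisq / df) / (r0 - 1)
  list(chisq = chisq, df = df, p = p_val, rmsea = rmsea,
       rmsea_pclose = pclose, cfi = cfi, tli = tli, note = NULL)
}

# ---- main fitting routine --------------------------------------------------

#' Fit a confirmatory factor or structural equation model by FIML
#'
#' Maximizes the casewise multivariate-normal log-likelihood summed over
#' missingness patterns (full-information maximum likelihood). Latent
#' (disturbance) variances are fixed to 1 for identification; all loadings,
#' indicator means, residual variances, specified residual covariances,
#' structural paths, and factor/disturbance correlations are free. Residual
#' variances are optimized on the log scale with a lower boundary (variance
#' 1e-6), so inadmissible negative estimates (Heywood cases) surface as
#' boundary warnings rather than negative variances. Standard errors come
#' from the observed information (numerical Hessian); standardized estimates
#' and their delta-method SEs are reported alongside.
#'
#' @param spec a [measurement_spec()].
#' @param data an `indicator_matrix`, a numeric matrix / data.frame with NA
#'   for missing entries, or a moment list `list(cov =, mean =, n =,
#'   cov_type = "ml"|"unbiased")`.
#' @param se compute standard errors (numerical Hessian; skip for speed in
#'   simulations).
#' @param max_iter optimizer iteration cap.
#' @param start optional starting parameter vector.
#' @param factr L-BFGS-B relative convergence tolerance (in units of machine
#'   precision; smaller is tighter).
#' @return a `latent_model_fit`: parameter table (`parameters`), matrices
#'   (`est`: `mu`, `Lambda`, `Theta`, `Psi`, `B`, `Sigma`), `loglik`,
#'   `fit_indices`, `convergence`, `n`, `n_free`, and the `spec`.
#' @export
fit_cfa <- function(spec, data, se = TRUE, max_iter = 2000, start = NULL,
                    factr = 1e7, warm_start = TRUE) {
  stopifnot(inherits(spec, "measurement_spec"))
  layout <- par_layout(spec)
  stats <- as_pattern_stats(data, spec)
  n <- attr(stats, "n_total")
  p <- attr(stats, "p")
  if (n < 5 * layout$n_par) {
    warning("fewer than 5 rows per free parameter (n = ", n, ", q = ",
            layout$n_par, "); estimates may be unstable")
  }
  theta0 <- if (is.null(start)) start_values(layout, stats) else start
  if (is.null(start) && warm_start && length(spec$factors) > 1) {
    theta0 <- tryCatch(
      warm_start_values(spec, data, layout, theta0),
      error = function(e) theta0)
  }
  lower <- rep(-Inf, layout$n_par)
  lower[layout$idx$logsd] <- log(1e-3)   # variance floor 1e-6
  opt <- stats::optim(theta0, neg_loglik, layout = layout, stats = stats,
                      method = "L-BFGS-B", lower = lower,
                      control = list(maxit = max_iter, factr = factr,
                                     pgtol = 1e-6))
  if (opt$convergence == 1) {
    stop("FIML optimization did not converge within ", max_iter,
         " iterations; final nll = ", format(opt$value),
         "; message: ", opt$message)
  }
  if (opt$convergence >= 52) {
    stop("FIML optimization failed: ", opt$message)
  }
  at_floor <- which(opt$par[layout$idx$logsd] <= log(1e-3) + 1e-6)
  if (length(at_floor)) {
    warning("Heywood case: residual variance at boundary for ",
            paste(spec$indicators[at_floor], collapse = ", "))
  }
  model <- canonicalize_signs(build_model(opt$par, layout), layout)
  theta_hat <- theta_from_model(model, layout)
  loglik <- -neg_loglik(theta_hat, layout, stats)

  sat <- fit_saturated_mvn(stats)
  nullm <- fit_null_mvn(stats)
  p_star <- p * (p + 3) / 2
  df <- p_star - layout$n_par
  df0 <- p_star - nullm$n_free
  chisq <- max(2 * (sat$loglik - loglik), 0)
  chisq0 <- max(2 * (sat$loglik - nullm$loglik), 0)
  fitidx <- compute_fit_indices(chisq, df, chisq0, df0, n)

  raw <- report_vector(theta_hat, layout, standardized = FALSE)
  std <- report_vector(theta_hat, layout, standardized = TRUE)
  params <- data.frame(label = raw$labels, type = raw$type,
                       estimate = raw$values, std_estimate = std$values,
                       se = NA_real_, z = NA_real_, p = NA_real_,
                       std_se = NA_real_, stringsAsFactors = FALSE)
  vcov_theta <- NULL
  if (se) {
    H <- numeric_hessian(function(th) neg_loglik(th, layout, stats), theta_hat)
    vcov_theta <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov_theta)) {
      Jr <- numeric_jacobian(function(th) {
        report_vector(th, layout, standardized = FALSE)$values
      }, theta_hat)
      Js <- numeric_jacobian(function(th) {
        report_vector(th, layout, standardized = TRUE)$values
      }, theta_hat)
      vr <- diag(Jr %*% vcov_theta %*% t(Jr))
      vs <- diag(Js %*% vcov_theta %*% t(Js))
      params$se <- sqrt(pmax(vr, 0))
      params$std_se <- sqrt(pmax(vs, 0))
      params$z <- params$estimate / params$se
      params$p <- 2 * stats::pnorm(-abs(params$z))
    } else {
      warning("observed information not invertible; SEs unavailable")
    }
  }
  structure(list(
    spec = spec, layout = layout, theta = theta_hat, est = model,
    parameters = params, loglik = loglik, saturated_loglik = sat$loglik,
    null_loglik = nullm$loglik, fit_indices = fitidx, n = n,
    n_free = layout$n_par, df = df, null_df = df0,
    convergence = list(code = opt$convergence, message = opt$message,
                       counts = opt$counts,
                       heywood = spec$indicators[at_floor]),
    vcov_theta = vcov_theta
  ), class = "latent_model_fit")
}

#' @rdname fit_cfa
#' @param paths optional data.frame (`from`, `to`) of structural paths added
#'   to `spec` before fitting.
#' @export
fit_sem <- function(spec, data, paths = NULL, se = TRUE, max_iter = 500) {
  if (!is.null(paths)) {
    spec <- measurement_spec(spec$factors, residual_cov = spec$residual_cov,
                             paths = paths, factor_cov = spec$factor_cov,
                             disturbance_cov = spec$disturbance_cov)
  }
  fit_cfa(spec, data, se = se, max_iter = max_iter)
}

#' @export
print.latent_model_fit <- function(x, ...) {
  cat("FIML latent variable model:", length(x$spec$factors), "factor(s),",
      length(x$spec$indicators), "indicators, n =", x$n, "\n")
  fi <- x$fit_indices
  cat(sprintf("chisq(%d) = %.3f, p = %.3f | RMSEA = %.3f (pclose = %.3f) | CFI = %.3f | TLI = %.3f\n",
              fi$df, fi$chisq, ifelse(is.na(fi$p), NaN, fi$p),
              fi$rmsea, fi$rmsea_pclose, fi$cfi, fi$tli))
  print(x$parameters[x$parameters$type %in%
                       c("loading", "path", "factor_covariance",
                         "disturbance_correlation"), ], digits = 3)
  invisible(x)
}

#' Log-likelihood of explicit model matrices on a dataset
#'
#' Evaluates the FIML log-likelihood of given model matrices (e.g. the
#' generating parameters of a simulation) on data, for optimizer sanity
#' checks.
#'
#' @param est list with `mu`, `Lambda`, `Psi`, `Theta` (as in a fit's `est`).
#' @param data matrix / data.frame / `indicator_matrix` with the indicator
#'   columns.
#' @return scalar log-likelihood.
#' @export
latent_model_loglik <- function(est, data) {
  ind <- rownames(est$Lambda)
  Y <- if (inherits(data, "indicator_matrix")) data$data[, ind, drop = FALSE]
       else as.matrix(as.data.frame(data)[, ind, drop = FALSE])
  stats <- pattern_stats(Y)
  Sigma <- est$Lambda %*% est$Psi %*% t(est$Lambda) + est$Theta
  fiml_loglik(est$mu, (Sigma + t(Sigma)) / 2, stats)
}

# ---- factor scores ---------------------------------------------------------

#' Extract latent factor scores
#'
#' Regression-method (conditional mean) scores computed per missingness
#' pattern from the fitted model's implied moments:
#' `E[eta | y_obs] = Psi Lambda_obs' Sigma_obs^{-1} (y_obs - mu_obs)`.
#' Bartlett (unbiased GLS) scores are available behind the `method` flag.
#' A person-wave with no observed indicator on a factor gets `NA` for that
#' factor. Scores are standardized to mean 0, SD 1 over person-waves unless
#' `standardize = FALSE`.
#'
#' @param fit a `latent_model_fit` (or any list with `est` and `spec`).
#' @param data the data the scores are computed for (same forms as
#'   [fit_cfa()], moment input excluded).
#' @param method `"regression"` (default) or `"bartlett"`.
#' @param standardize standardize score columns.
#' @return matrix of scores (rows = person-waves, columns = factors) with
#'   attributes `method` and `n_unscored` (per-factor count of all-missing
#'   rows).
#' @export
extract_factor_scores <- function(fit, data, method = c("regression", "bartlett"),
                                  standardize = TRUE) {
  method <- match.arg(method)
  est <- fit$est
  spec <- fit$spec
  ind <- spec$indicators
  Y <- if (inherits(data, "indicator_matrix")) data$data[, ind, drop = FALSE]
       else as.matrix(as.data.frame(data)[, ind, drop = FALSE])
  m <- ncol(est$Lambda)
  scores <- matrix(NA_real_, nrow(Y), m,
                   dimnames = list(rownames(Y), colnames(est$Lambda)))
  obs <- !is.na(Y)
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  Sigma <- est$Lambda %*% est$Psi %*% t(est$Lambda) + est$Theta
  for (kk in unique(key)) {
    rows <- which(key == kk)
    o <- which(obs[rows[1], ])
    if (length(o) == 0) next
    Lo <- est$Lambda[o, , drop = FALSE]
    resid <- sweep(Y[rows, o, drop = FALSE], 2, est$mu[o])
    if (method == "regression") {
      A <- est$Psi %*% t(Lo) %*% chol2inv(chol(Sigma[o, o, drop = FALSE]))
    } else {
      Th_inv <- chol2inv(chol(est$Theta[o, o, drop = FALSE]))
      M <- t(Lo) %*% Th_inv %*% Lo
      A <- tryCatch(solve(M) %*% t(Lo) %*% Th_inv, error = function(e) NULL)
      if (is.null(A)) {
        stop("Bartlett scores undefined for a missingness pattern ",
             "(singular Lambda' Theta^-1 Lambda)")
      }
    }
    sc <- resid %*% t(A)
    # factors with no observed indicator in this pattern stay NA
    loaded <- colSums(abs(Lo)) > 0
    sc[, !loaded] <- NA_real_
    scores[rows, ] <- sc
  }
  n_unscored <- colSums(is.na(scores))
  if (standardize) {
    for (j in seq_len(ncol(scores))) {
      s <- stats::sd(scores[, j], na.rm = TRUE)
      if (is.finite(s) && s > 0) {
        scores[, j] <- (scores[, j] - mean(scores[, j], na.rm = TRUE)) / s
      }
    }
  }
  attr(scores, "method") <- method
  attr(scores, "n_unscored") <- n_unscored
  scores
}
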