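# Shared fixtures, generated once per test run.

tiny_bundle <- make_fixtures("tiny")

# A random CPT-style trial table (counts vary; used for oracle equivalence).
random_cpt_table <- function(n_target = 123, n_lure = 27) {
  n <- n_target + n_lure
  stim <- sample(c(rep("target", n_target), rep("lure", n_lure)))
  responded <- stats::runif(n) < stats::runif(1, 0.05, 0.95)
  rt <- ifelse(responded, stats::runif(n, 200, 1500), NA_real_)
  data.frame(trial = seq_len(n), block = 1L, stimulus = stim,
             responded = responded, rt_ms = rt, stringsAsFactors = FALSE)
}

# Independent signal-detection oracle: recount the four cells and apply the
# formulas from first principles (with the same extreme-rate adjustment).
sdt_oracle <- function(trials) {
  hits <- sum(trials$stimulus == "target" & trials$responded)
  misses <- sum(trials$stimulus == "target" & !trials$responded)
  fas <- sum(trials$stimulus == "lure" & trials$responded)
  crs <- sum(trials$stimulus == "lure" & !trials$responded)
  nt <- hits + misses
  nl <- fas + crs
  h <- hits / nt
  f <- fas / nl
  if (h == 0) h <- 1 / (2 * nt)
  if (h == 1) h <- 1 - 1 / (2 * nt)
  if (f == 0) f <- 1 / (2 * nl)
  if (f == 1) f <- 1 - 1 / (2 * nl)
  zh <- stats::qnorm(h)
  zf <- stats::qnorm(f)
  list(d_prime = zh - zf, ln_beta = 0.5 * (zf^2 - zh^2))
}

# Fine-grid numerical integration of the linear interpolant of a normalized
# discounting curve (independent AUC oracle).
auc_grid_oracle <- function(t, v_norm, n_grid = 20001) {
  tt <- sort(unique(c(seq(min(t), max(t), length.out = n_grid), t)))
  vv <- stats::approx(t, v_norm, xout = tt)$y
  k <- length(tt)
  sum((tt[-1] - tt[-k]) * (vv[-1] + vv[-k]) / 2)
}

# simulate complete one-factor data from given loadings (unit factor, unit
# indicator variances)
simulate_factor_data <- function(n, loadings, names_ = paste0("x", seq_along(loadings))) {
  eta <- stats::rnorm(n)
  Y <- vapply(seq_along(loadings), function(j) {
    loadings[j] * eta + stats::rnorm(n, 0, sqrt(1 - loadings[j]^2))
  }, numeric(n))
  colnames(Y) <- names_
  list(Y = Y, eta = eta)
}
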