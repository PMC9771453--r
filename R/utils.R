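#' @keywords internal
"_PACKAGE"

# Deterministic substream seeds: one master seed fans out to named stages so
# adding a stage never perturbs the draws of an existing one.
substream_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer(((abs(master) %% 1000003) * 1009 + h) %% 2147483647)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Draw reaction times from a shifted lognormal
#'
#' Reaction times are drawn from a lognormal shifted by a fixed motor floor,
#' with the lognormal moments solved so the draws hit a configured mean and
#' standard deviation (in milliseconds).
#'
#' @param n number of draws.
#' @param mean_ms,sd_ms target mean and SD of the draws, in ms.
#' @param shift_ms motor non-decision floor in ms (default 150).
#' @return numeric vector of RTs in ms, all greater than `shift_ms`.
#' @export
rt_shifted_lognormal <- function(n, mean_ms, sd_ms, shift_ms = 150) {
  stopifnot(mean_ms > shift_ms, sd_ms > 0)
  m <- mean_ms - shift_ms
  s2 <- log(1 + sd_ms^2 / m^2)
  mu <- log(m) - s2 / 2
  shift_ms + stats::rlnorm(n, meanlog = mu, sdlog = sqrt(s2))
}

# z-score a vector ignoring NAs; errors on zero variance with the column name.
zscore_col <- function(x, name = "column") {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("indicator column '", name, "' has zero variance; cannot standardize")
  }
  (x - mean(x, na.rm = TRUE)) / s
}
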