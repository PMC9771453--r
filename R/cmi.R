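# The Cognitive Maturity Index and its covariate associations.

#' Compute the Cognitive Maturity Index
#'
#' CMI is the per-person-wave gap between model-predicted cognitive age and
#' chronological age. The default convention is `predicted - observed`, so a
#' positive CMI marks cognitive maturity in advance of the sample growth
#' curve; the reversed subtraction is available via `sign_convention`.
#'
#' @param predicted,observed aligned numeric vectors of ages (years).
#' @param participant,wave optional identifiers carried into the table.
#' @param sign_convention `"predicted_minus_observed"` (default) or
#'   `"observed_minus_predicted"`.
#' @return a `cmi_table` data.frame with `participant`, `wave`,
#'   `observed_age`, `predicted_age`, `cmi` (years).
#' @export
compute_cmi <- function(predicted, observed, participant = NULL, wave = NULL,
                        sign_convention = c("predicted_minus_observed",
                                            "observed_minus_predicted")) {
  sign_convention <- match.arg(sign_convention)
  if (length(predicted) != length(observed)) {
    stop("predicted and observed age vectors differ in length")
  }
  s <- if (sign_convention == "predicted_minus_observed") 1 else -1
  out <- data.frame(
    participant = if (is.null(participant)) seq_along(observed) else participant,
    wave = if (is.null(wave)) rep(1L, length(observed)) else wave,
    observed_age = observed, predicted_age = predicted,
    cmi = s * (predicted - observed),
    stringsAsFactors = FALSE
  )
  attr(out, "sign_convention") <- sign_convention
  class(out) <- c("cmi_table", "data.frame")
  out
}

#' Correlate the CMI with cohort covariates
#'
#' Pearson correlation (two-sided test) between CMI and each covariate over
#' person-waves. Repeated measures per participant are noted as a clustering
#' caveat but not adjusted for. Constant covariates yield NA.
#'
#' @param cmi a `cmi_table`.
#' @param covariates data.frame of covariates aligned with the CMI rows
#'   (numeric columns are correlated; others are skipped).
#' @return data.frame with `covariate`, `r`, `p`, `n`, carrying the attribute
#'   `clustering_caveat`.
#' @export
correlate_cmi <- function(cmi, covariates) {
  stopifnot(inherits(cmi, "cmi_table"), nrow(covariates) == nrow(cmi))
  num <- names(covariates)[vapply(covariates, is.numeric, logical(1))]
  rows <- lapply(num, function(v) {
    x <- covariates[[v]]
    ok <- is.finite(x) & is.finite(cmi$cmi)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(cmi$cmi[ok]) == 0) {
      return(data.frame(covariate = v, r = NA_real_, p = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(cmi$cmi[ok], x[ok], method = "pearson")
    data.frame(covariate = v, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "clustering_caveat") <-
    "person-waves are repeated measures within participant; p-values are unadjusted"
  out
}
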