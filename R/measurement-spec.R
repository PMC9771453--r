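#' Measurement / structural model specification
#'
#' Declares which indicators load on which latent factors, which residual
#' covariances are free, and (optionally) directed structural paths between
#' factors. Identification uses unit latent (co)variance: factor variances --
#' disturbance variances for endogenous factors -- are fixed to 1 and all
#' loadings estimated freely.
#'
#' @param factors named list mapping factor name to character vector of
#'   indicator names. No indicator may load on two factors.
#' @param residual_cov list of length-2 character vectors naming indicator
#'   pairs whose residual covariance is free.
#' @param paths optional data.frame with columns `from`, `to` giving directed
#'   factor paths (must be acyclic in the given factor order).
#' @param factor_cov for models without paths: `"free"` (all factor
#'   correlations estimated) or `"zero"`. With paths, exogenous/disturbance
#'   correlations listed in `disturbance_cov` are free instead.
#' @param disturbance_cov list of length-2 character vectors of factor pairs
#'   whose disturbance correlation is free (only with `paths`).
#' @return a `measurement_spec` object.
#' @export
measurement_spec <- function(factors, residual_cov = list(), paths = NULL,
                             factor_cov = c("free", "zero"),
                             disturbance_cov = list()) {
  factor_cov <- match.arg(factor_cov)
  stopifnot(is.list(factors), length(factors) >= 1, !is.null(names(factors)))
  ind <- unlist(factors, use.names = FALSE)
  if (anyDuplicated(ind)) {
    stop("an indicator may load on exactly one factor; duplicated: ",
         paste(unique(ind[duplicated(ind)]), collapse = ", "))
  }
  few <- names(factors)[vapply(factors, length, integer(1)) < 2]
  if (length(few)) {
    warning("factor(s) with fewer than 2 indicators may be under-identified: ",
            paste(few, collapse = ", "))
  }
  for (rc in residual_cov) {
    stopifnot(length(rc) == 2, all(rc %in% ind))
  }
  if (!is.null(paths)) {
    stopifnot(is.data.frame(paths), all(c("from", "to") %in% names(paths)),
              all(c(paths$from, paths$to) %in% names(factors)))
    ord <- match(paths$from, names(factors)) < match(paths$to, names(factors))
    if (!all(ord)) {
      stop("paths must be acyclic: each 'from' factor must precede its 'to' ",
           "factor in the factor list order")
    }
  }
  for (dc in disturbance_cov) {
    stopifnot(length(dc) == 2, all(dc %in% names(factors)))
  }
  structure(list(factors = factors, indicators = ind,
                 residual_cov = residual_cov, paths = paths,
                 factor_cov = factor_cov, disturbance_cov = disturbance_cov),
            class = "measurement_spec")
}

#' Default measurement specifications for the cognitive battery
#'
#' Returns the three per-domain measurement models (inhibitory control,
#' risk/reward, emotion recognition) and the combined structural model with
#' directed paths from inhibitory control onto the other three factors and a
#' free disturbance correlation between the two emotion factors. Free residual
#' covariances follow the fitted measurement structure of the study design
#' this package emulates (sensitivity with bias and with target-RT
#' variability; risky-choice probability with its RT and the two WOF RTs;
#' cross-valence EFR accuracy, mean-RT, and within-valence mean/SD RT pairs).
#'
#' @param which one of `"iclf"`, `"rrlf"`, `"efr"`, `"sem"`.
#' @return a [measurement_spec()].
#' @export
default_measurement_spec <- function(which = c("sem", "iclf", "rrlf", "efr")) {
  which <- match.arg(which)
  fi <- default_factor_indicators()
  rc_iclf <- list(c("cpt_dprime", "cpt_lnbeta"),
                  c("cpt_dprime", "cpt_hit_rt_sd"))
  rc_rrlf <- list(c("wof_p_highrisk", "wof_rt_high"),
                  c("wof_rt_low", "wof_rt_high"))
  rc_efr <- list(c("efr_neg_rt_mean", "efr_pos_rt_mean"),
                 c("efr_neg_acc", "efr_pos_acc"),
                 c("efr_neg_rt_mean", "efr_neg_rt_sd"),
                 c("efr_pos_rt_mean", "efr_pos_rt_sd"))
  switch(which,
    iclf = measurement_spec(fi["ICLF"], residual_cov = rc_iclf),
    rrlf = measurement_spec(fi["RRLF"], residual_cov = rc_rrlf),
    efr = measurement_spec(fi[c("ENLF", "EPLF")], residual_cov = rc_efr),
    sem = measurement_spec(
      fi, residual_cov = c(rc_iclf, rc_rrlf, rc_efr),
      paths = data.frame(from = "ICLF", to = c("RRLF", "ENLF", "EPLF"),
                         stringsAsFactors = FALSE),
      disturbance_cov = list(c("ENLF", "EPLF"))
    )
  )
}

#' Serialize / deserialize a measurement specification
#'
#' @param spec a [measurement_spec()].
#' @param path file path for the JSON representation.
#' @return `read_measurement_spec` returns a `measurement_spec`.
#' @export
write_measurement_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_measurement_spec
#' @export
read_measurement_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  factors <- lapply(x$factors, as.character)
  paths <- if (is.null(x$paths) || (is.data.frame(x$paths) && !nrow(x$paths)))
    NULL else as.data.frame(x$paths, stringsAsFactors = FALSE)
  rcov <- if (length(x$residual_cov)) {
    if (is.matrix(x$residual_cov)) {
      lapply(seq_len(nrow(x$residual_cov)), function(i) x$residual_cov[i, ])
    } else lapply(x$residual_cov, as.character)
  } else list()
  dcov <- if (length(x$disturbance_cov)) {
    if (is.matrix(x$disturbance_cov)) {
      lapply(seq_len(nrow(x$disturbance_cov)), function(i) x$disturbance_cov[i, ])
    } else lapply(x$disturbance_cov, as.character)
  } else list()
  measurement_spec(factors, residual_cov = rcov, paths = paths,
                   factor_cov = x$factor_cov, disturbance_cov = dcov)
}
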