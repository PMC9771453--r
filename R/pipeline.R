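# End-to-end pipeline: simulate -> score -> fit latent models -> fit age
# model -> CMI report, with a reproducible manifest.

#' Pipeline configuration
#'
#' Bundles the stage configurations. Every stage derives its seed
#' deterministically from the master seed via a named substream, so adding a
#' stage never perturbs earlier streams.
#'
#' @param cohort a [cohort_config()] (its `seed` is overridden from `seed`).
#' @param growth a [growth_spec()].
#' @param spec a [measurement_spec()] for the structural model.
#' @param age an [age_model_config()] (its `seed` is overridden from `seed`).
#' @param sign_convention CMI sign convention (see [compute_cmi()]).
#' @param outdir output directory.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            growth = growth_spec(),
                            spec = default_measurement_spec("sem"),
                            age = age_model_config(),
                            sign_convention = "predicted_minus_observed",
                            outdir = tempfile("cmi_run_"),
                            seed = 1L) {
  cohort$seed <- substream_seed(seed, "cohort")
  age$seed <- substream_seed(seed, "split")
  structure(list(cohort = cohort, growth = growth, spec = spec, age = age,
                 sign_convention = sign_convention, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration
#'
#' JSON round trip of all stage configurations (lossless up to numeric
#' printing, which is exact: digits are not truncated).
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  g <- unclass(config$growth)
  for (nm in c("intercepts", "age_slopes", "random_intercept_sd", "loadings",
               "residual_sd", "paths")) {
    g[[nm]] <- as.list(g[[nm]])   # keep names through JSON
  }
  x <- list(
    cohort = unclass(config$cohort), growth = g,
    spec = unclass(config$spec), age = unclass(config$age),
    sign_convention = config$sign_convention, outdir = config$outdir,
    seed = config$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- x$growth
  growth <- growth_spec(
    intercepts = unlist(g$intercepts), age_slopes = unlist(g$age_slopes),
    random_intercept_sd = unlist(g$random_intercept_sd),
    maturity_offset_sd = g$maturity_offset_sd,
    loadings = unlist(g$loadings), residual_sd = unlist(g$residual_sd),
    residual_cor = if (length(g$residual_cor)) g$residual_cor else list(),
    paths = unlist(g$paths),
    covariate_effects = lapply(seq_len(NROW(g$covariate_effects)), function(i) {
      as.list(g$covariate_effects[i, ])
    }),
    wave_cor = g$wave_cor
  )
  spec_tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(x$spec, spec_tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  spec <- read_measurement_spec(spec_tmp)
  unlink(spec_tmp)
  cfg <- pipeline_config(
    cohort = do.call(cohort_config, x$cohort[setdiff(names(x$cohort), "seed")]),
    growth = growth, spec = spec,
    age = do.call(age_model_config, x$age[setdiff(names(x$age), "seed")]),
    sign_convention = x$sign_convention, outdir = x$outdir, seed = x$seed
  )
  cfg
}

write_stage <- function(obj, path) {
  if (is.data.frame(obj)) {
    if (grepl("\\.tsv$", path)) {
      utils::write.table(obj, path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    } else {
      utils::write.csv(obj, path, row.names = FALSE)
    }
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  }
  path
}

#' Run the full CMI pipeline
#'
#' simulate -> score -> exclude -> indicator matrix -> structural model ->
#' factor scores -> age model -> CMI -> covariate correlations. All stage
#' outputs are written under `config$outdir` with MD5 checksums recorded in a
#' manifest; a stage error aborts with the stage name, persisting the outputs
#' of completed stages.
#'
#' @param config a [pipeline_config()].
#' @param se compute latent-model standard errors (slower).
#' @return invisibly, a list with the manifest and the in-memory stage
#'   objects (`bundle`, `indicators`, `sem_fit`, `scores`, `age_fit`, `cmi`,
#'   `correlations`).
#' @export
run_pipeline <- function(config, se = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest <- list(status = "error", failed_stage = name,
                       error = conditionMessage(e), files = files,
                       counts = counts)
      write_stage(manifest,
                  file.path(config$outdir, "manifest.json"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_lines <- c(sprintf("master seed: %d", config$seed))

  bundle <- stage("simulate", {
    generate_cohort(config$cohort, config$growth, trials = TRUE)
  })
  counts$generated_person_waves <- nrow(bundle$cohort)
  files <- c(files, write_cohort_bundle(bundle,
                                        file.path(config$outdir, "cohort")))

  summaries <- stage("score", score_cohort_bundle(bundle))
  excl <- stage("exclude", apply_exclusions(bundle$cohort))
  counts$excluded_participants <- nrow(excl$log)
  counts$excluded_person_waves <-
    counts$generated_person_waves - nrow(excl$cohort)
  counts$retained_person_waves <- nrow(excl$cohort)
  files <- c(files, write_stage(excl$log,
                                file.path(config$outdir, "exclusions.tsv")))

  indicators <- stage("indicator_matrix", {
    build_indicator_matrix(summaries, excl$cohort)
  })
  counts$masked_indicator_entries <- sum(indicators$mask)
  files <- c(files,
             write_stage(data.frame(indicators$info[, c("participant", "wave")],
                                    indicators$data, check.names = FALSE),
                         file.path(config$outdir, "indicators.csv")),
             write_stage(list(mask = apply(indicators$mask, 1, which)),
                         file.path(config$outdir, "indicator_mask.json")))

  sem_fit <- stage("fit_latent", fit_cfa(config$spec, indicators, se = se))
  files <- c(files,
             write_stage(sem_fit$parameters,
                         file.path(config$outdir, "latent_parameters.csv")),
             write_stage(list(loglik = sem_fit$loglik,
                              fit_indices = sem_fit$fit_indices,
                              n = sem_fit$n, n_free = sem_fit$n_free,
                              convergence = sem_fit$convergence),
                         file.path(config$outdir, "latent_model.json")))

  scores <- stage("factor_scores", extract_factor_scores(sem_fit, indicators))

  age_fit <- stage("fit_age", {
    fit_regularized_age_model(scores, indicators$info$age,
                              indicators$info$participant, config$age)
  })
  files <- c(files, write_stage(
    list(alpha = age_fit$alpha, lambda = age_fit$lambda,
         cv_r2 = age_fit$cv_r2, coefficients = as.list(age_fit$coefficients),
         test_r2 = age_fit$test_r2, test_mae_months = age_fit$test_mae_months,
         train_participants = age_fit$train_participants),
    file.path(config$outdir, "age_model.json")))

  cmi <- stage("cmi", {
    pred <- predict_age(age_fit, scores)
    compute_cmi(pred, indicators$info$age,
                participant = indicators$info$participant,
                wave = indicators$info$wave,
                sign_convention = config$sign_convention)
  })
  counts$predicted_person_waves <- sum(is.finite(cmi$cmi))
  files <- c(files, write_stage(cmi, file.path(config$outdir, "cmi.csv")),
             write_stage(data.frame(cmi[, c("participant", "wave",
                                            "observed_age", "predicted_age")],
                                    split = ifelse(
                                      cmi$participant %in%
                                        age_fit$train_participants,
                                      "train", "test")),
                         file.path(config$outdir,
                                   "predicted_vs_observed.csv")))

  correlations <- stage("correlate", {
    cov_cols <- intersect(c("bmi", "pds", "bas_d", "bas_fs", "bas_rr", "iq",
                            "ses", "bis_scale", "dusi_substance",
                            "dusi_health", "dusi_violence"),
                          names(indicators$info))
    correlate_cmi(cmi, indicators$info[, cov_cols, drop = FALSE])
  })
  files <- c(files, write_stage(correlations,
                                file.path(config$outdir,
                                          "cmi_correlations.tsv")))

  files <- c(files, write_stage(report_markdown(sem_fit, age_fit, cmi,
                                                correlations),
                                file.path(config$outdir, "report.md")))
  log_lines <- c(log_lines,
                 sprintf("%s: %s", names(counts), unlist(counts)))
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  files <- c(files, file.path(config$outdir, "run_log.txt"))

  manifest <- list(
    status = "ok", package_version = as.character(utils::packageVersion("cogmaturity")),
    r_version = as.character(getRversion()), master_seed = config$seed,
    stage_seeds = list(cohort = config$cohort$seed, split = config$age$seed),
    counts = counts,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  write_stage(manifest, file.path(config$outdir, "manifest.json"))
  invisible(list(manifest = manifest, bundle = bundle,
                 indicators = indicators, sem_fit = sem_fit, scores = scores,
                 age_fit = age_fit, cmi = cmi, correlations = correlations))
}

report_markdown <- function(sem_fit, age_fit, cmi, correlations) {
  fi <- sem_fit$fit_indices
  lines <- c(
    "# Cognitive maturity pipeline report", "",
    "## Structural model",
    sprintf("chisq(%d) = %.3f (p = %.3f), RMSEA = %.3f, CFI = %.3f, TLI = %.3f",
            fi$df, fi$chisq, fi$p, fi$rmsea, fi$cfi, fi$tli), "",
    "| parameter | estimate | std. estimate | SE | Z | p |",
    "|---|---|---|---|---|---|")
  pt <- sem_fit$parameters
  show <- pt$type %in% c("loading", "path", "residual_covariance",
                         "disturbance_correlation", "factor_covariance")
  for (i in which(show)) {
    lines <- c(lines, sprintf("| %s | %.3f | %.3f | %.3f | %.2f | %.3g |",
                              pt$label[i], pt$estimate[i], pt$std_estimate[i],
                              pt$se[i], pt$z[i], pt$p[i]))
  }
  lines <- c(lines, "", "## Age model",
             sprintf("alpha = %.2f, lambda = %.4g, CV R2 = %.3f", age_fit$alpha,
                     age_fit$lambda, age_fit$cv_r2),
             sprintf("test R2 = %.3f, test MAE = %.2f months", age_fit$test_r2,
                     age_fit$test_mae_months), "",
             "## CMI",
             sprintf("mean CMI = %.3f y, SD = %.3f y over %d person-waves",
                     mean(cmi$cmi, na.rm = TRUE), stats::sd(cmi$cmi, na.rm = TRUE),
                     sum(is.finite(cmi$cmi))), "",
             "| covariate | r | p | n |", "|---|---|---|---|")
  for (i in seq_len(nrow(correlations))) {
    lines <- c(lines, sprintf("| %s | %.3f | %.3g | %d |",
                              correlations$covariate[i], correlations$r[i],
                              correlations$p[i], correlations$n[i]))
  }
  paste(lines, collapse = "\n")
}

#' Build deterministic test fixtures
#'
#' `tiny` (n = 12 participants, 2 waves) for unit tests; `demo` (n = 141,
#' 3 waves) for acceptance-scale runs. Fixtures are generated, never stored:
#' regenerating under the pinned seed is byte-identical.
#'
#' @param scale `"tiny"` or `"demo"`.
#' @param growth growth specification (default [growth_spec()]).
#' @return a cohort bundle (see [generate_cohort()]).
#' @export
make_fixtures <- function(scale = c("tiny", "demo"), growth = growth_spec()) {
  scale <- match.arg(scale)
  config <- switch(scale,
    tiny = cohort_config(n_participants = 12, n_waves = 2,
                         dropout_rate_per_wave = 0,
                         indicator_missing_rate = 0, lie_gt6_rate = 1 / 6,
                         seed = 20260101L),
    demo = cohort_config(seed = 20260102L)
  )
  generate_cohort(config, growth, trials = TRUE)
}
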