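#!/usr/bin/env Rscript
# Stage 3: latent measurement and structural models.
#
# Fits the three domain measurement models (inhibitory control; risk/reward;
# positive and negative emotion recognition) and the combined structural
# model with directed paths from inhibitory control onto the other factors,
# all by full-information maximum likelihood over missingness patterns.
# Writes per-model parameter tables (estimate, SE, Z, p, standardized) and
# fit indices.

source("analysis/00_config.R")

im <- read_indicators()

fits <- list()
for (w in c("iclf", "rrlf", "efr", "sem")) {
  spec <- default_measurement_spec(w)
  fit <- suppressWarnings(fit_cfa(spec, im$data, se = TRUE))
  fits[[w]] <- fit
  fi <- fit$fit_indices
  cat(sprintf(
    "%-4s chisq(%d) = %7.2f  p = %.3f  RMSEA = %.3f  CFI = %.3f  TLI = %.3f\n",
    toupper(w), fi$df, fi$chisq, fi$p, fi$rmsea, fi$cfi, fi$tli))
  write.csv(fit$parameters,
            file.path(RESULTS_DIR, sprintf("latent_%s_parameters.csv", w)),
            row.names = FALSE)
}

idx <- lapply(fits, function(f) f$fit_indices[c("chisq", "df", "p", "rmsea",
                                                "cfi", "tli")])
jsonlite::write_json(idx, file.path(RESULTS_DIR, "latent_fit_indices.json"),
                     auto_unbox = TRUE, digits = NA)

pp <- fits$sem$parameters
paths <- pp[pp$type == "path", ]
cat("\nstructural paths (standardized):\n")
print(paths[, c("label", "std_estimate", "se", "z", "p")], row.names = FALSE)
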