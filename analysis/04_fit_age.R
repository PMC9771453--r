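#!/usr/bin/env Rscript
# Stage 4: regularized age prediction and the Cognitive Maturity Index.
#
# Extracts regression factor scores from the structural model, splits
# participants 50/50 into training and test halves, selects the elastic-net
# mixing and penalty by leave-one-participant-out cross-validation on the
# training half (smallest lambda at the highest cross-validated R2), and
# evaluates on the held-out half. CMI = predicted - observed age.

source("analysis/00_config.R")

im <- read_indicators()
sem <- suppressWarnings(fit_cfa(default_measurement_spec("sem"), im$data,
                                se = FALSE))
scores <- extract_factor_scores(sem, im$data)

age_fit <- fit_regularized_age_model(
  scores, im$info$age, im$info$participant,
  age_model_config(seed = MASTER_SEED + 1))

cat(sprintf("selected alpha = %.1f, lambda = %.4g (CV R2 = %.3f)\n",
            age_fit$alpha, age_fit$lambda, age_fit$cv_r2))
cat(sprintf("held-out: R2 = %.3f, MAE = %.2f months\n",
            age_fit$test_r2, age_fit$test_mae_months))
cat("coefficients (per SD of factor score):\n")
print(round(age_fit$coefficients, 4))

cmi <- compute_cmi(predict_age(age_fit, scores), im$info$age,
                   participant = im$info$participant, wave = im$info$wave)
cat(sprintf("CMI: mean %.3f y, SD %.3f y over %d person-waves\n",
            mean(cmi$cmi, na.rm = TRUE), sd(cmi$cmi, na.rm = TRUE),
            sum(is.finite(cmi$cmi))))

write.csv(data.frame(cmi,
                     split = ifelse(cmi$participant %in%
                                      age_fit$train_participants,
                                    "train", "test")),
          file.path(RESULTS_DIR, "cmi.csv"), row.names = FALSE)
jsonlite::write_json(
  list(alpha = age_fit$alpha, lambda = age_fit$lambda,
       cv_r2 = age_fit$cv_r2, test_r2 = age_fit$test_r2,
       test_mae_months = age_fit$test_mae_months,
       coefficients = as.list(age_fit$coefficients)),
  file.path(RESULTS_DIR, "age_model.json"), auto_unbox = TRUE, digits = NA)
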