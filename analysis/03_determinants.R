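#!/usr/bin/env Rscript

## Stage 3 — determinants of CHE.
## Fits the logistic model (with average marginal effects) and the
## linear probability model at the 30% threshold, compares them, runs
## stepwise entry-removal selection, repeats the logit at 40% (where
## the sex effect is expected to sharpen), and tests the association of
## CHE status with diagnosis group and patient sex.

suppressPackageStartupMessages(library(checap))

dir.create("results/determinants", recursive = TRUE,
           showWarnings = FALSE)

survey <- annualize(load_survey("results/data/survey.csv",
                                money_convention("MXN", "monthly")))
decomposition <- che_decompose(survey)

dm <- che_design_matrix(survey, decomposition, threshold = 0.30)
logit <- fit_logit(dm)
logit$marginal_effects <- marginal_effects(logit)
lpm <- fit_lpm(dm)

cat("== Logistic model, threshold 30% ==\n")
print(logit)
cat("\nAverage marginal effects (probability change per unit):\n")
print(round(logit$marginal_effects, 4))
cat("\n== Linear probability model, threshold 30% ==\n")
print(lpm)

cmp <- compare_models(logit, lpm)
cat("\nAME vs OLS slopes: sign agreement",
    sprintf("%.0f%%,", 100 * mean(cmp$sign_agree)),
    "max |difference|", sprintf("%.4f\n", max(cmp$abs_diff)))

step_logit <- stepwise_select(dm, "logit")
cat("\nStepwise (logit) selected:",
    paste(step_logit$selected, collapse = ", "), "\n")

## the 40% threshold model
dm40 <- che_design_matrix(survey, decomposition, threshold = 0.40)
logit40 <- fit_logit(dm40)
cat(sprintf("\nAt 40%%: male-patient coefficient %.3f (p = %.3f)\n",
            logit40$coefficients[["patient_male"]],
            logit40$p_values[["patient_male"]]))

## group associations
chi_dx <- contingency_chi2(decomposition$flag_30,
                           survey$records$patient_diagnosis)
chi_sex <- contingency_chi2(decomposition$flag_30,
                            survey$records$patient_sex)
cat(sprintf("\nCHE x diagnosis: chi2 = %.1f (df %d, p = %.3g)\n",
            chi_dx$chi2, chi_dx$df, chi_dx$p_value))
cat(sprintf("CHE x patient sex: chi2 = %.1f (df %d, p = %.3g)\n",
            chi_sex$chi2, chi_sex$df, chi_sex$p_value))

utils::write.csv(regression_table(logit),
                 "results/determinants/logit_30.csv", row.names = FALSE)
utils::write.csv(regression_table(lpm),
                 "results/determinants/ols_30.csv", row.names = FALSE)
utils::write.csv(regression_table(logit40),
                 "results/determinants/logit_40.csv", row.names = FALSE)
utils::write.csv(cmp, "results/determinants/model_comparison.csv",
                 row.names = FALSE)
utils::write.csv(step_logit$log,
                 "results/determinants/stepwise_log.csv",
                 row.names = FALSE)
cat("\nWrote regression tables under results/determinants/\n")
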