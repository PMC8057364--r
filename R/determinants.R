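## Determinants stage: logistic regression with average marginal effects,
## the linear probability model with robust SEs, stepwise entry-removal
## selection, and contingency chi-square association tests.

#' Build the determinants design matrix
#'
#' Assembles the response (the CHE flag at a chosen threshold) and the
#' covariate columns used by the regression models.  Money covariates are
#' rescaled to per-1000-currency-unit terms so a coefficient reads as the
#' probability change per 1000 pesos (about US$49 at the 20.48 rate).
#' `patient_sex` enters as a male indicator, `marital_status` as a
#' married indicator; other categorical covariates are expanded to
#' first-level-reference dummies.
#'
#' @param survey The annualized `household_survey` the decomposition was
#'   computed from.
#' @param decomposition The matching [che_decompose()] result.
#' @param threshold CHE threshold whose flag is the response (default
#'   0.30).
#' @param covariates Character vector of survey columns to include.  The
#'   default mirrors the conventional determinants set: income, the
#'   hospitalization and medicines OOP components, household size,
#'   patient sex and employment, and missed work days.
#' @param money_unit Divisor applied to money covariates (default 1000).
#' @return Data frame of class `che_design` with response column `che`
#'   and numeric covariate columns; threshold and unit are attributes.
#' @export
che_design_matrix <- function(survey, decomposition, threshold = 0.30,
                              covariates = NULL, money_unit = 1000) {
  stopifnot(inherits(survey, "household_survey"),
            inherits(decomposition, "che_decomposition"))
  if (nrow(survey$records) != nrow(decomposition)) {
    stop("survey and decomposition have different row counts",
         call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- c("income", "oop_hospitalization", "oop_medicines",
                    "household_size", "patient_sex", "patient_employed",
                    "missed_work_days")
  }
  col <- flag_column(threshold)
  if (!col %in% names(decomposition)) {
    stop("decomposition has no flags at threshold ", threshold,
         call. = FALSE)
  }
  records <- survey$records
  out <- data.frame(che = decomposition[[col]])
  for (v in covariates) {
    if (!v %in% names(records)) {
      stop("unknown covariate: ", v, call. = FALSE)
    }
    x <- records[[v]]
    if (v == "patient_sex") {
      out$patient_male <- as.integer(x == "male")
    } else if (v == "caregiver_sex") {
      out$caregiver_male <- as.integer(x == "male")
    } else if (v == "marital_status") {
      out$married <- as.integer(x == "married")
    } else if (is.numeric(x)) {
      out[[v]] <- if (v %in% money_columns()) x / money_unit else x
    } else {
      ## general categorical: dummies against the first observed level
      f <- factor(x)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste(v, levels(f)[-1], sep = "_")
      out <- cbind(out, as.data.frame(mm))
    }
  }
  if (anyNA(out)) {
    stop("design matrix contains missing cells", call. = FALSE)
  }
  structure(out,
            threshold = threshold, money_unit = money_unit,
            class = c("che_design", "data.frame"))
}

design_covariates <- function(dm, covariates = NULL) {
  covs <- setdiff(names(dm), "che")
  if (!is.null(covariates)) {
    missing <- setdiff(covariates, covs)
    if (length(missing) > 0L) {
      stop("covariates not in design: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    covs <- covariates
  }
  covs
}

design_formula <- function(covs) {
  rhs <- if (length(covs) == 0L) "1" else paste(covs, collapse = " + ")
  stats::as.formula(paste("che ~", rhs))
}

## Intercept-only Bernoulli log-likelihood, closed form.
null_loglik <- function(y) {
  n <- length(y)
  p <- mean(y)
  if (p == 0 || p == 1) return(0)
  n * (p * log(p) + (1 - p) * log(1 - p))
}

#' Fit the logistic CHE determinants model
#'
#' Maximum-likelihood logistic regression (IRLS) of the CHE indicator on
#' the design covariates, with Wald standard errors and 95% intervals,
#' McFadden pseudo-R² and the likelihood-ratio chi-square against the
#' intercept-only model.  The fit is honest about instability: complete
#' or quasi-complete separation (fitted probabilities numerically 0 or 1)
#' and IRLS non-convergence are surfaced through the `converged` /
#' `instability` fields and a warning naming the suspect covariates —
#' never silently returned as clean estimates.  High CHE prevalence at
#' low thresholds is the typical trigger.
#'
#' @param dm A [che_design_matrix()].
#' @param covariates Optional subset of design covariates to use.
#' @param on_instability `"warn"` (default) records the problem on the
#'   returned fit; `"error"` raises instead.
#' @return Object of class `che_fit` with elements `model = "logit"`,
#'   `coefficients`, `std_errors`, `ci95`, `p_values`, `pseudo_r2`,
#'   `lr_chi2`, `lr_df`, `log_lik`, `converged`, `instability`,
#'   `instability_reason`, `n_used`, `marginal_effects` (filled by
#'   [marginal_effects()]), and the underlying `glm` fit.
#' @export
fit_logit <- function(dm, covariates = NULL,
                      on_instability = c("warn", "error")) {
  on_instability <- match.arg(on_instability)
  covs <- design_covariates(dm, covariates)
  y <- dm$che
  if (length(unique(y)) < 2L && length(covs) > 0L) {
    stop("response is constant; cannot fit a determinants model",
         call. = FALSE)
  }
  warns <- character()
  fit <- withCallingHandlers(
    stats::glm(design_formula(covs), family = stats::binomial(),
               data = dm),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("singular design: collinear column(s) ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  boundary <- any(grepl("numerically 0 or 1", warns))
  nonconv <- !fit$converged || any(grepl("did not converge", warns))
  se <- sqrt(diag(stats::vcov(fit)))
  ## boundary fitted probabilities alone can be benign (a heavy-tailed
  ## covariate pushing a few fits to machine 0/1); call it separation
  ## only when coefficients or SEs have actually diverged
  separation <- boundary && (max(abs(beta)) > 10 || max(se) > 5)
  instability <- separation || nonconv
  reason <- NULL
  if (instability) {
    suspects <- names(beta)[abs(beta) > 10 | se > 100]
    suspects <- setdiff(suspects, "(Intercept)")
    reason <- paste0(
      if (nonconv) "IRLS did not converge" else
        "quasi-complete separation (fitted probabilities numerically 0 or 1)",
      if (length(suspects) > 0L) {
        paste0("; suspect covariate(s): ", paste(suspects, collapse = ", "))
      } else "")
    if (on_instability == "error") stop(reason, call. = FALSE)
    warning("unstable logistic fit: ", reason, call. = FALSE)
  }
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- null_loglik(y)
  z <- beta / se
  structure(
    list(model = "logit",
         threshold = attr(dm, "threshold"),
         coefficients = beta,
         std_errors = se,
         ci95 = cbind(lo = beta - stats::qnorm(0.975) * se,
                      hi = beta + stats::qnorm(0.975) * se),
         p_values = 2 * stats::pnorm(-abs(z)),
         marginal_effects = NULL,
         pseudo_r2 = if (ll0 == 0) NA_real_ else 1 - ll / ll0,
         lr_chi2 = 2 * (ll - ll0),
         lr_df = length(covs),
         log_lik = ll,
         converged = fit$converged && !nonconv,
         instability = instability,
         instability_reason = reason,
         n_used = length(y),
         glm = fit),
    class = "che_fit"
  )
}

#' Fit the linear probability model
#'
#' OLS of the CHE indicator on the design covariates.  Coefficients read
#' directly as probability changes; standard errors are HC1
#' heteroskedasticity-robust, since an LPM is heteroskedastic by
#' construction.
#'
#' @inheritParams fit_logit
#' @return A `che_fit` with `model = "ols"`, robust `std_errors`, `r2`,
#'   and `marginal_effects` equal to the slopes.
#' @export
fit_lpm <- function(dm, covariates = NULL) {
  covs <- design_covariates(dm, covariates)
  fit <- stats::lm(design_formula(covs), data = dm)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("rank-deficient design: collinear column(s) ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  vc <- sandwich::vcovHC(fit, type = "HC1")
  se <- sqrt(diag(vc))
  df <- stats::df.residual(fit)
  tcrit <- stats::qt(0.975, df)
  tval <- beta / se
  slopes <- beta[setdiff(names(beta), "(Intercept)")]
  structure(
    list(model = "ols",
         threshold = attr(dm, "threshold"),
         coefficients = beta,
         std_errors = se,
         ci95 = cbind(lo = beta - tcrit * se, hi = beta + tcrit * se),
         p_values = 2 * stats::pt(-abs(tval), df),
         marginal_effects = slopes,
         r2 = summary(fit)$r.squared,
         converged = TRUE,
         instability = FALSE,
         instability_reason = NULL,
         n_used = nrow(dm),
         lm = fit),
    class = "che_fit"
  )
}

#' Marginal effects of a logistic fit
#'
#' Average marginal effects (AME, the default): for a continuous
#' covariate, the sample mean of `b_j p_i (1 - p_i)`; for a binary
#' covariate, the difference in mean predicted probability between the
#' all-1 and all-0 counterfactuals.  Standard errors are delta-method,
#' propagating the coefficient covariance through a numerical Jacobian of
#' the effect vector.  `type = "mem"` gives effects at covariate means
#' instead.
#'
#' @param fit A converged (or at least fitted) logit `che_fit`.
#' @param type `"ame"` (average marginal effects) or `"mem"` (effects at
#'   means).
#' @return Named numeric vector of effects with attributes `"se"` (named
#'   delta-method standard errors) and `"type"`.
#' @export
marginal_effects <- function(fit, type = c("ame", "mem")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "che_fit"))
  if (fit$model == "ols") {
    return(fit$marginal_effects)
  }
  X <- stats::model.matrix(fit$glm)
  beta <- fit$coefficients
  covs <- setdiff(colnames(X), "(Intercept)")
  binary <- vapply(covs, function(j) all(X[, j] %in% c(0, 1)), logical(1))

  effect_fun <- function(b) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    vapply(covs, function(j) {
      if (binary[[j]]) {
        X1 <- X; X1[, j] <- 1
        X0 <- X; X0[, j] <- 0
        if (type == "ame") {
          mean(stats::plogis(drop(X1 %*% b))) -
            mean(stats::plogis(drop(X0 %*% b)))
        } else {
          x1 <- colMeans(X1); x0 <- colMeans(X0)
          stats::plogis(sum(x1 * b)) - stats::plogis(sum(x0 * b))
        }
      } else {
        if (type == "ame") {
          b[[j]] * mean(p * (1 - p))
        } else {
          xbar <- colMeans(X)
          b[[j]] * stats::dlogis(sum(xbar * b))
        }
      }
    }, numeric(1))
  }

  eff <- effect_fun(beta)
  ## delta method: numerical Jacobian of the effect vector in beta
  k <- length(beta)
  J <- matrix(0, nrow = length(eff), ncol = k)
  for (m in seq_len(k)) {
    h <- 1e-6 * (abs(beta[m]) + 1e-3)
    bp <- beta; bp[m] <- bp[m] + h
    bm <- beta; bm[m] <- bm[m] - h
    J[, m] <- (effect_fun(bp) - effect_fun(bm)) / (2 * h)
  }
  V <- J %*% stats::vcov(fit$glm) %*% t(J)
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- covs
  structure(eff, se = se, type = type)
}

## Wald p-values of individual terms for the stepwise search; lightweight
## (no che_fit construction).
term_p_values <- function(dm, covs, model) {
  f <- design_formula(covs)
  if (model == "logit") {
    fit <- suppressWarnings(
      stats::glm(f, family = stats::binomial(), data = dm))
    sm <- summary(fit)$coefficients
    p <- sm[, 4]
  } else {
    fit <- stats::lm(f, data = dm)
    sm <- summary(fit)$coefficients
    p <- sm[, 4]
  }
  p[setdiff(rownames(sm), "(Intercept)")]
}

#' Stepwise entry-removal covariate selection
#'
#' Classic bidirectional stepwise on Wald p-values: at each round the
#' candidate with the smallest p-value below `p_enter` is added, then the
#' included term with the largest p-value above `p_remove` is dropped.
#' Deterministic given column order and thresholds (ties resolve to the
#' earlier column); every entry and removal is recorded in an audit log.
#' Revisiting a previously visited model aborts with an oscillation
#' diagnostic.
#'
#' @param dm A [che_design_matrix()].
#' @param model `"logit"` or `"ols"`.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10); must be
#'   `>= p_enter`.
#' @param scope Candidate covariates (default: all design covariates).
#' @return Object of class `che_stepwise`: `selected` (covariates in
#'   entry order), `fit` (final [fit_logit()] / [fit_lpm()]), `log`
#'   (data frame of step, action, variable, p_value).
#' @export
stepwise_select <- function(dm, model = c("logit", "ols"),
                            p_enter = 0.05, p_remove = 0.10,
                            scope = NULL) {
  model <- match.arg(model)
  if (p_enter > p_remove) {
    stop("`p_enter` must be <= `p_remove`", call. = FALSE)
  }
  scope <- design_covariates(dm, scope)
  included <- character(0)
  visited <- paste(sort(included), collapse = "+")
  log <- list()
  step <- 0L
  repeat {
    changed <- FALSE
    ## entry
    excluded <- setdiff(scope, included)
    if (length(excluded) > 0L) {
      p_in <- vapply(excluded, function(v) {
        ps <- term_p_values(dm, c(included, v), model)
        unname(ps[v])
      }, numeric(1))
      best <- which.min(p_in)  # first index on ties: column order
      if (p_in[best] < p_enter) {
        included <- c(included, excluded[best])
        step <- step + 1L
        log[[step]] <- data.frame(step = step, action = "enter",
                                  variable = excluded[best],
                                  p_value = unname(p_in[best]))
        changed <- TRUE
      }
    }
    ## removal
    if (length(included) > 0L) {
      p_out <- term_p_values(dm, included, model)[included]
      worst <- which.max(p_out)
      if (p_out[worst] > p_remove) {
        victim <- included[worst]
        included <- setdiff(included, victim)
        step <- step + 1L
        log[[step]] <- data.frame(step = step, action = "remove",
                                  variable = victim,
                                  p_value = unname(p_out[worst]))
        changed <- TRUE
      }
    }
    if (!changed) break
    sig <- paste(sort(included), collapse = "+")
    if (sig %in% visited) {
      stop("stepwise selection oscillates: model {", sig,
           "} visited twice; adjust p_enter/p_remove", call. = FALSE)
    }
    visited <- c(visited, sig)
  }
  fit <- if (model == "logit") {
    suppressWarnings(fit_logit(dm, covariates = included))
  } else {
    fit_lpm(dm, covariates = included)
  }
  structure(
    list(selected = included, fit = fit,
         log = if (length(log) > 0L) do.call(rbind, log) else
           data.frame(step = integer(), action = character(),
                      variable = character(), p_value = numeric()),
         p_enter = p_enter, p_remove = p_remove, model = model),
    class = "che_stepwise"
  )
}

#' @export
print.che_stepwise <- function(x, ...) {
  cat(sprintf("<stepwise %s selection: %d covariate(s) selected>\n",
              x$model, length(x$selected)))
  if (length(x$selected) > 0L) {
    cat("  ", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare logit marginal effects with linear-probability slopes
#'
#' Aligns the average marginal effects of the logistic model with the
#' OLS slopes fitted on the same design, reporting the absolute
#' difference and whether the two agree in sign.  Close agreement at
#' mid-range prevalence is the standard justification for reading LPM
#' coefficients as probability changes.
#'
#' @param logit_fit A logit `che_fit` (AMEs are computed if absent).
#' @param lpm_fit An OLS `che_fit` on the same covariates.
#' @return Data frame: `covariate`, `logit_ame`, `ols_coef`, `abs_diff`,
#'   `sign_agree`.
#' @export
compare_models <- function(logit_fit, lpm_fit) {
  stopifnot(inherits(logit_fit, "che_fit"), logit_fit$model == "logit",
            inherits(lpm_fit, "che_fit"), lpm_fit$model == "ols")
  ame <- logit_fit$marginal_effects
  if (is.null(ame)) ame <- marginal_effects(logit_fit)
  ols <- lpm_fit$marginal_effects
  if (!setequal(names(ame), names(ols))) {
    stop("covariate names differ between the two fits: cannot align",
         call. = FALSE)
  }
  ols <- ols[names(ame)]
  data.frame(
    covariate = names(ame),
    logit_ame = as.numeric(ame),
    ols_coef = as.numeric(ols),
    abs_diff = abs(as.numeric(ame) - as.numeric(ols)),
    sign_agree = sign(as.numeric(ame)) == sign(as.numeric(ols)) |
      as.numeric(ame) == 0 | as.numeric(ols) == 0,
    row.names = NULL
  )
}

#' Pearson chi-square association between CHE status and a grouping
#'
#' Contingency chi-square (no continuity correction) of the CHE flags
#' against a categorical variable such as diagnosis group or patient
#' sex.  Empty groups are dropped with a warning.
#'
#' @param flags Vector of 0/1 CHE indicators.
#' @param group Categorical vector of the same length.
#' @return List with `chi2`, `df`, `p_value`, the contingency `table`,
#'   and `min_expected` (smallest expected cell count).
#' @export
contingency_chi2 <- function(flags, group) {
  if (length(flags) != length(group)) {
    stop("`flags` and `group` must have the same length", call. = FALSE)
  }
  g <- if (is.factor(group)) group else factor(group)
  empty <- levels(g)[tabulate(g, nbins = nlevels(g)) == 0L]
  if (length(empty) > 0L) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
    g <- droplevels(g)
  }
  if (nlevels(g) < 2L) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  tab <- table(group = g, che = factor(flags, levels = c(0, 1)))
  test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(test$statistic),
       df = unname(test$parameter),
       p_value = unname(test$p.value),
       table = tab,
       min_expected = min(test$expected))
}

#' Significance stars
#'
#' Two conventions are used in health-financing tables: descriptive
#' tables star at 0.001/0.01/0.05, regression tables at 0.01/0.05/0.1.
#'
#' @param p Numeric vector of p-values.
#' @param convention `"regression"` or `"descriptive"`.
#' @return Character vector of `""`, `"*"`, `"**"`, `"***"`.
#' @export
significance_stars <- function(p, convention = c("regression",
                                                 "descriptive")) {
  convention <- match.arg(convention)
  cuts <- if (convention == "regression") c(0.01, 0.05, 0.1) else
    c(0.001, 0.01, 0.05)
  out <- character(length(p))
  out[p < cuts[3]] <- "*"
  out[p < cuts[2]] <- "**"
  out[p < cuts[1]] <- "***"
  out[is.na(p)] <- ""
  out
}

#' Tidy coefficient table of a fitted model
#'
#' @param fit A `che_fit`.
#' @param stars Star convention for [significance_stars()].
#' @return Data frame: term, estimate, std_error, ci_lo, ci_hi, p_value,
#'   stars.
#' @export
regression_table <- function(fit, stars = "regression") {
  stopifnot(inherits(fit, "che_fit"))
  data.frame(
    term = names(fit$coefficients),
    estimate = as.numeric(fit$coefficients),
    std_error = as.numeric(fit$std_errors),
    ci_lo = as.numeric(fit$ci95[, "lo"]),
    ci_hi = as.numeric(fit$ci95[, "hi"]),
    p_value = as.numeric(fit$p_values),
    stars = significance_stars(fit$p_values, stars),
    row.names = NULL
  )
}

#' @export
print.che_fit <- function(x, digits = 4, ...) {
  label <- if (x$model == "logit") "Logistic" else "Linear probability"
  cat(sprintf("%s model of CHE at threshold %.0f%% (n = %d)\n",
              label, 100 * x$threshold, x$n_used))
  if (!x$converged || x$instability) {
    cat("  ** UNSTABLE FIT: ", x$instability_reason %||%
          "did not converge", " **\n", sep = "")
  }
  tab <- regression_table(x)
  tab[, 2:6] <- round(tab[, 2:6], digits)
  print(tab, row.names = FALSE)
  if (x$model == "logit") {
    cat(sprintf("McFadden pseudo-R2 = %.3f; LR chi2 = %.1f on %d df\n",
                x$pseudo_r2, x$lr_chi2, x$lr_df))
  } else {
    cat(sprintf("R2 = %.3f (HC1 robust SEs)\n", x$r2))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
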