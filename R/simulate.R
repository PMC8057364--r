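## Synthetic household-survey generator with known ground-truth effect
## structure.  Income is lognormal; the food share follows an Engel-type
## curve (declining in log income); each OOP component follows a two-part
## (hurdle) model: logistic occurrence, lognormal positive amount, both
## with configurable covariate loadings.  All randomness is coupled to
## explicit uniforms/normals so counterfactual re-simulation with the same
## seed changes only what the shifted covariate touches.

## Latent covariates the OOP loadings may reference (centered where noted)
latent_names <- c("male", "employed", "schizophrenia", "anxiety",
                  "hyperactive", "household_size", "missed_work_days")

oop_component <- function(p0, meanlog, sdlog,
                          prob_loadings = numeric(0),
                          mean_loadings = numeric(0)) {
  stopifnot(p0 > 0, p0 <= 1, sdlog > 0,
            all(names(prob_loadings) %in% latent_names),
            all(names(mean_loadings) %in% latent_names))
  list(p0 = p0, meanlog = meanlog, sdlog = sdlog,
       prob_loadings = prob_loadings, mean_loadings = mean_loadings)
}

default_oop_model <- function() {
  list(
    oop_consultation = oop_component(
      p0 = 0.90, meanlog = log(250), sdlog = 0.7,
      mean_loadings = c(missed_work_days = 0.04)),
    oop_hospitalization = oop_component(
      p0 = 0.18, meanlog = log(2500), sdlog = 0.9,
      prob_loadings = c(male = 0.5, employed = -0.6, schizophrenia = 0.8,
                        anxiety = -1.5, missed_work_days = 0.08),
      mean_loadings = c(male = 0.30)),
    oop_medicines = oop_component(
      p0 = 0.95, meanlog = log(900), sdlog = 0.8,
      prob_loadings = c(anxiety = -1.0),
      mean_loadings = c(male = 0.30, schizophrenia = 0.5, anxiety = -0.8,
                        household_size = 0.05)),
    oop_diagnostics = oop_component(
      p0 = 0.45, meanlog = log(500), sdlog = 0.8,
      prob_loadings = c(schizophrenia = 0.3)),
    oop_transport = oop_component(
      p0 = 0.92, meanlog = log(200), sdlog = 0.6,
      mean_loadings = c(missed_work_days = 0.03))
  )
}

#' Synthetic survey scenario configuration
#'
#' Defaults describe a "study-scale" scenario: 387 households, monthly
#' income lognormal with mean about 6930 MXN (≈ US$338 at 20.48 MXN/USD)
#' and coefficient of variation 0.65, 74% male patients, a diagnosis mix
#' led by schizophrenia, an Engel-type food share declining in income,
#' and a five-component two-part OOP model whose covariate loadings give
#' the generator known effect directions (male patient, larger household,
#' more missed work days raise OOP; an employed patient and an anxiety
#' diagnosis lower it).
#'
#' @param n_households Number of households to simulate.
#' @param seed Master seed; expands into per-purpose substreams so adding
#'   a component does not perturb earlier draws.
#' @param income_lognormal Named numeric, `meanlog` and `sdlog` of the
#'   monthly income distribution (MXN).
#' @param engel List: `baseline` food share at median income,
#'   `elasticity` (share drop per unit log-income above the median), and
#'   `noise_sd`.
#' @param household_size_probs Probabilities of sizes 1..10.
#' @param diagnosis_probs Named simplex over diagnosis groups.
#' @param patient_male_prob,patient_employed_prob,caregiver_female_prob,single_prob
#'   Bernoulli probabilities of the respective indicators.
#' @param oop_model Per-component two-part models; see source of
#'   `default_oop_model()`.
#' @param oop_scale Multiplier on all positive OOP amounts — the single
#'   knob [calibrate_to_incidence()] bisects on.
#' @param target_incidence Optional calibration goal in (0, 1); consumed
#'   by [run_pipeline()].
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n_households = 387,
                            seed = 20180615,
                            income_lognormal = c(meanlog = 8.667,
                                                 sdlog = 0.592),
                            engel = list(baseline = 0.42,
                                         elasticity = 0.08,
                                         noise_sd = 0.08),
                            household_size_probs =
                              c(0.09, 0.16, 0.22, 0.22, 0.15,
                                0.08, 0.04, 0.02, 0.01, 0.01),
                            diagnosis_probs = c(schizophrenia = 0.30,
                                                hyperactive = 0.25,
                                                anxiety = 0.15,
                                                other = 0.30),
                            patient_male_prob = 0.74,
                            patient_employed_prob = 0.25,
                            caregiver_female_prob = 0.86,
                            single_prob = 0.928,
                            oop_model = default_oop_model(),
                            oop_scale = 1,
                            target_incidence = NULL) {
  stopifnot(n_households >= 1,
            is.numeric(seed), length(seed) == 1L,
            income_lognormal[["sdlog"]] > 0,
            length(household_size_probs) == 10L,
            abs(sum(household_size_probs) - 1) < 1e-8,
            abs(sum(diagnosis_probs) - 1) < 1e-8,
            all(diagnosis_probs >= 0),
            engel$noise_sd >= 0,
            oop_scale >= 0)
  if (!is.null(target_incidence)) {
    stopifnot(target_incidence > 0, target_incidence < 1)
  }
  structure(
    list(n_households = as.integer(n_households),
         seed = as.integer(seed),
         income_lognormal = income_lognormal,
         engel = engel,
         household_size_probs = household_size_probs,
         diagnosis_probs = diagnosis_probs,
         patient_male_prob = patient_male_prob,
         patient_employed_prob = patient_employed_prob,
         caregiver_female_prob = caregiver_female_prob,
         single_prob = single_prob,
         oop_model = oop_model,
         oop_scale = oop_scale,
         target_incidence = target_incidence),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario: %d households, seed %d, oop_scale %.4g%s>\n",
    x$n_households, x$seed, x$oop_scale,
    if (!is.null(x$target_incidence)) {
      sprintf(", target incidence %.1f%%", 100 * x$target_incidence)
    } else ""))
  invisible(x)
}

## Deterministic substream seeds from a master seed
substream_seeds <- function(seed, labels) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(2^31 - 2, length(labels)), labels)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Exogenous covariates, including income
gen_covariates <- function(cfg, n, seed) {
  set.seed(seed)
  data.frame(
    household_id = sprintf("HH%05d", seq_len(n)),
    household_size = sample(1:10, n, replace = TRUE,
                            prob = cfg$household_size_probs),
    patient_sex = ifelse(stats::runif(n) < cfg$patient_male_prob,
                         "male", "female"),
    patient_age = round(clamp(stats::rnorm(n, 32, 12), 6, 80)),
    patient_education_years = round(clamp(stats::rnorm(n, 9, 3.5), 0, 20)),
    patient_diagnosis = sample(names(cfg$diagnosis_probs), n,
                               replace = TRUE, prob = cfg$diagnosis_probs),
    patient_employed = as.integer(stats::runif(n) <
                                    cfg$patient_employed_prob),
    caregiver_sex = ifelse(stats::runif(n) < cfg$caregiver_female_prob,
                           "female", "male"),
    caregiver_age = round(clamp(stats::rnorm(n, 45, 12), 18, 90)),
    caregiver_education_years = round(clamp(stats::rnorm(n, 11, 3.7),
                                            0, 20)),
    caregiver_relationship = sample(
      c("mother", "sibling", "grandmother", "other"), n, replace = TRUE,
      prob = c(0.71, 0.08, 0.06, 0.15)),
    missed_work_days = stats::rpois(n, 2),
    marital_status = ifelse(stats::runif(n) < cfg$single_prob,
                            "single", "married"),
    income = stats::rlnorm(n, cfg$income_lognormal[["meanlog"]],
                           cfg$income_lognormal[["sdlog"]]),
    stringsAsFactors = FALSE
  )
}

latent_matrix <- function(cov) {
  cbind(
    male = as.numeric(cov$patient_sex == "male"),
    employed = as.numeric(cov$patient_employed),
    schizophrenia = as.numeric(cov$patient_diagnosis == "schizophrenia"),
    anxiety = as.numeric(cov$patient_diagnosis == "anxiety"),
    hyperactive = as.numeric(cov$patient_diagnosis == "hyperactive"),
    household_size = cov$household_size - 3,
    missed_work_days = cov$missed_work_days - 2
  )
}

loading_eta <- function(L, loadings) {
  if (length(loadings) == 0L) return(rep(0, nrow(L)))
  drop(L[, names(loadings), drop = FALSE] %*% loadings)
}

## Expenditure given covariates.  Draws are coupled to explicit
## uniforms/normals so re-running with the same seed but shifted
## covariates yields the common-random-numbers counterfactual.
gen_expenditure <- function(cov, cfg, seed) {
  n <- nrow(cov)
  labels <- c("rate", "engel", paste0(names(cfg$oop_model), "_occ"),
              paste0(names(cfg$oop_model), "_amt"))
  seeds <- substream_seeds(seed, labels)
  L <- latent_matrix(cov)

  set.seed(seeds[["rate"]])
  rate <- stats::runif(n, 0.75, 0.95)
  consumption <- cov$income * rate

  set.seed(seeds[["engel"]])
  share <- clamp(cfg$engel$baseline -
                   cfg$engel$elasticity *
                   (log(cov$income) - cfg$income_lognormal[["meanlog"]]) +
                   stats::rnorm(n, 0, cfg$engel$noise_sd),
                 0.05, 0.90)
  food <- share * consumption

  oop <- matrix(0, nrow = n, ncol = length(cfg$oop_model),
                dimnames = list(NULL, names(cfg$oop_model)))
  for (comp in names(cfg$oop_model)) {
    m <- cfg$oop_model[[comp]]
    set.seed(seeds[[paste0(comp, "_occ")]])
    u <- stats::runif(n)
    p <- stats::plogis(stats::qlogis(m$p0) +
                         loading_eta(L, m$prob_loadings))
    occurs <- u < p
    set.seed(seeds[[paste0(comp, "_amt")]])
    z <- stats::rnorm(n)
    amount <- exp(m$meanlog + loading_eta(L, m$mean_loadings) +
                    m$sdlog * z) * cfg$oop_scale
    oop[, comp] <- ifelse(occurs, amount, 0)
  }

  out <- as.data.frame(oop)
  out$expenditure_food <- food
  out$expenditure_total <- consumption + rowSums(oop)
  out
}

assemble_survey <- function(cov, expd, convention) {
  records <- cbind(cov, expd)
  survey <- household_survey(records, convention)
  if (nrow(survey$rejects) > 0L) {
    stop("internal error: generated records failed validation (",
         nrow(survey$rejects), " reject reasons)", call. = FALSE)
  }
  survey
}

#' Simulate a household survey
#'
#' Generates `n_households` records (monthly, MXN) under the scenario's
#' income, Engel-curve and two-part OOP models.  Reproducible: the same
#' configuration and seed give byte-identical datasets.  Total
#' expenditure is built as consumption (food + non-food) plus the OOP
#' components, so food never exceeds total and every record passes
#' [household_survey()] validation.
#'
#' @param cfg A [scenario_config()].
#' @param n,seed Optional overrides of the scenario's size and seed.
#' @param convention [money_convention()] for the output (monthly MXN).
#' @return A `household_survey`.
#' @export
simulate_households <- function(cfg, n = cfg$n_households,
                                seed = cfg$seed,
                                convention = money_convention("MXN",
                                                              "monthly")) {
  stopifnot(inherits(cfg, "scenario_config"),
            convention$period == "monthly")
  seeds <- substream_seeds(seed, c("covariates", "expenditure"))
  cov <- gen_covariates(cfg, n, seeds[["covariates"]])
  expd <- gen_expenditure(cov, cfg, seeds[["expenditure"]])
  assemble_survey(cov, expd, convention)
}

## Simulated incidence at a threshold for a given scenario (fixed seed:
## deterministic, monotone in oop_scale)
simulated_incidence <- function(cfg, n, seed, threshold = 0.30,
                                beta = 0.56, window = c(45, 55)) {
  survey <- annualize(simulate_households(cfg, n = n, seed = seed))
  dec <- che_decompose(survey, beta = beta, window = window,
                       thresholds = threshold)
  mean(dec[[flag_column(threshold)]])
}

#' Calibrate the generator to a target CHE incidence
#'
#' Bisects on the single `oop_scale` knob — which multiplies every
#' positive OOP amount and therefore moves the per-household OOP/PC
#' ratio, and hence incidence, monotonically — until the simulated
#' incidence at large `n` is within `tol` of the target.  The evaluation
#' seed is fixed, so the objective is a deterministic monotone function
#' of the knob.  The current configuration is evaluated first and
#' returned unchanged if already within tolerance.
#'
#' @param cfg A [scenario_config()].
#' @param target Target incidence as a fraction in (0, 1).
#' @param tol Acceptable absolute deviation (default 0.01).
#' @param n Simulation size per evaluation (default 20000).
#' @param threshold CHE threshold calibrated at (default 0.30).
#' @param seed Evaluation seed (defaults to the scenario seed).
#' @param beta,window CHE parameters used in the evaluation, see
#'   [che_decompose()].
#' @param scale_range Bracketing range for the knob.
#' @param max_iter Bisection iteration cap.
#' @return The configuration with `oop_scale` adjusted; element
#'   `calibration` records target, achieved incidence, `n`, threshold
#'   and iterations used.
#' @export
calibrate_to_incidence <- function(cfg, target, tol = 0.01, n = 20000,
                                   threshold = 0.30, seed = cfg$seed,
                                   beta = 0.56, window = c(45, 55),
                                   scale_range = c(0, 1e4),
                                   max_iter = 60) {
  stopifnot(inherits(cfg, "scenario_config"), target >= 0, target < 1,
            tol > 0)
  eval_at <- function(scale) {
    cfg$oop_scale <- scale
    simulated_incidence(cfg, n = n, seed = seed, threshold = threshold,
                        beta = beta, window = window)
  }
  record <- function(cfg, scale, achieved, iterations) {
    cfg$oop_scale <- scale
    cfg$calibration <- list(target = target, achieved = achieved,
                            tol = tol, n = n, threshold = threshold,
                            iterations = iterations)
    cfg
  }
  current <- eval_at(cfg$oop_scale)
  if (abs(current - target) <= tol) {
    return(record(cfg, cfg$oop_scale, current, 0L))
  }
  lo <- scale_range[1]; hi <- scale_range[2]
  f_lo <- eval_at(lo); f_hi <- eval_at(hi)
  if (abs(f_lo - target) <= tol) return(record(cfg, lo, f_lo, 0L))
  if (abs(f_hi - target) <= tol) return(record(cfg, hi, f_hi, 0L))
  if (f_lo > target || f_hi < target) {
    stop(sprintf(
      paste0("calibration target %.3f not bracketed by scale range ",
             "[%g, %g] (incidence %.3f to %.3f)"),
      target, lo, hi, f_lo, f_hi), call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- eval_at(mid)
    if (abs(f_mid - target) <= tol) {
      return(record(cfg, mid, f_mid, i))
    }
    if (f_mid < target) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "calibration did not reach |incidence - %.3f| <= %.3f in %d bisections",
    target, tol, max_iter), call. = FALSE)
}

#' Ground-truth covariate effects by Monte-Carlo counterfactual
#'
#' The generator's implied average marginal effect of a covariate on
#' P(CHE = 1) is computed by counterfactual contrast: flip (binary) or
#' shift by one unit (continuous) the covariate for every simulated
#' household, re-simulate everything downstream with common random
#' numbers, and difference the CHE probabilities.  The poverty line is
#' held at its base-sample value across arms so the contrast isolates
#' the household-level effect rather than movement of the reference
#' line.  Monte-Carlo rather than closed form because CHE is a nonlinear
#' functional of the whole expenditure vector.
#'
#' Units match [che_design_matrix()]: the `income` effect is per 1000
#' (annual) MXN, `household_size` and `missed_work_days` per unit,
#' `patient_male` and `patient_employed` are 1-vs-0 contrasts.  A
#' covariate with no path into the expenditure model (for example
#' `caregiver_education_years`) has an exactly zero effect.
#'
#' @param cfg A [scenario_config()].
#' @param effects Character vector of effect names (defaults to the
#'   design-matrix exogenous covariates).
#' @param n Monte-Carlo sample size.
#' @param threshold CHE threshold.
#' @param seed Seed for the counterfactual draw.
#' @param money_unit Money shift unit in annual MXN (default 1000).
#' @return Named numeric vector of effects with attribute `"mc_se"`
#'   (paired Monte-Carlo standard errors).
#' @export
ground_truth <- function(cfg,
                         effects = c("income", "household_size",
                                     "patient_male", "patient_employed",
                                     "missed_work_days"),
                         n = 1e5, threshold = 0.30, seed = cfg$seed,
                         money_unit = 1000) {
  stopifnot(inherits(cfg, "scenario_config"))
  seeds <- substream_seeds(seed, c("covariates", "expenditure"))
  cov <- gen_covariates(cfg, n, seeds[["covariates"]])
  conv <- money_convention("MXN", "monthly")

  flags_for <- function(cov2, pl) {
    expd <- gen_expenditure(cov2, cfg, seeds[["expenditure"]])
    survey <- annualize(assemble_survey(cov2, expd, conv))
    dec <- che_decompose(survey, thresholds = threshold, pl = pl)
    dec[[flag_column(threshold)]]
  }

  base <- annualize(assemble_survey(
    cov, gen_expenditure(cov, cfg, seeds[["expenditure"]]), conv))
  pl <- poverty_line(base$records)

  arms <- function(name) {
    c1 <- cov; c0 <- cov
    unit <- 1
    switch(name,
      patient_male = {
        c1$patient_sex <- "male"; c0$patient_sex <- "female"
      },
      patient_employed = {
        c1$patient_employed <- 1L; c0$patient_employed <- 0L
      },
      income = {
        ## design unit is 1000 annual MXN = 1000/12 monthly
        c1$income <- cov$income + money_unit / 12
      },
      {
        if (!name %in% names(cov) || !is.numeric(cov[[name]])) {
          stop("cannot form a counterfactual for effect: ", name,
               call. = FALSE)
        }
        c1[[name]] <- cov[[name]] + 1
      })
    list(c1 = c1, c0 = c0, unit = unit)
  }

  est <- numeric(length(effects))
  mc_se <- numeric(length(effects))
  for (i in seq_along(effects)) {
    a <- arms(effects[i])
    f1 <- flags_for(a$c1, pl)
    f0 <- flags_for(a$c0, pl)
    d <- (f1 - f0) / a$unit
    est[i] <- mean(d)
    mc_se[i] <- stats::sd(d) / sqrt(n)
  }
  names(est) <- effects
  names(mc_se) <- effects
  structure(est, mc_se = mc_se)
}

#' Read / write scenario configurations as YAML
#'
#' @param path YAML file path.
#' @param cfg A [scenario_config()].
#' @return `read_scenario()` returns a `scenario_config`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$income_lognormal)) {
    raw$income_lognormal <- unlist(raw$income_lognormal)
  }
  if (!is.null(raw$household_size_probs)) {
    raw$household_size_probs <- as.numeric(raw$household_size_probs)
  }
  if (!is.null(raw$diagnosis_probs)) {
    raw$diagnosis_probs <- unlist(raw$diagnosis_probs)
  }
  if (!is.null(raw$oop_model)) {
    raw$oop_model <- lapply(raw$oop_model, function(m) {
      oop_component(p0 = m$p0, meanlog = m$meanlog, sdlog = m$sdlog,
                    prob_loadings = unlist(m$prob_loadings) %||%
                      numeric(0),
                    mean_loadings = unlist(m$mean_loadings) %||%
                      numeric(0))
    })
  }
  do.call(scenario_config, raw)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  out <- unclass(cfg)
  out$calibration <- NULL
  out$income_lognormal <- as.list(out$income_lognormal)
  out$diagnosis_probs <- as.list(out$diagnosis_probs)
  out$oop_model <- lapply(out$oop_model, function(m) {
    list(p0 = m$p0, meanlog = m$meanlog, sdlog = m$sdlog,
         prob_loadings = as.list(m$prob_loadings),
         mean_loadings = as.list(m$mean_loadings))
  })
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' The bundled study-scale scenario
#'
#' Loads the packaged scenario file: 387 households with the descriptive
#' anchors of a psychiatric-outpatient household survey (income scale,
#' sex and diagnosis mix).  Synthetic: it reproduces the *structure* of
#' such a survey, not any real sample.
#'
#' @return A `scenario_config`.
#' @export
study_scale_scenario <- function() {
  read_scenario(system.file("extdata", "scenario_study_scale.yaml",
                            package = "checap", mustWork = TRUE))
}
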