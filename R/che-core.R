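## The CHE statistic: equivalence scale, food-share poverty line,
## subsistence expenditure, capacity to pay, thresholded flags, incidence.

#' Equivalized household size
#'
#' Converts household size to equivalent adults via `size^beta`, the
#' power equivalence scale capturing consumption economies of scale.
#' `beta = 1` is the per-capita scale; `beta = 0.56` is the conventional
#' cross-country value for capacity-to-pay analyses.
#'
#' @param household_size Integer vector, each >= 1.
#' @param beta Equivalence-scale exponent in (0, 1].
#' @return Numeric vector of equivalent adults.
#' @examples
#' equivalized_size(4, 0.56)  # 4^0.56
#' @export
equivalized_size <- function(household_size, beta = 0.56) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0 || beta > 1) {
    stop("`beta` must be a single number in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(household_size)) || any(household_size < 1)) {
    stop("`household_size` must be >= 1", call. = FALSE)
  }
  household_size^beta
}

#' Food share of total household expenditure
#'
#' @param x A `household_survey` or data frame with `expenditure_food`
#'   and `expenditure_total` columns.
#' @return Numeric vector of shares in \[0, 1\]; `NA` (with a warning)
#'   where total expenditure is zero, since the share is undefined there
#'   and such households are excluded from the poverty-line reference
#'   window.
#' @export
food_share <- function(x) {
  records <- if (inherits(x, "household_survey")) x$records else x
  total <- records$expenditure_total
  food <- records$expenditure_food
  share <- ifelse(total > 0, food / total, NA_real_)
  if (anyNA(share)) {
    warning("households with zero total expenditure have undefined food ",
            "share and are excluded from the reference window",
            call. = FALSE)
  }
  share
}

#' Food-share poverty line
#'
#' The subsistence (poverty) line is the mean per-equivalent-adult food
#' expenditure of the households whose food budget share falls in a
#' mid-percentile window of the sample food-share distribution — these
#' "reference" households reveal typical subsistence food needs.
#' Percentiles use the empirical nearest-rank definition with inclusive
#' window bounds, so the result is fully reproducible across platforms.
#' If a `weights` column is present in the records it is used for the
#' window mean; otherwise the mean is unweighted (the unit-weight special
#' case of the weighted estimator).
#'
#' @param x A `household_survey` or data frame with `expenditure_total`,
#'   `expenditure_food` and `household_size` columns.
#' @param beta Equivalence-scale exponent, see [equivalized_size()].
#' @param window Length-2 numeric, the lower and upper food-share
#'   percentiles bounding the reference window (default 45–55).
#' @return An object of class `poverty_line` with elements
#'   `value_per_eq_adult`, `window_lo`, `window_hi`, `n_reference`,
#'   `beta`.
#' @export
poverty_line <- function(x, beta = 0.56, window = c(45, 55)) {
  records <- if (inherits(x, "household_survey")) x$records else x
  if (length(window) != 2L || window[1] < 0 || window[2] > 100 ||
      window[1] >= window[2]) {
    stop("`window` must be percentiles with 0 <= lo < hi <= 100",
         call. = FALSE)
  }
  if (nrow(records) < 1L) {
    stop("need at least one household", call. = FALSE)
  }
  share <- food_share(records)
  usable <- !is.na(share)
  if (!any(usable)) {
    stop("no household with positive total expenditure", call. = FALSE)
  }
  if (all(records$expenditure_food[usable] == 0)) {
    stop("degenerate poverty line: all food expenditures are zero",
         call. = FALSE)
  }
  ## nearest-rank empirical percentiles (quantile type 1)
  bounds <- stats::quantile(share[usable], probs = window / 100,
                            type = 1, names = FALSE)
  in_window <- usable & share >= bounds[1] & share <= bounds[2]
  if (!any(in_window)) {
    stop("no household falls inside the food-share window; ",
         "widen `window` and retry", call. = FALSE)
  }
  eq <- equivalized_size(records$household_size[in_window], beta)
  per_eq_food <- records$expenditure_food[in_window] / eq
  w <- if ("weights" %in% names(records)) {
    records$weights[in_window]
  } else {
    rep(1, sum(in_window))
  }
  structure(
    list(value_per_eq_adult = stats::weighted.mean(per_eq_food, w),
         window_lo = window[1], window_hi = window[2],
         n_reference = sum(in_window), beta = beta),
    class = "poverty_line"
  )
}

#' @export
print.poverty_line <- function(x, ...) {
  cat(sprintf(
    "<poverty line: %.2f per equivalent adult (window %g-%g%%, n_ref %d, beta %.2f)>\n",
    x$value_per_eq_adult, x$window_lo, x$window_hi, x$n_reference, x$beta))
  invisible(x)
}

#' Subsistence expenditure
#'
#' The minimum spending a household needs to stay at the poverty line:
#' the per-equivalent-adult line scaled by the household's equivalized
#' size.
#'
#' @param household_size Integer vector of household sizes.
#' @param pl A [poverty_line()].
#' @param beta Equivalence-scale exponent; defaults to the one the line
#'   was computed with.
#' @return Numeric vector SE_h.
#' @export
subsistence_expenditure <- function(household_size, pl, beta = pl$beta) {
  stopifnot(inherits(pl, "poverty_line"))
  pl$value_per_eq_adult * equivalized_size(household_size, beta)
}

#' Capacity to pay with the food-substitution rule
#'
#' Capacity to pay is total expenditure net of subsistence expenditure,
#' `PC_h = THE_h - SE_h`.  For very poor households this difference can
#' be negative; in that case the poverty line is substituted by the
#' household's own food expenditure, so `PC_h = THE_h - food_h`, which is
#' non-negative whenever food spending is contained in total spending.
#'
#' @param the_h Annual total household expenditure.
#' @param food_h Annual food expenditure.
#' @param se_h Subsistence expenditure from [subsistence_expenditure()].
#' @return List with numeric `pc_h` and logical `substitution_applied`.
#' @export
capacity_to_pay <- function(the_h, food_h, se_h) {
  if (any(se_h < 0)) stop("`se_h` must be non-negative", call. = FALSE)
  if (any(the_h < food_h)) {
    stop("integrity error: total expenditure below food expenditure; ",
         "such rows must be rejected upstream", call. = FALSE)
  }
  pc <- the_h - se_h
  substituted <- pc < 0
  pc[substituted] <- the_h[substituted] - food_h[substituted]
  list(pc_h = pc, substitution_applied = substituted)
}

#' Catastrophic-expenditure indicator
#'
#' A household is flagged as incurring catastrophic health expenditure
#' when its OOP health spending reaches the threshold share of its
#' capacity to pay: `flag = 1` iff `oop_h / pc_h >= threshold` (closed
#' boundary).  A household with zero capacity to pay is flagged iff it
#' has any positive OOP spending (any spending against zero capacity is
#' catastrophic at every threshold); this degenerate case is reported
#' with a warning.
#'
#' @param oop_h Annual OOP health expenditure.
#' @param pc_h Capacity to pay (non-negative).
#' @param threshold Fraction of capacity to pay (default 0.30).
#' @return Integer vector of 0/1 flags.
#' @export
che_flag <- function(oop_h, pc_h, threshold = 0.30) {
  stopifnot(length(threshold) == 1L, threshold > 0, threshold < 1)
  if (any(pc_h < 0)) stop("`pc_h` must be non-negative", call. = FALSE)
  flag <- integer(length(oop_h))
  degenerate <- pc_h == 0
  if (any(degenerate & oop_h > 0)) {
    warning("zero capacity to pay with positive OOP spending: flagged ",
            "catastrophic at every threshold", call. = FALSE)
  }
  flag[degenerate] <- as.integer(oop_h[degenerate] > 0)
  ok <- !degenerate
  flag[ok] <- as.integer(oop_h[ok] / pc_h[ok] >= threshold)
  flag
}

#' Per-household CHE decomposition
#'
#' Runs the full capacity-to-pay chain on an annualized survey and
#' returns one row per household with every intermediate quantity and
#' the CHE flag at each requested threshold.  Mixed or monthly input is
#' refused: the statistic is defined on annual, single-currency values.
#'
#' @param survey An annualized `household_survey`.
#' @param beta Equivalence-scale exponent.
#' @param window Food-share percentile window for [poverty_line()].
#' @param thresholds Ascending vector of CHE thresholds in (0, 1).
#' @param pl Optionally, a precomputed [poverty_line()] to use instead of
#'   estimating one from `survey` (e.g. to hold the line fixed across
#'   counterfactual datasets).
#' @return A data frame of class `che_decomposition` with columns
#'   `household_id`, `the_h`, `food_h`, `eq_size`, `se_h`, `pc_h`,
#'   `substitution_applied`, `oop_h`, `ratio` and one `flag_<pct>` column
#'   per threshold; the poverty line is attached as attribute
#'   `"poverty_line"`.
#' @export
che_decompose <- function(survey, beta = 0.56, window = c(45, 55),
                          thresholds = c(0.10, 0.20, 0.30, 0.40),
                          pl = NULL) {
  stopifnot(inherits(survey, "household_survey"))
  if (survey$convention$period != "annual") {
    stop("CHE decomposition requires annualized data; call annualize()",
         call. = FALSE)
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly ascending", call. = FALSE)
  }
  records <- survey$records
  if (is.null(pl)) {
    pl <- poverty_line(records, beta = beta, window = window)
  } else {
    stopifnot(inherits(pl, "poverty_line"))
  }
  eq <- equivalized_size(records$household_size, beta)
  se <- subsistence_expenditure(records$household_size, pl, beta)
  cap <- capacity_to_pay(records$expenditure_total,
                         records$expenditure_food, se)
  oop <- oop_total(records)
  ratio <- ifelse(cap$pc_h > 0, oop / cap$pc_h,
                  ifelse(oop > 0, Inf, 0))
  out <- data.frame(
    household_id = records$household_id,
    the_h = records$expenditure_total,
    food_h = records$expenditure_food,
    eq_size = eq,
    se_h = se,
    pc_h = cap$pc_h,
    substitution_applied = cap$substitution_applied,
    oop_h = oop,
    ratio = ratio,
    stringsAsFactors = FALSE
  )
  for (z in thresholds) {
    out[[flag_column(z)]] <- che_flag(oop, cap$pc_h, z)
  }
  attr(out, "poverty_line") <- pl
  attr(out, "thresholds") <- thresholds
  class(out) <- c("che_decomposition", "data.frame")
  out
}

flag_column <- function(threshold) {
  sprintf("flag_%g", round(threshold * 100))
}

#' CHE incidence with a Wilson confidence interval
#'
#' Incidence is the percentage of households whose CHE indicator is 1.
#' The 95% interval is the Wilson score interval, chosen for its
#' behavior near 0% and 100%.
#'
#' @param flags Vector of 0/1 CHE indicators.
#' @param threshold The threshold the flags were computed at (recorded in
#'   the output; `NA` if unknown).
#' @return One-row data frame: `threshold`, `n_households`, `n_che`,
#'   `incidence_pct`, `ci_lo`, `ci_hi`.
#' @export
che_incidence <- function(flags, threshold = NA_real_) {
  if (length(flags) == 0L) {
    stop("empty flag collection", call. = FALSE)
  }
  if (!all(flags %in% c(0L, 1L))) {
    stop("`flags` must be 0/1", call. = FALSE)
  }
  n <- length(flags)
  k <- sum(flags)
  ci <- stats::prop.test(k, n, correct = FALSE)$conf.int
  data.frame(
    threshold = threshold,
    n_households = n,
    n_che = k,
    incidence_pct = 100 * k / n,
    ci_lo = 100 * ci[1],
    ci_hi = 100 * ci[2]
  )
}

#' Threshold sensitivity analysis of CHE incidence
#'
#' Computes incidence at each threshold from a single decomposition pass
#' over the data.  Because the flag is monotone in the threshold, the
#' incidence column is non-increasing.
#'
#' @inheritParams che_decompose
#' @param decomposition Optionally a precomputed [che_decompose()] result
#'   covering all `thresholds`.
#' @return Data frame with one [che_incidence()] row per threshold.
#' @export
sensitivity_analysis <- function(survey = NULL, beta = 0.56,
                                 window = c(45, 55),
                                 thresholds = c(0.10, 0.20, 0.30, 0.40),
                                 decomposition = NULL) {
  if (is.null(decomposition)) {
    decomposition <- che_decompose(survey, beta = beta, window = window,
                                   thresholds = thresholds)
  }
  rows <- lapply(thresholds, function(z) {
    col <- flag_column(z)
    if (!col %in% names(decomposition)) {
      stop("decomposition lacks flags at threshold ", z, call. = FALSE)
    }
    che_incidence(decomposition[[col]], threshold = z)
  })
  do.call(rbind, rows)
}
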