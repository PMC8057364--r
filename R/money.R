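#' Money convention metadata
#'
#' Every dataset in the pipeline carries an explicit statement of the
#' currency its money fields are expressed in and the period they cover.
#' Keeping this as first-class metadata (rather than implied by column
#' names) makes unit errors such as double annualization detectable.
#'
#' @param currency Currency of the money fields, `"MXN"` or `"USD"`.
#' @param period Period the flows cover, `"monthly"` or `"annual"`.
#' @param exchange_rate_mxn_per_usd Pesos per US dollar.  The default,
#'   20.48, is the mid-2018 market rate commonly used for Mexican survey
#'   data of that period.
#'
#' @return An object of class `money_convention`.
#' @examples
#' money_convention("MXN", "monthly")
#' @export
money_convention <- function(currency = c("MXN", "USD"),
                             period = c("monthly", "annual"),
                             exchange_rate_mxn_per_usd = 20.48) {
  currency <- match.arg(currency)
  period <- match.arg(period)
  if (!is.numeric(exchange_rate_mxn_per_usd) ||
      length(exchange_rate_mxn_per_usd) != 1L ||
      !is.finite(exchange_rate_mxn_per_usd) ||
      exchange_rate_mxn_per_usd <= 0) {
    stop("`exchange_rate_mxn_per_usd` must be a single positive number",
         call. = FALSE)
  }
  structure(
    list(currency = currency, period = period,
         exchange_rate_mxn_per_usd = exchange_rate_mxn_per_usd),
    class = "money_convention"
  )
}

#' @export
print.money_convention <- function(x, ...) {
  cat(sprintf("<money convention: %s, %s, %.4f MXN/USD>\n",
              x$currency, x$period, x$exchange_rate_mxn_per_usd))
  invisible(x)
}

#' Convert an amount between pesos and US dollars
#'
#' MXN to USD divides by the exchange rate, USD to MXN multiplies;
#' converting to the currency the amount is already in is the identity.
#'
#' @param amount Numeric vector of non-negative, finite amounts.
#' @param convention A [money_convention()] describing the currency the
#'   amount is currently in and the exchange rate to use.
#' @param target Target currency, `"MXN"` or `"USD"`.
#'
#' @return Numeric vector in the target currency.
#' @examples
#' conv <- money_convention("MXN", "monthly", 20.48)
#' convert_currency(20.48, conv, "USD")   # 1
#' convert_currency(1000, conv, "USD")    # 48.828125
#' @export
convert_currency <- function(amount, convention, target = c("USD", "MXN")) {
  target <- match.arg(target)
  stopifnot(inherits(convention, "money_convention"))
  if (!is.numeric(amount) || any(!is.finite(amount)) || any(amount < 0)) {
    stop("`amount` must be finite and non-negative", call. = FALSE)
  }
  rate <- convention$exchange_rate_mxn_per_usd
  if (!is.finite(rate) || rate <= 0) {
    stop("exchange rate must be positive", call. = FALSE)
  }
  if (convention$currency == target) {
    return(amount)
  }
  if (convention$currency == "MXN" && target == "USD") {
    amount / rate
  } else {
    amount * rate
  }
}

#' Convert every money column of a survey to another currency
#'
#' @param survey A `household_survey` (see [load_survey()]).
#' @param target Target currency.
#' @return The survey with money columns converted and metadata updated.
#' @export
convert_survey <- function(survey, target = c("USD", "MXN")) {
  target <- match.arg(target)
  stopifnot(inherits(survey, "household_survey"))
  if (survey$convention$currency == target) {
    return(survey)
  }
  conv <- survey$convention
  for (col in money_columns()) {
    survey$records[[col]] <- convert_currency(survey$records[[col]], conv,
                                              target)
  }
  survey$convention$currency <- target
  survey
}
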