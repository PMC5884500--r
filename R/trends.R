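#' Constants for currency conversion and trend reporting
#'
#' GDP deflators used to express 1995 Nepali rupee amounts in 2010 prices
#' (65.8 and 192.8), the 2010 exchange rate of 73.16 NPR per US dollar, and
#' the 15-year horizon between the two survey rounds.
#'
#' @param deflator_base GDP deflator of the base (earlier) year.
#' @param deflator_target GDP deflator of the target (later) year.
#' @param usd_rate NPR per USD in the target year.
#' @param horizon Years between the two survey rounds.
#' @return A list of class `trend_constants`.
#' @export
trend_constants <- function(deflator_base = 65.8, deflator_target = 192.8,
                            usd_rate = 73.16, horizon = 15) {
  assert_positive(c(deflator_base, deflator_target, usd_rate, horizon),
                  "trend constants")
  structure(list(deflator_base = deflator_base, deflator_target = deflator_target,
                 usd_rate = usd_rate, horizon = as.integer(horizon)),
            class = "trend_constants")
}

#' Convert between price years with GDP deflators
#'
#' @param value Currency amount(s).
#' @param from_deflator Deflator of the year the value is expressed in.
#' @param to_deflator Deflator of the target year.
#' @return `value * to_deflator / from_deflator`.
#' @examples
#' deflate(1, 65.8, 192.8) # 1995 NPR in 2010 prices
#' @export
deflate <- function(value, from_deflator, to_deflator) {
  assert_positive(c(from_deflator, to_deflator), "deflator")
  value * to_deflator / from_deflator
}

#' Convert Nepali rupees to US dollars
#'
#' @param value_npr Amount(s) in NPR.
#' @param rate NPR per USD (default the 2010 rate, 73.16).
#' @return Amount in USD.
#' @export
to_usd <- function(value_npr, rate = 73.16) {
  assert_nonnegative(value_npr, "value_npr")
  assert_positive(rate, "rate")
  value_npr / rate
}

#' Average annual rate of change
#'
#' Compound annual growth between two values a fixed number of years apart:
#' `100 * ((v_end / v_start)^(1/years) - 1)`, in percent per year. Both
#' values must be in the same price year (deflate first).
#'
#' @param v_start,v_end Positive start and end values.
#' @param years Number of years between them (>= 1).
#' @return Percent per year (full precision; round for display).
#' @examples
#' annual_rate_of_change(5.9, 11.6, 15) # ~4.6 %/year
#' @export
annual_rate_of_change <- function(v_start, v_end, years) {
  assert_positive(v_start, "v_start")
  assert_positive(v_end, "v_end")
  if (any(years < 1)) abort("`years` must be >= 1.")
  100 * ((v_end / v_start)^(1 / years) - 1)
}

#' Published disease-specific summary values for Nepal, 1995 and 2010
#'
#' Two shipped reference tables of published national estimates for Nepal:
#' `"oop_usd"` — mean monthly out-of-pocket payment per illness (2010 USD,
#' both years in 2010 prices); `"catastrophic_total10"` — incidence (%) of
#' catastrophic health payment at the 10%-of-total-consumption threshold.
#' Columns: `illness`, `value_1995`, `value_2010`, `printed_rate` (the
#' published average annual rate of change, % per year; `NA` where an
#' illness was observed in only one round), and `exact` (`TRUE` when the
#' published rate is exactly the compound rate of the two printed values to
#' one decimal; `FALSE` for rows where the publishers evidently rounded from
#' unrounded inputs, leaving a one-final-digit discrepancy).
#'
#' @param table `"oop_usd"` or `"catastrophic_total10"`.
#' @return A tibble.
#' @export
nepal_reference <- function(table = c("oop_usd", "catastrophic_total10")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("nepal_", table, ".csv"),
                      package = "oopburden")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Assemble a burden report
#'
#' Joins per-illness cost posteriors, incidence estimates and concentration
#' indices into one report table, optionally adding average annual rates of
#' change when results for two survey rounds are supplied.
#'
#' @param costs Tibble from [fit_costs()] (NPR/month), or `NULL`.
#' @param burdens Tibble of glanced [fit_incidence()] rows with a `code`
#'   column (use the `scope` label), or `NULL`.
#' @param concentrations Tibble of glanced [concentration()] rows (`scope`,
#'   `index`), or `NULL`.
#' @param constants A [trend_constants()]; costs are converted to USD with
#'   its exchange rate.
#' @param previous A report from an earlier survey round (same structure);
#'   when given, `rate_cost` and `rate_incidence` columns are added using
#'   `constants$horizon`, `NA` where either round lacks the illness.
#' @return A tibble with one row per illness code; missing upstream pieces
#'   leave their columns `NA`.
#' @export
build_report <- function(costs = NULL, burdens = NULL, concentrations = NULL,
                         constants = trend_constants(), previous = NULL) {
  pieces <- list()
  if (!is.null(costs)) {
    pieces$costs <- costs %>%
      mutate(mean_cost_usd = to_usd(.data$mean_cost, constants$usd_rate),
             cost_cri_low_usd = to_usd(.data$cri_low, constants$usd_rate),
             cost_cri_high_usd = to_usd(.data$cri_high, constants$usd_rate)) %>%
      select("code", "mean_cost_usd", "cost_cri_low_usd", "cost_cri_high_usd")
  }
  if (!is.null(burdens)) {
    pieces$burdens <- burdens %>%
      rename(code = "scope") %>%
      select("code", incidence_pct = "incidence",
             incidence_cri_low = "cri_low", incidence_cri_high = "cri_high") %>%
      mutate(dplyr::across(dplyr::starts_with("incidence"), ~ 100 * .x))
  }
  if (!is.null(concentrations)) {
    pieces$conc <- concentrations %>%
      rename(code = "scope") %>%
      select("code", concentration_index = "index")
  }
  if (!length(pieces)) abort("Nothing to report: all inputs are NULL.")
  report <- purrr::reduce(pieces, dplyr::full_join, by = "code")
  if (!is.null(previous)) {
    prev <- select(previous, "code",
                   prev_cost = dplyr::any_of("mean_cost_usd"),
                   prev_incidence = dplyr::any_of("incidence_pct"))
    report <- report %>%
      left_join(prev, by = "code") %>%
      mutate(
        rate_cost = safe_rate(.data$prev_cost, .data$mean_cost_usd, constants$horizon),
        rate_incidence = safe_rate(.data$prev_incidence, .data$incidence_pct,
                                   constants$horizon)
      ) %>%
      select(-dplyr::any_of(c("prev_cost", "prev_incidence")))
  }
  report
}

# rate of change that propagates NA instead of erroring (single-round rows)
safe_rate <- function(v_start, v_end, years) {
  out <- rep(NA_real_, length(v_end))
  ok <- !is.na(v_start) & !is.na(v_end) & v_start > 0 & v_end > 0
  out[ok] <- annual_rate_of_change(v_start[ok], v_end[ok], years)
  out
}

#' Format a report for display
#'
#' Rounds rate and cost columns half-away-from-zero to one decimal, the
#' convention used in published tables (full precision is retained in the
#' unformatted report).
#'
#' @param report A tibble from [build_report()].
#' @param digits Decimal places (default 1).
#' @return The report with numeric columns rounded.
#' @export
format_report <- function(report, digits = 1) {
  mutate(report, dplyr::across(dplyr::where(is.numeric),
                               ~ round_half_up(.x, digits)))
}
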