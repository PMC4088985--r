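# Indirect standardization: expected counts from reference age-sex rates,
# standardized incidence ratios and standardized rates.

#' Expected case counts by indirect standardization
#'
#' E = sum over age bands of person_count x reference rate, per
#' area-year-sex stratum. Every population cell must have a matching
#' reference rate.
#'
#' @param population Data frame `area_id`, `year`, `sex`, `age_group`,
#'   `person_count` (persons aged 35+, 5-year bands, open-ended top band).
#' @param ref_rates Data frame `sex`, `age_group`, `rate` (cases per
#'   person-year).
#' @return Data frame `area_id`, `year`, `sex`, `E`.
#' @export
expected_counts <- function(population, ref_rates) {
  m <- merge(population, ref_rates, by = c("sex", "age_group"),
             all.x = TRUE, sort = FALSE)
  if (anyNA(m$rate)) {
    bad <- unique(paste(m$sex[is.na(m$rate)], m$age_group[is.na(m$rate)],
                        sep = "/"))
    stop("no reference rate for cell(s): ", paste(bad, collapse = ", "))
  }
  m$contrib <- m$person_count * m$rate
  out <- aggregate(contrib ~ area_id + year + sex, data = m, FUN = sum)
  names(out)[names(out) == "contrib"] <- "E"
  out[order(out$area_id, out$year, out$sex), , drop = FALSE]
}

#' Standardized incidence ratio with exact Poisson limits
#'
#' Point estimate O/E with an exact (chi-square quantile) interval for the
#' Poisson count O, scaled by 1/E. For O = 0 the lower limit is 0 and the
#' upper limit is -log((1-conf)/2)/E.
#'
#' @param O Observed case count(s), non-negative integers.
#' @param E Expected count(s), strictly positive.
#' @param conf Coverage of the interval (default 0.95).
#' @return Data frame `O`, `E`, `sir`, `lower`, `upper`.
#' @export
sir <- function(O, E, conf = 0.95) {
  if (any(E <= 0)) stop("E must be strictly positive")
  if (any(O < 0)) stop("O must be non-negative")
  a <- 1 - conf
  lower <- ifelse(O == 0, 0, qchisq(a / 2, 2 * O) / 2) / E
  upper <- qchisq(1 - a / 2, 2 * (O + 1)) / 2 / E
  data.frame(O = O, E = E, sir = O / E, lower = lower, upper = upper)
}

#' Indirectly standardized rate
#'
#' Multiplies a standardized incidence ratio (and its interval limits) by
#' the reference population's crude rate, conventionally per 100,000
#' person-years.
#'
#' @param sir_value SIR point estimate(s), or the data frame returned by
#'   [sir()].
#' @param ref_crude_rate Crude rate of the reference population (per
#'   100,000), strictly positive.
#' @return Rates on the scale of `ref_crude_rate`; a data frame with
#'   `rate`, `lower`, `upper` when given a [sir()] result.
#' @export
standardized_rate <- function(sir_value, ref_crude_rate) {
  if (any(ref_crude_rate <= 0)) stop("ref_crude_rate must be positive")
  if (is.data.frame(sir_value)) {
    data.frame(rate = sir_value$sir * ref_crude_rate,
               lower = sir_value$lower * ref_crude_rate,
               upper = sir_value$upper * ref_crude_rate)
  } else {
    sir_value * ref_crude_rate
  }
}
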