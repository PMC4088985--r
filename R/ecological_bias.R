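# Pure-specification (within-area variability) bias correction for the
# ecological log-linear model.

#' Bias-corrected exposure contribution to the linear predictor
#'
#' When individual exposures within an area are Normal(xbar, s2) and
#' individual risk is proportional to exp(beta X), the area-level mean
#' risk is exp(beta xbar + beta^2 s2 / 2). The correction therefore adds
#' a within-area variance term whose coefficient is beta^2/2 -- a function
#' of beta, not a free parameter.
#'
#' @param beta Log rate ratio per unit of the scaled exposure axis.
#' @param xbar Area mean exposure (scaled).
#' @param s2 Within-area exposure variance on the same scaled axis
#'   (i.e. divided by IQR^2), non-negative.
#' @return `beta * xbar + beta^2/2 * s2`.
#' @export
corrected_linear_predictor <- function(beta, xbar, s2) {
  if (any(s2 < 0)) stop("s2 must be non-negative")
  beta * xbar + 0.5 * beta^2 * s2
}

#' Handle records with unavailable exposure variance
#'
#' Areas covered by a single water system have no between-system variance.
#' `"zero_term"` keeps every record and sets the variance term to zero
#' where unavailable; `"restrict"` drops such records (sensitivity
#' analysis) and records the retained fraction as an attribute.
#'
#' @param records Data frame with columns `s2` and `variance_available`.
#' @param policy `"zero_term"` or `"restrict"`.
#' @return `records`, possibly filtered, with `s2` filled; attribute
#'   `retained_fraction` gives the share of records kept.
#' @export
apply_variance_policy <- function(records, policy = c("zero_term", "restrict")) {
  policy <- match.arg(policy)
  if (is.null(records$variance_available))
    records$variance_available <- !is.na(records$s2)
  avail <- records$variance_available & !is.na(records$s2)
  if (policy == "zero_term") {
    records$s2[!avail] <- 0
    attr(records, "retained_fraction") <- 1
  } else {
    frac <- mean(avail)
    if (frac == 0)
      stop("restrict policy would drop every record")
    records <- records[avail, , drop = FALSE]
    attr(records, "retained_fraction") <- frac
    message(sprintf("variance restriction retained %.0f%% of records",
                    100 * frac))
  }
  records
}
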