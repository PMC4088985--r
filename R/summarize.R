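# Posterior summaries: per-IQR incidence rate ratios, the relative index
# of inequality, and sensitivity-analysis tables.

#' Incidence rate ratio per IQR increase in exposure
#'
#' Because the exposure enters the model in IQR units, exp(beta) is the
#' multiplicative change in incidence per interquartile-range increase.
#' The point estimate is the exponential of the posterior median and the
#' interval the exponential of the equal-tailed 2.5/97.5 percentiles
#' (exact, since exp is monotone).
#'
#' @param beta_draws Posterior draws of the exposure coefficient, or a
#'   `bym_fit` (its `"beta"` draws are used).
#' @return Data frame `irr`, `lo95`, `hi95`.
#' @export
irr_per_iqr <- function(beta_draws) {
  if (inherits(beta_draws, "bym_fit"))
    beta_draws <- parameter_draws(beta_draws, "beta")
  if (length(beta_draws) == 0) stop("no posterior draws supplied")
  q <- quantile(beta_draws, c(0.5, 0.025, 0.975), names = FALSE)
  data.frame(irr = exp(q[1]), lo95 = exp(q[2]), hi95 = exp(q[3]))
}

#' Relative index of inequality
#'
#' The RII is the rate ratio across the full socioeconomic gradient,
#' computed as exp(-beta) where beta is the coefficient of the
#' unit-interval-scaled socioeconomic score (ascending in the IRSD index, i.e. in
#' advantage). An RII below 1 means the most disadvantaged areas have
#' lower incidence.
#'
#' @param beta_irsd_draws Posterior draws of the socioeconomic-score
#'   coefficient on the unit-interval gradient scale.
#' @return Data frame `rii`, `lo95`, `hi95` (posterior median and
#'   equal-tailed 95% interval of exp(-beta)).
#' @export
rii <- function(beta_irsd_draws) {
  q <- quantile(beta_irsd_draws, c(0.5, 0.975, 0.025), names = FALSE)
  data.frame(rii = exp(-q[1]), lo95 = exp(-q[2]), hi95 = exp(-q[3]))
}

#' Sensitivity-analysis grid
#'
#' Assembles per-variant IRR summaries from a named list of fits
#' (baseline, averaged exposure, no spatial effect, variance term, ...)
#' into one table. Variants are reported as supplied, never imputed.
#'
#' @param fits Named list of `bym_fit` objects; names are the variant
#'   labels. Metadata (`species`, `sex`, `site`) is taken from each fit's
#'   `meta`.
#' @param diagnostics Also compute R-hat for beta and the DIC per variant.
#' @return Data frame, one row per variant.
#' @export
sensitivity_grid <- function(fits, diagnostics = TRUE) {
  if (is.null(names(fits)) || any(names(fits) == "") ||
      anyDuplicated(names(fits)))
    stop("fits must be a uniquely named list of model variants")
  rows <- lapply(names(fits), function(vn) {
    f <- fits[[vn]]
    s <- irr_per_iqr(f)
    out <- data.frame(variant = vn,
                      species = f$meta$species %||% NA_character_,
                      sex = f$meta$sex %||% NA_character_,
                      site = f$meta$site %||% NA_character_,
                      irr = s$irr, lo95 = s$lo95, hi95 = s$hi95,
                      stringsAsFactors = FALSE)
    if (diagnostics) {
      out$rhat_beta <- gelman_rubin(f$chains, "beta")
      out$dic <- dic(f)$dic
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
summary.bym_fit <- function(object, ...) {
  core <- c("alpha", "beta",
            if (length(object$covariates) > 0)
              paste0("gamma_", object$covariates),
            "tau_u", if (object$spatial) "tau_v")
  tab <- do.call(rbind, lapply(core, function(p) {
    d <- parameter_draws(object, p)
    q <- quantile(d, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(parameter = p, median = q[1], lo95 = q[2], hi95 = q[3],
               rhat = gelman_rubin(object$chains, p),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  d <- dic(object)
  structure(list(parameters = tab, irr = irr_per_iqr(object),
                 dic = d$dic, pd = d$pd,
                 retained_fraction = object$retained_fraction,
                 meta = object$meta),
            class = "summary.bym_fit")
}

#' @export
print.summary.bym_fit <- function(x, ...) {
  cat("Hierarchical spatial Poisson model\n")
  if (length(x$meta) > 0)
    cat(" ", paste(names(x$meta), unlist(x$meta), sep = "=",
                   collapse = ", "), "\n")
  cat(sprintf("  IRR per IQR: %.3f (95%% CI %.3f, %.3f)\n",
              x$irr$irr, x$irr$lo95, x$irr$hi95))
  cat(sprintf("  DIC %.1f (pD %.1f)\n", x$dic, x$pd))
  print(x$parameters, digits = 3)
  invisible(x)
}
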