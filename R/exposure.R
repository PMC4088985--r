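# Reconstruction of annual area-level THM exposure from monthly site
# samples collected in water distribution systems that do not align with
# administrative area boundaries.

#' Substitute concentrations reported below the detection limit
#'
#' Left-censored sample values are replaced by a deterministic fraction of
#' their detection limit (DL): two thirds of the DL (the primary rule) or
#' DL divided by sqrt(2) (a common alternative used for sensitivity
#' analysis). Observed values are never altered, and the substitution is
#' idempotent because it is recomputed from the stored DL.
#'
#' @param samples Data frame of monthly samples with columns `site_id`,
#'   `dist_system_id`, `delivery_system_id`, `year`, `month`, `species`,
#'   `value` (µg/L, `NA` allowed when `below_dl` is 1), `below_dl` (0/1)
#'   and `dl` (detection limit, µg/L).
#' @param method `"two_thirds_dl"` (default) or `"dl_sqrt2"`.
#' @return `samples` with censored values filled in.
#' @export
substitute_below_dl <- function(samples, method = c("two_thirds_dl", "dl_sqrt2")) {
  method <- match.arg(method)
  cens <- samples$below_dl == 1
  bad <- cens & (is.na(samples$dl) | samples$dl <= 0)
  if (any(bad)) {
    warning(sprintf("rejected %d censored record(s) without a valid detection limit",
                    sum(bad)))
    samples <- samples[!bad, , drop = FALSE]
    cens <- samples$below_dl == 1
  }
  f <- if (method == "two_thirds_dl") 2 / 3 else 1 / sqrt(2)
  samples$value[cens] <- f * samples$dl[cens]
  samples
}

#' Monthly mean concentration per distribution system
#'
#' First stage of the two-stage annual mean: sample values are averaged
#' over sites within each system-month. The result is a complete grid over
#' system x year x month x species with `NA` where no sample exists, which
#' is the unit the cluster-mean imputation operates on.
#'
#' @param samples Data frame as in [substitute_below_dl()], with censored
#'   values already substituted.
#' @param systems,years Systems and years spanning the grid; default those
#'   present in `samples`. Supplying the full system list from the
#'   hierarchy lets wholly unmonitored systems enter the imputation stage.
#' @return Data frame `dist_system_id`, `year`, `month`, `species`,
#'   `value`, `imputation_source` (`"observed"` or `"missing"`).
#' @export
zone_month_means <- function(samples, systems = NULL, years = NULL) {
  if (nrow(samples) == 0) {
    return(data.frame(dist_system_id = character(), year = integer(),
                      month = integer(), species = character(),
                      value = numeric(), imputation_source = character(),
                      stringsAsFactors = FALSE))
  }
  if (anyNA(samples$value))
    stop("samples contain NA values; run substitute_below_dl() first")
  agg <- aggregate(value ~ dist_system_id + year + month + species,
                   data = samples, FUN = mean)
  grid <- expand.grid(dist_system_id = systems %||%
                        unique(samples$dist_system_id),
                      year = years %||% sort(unique(samples$year)),
                      month = 1:12,
                      species = unique(samples$species),
                      stringsAsFactors = FALSE)
  out <- merge(grid, agg, all.x = TRUE, sort = FALSE)
  out$imputation_source <- ifelse(is.na(out$value), "missing", "observed")
  out[order(out$species, out$dist_system_id, out$year, out$month), ,
      drop = FALSE]
}

#' Cluster-mean imputation of missing system-months
#'
#' Distribution systems are nested in delivery systems. A missing
#' system-month is imputed by the mean of the observed values of its
#' sister systems (same delivery system) for that month; system-months
#' still missing afterwards fall back to the system's annual mean over its
#' observed months; anything left is flagged missing. Observed values are
#' never modified.
#'
#' @param zone_months Output of [zone_month_means()].
#' @param hierarchy Data frame `dist_system_id`, `delivery_system_id`
#'   mapping each distribution system to exactly one delivery system.
#' @return `zone_months` with imputed values and `imputation_source` set to
#'   `"observed"`, `"delivery_month"`, `"system_annual"` or `"missing"`.
#' @export
impute_cluster_mean <- function(zone_months, hierarchy) {
  zm <- zone_months
  unknown <- setdiff(unique(zm$dist_system_id), hierarchy$dist_system_id)
  if (length(unknown) > 0)
    stop("distribution system(s) absent from hierarchy: ",
         paste(unknown, collapse = ", "))
  deliv <- hierarchy$delivery_system_id[match(zm$dist_system_id,
                                              hierarchy$dist_system_id)]
  obs <- zm$imputation_source == "observed"

  # stage 1: delivery-system mean of sister systems for that month
  key_dm <- paste(deliv, zm$year, zm$month, zm$species, sep = "\r")
  dm_mean <- tapply(zm$value[obs], key_dm[obs], mean)
  miss <- !obs
  fill <- dm_mean[key_dm]
  use1 <- miss & !is.na(fill)
  zm$value[use1] <- fill[use1]
  zm$imputation_source[use1] <- "delivery_month"

  # stage 2: the system's own annual mean over observed months
  key_sy <- paste(zm$dist_system_id, zm$year, zm$species, sep = "\r")
  sy_mean <- tapply(zm$value[obs], key_sy[obs], mean)
  miss <- zm$imputation_source == "missing"
  fill <- sy_mean[key_sy]
  use2 <- miss & !is.na(fill)
  zm$value[use2] <- fill[use2]
  zm$imputation_source[use2] <- "system_annual"
  zm
}

#' Annualize system-month means
#'
#' Second stage of the two-stage mean: months with a (possibly imputed)
#' value are averaged into a system-year mean. A year with no usable month
#' is reported missing.
#'
#' @param zone_months Output of [zone_month_means()] or
#'   [impute_cluster_mean()].
#' @return Data frame `dist_system_id`, `year`, `species`, `mean`,
#'   `n_months_observed`, `imputation_source` (deepest fallback used),
#'   `imputed_fraction`.
#' @export
annualize_zone_months <- function(zone_months) {
  zm <- zone_months
  key <- paste(zm$dist_system_id, zm$year, zm$species, sep = "\r")
  groups <- split(seq_len(nrow(zm)), key)
  rows <- lapply(groups, function(idx) {
    g <- zm[idx, , drop = FALSE]
    usable <- !is.na(g$value)
    n_obs <- sum(g$imputation_source == "observed")
    if (!any(usable)) {
      src <- "missing"; m <- NA_real_; frac <- NA_real_
    } else {
      m <- mean(g$value[usable])
      srcs <- g$imputation_source[usable]
      src <- if (any(srcs == "system_annual")) "system_annual"
             else if (any(srcs == "delivery_month")) "delivery_month"
             else "observed"
      frac <- mean(srcs != "observed")
    }
    data.frame(dist_system_id = g$dist_system_id[1], year = g$year[1],
               species = g$species[1], mean = m, n_months_observed = n_obs,
               imputation_source = src, imputed_fraction = frac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$species, out$dist_system_id, out$year), , drop = FALSE]
}

#' Two-stage annual mean per distribution system
#'
#' Convenience composition of [zone_month_means()] and
#' [annualize_zone_months()] without imputation: sites are averaged within
#' system-months, then observed months within years.
#'
#' @inheritParams zone_month_means
#' @return See [annualize_zone_months()].
#' @export
aggregate_to_zone_year <- function(samples) {
  annualize_zone_months(zone_month_means(samples))
}

#' Area-weighted exposure means and variances
#'
#' Annual system means are carried onto areas using the fraction of each
#' area's surface covered by each system. Weights are renormalized over
#' the systems with a non-missing mean; the weighted between-system
#' variance (population form) is reported when at least two systems
#' contribute, and flagged unavailable otherwise. Area-years with no
#' contributing system are dropped with a message.
#'
#' @param zone_years Output of [annualize_zone_months()].
#' @param weights Data frame `area_id`, `dist_system_id`, `weight`; per
#'   area the weights must be non-negative and sum to 1 (tolerance 1e-6).
#' @return Data frame `area_id`, `year`, `species`, `xbar`, `s2`,
#'   `variance_available`, `n_zones`, `imputed_fraction`.
#' @export
area_weighted_exposure <- function(zone_years, weights) {
  if (any(weights$weight < 0)) stop("negative overlap weight")
  rs <- tapply(weights$weight, weights$area_id, sum)
  off <- abs(rs - 1) > 1e-6
  if (any(off))
    stop("overlap weights do not sum to 1 for area(s): ",
         paste(names(rs)[off], collapse = ", "))
  m <- merge(weights, zone_years, by = "dist_system_id")
  if (nrow(m) == 0)
    stop("no distribution system shared between weights and zone_years")
  key <- paste(m$area_id, m$year, m$species, sep = "\r")
  groups <- split(seq_len(nrow(m)), key)
  dropped <- character()
  rows <- lapply(groups, function(idx) {
    g <- m[idx, , drop = FALSE]
    ok <- !is.na(g$mean)
    if (!any(ok)) {
      dropped <<- c(dropped, paste0(g$area_id[1], "/", g$year[1]))
      return(NULL)
    }
    w <- g$weight[ok] / sum(g$weight[ok])
    mm <- g$mean[ok]
    xbar <- sum(w * mm)
    nz <- sum(ok)
    s2 <- if (nz >= 2) sum(w * (mm - xbar)^2) else NA_real_
    data.frame(area_id = g$area_id[1], year = g$year[1],
               species = g$species[1], xbar = xbar, s2 = s2,
               variance_available = nz >= 2, n_zones = nz,
               imputed_fraction = mean(g$imputed_fraction[ok]),
               stringsAsFactors = FALSE)
  })
  dropped <- unique(dropped)
  if (length(dropped) > 0)
    message("dropped ", length(dropped),
            " area-year(s) with no exposure data: ",
            paste(utils::head(dropped, 10), collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$species, out$area_id, out$year), , drop = FALSE]
}

#' Align exposure years to outcome years
#'
#' Under the lag design, exposure measured in calendar year y informs
#' outcomes in year y + lag (default lag 5). The alternative design
#' replaces the lag by the mean exposure over all available calendar
#' years, assigned identically to every outcome year (variances pooled as
#' the mean of the yearly variances).
#'
#' @param area_exposure Output of [area_weighted_exposure()].
#' @param mode `"lag5"` (default) or `"average_years"`.
#' @param outcome_years Integer vector of outcome calendar years.
#' @param lag Lag in years used by `"lag5"`.
#' @return Data frame keyed by outcome `year` with the same exposure
#'   columns.
#' @export
align_exposure <- function(area_exposure, mode = c("lag5", "average_years"),
                           outcome_years, lag = 5) {
  mode <- match.arg(mode)
  if (mode == "lag5") {
    covered <- unique(area_exposure$year + lag)
    missing_years <- setdiff(outcome_years, covered)
    if (length(missing_years) > 0)
      stop("no exposure year covers outcome year(s): ",
           paste(sort(missing_years), collapse = ", "))
    out <- area_exposure
    out$year <- out$year + lag
    out[out$year %in% outcome_years, , drop = FALSE]
  } else {
    key <- paste(area_exposure$area_id, area_exposure$species, sep = "\r")
    groups <- split(seq_len(nrow(area_exposure)), key)
    rows <- lapply(groups, function(idx) {
      g <- area_exposure[idx, , drop = FALSE]
      s2 <- if (any(g$variance_available)) {
        mean(g$s2[g$variance_available])
      } else NA_real_
      data.frame(area_id = g$area_id[1], species = g$species[1],
                 xbar = mean(g$xbar, na.rm = TRUE), s2 = s2,
                 variance_available = any(g$variance_available),
                 n_zones = max(g$n_zones),
                 imputed_fraction = mean(g$imputed_fraction),
                 stringsAsFactors = FALSE)
    })
    avg <- do.call(rbind, rows)
    out <- merge(data.frame(year = outcome_years), avg)
    out[, c("area_id", "year", "species", "xbar", "s2",
            "variance_available", "n_zones", "imputed_fraction")]
  }
}

#' Pooled interquartile range
#'
#' IQR over all area-years in the analysis dataset, computed with linear
#' interpolation between order statistics (quantile type 7). One unit of
#' the scaled exposure axis then corresponds to one IQR.
#'
#' @param x Numeric vector of exposure values; `NA`s dropped.
#' @return The interquartile range.
#' @export
pooled_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  q[2] - q[1]
}

#' Scale exposure to interquartile-range units
#'
#' @param x Exposure values (µg/L).
#' @param iqr Interquartile range (µg/L), must be positive.
#' @return `x / iqr`, so a unit change is one IQR.
#' @export
iqr_scale <- function(x, iqr) {
  if (!is.finite(iqr) || iqr <= 0) stop("iqr must be a positive number")
  x / iqr
}

#' Full exposure reconstruction pipeline
#'
#' DL substitution, two-stage aggregation, cluster-mean imputation and
#' area weighting in one call.
#'
#' @inheritParams substitute_below_dl
#' @inheritParams impute_cluster_mean
#' @inheritParams area_weighted_exposure
#' @param dl_method Below-DL substitution rule, see [substitute_below_dl()].
#' @return See [area_weighted_exposure()].
#' @export
estimate_area_exposure <- function(samples, weights, hierarchy,
                                   dl_method = "two_thirds_dl") {
  s <- substitute_below_dl(samples, dl_method)
  zm <- zone_month_means(s, systems = hierarchy$dist_system_id)
  zm <- impute_cluster_mean(zm, hierarchy)
  area_weighted_exposure(annualize_zone_months(zm), weights)
}
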