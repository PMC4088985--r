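# Synthetic study generator: geography, misaligned water systems, monthly
# THM series with missingness and detection-limit censoring, populations,
# reference rates, and Poisson outcomes under known parameters.

#' Synthetic study configuration
#'
#' Defaults emulate the study conditions: 50 areas on a 10 x 5 grid (45
#' in a large "SWC"-like region, 5 in a small "HWC"-like region), 33
#' distribution systems nested in 14 delivery systems, exposure years
#' 1995-2001 informing outcome years 2000-2006 through a 5-year lag,
#' monthly missingness of 15% before 2000 and 5% after, a bromoform
#' detection limit of 1 ug/L stepping to 3 ug/L in 1999, species
#' magnitudes anchored to realistic distribution-level THM
#' concentrations, and a true per-IQR log incidence rate ratio of
#' log(1.025) for bromoform.
#'
#' @param n_areas,grid_nrow,grid_ncol Number of areas and grid layout
#'   (`n_areas` must equal `grid_nrow * grid_ncol`).
#' @param n_hwc Number of areas in the small region.
#' @param n_dist_systems,n_delivery_systems Water system counts;
#'   distribution systems are nested in delivery systems.
#' @param mean_systems_per_area Mean number of distribution systems
#'   covering an area (1 to 8).
#' @param exposure_years,outcome_years,lag Calendar design.
#' @param missing_pre2000,missing_post2000 Monthly missingness rates.
#' @param dl_bromoform Length-2 vector: DL before 1999 and from 1999 on.
#' @param dl_other DL for the remaining species (rarely binding).
#' @param species_mean Named mean concentrations (ug/L) of the four
#'   measured species; the total (TTHM) is their sum.
#' @param cv_between,cv_within Log-scale SD between systems and within
#'   system-months.
#' @param seasonal_amp,trend Seasonal log-amplitude and yearly log trend.
#' @param beta Named true per-IQR log-IRR per species.
#' @param alpha True intercept.
#' @param gamma Named true covariate effects (year is per centered year,
#'   ses per unit of the unit-interval score, proportions per unit, region for
#'   the small-region indicator).
#' @param sigma_u,sigma_v SDs of the exchangeable and ICAR random effects
#'   (the ICAR precision is 1/sigma_v^2).
#' @param pop_base_mean Mean population aged 35+ per area and sex.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_areas = 50, grid_nrow = 10, grid_ncol = 5,
                       n_hwc = 5, n_dist_systems = 33,
                       n_delivery_systems = 14, mean_systems_per_area = 3,
                       exposure_years = 1995:2001,
                       outcome_years = 2000:2006, lag = 5,
                       missing_pre2000 = 0.15, missing_post2000 = 0.05,
                       dl_bromoform = c(1, 3), dl_other = 0.5,
                       species_mean = c(chloroform = 37.7, bromoform = 2.8,
                                        BDCM = 16.7, DBCM = 7.0),
                       cv_between = 0.45, cv_within = 0.2,
                       seasonal_amp = 0.25, trend = 0.03,
                       beta = c(chloroform = 0, bromoform = log(1.025),
                                BDCM = 0, DBCM = 0, TTHM = 0),
                       alpha = 0,
                       gamma = c(yearc = -0.01, ses = 0.073,
                                 smoking = 0.3, drinking = 0.25,
                                 tap = 0.2, region = 0.15),
                       sigma_u = 0.1, sigma_v = 0.1,
                       pop_base_mean = 6000) {
  stopifnot(n_areas == grid_nrow * grid_ncol, n_areas >= 4,
            n_hwc < n_areas, mean_systems_per_area >= 1,
            mean_systems_per_area <= 8,
            missing_pre2000 >= 0, missing_pre2000 <= 1,
            missing_post2000 >= 0, missing_post2000 <= 1,
            sigma_u >= 0, sigma_v >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate synthetic geography
#'
#' Rook-contiguity grid adjacency; each area is covered by 1-8
#' distribution systems (mean as configured) with Dirichlet-distributed
#' overlap weights summing to 1; each distribution system is nested in
#' exactly one delivery system. Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @return List with `graph` ([adjacency_graph()]), `weights`,
#'   `hierarchy`, `areas` and `region` (per-area region data frame).
#' @export
make_geography <- function(config) {
  graph <- grid_adjacency(config$grid_nrow, config$grid_ncol)
  areas <- graph$ids
  nd <- config$n_dist_systems
  dist_ids <- sprintf("D%02d", seq_len(nd))
  deliv_ids <- sprintf("S%02d", seq_len(config$n_delivery_systems))
  hierarchy <- data.frame(
    dist_system_id = dist_ids,
    delivery_system_id = deliv_ids[rep_len(seq_len(config$n_delivery_systems), nd)],
    stringsAsFactors = FALSE)
  k <- 1L + rbinom(config$n_areas, 7L, (config$mean_systems_per_area - 1) / 7)
  if (any(k > nd))
    stop("infeasible geography: an area requires more covering systems ",
         "than there are distribution systems")
  rows <- lapply(seq_len(config$n_areas), function(i) {
    sys <- sample(dist_ids, k[i])
    w <- rgamma(k[i], 1)
    data.frame(area_id = areas[i], dist_system_id = sys, weight = w / sum(w),
               stringsAsFactors = FALSE)
  })
  weights <- do.call(rbind, rows)
  rownames(weights) <- NULL
  region <- data.frame(area_id = areas,
                       region = ifelse(seq_along(areas) >
                                         config$n_areas - config$n_hwc,
                                       "HWC", "SWC"),
                       stringsAsFactors = FALSE)
  list(graph = graph, weights = weights, hierarchy = hierarchy,
       areas = areas, region = region)
}

# detection limit per species and year
dl_for <- function(config, species, year) {
  ifelse(species == "bromoform",
         ifelse(year >= 1999, config$dl_bromoform[2], config$dl_bromoform[1]),
         config$dl_other)
}

#' Simulate monthly THM samples
#'
#' Per-system lognormal concentration levels modulated by a seasonal
#' sinusoid and a yearly trend, observed at 1-3 sampling sites per
#' system. The total (TTHM) is the sum of the four species at the sample
#' level. Whole system-months are dropped at the configured missingness
#' rate, and values below the year's detection limit are emitted censored
#' (value `NA`, `below_dl` 1) with the DL recorded.
#'
#' @param config A [sim_config()].
#' @param geography Output of [make_geography()].
#' @return Monthly sample data frame (see [substitute_below_dl()]), plus
#'   a `true_zone_month` attribute used by round-trip checks: the exact
#'   system-month species means before censoring and missingness.
#' @export
simulate_thm <- function(config, geography) {
  nd <- config$n_dist_systems
  dist_ids <- geography$hierarchy$dist_system_id
  deliv <- geography$hierarchy$delivery_system_id
  n_sites <- sample(1:3, nd, replace = TRUE)
  years <- config$exposure_years
  spn <- names(config$species_mean)

  # system base levels per species (lognormal, mean anchored)
  L <- sapply(spn, function(sp) {
    config$species_mean[[sp]] *
      exp(rnorm(nd, 0, config$cv_between) - config$cv_between^2 / 2)
  })

  grid <- expand.grid(sys = seq_len(nd), year = years, month = 1:12,
                      KEEP.OUT.ATTRS = FALSE)
  rate <- ifelse(grid$year < 2000, config$missing_pre2000,
                 config$missing_post2000)
  grid$missing <- runif(nrow(grid)) < rate

  rows <- vector("list", length(spn))
  true_rows <- vector("list", length(spn))
  for (si in seq_along(spn)) {
    sp <- spn[si]
    g <- grid[rep(seq_len(nrow(grid)), n_sites[grid$sys]), , drop = FALSE]
    site_no <- sequence(n_sites[grid$sys])
    logmult <- config$seasonal_amp * sin(2 * pi * g$month / 12) +
      config$trend * (g$year - years[1]) +
      rnorm(nrow(g), 0, config$cv_within)
    val <- L[g$sys, si] * exp(logmult)
    rows[[si]] <- data.frame(
      site_id = paste0(dist_ids[g$sys], "_s", site_no),
      dist_system_id = dist_ids[g$sys],
      delivery_system_id = deliv[g$sys],
      year = g$year, month = g$month, species = sp, value = val,
      missing = g$missing, stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  # total THM = sum of species within each sample
  key <- paste(samples$site_id, samples$year, samples$month, sep = "\r")
  tt <- rows[[1]]
  tt$species <- "TTHM"
  tt$value <- as.numeric(tapply(samples$value, key, sum)[
    paste(tt$site_id, tt$year, tt$month, sep = "\r")])
  samples <- rbind(samples, tt)

  # exact system-month means before censoring/missingness (oracle record)
  truth <- aggregate(value ~ dist_system_id + year + month + species,
                     data = samples, FUN = mean)

  samples <- samples[!samples$missing, , drop = FALSE]
  samples$missing <- NULL
  samples$dl <- dl_for(config, samples$species, samples$year)
  cens <- samples$value < samples$dl
  samples$below_dl <- as.integer(cens)
  samples$value[cens] <- NA_real_
  rownames(samples) <- NULL
  attr(samples, "true_zone_month") <- truth
  samples
}

#' Simulate area-level covariates
#'
#' Socioeconomic score as a unit-interval-scaled quintile (ascending in the
#' socioeconomic index, i.e. in advantage), smoking / high-risk drinking
#' / tap-water proportions from Beta distributions, and the small-region
#' indicator.
#'
#' @inheritParams simulate_thm
#' @return Data frame `area_id`, `ses`, `smoking`, `drinking`, `tap`,
#'   `region` (0/1 indicator of the small region).
#' @export
simulate_covariates <- function(config, geography) {
  n <- config$n_areas
  rank_adv <- rank(runif(n), ties.method = "first")
  quintile <- ceiling(5 * rank_adv / n)
  rb <- function(m, conc) rbeta(n, m * conc, (1 - m) * conc)
  data.frame(area_id = geography$areas,
             ses = (quintile - 1) / 4,
             smoking = rb(0.22, 60),
             drinking = rb(0.35, 60),
             tap = rb(0.88, 30),
             region = as.integer(geography$region$region == "HWC"),
             stringsAsFactors = FALSE)
}

#' Default reference incidence rates
#'
#' Age- and sex-specific colorectal-cancer-like reference rates (cases
#' per person-year) for the eleven 5-year bands from 35-39 to 85+,
#' rising steeply with age and about a third higher in men.
#'
#' @return Data frame `sex`, `age_group`, `rate`.
#' @export
default_ref_rates <- function() {
  bands <- c("35-39", "40-44", "45-49", "50-54", "55-59", "60-64",
             "65-69", "70-74", "75-79", "80-84", "85+")
  male <- c(10, 16, 26, 42, 68, 110, 170, 250, 340, 420, 480) / 1e5
  rbind(data.frame(sex = "male", age_group = bands, rate = male,
                   stringsAsFactors = FALSE),
        data.frame(sex = "female", age_group = bands, rate = 0.75 * male,
                   stringsAsFactors = FALSE))
}

#' Simulate area populations
#'
#' Lognormal area sizes with a declining age profile and mild yearly
#' growth, for both sexes and the eleven age bands 35+.
#'
#' @inheritParams simulate_thm
#' @return Data frame `area_id`, `year`, `sex`, `age_group`,
#'   `person_count`.
#' @export
simulate_population <- function(config, geography) {
  bands <- unique(default_ref_rates()$age_group)
  w <- exp(-0.18 * (seq_along(bands) - 1))
  w <- w / sum(w)
  base <- rlnorm(config$n_areas, log(config$pop_base_mean), 0.4)
  g <- expand.grid(area = seq_len(config$n_areas),
                   year = config$outcome_years,
                   sex = c("male", "female"), band = seq_along(bands),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  growth <- 1.01^(g$year - min(config$outcome_years))
  sexf <- ifelse(g$sex == "male", 0.48, 0.52)
  data.frame(area_id = geography$areas[g$area], year = g$year, sex = g$sex,
             age_group = bands[g$band],
             person_count = round(base[g$area] * w[g$band] * sexf * growth),
             stringsAsFactors = FALSE)
}

#' Simulate Poisson outcomes under the generative model
#'
#' Draws the exchangeable effects u iid normal, the spatial field v from
#' the ICAR distribution (constrained multivariate normal on the
#' sum-to-zero subspace), and counts
#' O ~ Poisson(E exp(alpha + beta x + gamma' z + u_i + v_i)).
#'
#' @param records Data frame with `area_id`, `E`, `x` and the covariate
#'   columns named in `gamma`.
#' @param graph [adjacency_graph()] over the areas.
#' @param beta True exposure coefficient (per IQR).
#' @param gamma Named vector of covariate effects (may be empty).
#' @param alpha Intercept.
#' @param sigma_u,sigma_v Random-effect SDs (0 disables the component).
#' @return List `records` (with `O` added) and `truth` (all parameters
#'   and realized effects).
#' @export
simulate_outcomes <- function(records, graph, beta, gamma = numeric(0),
                              alpha = 0, sigma_u = 0.1, sigma_v = 0.1) {
  n <- length(graph$ids)
  u <- if (sigma_u > 0) rnorm(n, 0, sigma_u) else rep(0, n)
  v <- if (sigma_v > 0) ricar(graph, tau_v = 1 / sigma_v^2) else rep(0, n)
  ai <- match(as.character(records$area_id), graph$ids)
  if (anyNA(ai)) stop("record area absent from graph")
  eta <- alpha + beta * records$x + u[ai] + v[ai]
  for (nm in names(gamma)) {
    if (is.null(records[[nm]])) stop("covariate column missing: ", nm)
    eta <- eta + gamma[[nm]] * records[[nm]]
  }
  mu <- records$E * exp(eta)
  if (any(!is.finite(mu))) stop("non-finite Poisson rate")
  records$O <- rpois(nrow(records), mu)
  list(records = records,
       truth = list(alpha = alpha, beta = beta, gamma = gamma,
                    u = u, v = v, sigma_u = sigma_u, sigma_v = sigma_v))
}

#' Generate a complete synthetic study
#'
#' Runs the whole generative chain: geography, monthly THM samples,
#' exposure reconstruction (DL substitution, imputation, area weighting,
#' lag alignment, IQR scaling), populations and expected counts, and
#' Poisson outcomes for the requested species and sex under known
#' parameters. The analysis dataset uses the reconstructed exposure, so
#' estimators can be scored against the generating coefficients exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole study is reproducible from it.
#' @param species Exposure species for the outcome model.
#' @param sex Modelled sex stratum.
#' @return List with `records` (analysis dataset: `area_id`, `year`, `O`,
#'   `E`, `x`, `s2`, `variance_available`, covariates), `graph`, `truth`,
#'   `iqr`, `species`, `sex` and `inputs` (all raw input tables:
#'   `samples`, `weights`, `hierarchy`, `population`, `ref_rates`,
#'   `counts`).
#' @export
simulate_study <- function(config = sim_config(), seed = 1,
                           species = "bromoform", sex = "male") {
  set.seed(seed)
  geo <- make_geography(config)
  samples <- simulate_thm(config, geo)
  exposure <- estimate_area_exposure(samples, geo$weights, geo$hierarchy)
  aligned <- align_exposure(exposure[exposure$species == species, ,
                                     drop = FALSE],
                            "lag5", config$outcome_years, config$lag)
  iqr <- pooled_iqr(aligned$xbar)
  aligned$x <- iqr_scale(aligned$xbar, iqr)
  aligned$s2_scaled <- aligned$s2 / iqr^2

  covars <- simulate_covariates(config, geo)
  population <- simulate_population(config, geo)
  ref_rates <- default_ref_rates()
  E <- expected_counts(population, ref_rates)
  E <- E[E$sex == sex, , drop = FALSE]

  rec <- merge(E, aligned[, c("area_id", "year", "x", "s2_scaled",
                              "variance_available")],
               by = c("area_id", "year"))
  rec <- merge(rec, covars, by = "area_id")
  rec$yearc <- rec$year - mean(config$outcome_years)
  names(rec)[names(rec) == "s2_scaled"] <- "s2"

  out <- simulate_outcomes(rec, geo$graph, beta = config$beta[[species]],
                           gamma = config$gamma, alpha = config$alpha,
                           sigma_u = config$sigma_u,
                           sigma_v = config$sigma_v)
  rec <- out$records
  counts <- data.frame(area_id = rec$area_id, year = rec$year,
                       sex = rec$sex, site = "colorectal", O = rec$O,
                       stringsAsFactors = FALSE)
  list(records = rec, graph = geo$graph, truth = out$truth, iqr = iqr,
       species = species, sex = sex,
       inputs = list(samples = samples, weights = geo$weights,
                     hierarchy = geo$hierarchy, population = population,
                     ref_rates = ref_rates, counts = counts))
}

#' Simulate individual-level exposures aggregated to areas
#'
#' Generative twin of the pure-specification-bias setting: individual
#' exposures are Normal(xbar_i, s_i^2) within area i, individual risk is
#' proportional to exp(beta X), and counts are Poisson with mean equal to
#' the sum of individual rates. The emitted area summaries are the
#' empirical mean and variance of the individuals, i.e. what an
#' area-level analyst would observe.
#'
#' @param n_areas Number of areas.
#' @param n_indiv Individuals per area.
#' @param beta True individual-level log rate ratio per exposure unit.
#' @param alpha Intercept.
#' @param base_E Null-expected count per area.
#' @param heterogeneous If `TRUE`, the within-area SD scales with the
#'   area mean (`s_i = s_scale * xbar_i`), which makes the naive
#'   area-mean model biased; if `FALSE`, s_i = 0.
#' @param s_scale Proportionality constant of the within-area SD.
#' @return List `records` (`area_id`, `O`, `E`, `x`, `s2`,
#'   `variance_available`) and `truth`.
#' @export
simulate_individual_aggregation <- function(n_areas = 50, n_indiv = 500,
                                            beta = 0.3, alpha = 0,
                                            base_E = 25,
                                            heterogeneous = TRUE,
                                            s_scale = 0.5) {
  xbar <- runif(n_areas, 0.5, 4)
  s <- if (heterogeneous) s_scale * xbar else rep(0, n_areas)
  X <- matrix(rnorm(n_areas * n_indiv, rep(xbar, n_indiv),
                    rep(s, n_indiv)), nrow = n_areas)
  mean_risk <- rowMeans(exp(beta * X))
  mu <- base_E * exp(alpha) * mean_risk
  records <- data.frame(area_id = sprintf("A%02d", seq_len(n_areas)),
                        O = rpois(n_areas, mu), E = base_E,
                        x = rowMeans(X), s2 = apply(X, 1, var),
                        variance_available = TRUE,
                        stringsAsFactors = FALSE)
  list(records = records,
       truth = list(beta = beta, alpha = alpha, xbar = xbar, s2 = s^2,
                    mean_risk = mean_risk))
}
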