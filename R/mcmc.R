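# Bayesian hierarchical Poisson regression with log-expected offset,
# exchangeable and ICAR spatial random effects, fitted by a bespoke
# Metropolis-within-Gibbs sampler (C++ core in src/sampler.cpp).

#' MCMC specification
#'
#' Chain and prior settings for [fit_bym()]. Defaults follow disease-
#' mapping convention: two chains, burn-in equal to half the iterations,
#' N(0, 10^2) priors on fixed effects (applied to standardized
#' covariates), Gamma(0.5, 0.0005) priors on the random-effect precisions,
#' and random-walk proposals adapted towards 0.44 acceptance during
#' burn-in only.
#'
#' @param iterations Total iterations per chain.
#' @param burn_in Discarded initial iterations (default `iterations / 2`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param chains Number of chains, at least 2.
#' @param prior_sd_fixed Normal prior SD for intercept, exposure and
#'   covariate coefficients.
#' @param prior_shape,prior_rate Gamma prior for precisions tau_u, tau_v.
#' @param adapt Adapt proposal scales during burn-in.
#' @param init_step Initial random-walk proposal SD.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(iterations = 10000, burn_in = NULL, thin = 1,
                       chains = 2, prior_sd_fixed = 10,
                       prior_shape = 0.5, prior_rate = 0.0005,
                       adapt = TRUE, init_step = 0.1) {
  if (is.null(burn_in)) burn_in <- floor(iterations / 2)
  stopifnot(iterations > burn_in, burn_in >= 0, thin >= 1, chains >= 2,
            prior_sd_fixed > 0, prior_shape > 0, prior_rate > 0,
            init_step > 0)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 chains = as.integer(chains),
                 prior_sd_fixed = prior_sd_fixed,
                 prior_shape = prior_shape, prior_rate = prior_rate,
                 adapt = adapt, init_step = init_step),
            class = "model_spec")
}

#' Fit the hierarchical spatial Poisson model
#'
#' Observed counts O are modelled as Poisson with mean E exp(eta), where
#' the log expected count enters as an offset and
#' eta = alpha + beta x + (beta^2/2) s2 + gamma' z + u_i + v_i.
#' x is the IQR-scaled exposure mean, the optional s2 term is the
#' pure-specification-bias correction (its coefficient is beta^2/2 by
#' construction, tied to the current beta draw), u are exchangeable
#' normal random effects and v an ICAR spatial field with sum-to-zero
#' constraint per connected component. Covariates are standardized
#' internally; draws are reported on the original covariate scale.
#'
#' @param records Data frame with columns `area_id`, `O`, `E`, `x`
#'   (IQR-scaled exposure) and, when `variance_term` is used, `s2`
#'   (IQR^2-scaled within-area variance) and `variance_available`;
#'   covariate columns as named in `covariates`.
#' @param graph [adjacency_graph()] covering every `area_id`.
#' @param covariates Character vector of covariate column names.
#' @param spatial Include the ICAR field (otherwise v = 0 and tau_v is
#'   absent from the chains).
#' @param variance_term Include the (beta^2/2) s2 correction term.
#' @param variance_policy How records with unavailable variance are
#'   handled: `"zero_term"` keeps them with a zero variance term,
#'   `"restrict"` drops them (see [apply_variance_policy()]).
#' @param spec A [model_spec()].
#' @param seed Integer seed; chain c uses `seed + 7919 (c-1)`. Identical
#'   seed and spec give bit-identical chains.
#' @param meta Optional named list (species, sex, site, variant label...)
#'   carried into summaries.
#' @return Object of class `bym_fit` with elements `chains`
#'   (`posterior_chains`), `spec`, `frame`, `graph`, `scaling`,
#'   `retained_fraction` and `meta`.
#' @export
fit_bym <- function(records, graph, covariates = character(),
                    spatial = TRUE, variance_term = FALSE,
                    variance_policy = c("zero_term", "restrict"),
                    spec = model_spec(), seed = 1, meta = list()) {
  variance_policy <- match.arg(variance_policy)
  stopifnot(inherits(graph, "adjacency_graph"), inherits(spec, "model_spec"))
  if (any(records$E <= 0)) stop("all E must be strictly positive")
  if (any(records$O < 0)) stop("all O must be non-negative")

  retained_fraction <- 1
  if (variance_term) {
    records <- apply_variance_policy(records, variance_policy)
    retained_fraction <- attr(records, "retained_fraction") %||% 1
    s2 <- records$s2
    if (any(s2 < 0)) stop("negative within-area variance")
  } else {
    s2 <- rep(0, nrow(records))
  }

  area <- match(as.character(records$area_id), graph$ids)
  if (anyNA(area))
    stop("record area_id(s) absent from graph: ",
         paste(unique(records$area_id[is.na(area)]), collapse = ", "))

  p <- length(covariates)
  Z <- matrix(0, nrow(records), p)
  mu_z <- sd_z <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    zc <- records[[covariates[j]]]
    if (is.null(zc)) stop("covariate column not found: ", covariates[j])
    mu_z[j] <- mean(zc); sd_z[j] <- sd(zc)
    if (!is.finite(sd_z[j]) || sd_z[j] == 0)
      stop("covariate has zero variance: ", covariates[j])
    Z[, j] <- (zc - mu_z[j]) / sd_z[j]
  }

  n <- length(graph$ids)
  comp0 <- ifelse(is.na(graph$comp), -1L, graph$comp - 1L)
  nbrs0 <- lapply(graph$nbr, function(x) as.integer(x - 1L))
  param_names <- c("alpha", "beta",
                   if (p > 0) paste0("gamma_", covariates),
                   paste0("u[", graph$ids, "]"),
                   if (spatial) paste0("v[", graph$ids, "]"),
                   "tau_u", if (spatial) "tau_v", "deviance")

  draws <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    set.seed(seed + 7919L * (ch - 1L))
    init_fixed <- rnorm(2 + p, 0, 0.25)      # dispersed starting points
    res <- bym_mcmc_cpp(
      O = as.integer(records$O), logE = log(records$E),
      x = as.numeric(records$x), s2 = as.numeric(s2), Z = Z,
      area = as.integer(area - 1L), nbrs = nbrs0, comp = comp0,
      n_comp = graph$n_comp, spatial = spatial,
      variance_term = variance_term,
      sd_fixed = spec$prior_sd_fixed, prior_a = spec$prior_shape,
      prior_b = spec$prior_rate, iterations = spec$iterations,
      burn_in = spec$burn_in, thin = spec$thin, adapt = spec$adapt,
      init_fixed = init_fixed, init_u = rep(0, n), init_v = rep(0, n),
      init_tau_u = runif(1, 1, 20), init_tau_v = runif(1, 1, 20),
      init_step = spec$init_step)
    m <- res$draws
    colnames(m) <- param_names
    if (!all(is.finite(m)))
      stop("non-finite posterior draws; consider rescaling covariates")
    draws[[ch]] <- m
  }

  chains <- structure(list(draws = draws, params = param_names,
                           iterations = spec$iterations,
                           burn_in = spec$burn_in, thin = spec$thin),
                      class = "posterior_chains")
  structure(list(chains = chains, spec = spec, covariates = covariates,
                 scaling = list(mean = mu_z, sd = sd_z),
                 frame = list(O = records$O, E = records$E,
                              x = records$x, s2 = s2, area = area, Z = Z),
                 graph = graph, spatial = spatial,
                 variance_term = variance_term,
                 retained_fraction = retained_fraction,
                 seed = seed, meta = meta),
            class = "bym_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.posterior_chains <- function(x, ...) {
  cat("posterior_chains:", length(x$draws), "chain(s) x",
      nrow(x$draws[[1]]), "retained draws,", length(x$params),
      "parameters\n")
  invisible(x)
}

#' Extract posterior draws of one parameter
#'
#' @param fit A `bym_fit` or `posterior_chains` object.
#' @param parameter Parameter name (e.g. `"beta"`, `"gamma_irsd"`,
#'   `"u[A01]"`).
#' @param scale `"original"` rescales covariate coefficients back to the
#'   raw covariate units; `"sampler"` returns the standardized-scale
#'   draws. Other parameters are unaffected.
#' @param combine Concatenate chains into one vector (default) or return a
#'   draws-by-chain matrix.
#' @return Numeric vector (or matrix when `combine = FALSE`).
#' @export
parameter_draws <- function(fit, parameter, scale = c("original", "sampler"),
                            combine = TRUE) {
  scale <- match.arg(scale)
  chains <- if (inherits(fit, "bym_fit")) fit$chains else fit
  if (!parameter %in% chains$params)
    stop("unknown parameter: ", parameter)
  m <- vapply(chains$draws, function(d) d[, parameter],
              numeric(nrow(chains$draws[[1]])))
  if (scale == "original" && inherits(fit, "bym_fit") &&
      startsWith(parameter, "gamma_")) {
    j <- match(sub("^gamma_", "", parameter), fit$covariates)
    m <- m / fit$scaling$sd[j]
  }
  if (combine) as.vector(m) else m
}

#' Poisson log-likelihood with log-expected offset
#'
#' Sum over records of the Poisson log-pmf of O with mean E exp(eta).
#'
#' @param O Observed counts.
#' @param E Expected counts (offset), strictly positive.
#' @param eta Linear predictor values (excluding the offset).
#' @return The log-likelihood.
#' @export
poisson_offset_loglik <- function(O, E, eta) {
  if (any(E <= 0)) stop("E must be strictly positive")
  if (!all(is.finite(eta)))
    stop("non-finite linear predictor at record(s): ",
         paste(utils::head(which(!is.finite(eta)), 5), collapse = ", "))
  sum(dpois(O, E * exp(eta), log = TRUE))
}

#' ICAR log-density (pairwise-difference form)
#'
#' Log-density of the intrinsic CAR field, up to a constant per connected
#' component: (n - G)/2 log(tau_v) - tau_v/2 sum over unique edges of
#' (v_i - v_j)^2, where n is the number of areas in the field and G the
#' number of connected components. The field must sum to zero within each
#' component.
#'
#' @param v Numeric vector, one value per area in `graph` (entries for
#'   isolated areas are ignored).
#' @param graph An [adjacency_graph()].
#' @param tau_v Precision, positive.
#' @param tol Tolerance for the per-component sum-to-zero check.
#' @return Log-density value.
#' @export
icar_log_prior <- function(v, graph, tau_v, tol = 1e-8) {
  stopifnot(length(v) == length(graph$ids), tau_v > 0)
  live <- !is.na(graph$comp)
  sums <- tapply(v[live], graph$comp[live], sum)
  if (any(abs(sums) > tol))
    stop("v violates the per-component sum-to-zero constraint")
  em <- graph$edges
  ss <- if (nrow(em) > 0) sum((v[em[, 1]] - v[em[, 2]])^2) else 0
  (sum(live) - graph$n_comp) / 2 * log(tau_v) - tau_v / 2 * ss
}

#' ICAR full conditional of one area
#'
#' Conditionally on its neighbours, an area's spatial effect is normal
#' with mean the neighbour average and precision `n_i * tau_v`.
#'
#' @param i Area id or index.
#' @param v Current field values.
#' @param graph An [adjacency_graph()].
#' @param tau_v Precision.
#' @return List with `mean` and `precision`.
#' @export
icar_full_conditional <- function(i, v, graph, tau_v) {
  if (is.character(i)) i <- match(i, graph$ids)
  if (is.na(i) || i < 1 || i > length(graph$ids)) stop("unknown area")
  nb <- graph$nbr[[i]]
  if (length(nb) == 0)
    stop("area is isolated: it is excluded from the ICAR field ",
         "and carries only the exchangeable effect")
  list(mean = mean(v[nb]), precision = length(nb) * tau_v)
}

#' Simulate an ICAR field
#'
#' Draws from the intrinsic CAR distribution with precision
#' `tau_v (D - W)` restricted to the sum-to-zero subspace of each
#' connected component, via eigendecomposition of the graph Laplacian.
#' Isolated areas receive 0.
#'
#' @param graph An [adjacency_graph()].
#' @param tau_v Precision.
#' @return Numeric vector, one value per area.
#' @export
ricar <- function(graph, tau_v = 1) {
  n <- length(graph$ids)
  v <- rep(0, n)
  live <- which(!is.na(graph$comp))
  if (length(live) == 0) return(v)
  W <- matrix(0, length(live), length(live))
  idx <- match(seq_len(n), live)
  for (k in seq_along(live)) {
    nb <- idx[graph$nbr[[live[k]]]]
    W[k, nb] <- 1
  }
  L <- diag(rowSums(W)) - W
  eig <- eigen(L, symmetric = TRUE)
  keep <- eig$values > 1e-8
  z <- rnorm(sum(keep), 0, 1 / sqrt(tau_v * eig$values[keep]))
  v[live] <- as.vector(eig$vectors[, keep, drop = FALSE] %*% z)
  v
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Variance-ratio form R-hat = sqrt(1 + B/(n W)), where W is the mean
#' within-chain variance and B/n the variance of the chain means. This
#' form is bounded below by 1, equals 1 exactly for identical chains, and
#' converges to the conventional statistic as the chain length grows.
#'
#' @param chains A `posterior_chains` object, a draws-by-chains matrix, or
#'   a list of equal-length numeric vectors.
#' @param parameter Parameter name (required for `posterior_chains`).
#' @return R-hat (>= 1).
#' @export
gelman_rubin <- function(chains, parameter = NULL) {
  m <- if (inherits(chains, "posterior_chains")) {
    parameter_draws(chains, parameter, scale = "sampler", combine = FALSE)
  } else if (is.list(chains)) {
    do.call(cbind, chains)
  } else {
    as.matrix(chains)
  }
  if (ncol(m) < 2) stop("at least two chains are required")
  if (nrow(m) < 10) stop("at least 10 draws per chain are required")
  W <- mean(apply(m, 2, var))
  B_n <- var(colMeans(m))
  if (B_n == 0) return(1)
  if (W == 0) return(Inf)
  sqrt(1 + B_n / W)
}

#' Deviance information criterion
#'
#' Dbar is the posterior mean deviance (stored per retained draw), the
#' effective number of parameters pD is Dbar minus the deviance at the
#' posterior mean of the parameters, and DIC = Dbar + pD.
#'
#' @param fit A `bym_fit`.
#' @return List with `dic`, `pd`, `dbar`, `dhat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  all_draws <- do.call(rbind, fit$chains$draws)
  dbar <- mean(all_draws[, "deviance"])
  post_mean <- colMeans(all_draws)
  eta <- linear_predictor(fit, post_mean)
  dhat <- -2 * poisson_offset_loglik(fit$frame$O, fit$frame$E, eta)
  pd <- dbar - dhat
  list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat)
}

# eta at a named parameter vector (sampler scale, standardized covariates)
linear_predictor <- function(fit, state) {
  fr <- fit$frame
  eta <- state[["alpha"]] + state[["beta"]] * fr$x
  if (fit$variance_term) eta <- eta + 0.5 * state[["beta"]]^2 * fr$s2
  if (length(fit$covariates) > 0) {
    gam <- state[paste0("gamma_", fit$covariates)]
    eta <- eta + as.numeric(fr$Z %*% gam)
  }
  u <- state[paste0("u[", fit$graph$ids, "]")]
  eta <- eta + u[fr$area]
  if (fit$spatial) {
    v <- state[paste0("v[", fit$graph$ids, "]")]
    eta <- eta + v[fr$area]
  }
  as.numeric(eta)
}

#' Scalar random-walk Metropolis sampler
#'
#' Generic building block used for toy posteriors and validation: a
#' Gaussian random-walk Metropolis chain targeting an arbitrary
#' univariate log-density, with optional step adaptation (towards 0.44
#' acceptance) during burn-in only.
#'
#' @param log_target Function of one numeric argument returning the log
#'   target density (up to a constant).
#' @param init Starting value.
#' @param iterations Total iterations.
#' @param burn_in Discarded initial iterations (default half).
#' @param step Initial proposal SD.
#' @param adapt Adapt during burn-in.
#' @return List with `draws` (post burn-in), `acceptance`, `step`.
#' @export
rw_metropolis <- function(log_target, init, iterations,
                          burn_in = floor(iterations / 2),
                          step = 1, adapt = TRUE) {
  stopifnot(iterations > burn_in, step > 0)
  theta <- init
  lp <- log_target(theta)
  draws <- numeric(iterations - burn_in)
  acc <- 0L; win_acc <- 0L
  for (it in seq_len(iterations)) {
    prop <- theta + step * rnorm(1)
    lp_prop <- log_target(prop)
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
      theta <- prop; lp <- lp_prop
      if (it > burn_in) acc <- acc + 1L
      win_acc <- win_acc + 1L
    }
    if (adapt && it <= burn_in && it %% 50 == 0) {
      step <- max(1e-4, min(25, step * exp(win_acc / 50 - 0.44)))
      win_acc <- 0L
    }
    if (it > burn_in) draws[it - burn_in] <- theta
  }
  list(draws = draws, acceptance = acc / (iterations - burn_in),
       step = step)
}

#' Monte-Carlo standard error of a chain mean
#'
#' Batch-means estimate accounting for autocorrelation: the chain is cut
#' into about sqrt(n) batches and the standard error of the batch means
#' is reported.
#'
#' @param x Numeric vector of MCMC draws.
#' @return Estimated standard error of `mean(x)`.
#' @export
mcse <- function(x) {
  n <- length(x)
  b <- max(1L, floor(sqrt(n)))
  a <- n %/% b
  bm <- colMeans(matrix(x[seq_len(a * b)], nrow = b))
  sd(bm) / sqrt(a)
}
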