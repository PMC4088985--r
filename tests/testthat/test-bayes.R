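test_that("Poisson offset log-likelihood matches closed forms", {
  expect_equal(poisson_offset_loglik(0, 1, 0), -1)
  expect_equal(poisson_offset_loglik(2, 1, 0), 2 * 0 - 1 - log(2))
  # offset contract: scaling E by c and shifting eta by -log(c) is invariant
  set.seed(3)
  O <- rpois(20, 4); E <- runif(20, 1, 9); eta <- rnorm(20, 0, 0.3)
  expect_equal(poisson_offset_loglik(O, 2 * E, eta - log(2)),
               poisson_offset_loglik(O, E, eta))
  expect_error(poisson_offset_loglik(1, 1, Inf), "record")
})

test_that("ICAR pairwise-difference density matches its closed forms", {
  g <- path3()
  expect_equal(icar_log_prior(c(0, 0, 0), g, tau_v = 2),
               (3 - 1) / 2 * log(2))
  expect_equal(icar_log_prior(c(-1, 0, 1), g, tau_v = 1), -1)
  expect_error(icar_log_prior(c(1, 1, 1), g, 1), "sum-to-zero")
})

test_that("ICAR density equals the constrained-normal oracle up to a constant", {
  set.seed(21)
  for (n in c(3, 4, 6)) {
    g <- random_connected_graph(n, extra = 2)
    diffs <- replicate(20, {
      v <- rnorm(n); v <- v - mean(v)
      tau <- runif(1, 0.2, 5)
      icar_log_prior(v, g, tau) - icar_mvn_logdensity(v, g, tau)
    })
    expect_lt(max(diffs) - min(diffs), 1e-8)
  }
})

test_that("ICAR full conditional is the neighbour mean with precision n_i tau", {
  g <- path3()
  fc <- icar_full_conditional("A2", c(2, 0, 4), g, tau_v = 1)
  expect_equal(fc$mean, 3)
  expect_equal(fc$precision, 2)
  expect_equal(icar_full_conditional("A1", c(0, 5, 0), g, 3),
               list(mean = 5, precision = 3))
  g_iso <- adjacency_graph(data.frame(from = "A1", to = "A2"),
                           areas = c("A1", "A2", "A3"))
  expect_error(icar_full_conditional("A3", c(0, 0, 0), g_iso, 1), "isolated")
})

test_that("random-walk Metropolis reproduces a conjugate Gamma posterior", {
  # single-area Poisson with Gamma(2, 1) prior on the rate, O = 7, E = 4:
  # posterior is Gamma(9, 5); sample theta = log(rate)
  set.seed(8)
  lt <- function(th) 9 * th - 5 * exp(th)
  out <- rw_metropolis(lt, init = 0, iterations = 12000, step = 0.5)
  lam <- exp(out$draws)
  expect_lt(abs(mean(lam) - 9 / 5), 4 * mcse(lam))
  expect_gt(out$acceptance, 0.2)
})

test_that("precision posteriors concentrate near the generating value", {
  set.seed(91)
  g <- grid_adjacency(10, 10)
  u <- rnorm(100, 0, 0.5)                       # tau_u = 4
  rec <- data.frame(area_id = rep(g$ids, each = 8), E = 40, x = 0)
  rec$O <- rpois(nrow(rec), rec$E * exp(u[match(rec$area_id, g$ids)]))
  fit <- fit_bym(rec, g, spatial = FALSE, spec = quick_spec(3000), seed = 4)
  tau_med <- median(parameter_draws(fit, "tau_u"))
  expect_gt(tau_med, 4 / 3)
  expect_lt(tau_med, 4 * 3)
})

test_that("the sampler honours the retention and model-reduction contracts", {
  set.seed(2)
  g <- grid_adjacency(2, 2)
  rec <- data.frame(area_id = rep(g$ids, each = 2), O = rpois(8, 5), E = 5,
                    x = rnorm(8))
  fit <- fit_bym(rec, g, spec = quick_spec(400), seed = 1)
  expect_equal(nrow(fit$chains$draws[[1]]), 200)
  expect_equal(length(fit$chains$draws), 2)
  expect_true("tau_v" %in% fit$chains$params)

  nosp <- fit_bym(rec, g, spatial = FALSE, spec = quick_spec(400), seed = 1)
  expect_false(any(grepl("^v\\[|tau_v", nosp$chains$params)))

  # identical spec + seed: bit-identical chains
  fit2 <- fit_bym(rec, g, spec = quick_spec(400), seed = 1)
  expect_identical(fit$chains$draws, fit2$chains$draws)
})

test_that("Gelman-Rubin statistic behaves at its limits", {
  set.seed(14)
  x <- rnorm(200)
  expect_equal(gelman_rubin(list(x, x)), 1)
  expect_error(gelman_rubin(matrix(x, ncol = 1)), "two chains")

  a <- rnorm(500); b <- rnorm(500) + 10
  W <- mean(c(var(a), var(b)))
  closed <- sqrt(1 + var(c(mean(a), mean(b))) / W)
  expect_equal(gelman_rubin(list(a, b)), closed)
  expect_gt(closed, 5)

  # long chains from the same stationary normal drift to 1
  expect_lt(gelman_rubin(list(rnorm(5000), rnorm(5000))), 1.01)
})

test_that("DIC is Dbar plus the effective parameter count", {
  set.seed(6)
  g <- grid_adjacency(2, 2)
  rec <- data.frame(area_id = rep(g$ids, each = 3), O = rpois(12, 6), E = 6,
                    x = rnorm(12))
  fit <- fit_bym(rec, g, spec = quick_spec(600), seed = 3)
  d <- dic(fit)
  expect_equal(d$dic, d$dbar + d$pd)
  expect_gt(d$pd, 0)

  # degenerate chain: a single repeated draw has no spread, pD = 0
  one <- fit$chains$draws[[1]][5, , drop = FALSE]
  fit$chains$draws <- list(one[rep(1, 40), ], one[rep(1, 40), ])
  d0 <- dic(fit)
  expect_equal(d0$pd, 0, tolerance = 1e-8)
  expect_equal(d0$dic, d0$dbar, tolerance = 1e-8)
})
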