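test_that("synthetic geography has rook adjacency and unit weight rows", {
  set.seed(1)
  expect_equal(nrow(grid_adjacency(2, 2)$edges), 4)
  geo <- make_geography(small_config())
  rs <- tapply(geo$weights$weight, geo$weights$area_id, sum)
  expect_true(all(abs(rs - 1) < 1e-12))
  expect_true(all(table(geo$hierarchy$dist_system_id) == 1))
  expect_equal(sum(geo$region$region == "HWC"), 2)
})

test_that("systems-per-area follows the configured mean", {
  set.seed(77)
  cfg <- sim_config(n_areas = 1000, grid_nrow = 40, grid_ncol = 25,
                    n_hwc = 5)
  geo <- make_geography(cfg)
  k <- table(geo$weights$area_id)
  expect_equal(mean(k), 3, tolerance = 0.05)
  expect_true(all(k >= 1 & k <= 8))
})

test_that("simulated THM series are positive with a DL step in 1999", {
  set.seed(13)
  cfg <- small_config()
  geo <- make_geography(cfg)
  s <- simulate_thm(cfg, geo)
  expect_true(all(s$value[s$below_dl == 0] > 0))
  br <- s[s$species == "bromoform", ]
  cens_rate <- tapply(br$below_dl, br$year, mean)
  expect_gt(cens_rate[["1999"]], cens_rate[["1998"]])
  expect_true(all(br$dl[br$year >= 1999] == 3))
  expect_true(all(br$dl[br$year < 1999] == 1))
})

test_that("the pipeline round-trips uncensored, complete samples exactly", {
  set.seed(23)
  cfg <- small_config(missing_pre2000 = 0, missing_post2000 = 0,
                      dl_bromoform = c(0, 0), dl_other = 0)
  geo <- make_geography(cfg)
  s <- simulate_thm(cfg, geo)
  expect_equal(sum(s$below_dl), 0)
  truth <- attr(s, "true_zone_month")
  want <- aggregate(value ~ dist_system_id + year + species, data = truth,
                    FUN = mean)
  got <- aggregate_to_zone_year(s)
  m <- merge(got, want, by = c("dist_system_id", "year", "species"))
  expect_equal(nrow(m), nrow(got))
  expect_lt(max(abs(m$mean - m$value)), 1e-9)
})

test_that("outcome generation is a faithful Poisson log-linear twin", {
  set.seed(31)
  g <- grid_adjacency(5, 5)
  rec <- data.frame(area_id = rep(g$ids, each = 20), E = 10, x = 0)
  out <- simulate_outcomes(rec, g, beta = 0, sigma_u = 0, sigma_v = 0)
  r <- out$records$O / out$records$E
  expect_lt(abs(mean(r) - 1), 3 * sd(r) / sqrt(length(r)))
  expect_equal(out$truth$u, rep(0, 25))
  expect_equal(out$truth$v, rep(0, 25))

  # ICAR field sums to zero and the truth record is complete
  set.seed(32)
  out2 <- simulate_outcomes(rec, g, beta = 0.1, sigma_u = 0.1, sigma_v = 0.3)
  expect_lt(abs(sum(out2$truth$v)), 1e-8)
  expect_named(out2$truth,
               c("alpha", "beta", "gamma", "u", "v", "sigma_u", "sigma_v"))
})

test_that("a full synthetic study is reproducible from its seed", {
  cfg <- small_config()
  a <- simulate_study(cfg, seed = 99)
  b <- simulate_study(cfg, seed = 99)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_true(all(c("O", "E", "x", "s2", "ses", "region") %in%
                    names(a$records)))
  expect_true(all(a$records$E > 0))
  # IQR scaling: one IQR of the reconstructed exposure is one unit
  expect_equal(pooled_iqr(a$records$x[!duplicated(
    paste(a$records$area_id, a$records$year))]), 1, tolerance = 1e-9)
})

test_that("individual-level aggregation matches the lognormal-mean identity", {
  set.seed(55)
  z <- simulate_individual_aggregation(n_areas = 5, n_indiv = 50000,
                                       beta = 0.3)
  want <- exp(0.3 * z$truth$xbar + 0.3^2 * z$truth$s2 / 2)
  expect_equal(z$truth$mean_risk, want, tolerance = 0.02)

  # no within-area spread: aggregation equals the area-level model exactly
  set.seed(56)
  z0 <- simulate_individual_aggregation(n_areas = 10, n_indiv = 100,
                                        beta = 0.3, heterogeneous = FALSE)
  expect_equal(z0$records$s2, rep(0, 10))
  expect_equal(z0$truth$mean_risk, exp(0.3 * z0$truth$xbar))
})
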