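test_that("below-DL substitution follows the chosen rule and is idempotent", {
  s <- samples_df(
    sample_row(value = NA, below_dl = 1L, dl = 3),
    sample_row(site = "s2", value = 17.3, below_dl = 0L, dl = 3),
    sample_row(site = "s3", value = NA, below_dl = 1L, dl = 1))
  two3 <- substitute_below_dl(s, "two_thirds_dl")
  expect_equal(two3$value[1], 2.0)
  expect_equal(two3$value[2], 17.3)
  alt <- substitute_below_dl(s, "dl_sqrt2")
  expect_equal(alt$value[3], 1 / sqrt(2))
  expect_identical(substitute_below_dl(two3, "two_thirds_dl"), two3)
  # censored record without a DL is rejected, others survive
  s$dl[1] <- NA
  expect_warning(out <- substitute_below_dl(s), "detection limit")
  expect_equal(nrow(out), 2)
})

test_that("two-stage zone-year aggregation averages sites then months", {
  s <- samples_df(sample_row(site = "s1", value = 10),
                  sample_row(site = "s2", value = 20))
  zy <- aggregate_to_zone_year(s)
  expect_equal(zy$mean, 15)
  expect_equal(zy$n_months_observed, 1L)

  s12 <- do.call(rbind, lapply(1:12, function(m) sample_row(month = m, value = 5)))
  expect_equal(aggregate_to_zone_year(s12)$mean, 5)

  # Jan: sites 8, 12 -> 10; Feb: 20 -> annual (10 + 20)/2 = 15
  s2 <- samples_df(sample_row(site = "s1", month = 1, value = 8),
                   sample_row(site = "s2", month = 1, value = 12),
                   sample_row(site = "s1", month = 2, value = 20))
  expect_equal(aggregate_to_zone_year(s2)$mean, 15)
})

test_that("cluster-mean imputation uses delivery sisters then the annual mean", {
  hier <- data.frame(dist_system_id = c("A", "B", "C"),
                     delivery_system_id = "S1", stringsAsFactors = FALSE)
  mk <- function(dist, month, value) {
    sample_row(site = paste0(dist, "s"), dist = dist, month = month,
               value = value)
  }
  # A missing March; sisters B = 10, C = 14 in March
  s <- samples_df(mk("A", 1, 99), mk("B", 3, 10), mk("C", 3, 14))
  zm <- impute_cluster_mean(zone_month_means(s), hier)
  amar <- zm[zm$dist_system_id == "A" & zm$month == 3, ]
  expect_equal(amar$value, 12)
  expect_equal(amar$imputation_source, "delivery_month")

  # all sisters missing in a month: A's own annual mean over observed months
  s2 <- samples_df(mk("A", 1, 10), mk("A", 2, 20))
  zm2 <- impute_cluster_mean(zone_month_means(s2, systems = c("A", "B", "C")),
                             hier)
  amar2 <- zm2[zm2$dist_system_id == "A" & zm2$month == 3, ]
  expect_equal(amar2$value, 15)
  expect_equal(amar2$imputation_source, "system_annual")
  # B has no observation anywhere that year -> stays missing
  bmar <- zm2[zm2$dist_system_id == "B" & zm2$month == 3, ]
  expect_true(is.na(bmar$value))
  expect_equal(bmar$imputation_source, "missing")

  expect_error(impute_cluster_mean(zone_month_means(mk("X", 1, 1)), hier),
               "X")
})

test_that("imputation never alters observed values and stays in donor range", {
  set.seed(41)
  hier <- data.frame(dist_system_id = paste0("D", 1:4),
                     delivery_system_id = c("S1", "S1", "S1", "S2"),
                     stringsAsFactors = FALSE)
  for (rep in 1:5) {
    rows <- lapply(1:40, function(i) {
      sample_row(site = "s1", dist = sample(paste0("D", 1:4), 1),
                 month = sample(1:12, 1), value = runif(1, 1, 50))
    })
    s <- do.call(rbind, rows)
    s <- s[!duplicated(s[, c("dist_system_id", "month")]), ]
    zm0 <- zone_month_means(s)
    zm1 <- impute_cluster_mean(zm0, hier)
    obs <- zm0$imputation_source == "observed"
    expect_identical(zm1$value[obs], zm0$value[obs])
    dm <- zm1$imputation_source == "delivery_month"
    if (any(dm)) {
      expect_true(all(zm1$value[dm] >= min(zm0$value, na.rm = TRUE) - 1e-12))
      expect_true(all(zm1$value[dm] <= max(zm0$value, na.rm = TRUE) + 1e-12))
    }
  }
})

test_that("area weighting renormalizes over observed zones and flags variance", {
  zy <- data.frame(dist_system_id = c("D1", "D2"), year = 1995,
                   species = "bromoform", mean = c(10, 20),
                   n_months_observed = 12L, imputation_source = "observed",
                   imputed_fraction = 0, stringsAsFactors = FALSE)
  w <- data.frame(area_id = "A", dist_system_id = c("D1", "D2"),
                  weight = c(0.5, 0.5), stringsAsFactors = FALSE)
  ae <- area_weighted_exposure(zy, w)
  expect_equal(ae$xbar, 15)
  expect_equal(ae$s2, 25)
  expect_true(ae$variance_available)

  # a single covering zone: mean passes through, no variance
  w1 <- data.frame(area_id = "A", dist_system_id = "D1", weight = 1)
  zy1 <- zy[1, ]; zy1$mean <- 7
  ae1 <- area_weighted_exposure(zy1, w1)
  expect_equal(ae1$xbar, 7)
  expect_false(ae1$variance_available)

  # missing zone: weights renormalized over the observed one
  zy2 <- zy; zy2$mean[2] <- NA
  w2 <- w; w2$weight <- c(0.8, 0.2)
  ae2 <- area_weighted_exposure(zy2, w2)
  expect_equal(ae2$xbar, 10)

  expect_error(area_weighted_exposure(zy, transform(w, weight = c(-0.1, 1.1))),
               "negative")
  expect_error(area_weighted_exposure(zy, transform(w, weight = c(0.5, 0.6))),
               "sum to 1")
})

test_that("lag alignment maps exposure year y to outcome year y + lag", {
  ae <- data.frame(area_id = "A", year = 1995:2001, species = "bromoform",
                   xbar = c(8, 2, 4, 6, 5, 3, 9), s2 = 1,
                   variance_available = TRUE, n_zones = 2L,
                   imputed_fraction = 0, stringsAsFactors = FALSE)
  lag5 <- align_exposure(ae, "lag5", outcome_years = 2000:2006)
  expect_equal(lag5$xbar[lag5$year == 2000], 8)
  expect_equal(sort(lag5$year), 2000:2006)
  expect_error(align_exposure(ae[1:3, ], "lag5", outcome_years = 2000:2006),
               "2004")

  avg <- align_exposure(ae, "average_years", outcome_years = 2000:2006)
  expect_equal(avg$xbar, rep(mean(ae$xbar), 7))
  ae3 <- ae[1:3, ]; ae3$xbar <- c(2, 4, 6)
  expect_equal(unique(align_exposure(ae3, "average_years", 2000:2002)$xbar), 4)
})

test_that("IQR scaling turns one IQR into one unit", {
  expect_equal(iqr_scale(2.6, 1.3), 2)
  expect_equal(iqr_scale(44.4, 22.2), 2)
  expect_equal(iqr_scale(0, 5), 0)
  expect_error(iqr_scale(1, 0), "positive")
  expect_equal(pooled_iqr(c(1, 2, 3, 4, 5)), 2)  # type-7 interpolation
})

test_that("complete-data pipeline equals a brute-force weighted-mean oracle", {
  set.seed(7)
  hier <- data.frame(dist_system_id = c("D1", "D2", "D3"),
                     delivery_system_id = "S1", stringsAsFactors = FALSE)
  rows <- list()
  for (d in hier$dist_system_id) for (m in 1:6) for (st in 1:2) {
    rows[[length(rows) + 1]] <- sample_row(site = paste0(d, st), dist = d,
                                           month = m,
                                           value = runif(1, 1, 100))
  }
  s <- do.call(rbind, rows)
  w <- data.frame(area_id = c("A", "A", "B", "B"),
                  dist_system_id = c("D1", "D2", "D2", "D3"),
                  weight = c(0.3, 0.7, 0.4, 0.6), stringsAsFactors = FALSE)
  got <- estimate_area_exposure(s, w, hier)

  oracle_zone <- function(d) {
    sd <- s[s$dist_system_id == d, ]
    mean(tapply(sd$value, sd$month, mean))
  }
  for (a in c("A", "B")) {
    wa <- w[w$area_id == a, ]
    want <- sum(wa$weight * vapply(wa$dist_system_id, oracle_zone, 0))
    expect_equal(got$xbar[got$area_id == a], want, tolerance = 1e-10)
  }

  # shifting every raw value by +c shifts xbar by c and leaves s2 unchanged
  s_up <- s; s_up$value <- s_up$value + 11.5
  got_up <- estimate_area_exposure(s_up, w, hier)
  expect_equal(got_up$xbar, got$xbar + 11.5, tolerance = 1e-9)
  expect_equal(got_up$s2, got$s2, tolerance = 1e-9)
})
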