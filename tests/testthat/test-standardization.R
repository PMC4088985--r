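pop_cell <- function(area = "A", year = 2000, sex = "male",
                     age_group = "65-69", person_count = 1000) {
  data.frame(area_id = area, year = year, sex = sex, age_group = age_group,
             person_count = person_count, stringsAsFactors = FALSE)
}

test_that("expected counts sum person-years times reference rates", {
  rr <- data.frame(sex = "male", age_group = c("65-69", "70-74"),
                   rate = c(0.002, 0.001), stringsAsFactors = FALSE)
  expect_equal(expected_counts(pop_cell(), rr)$E, 2.0)

  pop2 <- rbind(pop_cell(person_count = 500),
                pop_cell(age_group = "70-74", person_count = 500))
  rr2 <- data.frame(sex = "male", age_group = c("65-69", "70-74"),
                    rate = c(0.001, 0.003), stringsAsFactors = FALSE)
  expect_equal(expected_counts(pop2, rr2)$E, 2.0)

  expect_equal(expected_counts(pop_cell(person_count = 0), rr)$E, 0)
  expect_error(expected_counts(pop_cell(age_group = "35-39"), rr), "35-39")
})

test_that("E is linear in population and consistent under aggregation", {
  set.seed(11)
  rr <- default_ref_rates()
  bands <- unique(rr$age_group)
  pop <- do.call(rbind, lapply(bands, function(b)
    pop_cell(age_group = b, person_count = sample(100:2000, 1))))
  E1 <- expected_counts(pop, rr)$E
  pop2 <- pop; pop2$person_count <- 2 * pop2$person_count
  expect_equal(expected_counts(pop2, rr)$E, 2 * E1)

  # band-wise E sums to the pooled E
  per_band <- vapply(seq_len(nrow(pop)), function(i)
    expected_counts(pop[i, ], rr)$E, 0)
  expect_equal(sum(per_band), E1)
})

test_that("SIR uses exact Poisson limits", {
  expect_equal(sir(10, 10)$sir, 1)
  expect_equal(sir(20, 10)$sir, 2)
  z <- sir(0, 4)
  expect_equal(z$lower, 0)
  expect_equal(z$upper, -log(0.025) / 4)
  expect_error(sir(1, 0), "positive")
  # interval covers the point estimate
  s <- sir(7, 5.5)
  expect_true(s$lower <= s$sir && s$sir <= s$upper)
})

test_that("standardized rates scale the SIR by the reference crude rate", {
  expect_equal(standardized_rate(1, 60), 60)
  expect_equal(standardized_rate(1.25, 80), 100)
  s <- data.frame(O = 9, E = 10, sir = 0.9, lower = 0.9, upper = 1.1)
  r <- standardized_rate(s, 50)
  expect_equal(unlist(r), c(rate = 45, lower = 45, upper = 55))
})

test_that("counts drawn at the reference rates give mean SIR near 1", {
  set.seed(5)
  E <- runif(200, 5, 30)
  O <- rpois(200, E)
  s <- sir(O, E)$sir
  expect_lt(abs(mean(s) - 1), 3 * sd(s) / sqrt(200))
})
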