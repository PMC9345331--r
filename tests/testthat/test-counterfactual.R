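test_that("percentile intervals match an order-statistic interpolation oracle", {
  expect_equal(percentile_ci(rep(7, 50), 0.95),
               c(lower = 7, upper = 7))
  draws <- as.numeric(1:1000)
  ci <- percentile_ci(draws, 0.95)
  expect_equal(unname(ci["lower"]), quantile_interp_oracle(draws, 0.025))
  expect_equal(unname(ci["upper"]), quantile_interp_oracle(draws, 0.975))
  set.seed(8)
  skewed <- rlnorm(777)
  ci2 <- percentile_ci(skewed, 0.8)
  expect_equal(unname(ci2), quantile_interp_oracle(skewed, c(0.1, 0.9)))
  # a tiny level collapses toward the median
  ci3 <- percentile_ci(draws, 1e-6)
  expect_lt(ci3["upper"] - ci3["lower"], 0.01)
  expect_equal(unname(ci3["lower"]), 500.5, tolerance = 1e-3)
  expect_error(percentile_ci(numeric(0)), "non-empty")
  expect_error(percentile_ci(1:5, 1), "between 0 and 1")
})

test_that("identical outcomes give a null difference with a degenerate CI", {
  carers <- cell_people(5, income = 400)
  pool <- cell_people(8, income = 0, carer = FALSE)
  pool <- with_econ(pool, cp = 400)  # same total income as the carers
  res <- run_monte_carlo(carers, pool, outcomes = "total_income",
                         config = mc_config(n_iterations = 200, seed = 1))
  expect_equal(res$estimates$mean_weekly_difference, 0)
  expect_equal(res$estimates$ci_lower, 0)
  expect_equal(res$estimates$ci_upper, 0)
})

test_that("one carer with a two-donor cell matches the exact enumeration", {
  carers <- cell_people(1, income = 120)
  pool <- rbind(cell_people(1, income = 100, carer = FALSE),
                cell_people(1, income = 200, carer = FALSE))
  pool$record_id <- c("p1", "p2")
  pool$weight <- 1   # uniform via equal weights
  K <- 5000
  res <- run_monte_carlo(carers, pool, outcomes = "total_income",
                         config = mc_config(n_iterations = K, seed = 42))
  # enumeration: draws are (100-120) or (200-120) with probability 1/2
  exact_mean <- mean(c(100, 200)) - 120
  exact_sd <- 50
  expect_lt(abs(res$estimates$mean_weekly_difference - exact_mean),
            3 * exact_sd / sqrt(K))
  # iteration means are the raw draws here: CI must sit inside the support
  expect_gte(res$estimates$ci_lower, -20)
  expect_lte(res$estimates$ci_upper, 80)
})

test_that("a constructed cell-wise gap of 500 is recovered within 3 standard errors", {
  set.seed(77)
  n_c <- 60; n_p <- 200; sd_inc <- 150
  carers <- cell_people(n_c, income = stats::rnorm(n_c, 600, sd_inc))
  pool <- cell_people(n_p, income = stats::rnorm(n_p, 1100, sd_inc),
                      carer = FALSE)
  K <- 2000
  res <- run_monte_carlo(carers, pool, outcomes = "total_income",
                         config = mc_config(n_iterations = K, seed = 5))
  se_data <- sd_inc * sqrt(1 / n_c + 1 / n_p)
  se_mc <- stats::sd(res$iteration_means[, 1]) / sqrt(K)
  expect_lt(abs(res$estimates$mean_weekly_difference - 500),
            3 * sqrt(se_data^2 + se_mc^2))
})

test_that("the estimator is unbiased over replicates with a known gap", {
  # 120 small replicates, each with its own data draw and MC run
  ests <- vapply(1:120, function(s) {
    set.seed(1000 + s)
    carers <- cell_people(15, income = stats::rnorm(15, 600, 100))
    pool <- cell_people(60, income = stats::rnorm(60, 1100, 100),
                        carer = FALSE)
    res <- run_monte_carlo(carers, pool, outcomes = "total_income",
                           config = mc_config(n_iterations = 100,
                                              seed = 2000 + s))
    res$estimates$mean_weekly_difference
  }, numeric(1))
  expect_lt(abs(mean(ests) - 500), 3 * stats::sd(ests) / sqrt(length(ests)))
})

test_that("weights scale aggregates but not mean differences; seeds reproduce", {
  set.seed(12)
  carers <- cell_people(20, income = stats::rnorm(20, 500, 80),
                        weight = stats::runif(20, 100, 900))
  pool <- cell_people(50, income = stats::rnorm(50, 1000, 80), carer = FALSE)
  cfg <- mc_config(n_iterations = 300, seed = 4)
  r1 <- run_monte_carlo(carers, pool, config = cfg)
  r2 <- run_monte_carlo(carers, pool, config = cfg)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))

  carers10 <- carers
  carers10$weight <- carers$weight * 10
  r10 <- run_monte_carlo(carers10, pool, config = cfg)
  expect_equal(r10$estimates$mean_weekly_difference,
               r1$estimates$mean_weekly_difference, tolerance = 1e-12)
  a1 <- aggregate_national(r1)
  a10 <- aggregate_national(r10)
  expect_equal(a10$point, 10 * a1$point, tolerance = 1e-12)
  expect_equal(a10$ci_upper, 10 * a1$ci_upper, tolerance = 1e-12)
})

test_that("empty matching cells error unless fallback is enabled, which coarsens", {
  carers <- cell_people(3, income = 300)
  pool <- cell_people(10, income = 900, carer = FALSE)
  pool$age_band <- "40-44"   # same 10-year band, different 5-year band
  expect_error(run_monte_carlo(carers, pool,
                               config = mc_config(n_iterations = 10,
                                                  seed = 1)),
               "matching cell")
  res <- run_monte_carlo(carers, pool, outcomes = "total_income",
                         config = mc_config(n_iterations = 50, seed = 1,
                                            fallback = TRUE))
  expect_equal(res$estimates$mean_weekly_difference, 600, tolerance = 1e-9)

  pool2 <- pool
  pool2$age_band <- "55-59"  # different 10-year band: fallback cannot rescue
  expect_error(run_monte_carlo(carers, pool2,
                               config = mc_config(n_iterations = 10, seed = 1,
                                                  fallback = TRUE)),
               "matching cell")
  expect_error(run_monte_carlo(carers[0, ], pool,
                               config = mc_config(seed = 1)), "empty")
})

test_that("percentile CIs cover the construction's true gap at close to nominal rate", {
  # each replicate redraws carers and pool around a known gap of 500;
  # CI checked against that superpopulation truth
  n_rep <- 200
  cover <- logical(n_rep)
  for (s in seq_len(n_rep)) {
    set.seed(3000 + s)
    carers <- cell_people(20, income = stats::rnorm(20, 600, 120))
    pool <- cell_people(200, income = stats::rnorm(200, 1100, 120),
                        carer = FALSE)
    res <- run_monte_carlo(carers, pool, outcomes = "total_income",
                           config = mc_config(n_iterations = 300,
                                              seed = 5000 + s,
                                              retain_draws = FALSE))
    cover[s] <- res$estimates$ci_lower <= 500 &&
      res$estimates$ci_upper >= 500
  }
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})
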