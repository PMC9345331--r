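test_that("configuration errors name the offending field", {
  expect_error(pop_config(carer_share = 1.2), "carer_share")
  expect_error(pop_config(education_distribution = c(a = 0.5, b = 0.4)),
               "education_distribution")
  expect_error(pop_config(lf_status_distribution = list(
    non_carer = c(employed_ft = 0.5, employed_pt = 0.5),
    carer = c(employed_ft = 0.7, nilf = 0.2))),
    "lf_status_distribution\\$carer")
  expect_error(pop_config(age_bands = c("15-19", "25-29")), "age_bands")
  expect_error(pop_config(age_bands = character()), "age_bands")
  expect_error(pop_config(n_records = 0), "n_records")
})

test_that("generation is byte-identical for identical config and seed", {
  cfg <- small_config()
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  da <- generate_donor_pool(cfg, n_donors = 1000)
  db <- generate_donor_pool(cfg, n_donors = 1000)
  expect_identical(serialize(da, NULL), serialize(db, NULL))
  expect_false(identical(generate_population(cfg, seed = 7), a))
})

test_that("records satisfy their structural invariants", {
  pop <- generate_population(small_config())
  expect_true(all(pop$weight >= 0))
  expect_identical(is.na(pop$nilf_main_reason), pop$lf_status != "nilf")
  expect_identical(is.na(pop$cared_condition), !pop$is_primary_carer)
  bands <- paste(seq(15, 60, 5), seq(19, 64, 5), sep = "-")
  expect_true(all(pop$age_band %in% bands))
})

test_that("weighted mental-illness carer count matches the configured total", {
  pop <- generate_population(small_config())
  mental <- pop$is_primary_carer &
    pop$cared_condition %in% "mental and behavioural disorders"
  expect_equal(sum(pop$weight[mental]), 53700, tolerance = 1e-12)
})

test_that("zero carer share yields no carers", {
  pop <- generate_population(small_config(carer_share = 0))
  expect_false(any(pop$is_primary_carer))
})

test_that("realized shares converge to configured shares (75% female carers)", {
  cfg <- pop_config(n_records = 50000, rng_seed = 11)
  pop <- generate_population(cfg)
  carers <- pop[pop$is_primary_carer, ]
  p <- 0.75
  se <- sqrt(p * (1 - p) / nrow(carers))
  expect_lt(abs(mean(carers$sex == "female") - p), 3 * se)
})

test_that("configured shares are recovered within 3 binomial SEs across seeds", {
  # fixed seed panel; each check is |realized - configured| <= 3 sqrt(pq/n)
  n <- 20000
  checks <- c()
  for (s in 1:50) {
    pop <- generate_population(pop_config(n_records = n, rng_seed = s))
    carers <- pop$is_primary_carer
    share_checks <- c(
      carer = abs(mean(carers) - 0.03) <=
        3 * sqrt(0.03 * 0.97 / n),
      female_carer = {
        p <- 0.75; nc <- sum(carers)
        abs(mean(pop$sex[carers] == "female") - p) <=
          3 * sqrt(p * (1 - p) / nc)
      },
      nilf_carer = {
        p <- 12900 / 53700; nc <- sum(carers)
        got <- mean(pop$nilf_main_reason[carers] %in%
                      "someone else's ill health or disability")
        abs(got - p) <= 3 * sqrt(p * (1 - p) / nc)
      },
      mental = {
        p <- 0.13; nc <- sum(carers)
        abs(mean(pop$cared_condition[carers] %in%
                   "mental and behavioural disorders") - p) <=
          3 * sqrt(p * (1 - p) / nc)
      })
    checks <- c(checks, share_checks)
  }
  expect_gte(mean(checks), 0.99)
})

test_that("donor pool covers every matching cell and reports coverage errors", {
  cfg <- small_config()
  donors <- generate_donor_pool(cfg, n_donors = 1000)
  n_cells <- 10 * 2 * 4 * 4 * 2
  key <- interaction(donors$age_band, donors$sex, donors$education,
                     donors$lf_status, donors$is_primary_carer, drop = TRUE)
  expect_equal(length(unique(key)), n_cells)
  expect_error(generate_donor_pool(cfg, n_donors = n_cells - 1),
               "cells")
})

test_that("donor economics respect the zero-income tax convention", {
  donors <- generate_donor_pool(small_config(), n_donors = 2000)
  zero <- donors$earned_income == 0
  expect_true(any(zero))
  expect_true(all(donors$income_tax[zero] == 0))
  expect_true(all(donors$income_tax[!zero] >= 0))
  expect_true(all(donors[caresim:::ECON_COLS] >= 0))
  expect_equal(donors$total_income,
               donors$earned_income + donors$total_welfare)
})

test_that("donor pool means are calibrated to the configured magnitudes", {
  donors <- generate_donor_pool(pop_config(rng_seed = 3), n_donors = 20000)
  ft <- donors[donors$lf_status == "employed_ft" & !donors$is_primary_carer, ]
  se_ft <- stats::sd(ft$total_income) / sqrt(nrow(ft))
  expect_lt(abs(mean(ft$total_income) - 1544), 3 * se_ft)

  nc <- donors[donors$lf_status == "nilf" & donors$is_primary_carer, ]
  se_nc <- stats::sd(nc$total_welfare) / sqrt(nrow(nc))
  expect_lt(abs(mean(nc$total_welfare) - 343), 3 * se_nc)
})

test_that("benchmarks follow compound growth and zero growth is the identity", {
  pop <- generate_population(small_config())
  bm0 <- generate_benchmarks(pop, c(2015, 2020, 2030), growth = 0)
  base <- bm0[bm0$year == 2015, ]
  for (y in c(2020, 2030)) {
    expect_equal(bm0$target[bm0$year == y], base$target, tolerance = 1e-12)
  }
  # exhaustive age x sex family sums to the file total each year
  agesex <- bm0[bm0$variable == "age_band|sex", ]
  for (y in unique(agesex$year))
    expect_equal(sum(agesex$target[agesex$year == y]), sum(pop$weight))

  one <- data.frame(record_id = "a", age_band = "15-19", sex = "female",
                    weight = 100, stringsAsFactors = FALSE)
  bm <- generate_benchmarks(one, 2020, growth = 0.02,
                            families = list("sex"), base_year = 2015)
  expect_equal(bm$target, compound_growth_oracle(100, 0.02, 5),
               tolerance = 1e-12)
  expect_equal(bm$target, 110.40808032, tolerance = 1e-8)

  expect_error(generate_benchmarks(one, 2010, growth = 0), "base year")
})

test_that("carer growth calibrated to the 2030 target implies the right factor", {
  g <- (63200 / 53700)^(1 / 15) - 1
  pop <- generate_population(small_config())
  bm <- generate_benchmarks(pop, c(2015, 2030), growth = g)
  carer <- bm[bm$variable == "is_primary_carer|cared_condition" &
                grepl("mental", bm$category), ]
  expect_equal(carer$target[carer$year == 2030] /
                 carer$target[carer$year == 2015],
               63200 / 53700, tolerance = 1e-10)
})

test_that("microdata and benchmarks survive a CSV round trip", {
  pop <- generate_population(small_config())
  f <- withr::local_tempfile(fileext = ".csv")
  write_microdata(pop, f)
  back <- read_microdata(f)
  expect_equal(back$weight, pop$weight)
  expect_identical(back$nilf_main_reason, pop$nilf_main_reason)
  expect_identical(back$is_primary_carer, pop$is_primary_carer)

  bm <- generate_benchmarks(pop, c(2015, 2020), growth = 0.01)
  fb <- withr::local_tempfile(fileext = ".csv")
  write_benchmarks(bm, fb)
  expect_equal(read_benchmarks(fb)$target, bm$target)
})

test_that("YAML configuration files address every generator field", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_records: 500",
    "carer_share: 0.05",
    "rng_seed: 9",
    "welfare_params:",
    "  carer_payment_mean: 400",
    "lf_status_distribution:",
    "  non_carer:",
    "    employed_ft: 0.5",
    "    employed_pt: 0.2",
    "    unemployed: 0.05",
    "    nilf: 0.25"), f)
  cfg <- read_config(f)
  expect_equal(cfg$n_records, 500)
  expect_equal(cfg$carer_share, 0.05)
  expect_equal(cfg$welfare_params$carer_payment_mean, 400)
  expect_equal(unname(cfg$lf_status_distribution$non_carer["employed_ft"]),
               0.5)
  # untouched defaults survive
  expect_equal(cfg$welfare_params$dsp_mean, 340)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 500)

  writeLines("not_a_field: 1", f)
  expect_error(read_config(f), "unknown field")
})
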