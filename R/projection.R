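#' Real-growth indexation rules
#'
#' Annual real growth applied to each economic variable between the base
#' year and a projection year. Defaults follow Treasury-style
#' assumptions: earned income and income tax grow 1% per year in real
#' terms, as do the Carer Payment and the Disability Support Pension
#' (their statutory indexation), while other benefits are indexed to
#' consumer prices and so have zero real growth.
#'
#' @param earned_income,income_tax,welfare_carer_payment,welfare_dsp,welfare_other
#'   annual real growth rates (proportions per year).
#' @return data.frame with columns `variable`, `annual_real_growth`.
#' @export
indexation_rules <- function(earned_income = 0.01, income_tax = 0.01,
                             welfare_carer_payment = 0.01,
                             welfare_dsp = 0.01, welfare_other = 0) {
  rates <- c(earned_income = earned_income, income_tax = income_tax,
             welfare_carer_payment = welfare_carer_payment,
             welfare_dsp = welfare_dsp, welfare_other = welfare_other)
  if (any(!is.finite(rates)))
    stop("growth rates must be finite", call. = FALSE)
  data.frame(variable = names(rates), annual_real_growth = unname(rates),
             stringsAsFactors = FALSE)
}

#' Index economic attributes to a projection year
#'
#' Multiplies each economic variable by `(1 + g)^years_elapsed` using its
#' rule's annual real growth `g`, then recomputes the derived totals.
#' With `years_elapsed = 0` the input is returned unchanged.
#'
#' @param data data.frame carrying the economic attribute columns.
#' @param rules an [indexation_rules()] data.frame.
#' @param years_elapsed non-negative integer number of years since the
#'   base year.
#' @return `data` with indexed economics and recomputed totals.
#' @export
index_economics <- function(data, rules = indexation_rules(),
                            years_elapsed) {
  if (years_elapsed < 0)
    stop("years_elapsed must be non-negative", call. = FALSE)
  for (i in seq_len(nrow(rules))) {
    v <- rules$variable[i]
    if (!v %in% names(data))
      stop("indexation rule references unknown variable: ", v, call. = FALSE)
    data[[v]] <- data[[v]] * (1 + rules$annual_real_growth[i])^years_elapsed
  }
  economics_totals(data)
}

#' Run the full pipeline for one projection year
#'
#' Composes the per-year stages in fixed order: calibrate weights to the
#' year's benchmarks (static ageing), index economic values from the base
#' year, select the carer cohort and comparison pools, run the matched
#' Monte Carlo counterfactual per pool, and aggregate nationally.
#' Indexation is weight-independent, so reweighting and indexation
#' commute; the fixed order is a convention.
#'
#' @param records imputed base-year microdata (output of
#'   [synthetic_match()]).
#' @param benchmarks benchmark table covering `year` (columns `year`,
#'   `variable`, `category`, `target`).
#' @param year projection year.
#' @param base_year base calendar year of `records`.
#' @param rules an [indexation_rules()] data.frame.
#' @param mc an [mc_config()]; its seed is derived from `seed`.
#' @param pools comparison pools to run.
#' @param outcomes outcome columns to difference.
#' @param weeks_per_year weeks used to annualize weekly differences.
#' @param seed integer seed for the Monte Carlo stage.
#' @param keep_records keep the reweighted, indexed microdata in the
#'   result (default `TRUE`).
#' @return an object of class `projection_year_result`: year, the
#'   [gregwt_solve()] solution, weighted cohort sizes, the per-group
#'   weekly summary table, the weekly difference estimates, and the
#'   national aggregates.
#' @export
run_year <- function(records, benchmarks, year, base_year = 2015,
                     rules = indexation_rules(), mc = mc_config(),
                     pools = c("labour_force_all", "ft_only", "pt_only"),
                     outcomes = c("total_income", "total_welfare",
                                  "income_tax"),
                     weeks_per_year = 52, seed = 1L, keep_records = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s, year %s] %s", name, year, conditionMessage(e)),
           call. = FALSE))
  }
  bm <- benchmarks[benchmarks$year == year, , drop = FALSE]
  if (nrow(bm) == 0)
    stop("no benchmark rows for year ", year, call. = FALSE)

  sol <- stage("reweighting", {
    cm <- build_constraints(records, bm)
    gregwt_solve(cm)
  })
  records$weight <- sol$weights
  records <- stage("indexation",
                   index_economics(records, rules, year - base_year))

  carers <- stage("cohort", select_nilf_carers(records))
  carer_mask <- records$is_primary_carer %in% TRUE &
    !is.na(records$cared_condition) &
    norm_cat(records$cared_condition) == norm_cat(CONDITION_MENTAL)

  estimates <- list()
  aggregates <- list()
  for (pi in seq_along(pools)) {
    pk <- pools[pi]
    pool <- stage("cohort", select_pool(records, pk))
    mc_p <- mc
    mc_p$seed <- seed + pi
    res <- stage("counterfactual",
                 run_monte_carlo(carers, pool, outcomes, mc_p,
                                 pool_kind = pk))
    estimates[[pi]] <- cbind(year = year, res$estimates)
    aggregates[[pi] ] <- cbind(year = year,
                               stage("aggregation",
                                     aggregate_national(res, weeks_per_year)))
  }

  structure(list(
    year = year,
    weight_solution = sol,
    carer_count = sum(records$weight[carer_mask]),
    nilf_carer_count = sum(carers$weight),
    group_summary = weekly_group_summary(records, outcomes, year),
    estimates = do.call(rbind, estimates),
    aggregates = do.call(rbind, aggregates),
    records = if (keep_records) records else NULL
  ), class = "projection_year_result")
}

#' Run the whole projection pipeline
#'
#' End-to-end orchestration: generate the synthetic survey file and donor
#' pool, fuse economics by statistical matching, project benchmarks, run
#' every projection year, and build the report tables. All randomness is
#' derived from `seed`.
#'
#' @param config a [pop_config()].
#' @param years projection years (default 2015, 2020, 2025, 2030).
#' @param growth annual benchmark growth (scalar or function; see
#'   [generate_benchmarks()]). The default 0.011/year takes the carer
#'   population from 53 700 to about 63 300 over 15 years.
#' @param n_donors donor-pool size.
#' @param mc an [mc_config()].
#' @param weeks_per_year annualization constant.
#' @param seed master integer seed.
#' @return an object of class `care_projection`: list with per-year
#'   results (`years`), the `report`, the imputed base `population` and
#'   the `benchmarks`.
#' @examples
#' \donttest{
#' proj <- run_projection(pop_config(n_records = 5000), seed = 1,
#'                        mc = mc_config(n_iterations = 200))
#' proj$report$aggregates
#' }
#' @export
run_projection <- function(config = pop_config(),
                           years = c(2015, 2020, 2025, 2030),
                           growth = 0.011, n_donors = 20000,
                           mc = mc_config(), weeks_per_year = 52, seed) {
  if (missing(seed) || is.null(seed))
    stop("a master seed is required", call. = FALSE)
  pop <- generate_population(config, seed = seed)
  donors <- generate_donor_pool(config, n_donors = n_donors, seed = seed + 1)
  imputed <- synthetic_match(pop, donors, match_spec(), seed = seed + 2)
  benchmarks <- generate_benchmarks(imputed, years, growth = growth,
                                    base_year = config$base_year)
  results <- lapply(seq_along(years), function(i)
    run_year(imputed, benchmarks, years[i], base_year = config$base_year,
             mc = mc, weeks_per_year = weeks_per_year,
             seed = seed + 100 * i, keep_records = FALSE))
  structure(list(years = results,
                 report = build_report(results),
                 population = imputed,
                 benchmarks = benchmarks,
                 seed = seed),
            class = "care_projection")
}

#' @export
print.care_projection <- function(x, ...) {
  yrs <- vapply(x$years, `[[`, numeric(1), "year")
  cat(sprintf("Care-cost projection: years %s\n",
              paste(yrs, collapse = ", ")))
  cat("\nNational aggregates (AU$ million/year):\n")
  print(x$report$aggregates, row.names = FALSE, digits = 4)
  if (!is.null(x$report$changes)) {
    cat("\nChanges over the horizon:\n")
    print(x$report$changes, row.names = FALSE)
  }
  invisible(x)
}
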