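#' Annualize a weekly amount
#'
#' @param weekly AU$/week amount (vectorized).
#' @param weeks_per_year weeks per year; defaults to 52 (365.25/7 is the
#'   obvious alternative and is accepted).
#' @return AU$/year; linear in `weekly`.
#' @export
annualize <- function(weekly, weeks_per_year = 52) {
  if (weeks_per_year <= 0) stop("weeks_per_year must be > 0", call. = FALSE)
  weekly * weeks_per_year
}

mc_sign <- function(outcome) {
  # differences are stored counterfactual - carer; welfare is reported in
  # the carer - counterfactual direction (extra payments received)
  ifelse(outcome == "total_welfare", -1, 1)
}

#' National annual aggregates from Monte Carlo differences
#'
#' Converts the per-iteration weekly differences of a [run_monte_carlo()]
#' result into national annual totals. For iteration `k` the aggregate is
#' `A_k = sum_i w_i * delta_ik * weeks_per_year` (AU$; reported in
#' AU$ million): the income and tax aggregates are losses
#' (counterfactual minus carer) and the welfare aggregate is the extra
#' payments received (carer minus counterfactual). The point estimate is
#' the mean of the `A_k` and the interval their percentile CI. Passing
#' `by` (a grouping factor over carers) returns per-stratum aggregates,
#' which sum exactly to the national ones.
#'
#' @param mc an `mc_result` (must retain draws when `by` is used).
#' @param weeks_per_year annualization constant.
#' @param by optional factor/vector of length `nrow(carers)` defining
#'   strata.
#' @return data.frame with columns (`group`,) `outcome`, `pool_kind`,
#'   `point`, `ci_lower`, `ci_upper` (AU$ million/year) and
#'   `weighted_cohort_size`.
#' @export
aggregate_national <- function(mc, weeks_per_year = 52, by = NULL) {
  stopifnot(inherits(mc, "mc_result"))
  outcomes <- colnames(mc$iteration_means)
  lev <- mc$config$ci_level
  if (is.null(by)) {
    rows <- lapply(outcomes, function(o) {
      A <- mc_sign(o) * mc$iteration_means[, o] * mc$total_weight *
        weeks_per_year / 1e6
      ci <- percentile_ci(A, lev)
      data.frame(outcome = o, pool_kind = mc$pool_kind, point = mean(A),
                 ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
                 weighted_cohort_size = mc$total_weight,
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  if (is.null(mc$deltas))
    stop("stratified aggregation needs retain_draws = TRUE", call. = FALSE)
  if (length(by) != length(mc$carer_weights))
    stop("'by' must have one entry per carer", call. = FALSE)
  rows <- list()
  for (g in sort(unique(as.character(by)))) {
    sel <- as.character(by) == g
    for (o in outcomes) {
      A <- mc_sign(o) *
        drop(crossprod(mc$carer_weights[sel],
                       mc$deltas[[o]][sel, , drop = FALSE])) *
        weeks_per_year / 1e6
      ci <- percentile_ci(A, lev)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, outcome = o, pool_kind = mc$pool_kind, point = mean(A),
        ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
        weighted_cohort_size = sum(mc$carer_weights[sel]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Percent change between two values
#'
#' `(to - from) / from * 100`, the convention used in the report layer's
#' change rows (e.g. aggregate income loss 450.9 to 645.4 AU$ million is
#' a 43% increase when rounded to the nearest whole percent).
#'
#' @param from,to numeric values (vectorized).
#' @return percent change.
#' @export
percent_change <- function(from, to) {
  (to - from) / from * 100
}

weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  stats::approx(cw, x, xout = p, rule = 2, ties = "ordered")$y
}

#' Weighted weekly summary by comparison group
#'
#' Weighted mean, standard deviation and median of each outcome for the
#' nilf-carer cohort and the full-time, part-time and unemployed
#' non-carer groups — the layout of a "weekly income, welfare and taxes
#' by group" table.
#'
#' @param records person-level data.frame with economics and weights.
#' @param outcomes outcome columns to summarise.
#' @param year optional year column value.
#' @return long data.frame: `year`, `group`, `outcome`, `mean`, `sd`,
#'   `median`, `weighted_n`.
#' @export
weekly_group_summary <- function(records,
                                 outcomes = c("total_income",
                                              "total_welfare", "income_tax"),
                                 year = NA) {
  groups <- list(
    nilf_carers = select_nilf_carers(records),
    non_carer_ft = select_pool(records, "ft_only"),
    non_carer_pt = select_pool(records, "pt_only"),
    non_carer_unemployed = {
      r <- records[!(records$is_primary_carer %in% TRUE) &
                     norm_cat(records$lf_status) == "unemployed", ,
                   drop = FALSE]
      r
    })
  rows <- list()
  for (g in names(groups)) {
    df <- groups[[g]]
    if (nrow(df) == 0) next
    w <- df$weight
    for (o in outcomes) {
      x <- df[[o]]
      m <- sum(w * x) / sum(w)
      v <- sum(w * (x - m)^2) / sum(w)
      rows[[length(rows) + 1]] <- data.frame(
        year = year, group = g, outcome = o, mean = m, sd = sqrt(v),
        median = weighted_quantile(x, w, 0.5), weighted_n = sum(w),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build the report tables
#'
#' Renders the three result-table shapes from one or more
#' `projection_year_result`s: per-group weekly means/SDs/medians
#' (`weekly`), weekly differences with percentile CIs by pool
#' (`differences`, welfare flipped to the carer-minus-counterfactual
#' direction), and national annual aggregates with CIs in AU$ million
#' (`aggregates`). With two or more years, `changes` adds percent-change
#' rows (nearest whole percent) for each aggregate outcome/pool and for
#' the weighted carer counts; with a single year `changes` is `NULL`.
#' Machine-readable columns keep full precision; `printed` columns round
#' weekly values to AU$1 and aggregates to AU$0.1 million.
#'
#' @param results list of `projection_year_result`s.
#' @return an object of class `care_report`: list of data.frames
#'   `weekly`, `differences`, `aggregates`, `cohorts`, `changes`.
#' @export
build_report <- function(results) {
  if (length(results) == 0) stop("no year results supplied", call. = FALSE)
  if (inherits(results, "projection_year_result")) results <- list(results)
  years <- vapply(results, `[[`, numeric(1), "year")
  ord <- order(years)
  results <- results[ord]; years <- years[ord]

  weekly <- do.call(rbind, lapply(results, `[[`, "group_summary"))

  differences <- do.call(rbind, lapply(results, `[[`, "estimates"))
  flip <- differences$outcome == "total_welfare"
  if (any(flip)) {
    lo <- differences$ci_lower[flip]
    differences$mean_weekly_difference[flip] <-
      -differences$mean_weekly_difference[flip]
    differences$ci_lower[flip] <- -differences$ci_upper[flip]
    differences$ci_upper[flip] <- -lo
  }
  differences$printed <- sprintf(
    "%d (%d to %d)", round(differences$mean_weekly_difference),
    round(differences$ci_lower), round(differences$ci_upper))

  aggregates <- do.call(rbind, lapply(results, `[[`, "aggregates"))
  aggregates$printed <- sprintf(
    "%.1f (%.1f to %.1f)", round(aggregates$point, 1),
    round(aggregates$ci_lower, 1), round(aggregates$ci_upper, 1))

  cohorts <- data.frame(
    year = years,
    carer_count = vapply(results, `[[`, numeric(1), "carer_count"),
    nilf_carer_count = vapply(results, `[[`, numeric(1), "nilf_carer_count"),
    stringsAsFactors = FALSE)

  changes <- NULL
  if (length(years) >= 2) {
    first <- years[1]; last <- years[length(years)]
    a1 <- aggregates[aggregates$year == first, ]
    a2 <- aggregates[aggregates$year == last, ]
    key <- paste(a1$outcome, a1$pool_kind)
    stopifnot(identical(key, paste(a2$outcome, a2$pool_kind)))
    changes <- data.frame(
      quantity = paste0("aggregate_", a1$outcome),
      pool_kind = a1$pool_kind,
      from_year = first, to_year = last,
      from = a1$point, to = a2$point,
      change_pct = round(percent_change(a1$point, a2$point)),
      stringsAsFactors = FALSE)
    changes <- rbind(changes, data.frame(
      quantity = c("carer_count", "nilf_carer_count"),
      pool_kind = NA_character_,
      from_year = first, to_year = last,
      from = c(cohorts$carer_count[1], cohorts$nilf_carer_count[1]),
      to = c(cohorts$carer_count[nrow(cohorts)],
             cohorts$nilf_carer_count[nrow(cohorts)]),
      change_pct = round(percent_change(
        c(cohorts$carer_count[1], cohorts$nilf_carer_count[1]),
        c(cohorts$carer_count[nrow(cohorts)],
          cohorts$nilf_carer_count[nrow(cohorts)]))),
      stringsAsFactors = FALSE))
    rownames(changes) <- NULL
  }

  structure(list(weekly = weekly, differences = differences,
                 aggregates = aggregates, cohorts = cohorts,
                 changes = changes),
            class = "care_report")
}

#' Write report tables to a directory
#'
#' One CSV per table, named `weekly.csv`, `differences.csv`,
#' `aggregates.csv`, `cohorts.csv` and (when present) `changes.csv`.
#'
#' @param report a [build_report()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "care_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(report)) {
    if (is.null(report[[nm]])) next
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
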