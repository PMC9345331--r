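#' Monte Carlo counterfactual configuration
#'
#' @param n_iterations number of counterfactual data-sets to simulate
#'   (default 5000).
#' @param ci_level confidence level for the percentile intervals.
#' @param match_variables fields defining the counterfactual matching
#'   cells (default age group, sex, education).
#' @param donor_sampling `"weight_proportional"` (default; pool members
#'   represent unequal population counts) or `"uniform"`.
#' @param seed integer seed; estimates are deterministic given the seed.
#' @param fallback if `TRUE`, a carer whose matching cell holds no pool
#'   member is matched after widening the age band to 10 years, then
#'   after also dropping education; disabled by default so silent
#'   coarsening cannot occur.
#' @param retain_draws keep the per-carer, per-iteration difference
#'   matrices (needed for stratified aggregation; default `TRUE`).
#' @return an object of class `mc_config`.
#' @export
mc_config <- function(n_iterations = 5000, ci_level = 0.95,
                      match_variables = c("age_band", "sex", "education"),
                      donor_sampling = c("weight_proportional", "uniform"),
                      seed = NULL, fallback = FALSE, retain_draws = TRUE) {
  donor_sampling <- match.arg(donor_sampling)
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1)
    stop("ci_level must be strictly between 0 and 1", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 ci_level = ci_level, match_variables = match_variables,
                 donor_sampling = donor_sampling, seed = seed,
                 fallback = fallback, retain_draws = retain_draws),
            class = "mc_config")
}

#' Percentile-method confidence interval
#'
#' Empirical quantiles of the Monte Carlo draws at `(1 - level)/2` and
#' `1 - (1 - level)/2`, with linear interpolation between order
#' statistics.
#'
#' @param draws numeric vector of replicate statistics (non-empty).
#' @param level confidence level in (0, 1).
#' @return named numeric vector `c(lower, upper)` with `lower <= upper`.
#' @export
percentile_ci <- function(draws, level = 0.95) {
  if (length(draws) == 0) stop("draws must be non-empty", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("level must be strictly between 0 and 1", call. = FALSE)
  q <- stats::quantile(draws, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

widen_band <- function(band) {
  lo <- as.numeric(vapply(strsplit(band, "-", fixed = TRUE), `[`, "", 1))
  dec <- lo - ((lo - 15) %% 10)
  paste0(dec, "-", dec + 9)
}

mc_cell_key <- function(df, vars) {
  do.call(paste, c(lapply(df[vars], norm_cat), sep = "\r"))
}

#' Matched counterfactual Monte Carlo estimator
#'
#' For each carer out of the labour force due to caring, each iteration
#' draws — at random, with replacement — one counterfactual record with
#' the same age group, sex and highest level of education from the
#' comparison pool, and takes the weekly difference
#' `counterfactual - carer` in each outcome; the same drawn record
#' supplies all outcomes. The iteration's summary is the carer-weighted
#' mean difference, so it describes the represented population. The point
#' estimate is the average over iterations and the confidence interval is
#' the percentile interval of the iteration means.
#'
#' Differences are stored as `counterfactual - carer` for every outcome;
#' the reporting layer flips welfare to the carer-minus-counterfactual
#' direction (carers receive *more* welfare).
#'
#' @param carers cohort data.frame (see [select_nilf_carers()]) with
#'   economic attributes and weights.
#' @param pool comparison pool data.frame (see [select_pool()]) with
#'   economic attributes.
#' @param outcomes outcome columns to difference.
#' @param config an [mc_config()]; `config$seed` must be set.
#' @param pool_kind label stored in the result.
#' @return an object of class `mc_result`: list with `estimates` (one
#'   row per outcome: `mean_weekly_difference`, `ci_lower`, `ci_upper`),
#'   `iteration_means` (iterations x outcomes), per-outcome difference
#'   matrices in `deltas` (if retained), `carer_weights`, `total_weight`,
#'   and the configuration.
#' @export
run_monte_carlo <- function(carers, pool,
                            outcomes = c("total_income", "total_welfare",
                                         "income_tax"),
                            config = mc_config(), pool_kind = NA_character_) {
  stopifnot(inherits(config, "mc_config"))
  if (nrow(carers) == 0) stop("carer set is empty", call. = FALSE)
  if (nrow(pool) == 0) stop("comparison pool is empty", call. = FALSE)
  if (is.null(config$seed))
    stop("config$seed must be set for reproducible estimation",
         call. = FALSE)
  miss <- setdiff(outcomes, intersect(names(carers), names(pool)))
  if (length(miss))
    stop("outcome column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)

  set.seed(config$seed)
  n_c <- nrow(carers)
  K <- config$n_iterations
  vars <- config$match_variables
  pw <- if (config$donor_sampling == "weight_proportional" &&
            !is.null(pool$weight)) pool$weight else rep(1, nrow(pool))

  ckey <- mc_cell_key(carers, vars)
  pkey <- mc_cell_key(pool, vars)
  psplit <- split(seq_len(nrow(pool)), pkey)

  cell_pool <- psplit[ckey]
  unmatched <- vapply(cell_pool, is.null, TRUE)
  if (any(unmatched) && config$fallback && "age_band" %in% vars) {
    # level 1: widen age band to 10 years; level 2: drop education too
    cw <- carers; cw$age_band <- widen_band(cw$age_band)
    pw2 <- pool; pw2$age_band <- widen_band(pw2$age_band)
    for (fv in list(vars, setdiff(vars, "education"))) {
      idx <- which(unmatched)
      if (!length(idx)) break
      ps <- split(seq_len(nrow(pool)), mc_cell_key(pw2, fv))
      repl <- ps[mc_cell_key(cw[idx, , drop = FALSE], fv)]
      ok <- !vapply(repl, is.null, TRUE)
      cell_pool[idx[ok]] <- repl[ok]
      unmatched[idx[ok]] <- FALSE
    }
  }
  if (any(unmatched)) {
    cells <- unique(gsub("\r", " | ", ckey[unmatched], fixed = TRUE))
    stop("no comparison-pool member in matching cell(s): ",
         paste(utils::head(cells, 10), collapse = "; "), call. = FALSE)
  }

  # one drawn pool record per carer per iteration, shared across outcomes
  J <- matrix(NA_integer_, n_c, K)
  for (key in sort(unique(ckey))) {
    rows <- which(ckey == key)
    p <- cell_pool[[rows[1]]]
    J[rows, ] <- p[sample.int(length(p), length(rows) * K, replace = TRUE,
                              prob = pw[p])]
  }

  w <- if (!is.null(carers$weight)) as.numeric(carers$weight) else rep(1, n_c)
  W <- sum(w)
  iter_means <- matrix(NA_real_, K, length(outcomes),
                       dimnames = list(NULL, outcomes))
  deltas <- if (config$retain_draws) stats::setNames(
    vector("list", length(outcomes)), outcomes) else NULL
  est <- data.frame(outcome = outcomes, pool_kind = pool_kind,
                    mean_weekly_difference = NA_real_, ci_lower = NA_real_,
                    ci_upper = NA_real_, stringsAsFactors = FALSE)
  for (oi in seq_along(outcomes)) {
    o <- outcomes[oi]
    D <- matrix(pool[[o]][J], n_c, K) - carers[[o]]
    mk <- drop(crossprod(w, D)) / W
    iter_means[, oi] <- mk
    ci <- percentile_ci(mk, config$ci_level)
    est$mean_weekly_difference[oi] <- mean(mk)
    est$ci_lower[oi] <- ci[["lower"]]
    est$ci_upper[oi] <- ci[["upper"]]
    if (config$retain_draws) deltas[[o]] <- D
  }

  structure(list(estimates = est, iteration_means = iter_means,
                 deltas = deltas, carer_weights = w, total_weight = W,
                 config = config, pool_kind = pool_kind),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Counterfactual Monte Carlo (%d iterations, pool: %s)\n",
              x$config$n_iterations, x$pool_kind))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}
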