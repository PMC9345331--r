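#' Generate a synthetic carer survey file
#'
#' Draws `n_records` person records aged 15-64 with the joint structure the
#' downstream analysis assumes: a small minority are primary informal
#' carers (mostly women), a configurable share of carers are out of the
#' labour force with main reason "someone else's ill health or disability",
#' and a configurable share of carers look after someone whose main
#' condition is a mental or behavioural disorder. Record weights are a
#' single constant calibrated so that the weighted count of mental-illness
#' primary carers equals `config$carer_population_total`.
#'
#' Economic attributes are *not* attached here; they are imputed from a
#' donor pool with [synthetic_match()], mirroring a survey file fused with
#' a tax/transfer model's output.
#'
#' @param config a [pop_config()].
#' @param seed integer seed; defaults to `config$rng_seed`. Output is
#'   byte-identical for identical config + seed.
#' @return a data.frame with columns `record_id`, `wave` (synthetic survey
#'   wave provenance, unused downstream), `age_band`, `sex`, `education`,
#'   `lf_status`, `is_primary_carer`, `nilf_main_reason` (`NA` unless out
#'   of the labour force), `cared_condition` (`NA` unless a carer), and
#'   `weight`.
#' @seealso [generate_donor_pool()], [generate_benchmarks()]
#' @export
generate_population <- function(config, seed = config$rng_seed) {
  validate_pop_config(config)
  if (is.null(seed))
    stop("a seed is required: set config$rng_seed or pass seed=", call. = FALSE)
  set.seed(seed)
  n <- as.integer(config$n_records)

  is_carer <- stats::runif(n) < config$carer_share
  sex <- ifelse(stats::runif(n) < ifelse(is_carer,
                                         config$female_share_carers,
                                         config$female_share_non_carers),
                "female", "male")
  age_band <- sample(config$age_bands, n, replace = TRUE)
  education <- sample(names(config$education_distribution), n, replace = TRUE,
                      prob = config$education_distribution)

  # care recipient's main condition (carers only)
  m <- config$mental_illness_care_share
  cond_levels <- c(CONDITION_MENTAL, CONDITION_OTHER)
  cond_prob <- c(m, (1 - m) * c(0.75, 0.25))
  cared_condition <- rep(NA_character_, n)
  cared_condition[is_carer] <- sample(cond_levels, sum(is_carer),
                                      replace = TRUE, prob = cond_prob)

  # labour-force status: carers are first at risk of being out of the
  # labour force *because of caring*; everyone else draws from the
  # status distribution for their group
  lf_status <- character(n)
  nilf_due_care <- is_carer & stats::runif(n) < config$nilf_carer_share
  lf_status[nilf_due_care] <- "nilf"
  idx_c <- which(is_carer & !nilf_due_care)
  lf_status[idx_c] <- sample(names(config$lf_status_distribution$carer),
                             length(idx_c), replace = TRUE,
                             prob = config$lf_status_distribution$carer)
  idx_n <- which(!is_carer)
  lf_status[idx_n] <- sample(names(config$lf_status_distribution$non_carer),
                             length(idx_n), replace = TRUE,
                             prob = config$lf_status_distribution$non_carer)

  nilf_main_reason <- rep(NA_character_, n)
  nilf_main_reason[nilf_due_care] <- REASON_CARE
  for (grp in c("carer", "non_carer")) {
    sel <- if (grp == "carer") is_carer & !nilf_due_care & lf_status == "nilf"
           else !is_carer & lf_status == "nilf"
    if (any(sel)) {
      d <- config$nilf_reason_distribution[[grp]]
      nilf_main_reason[sel] <- sample(names(d), sum(sel), replace = TRUE,
                                      prob = d)
    }
  }

  n_mental <- sum(is_carer & cared_condition == CONDITION_MENTAL, na.rm = TRUE)
  w0 <- if (n_mental > 0) config$carer_population_total / n_mental else 1

  data.frame(
    record_id = sprintf("P%07d", seq_len(n)),
    wave = sample(c(2003L, 2009L, 2012L), n, replace = TRUE),
    age_band = age_band,
    sex = sex,
    education = education,
    lf_status = lf_status,
    is_primary_carer = is_carer,
    nilf_main_reason = nilf_main_reason,
    cared_condition = cared_condition,
    weight = rep(w0, n),
    stringsAsFactors = FALSE
  )
}

# weekly income tax from weekly earned income via the annualized
# piecewise-linear progressive schedule; zero income pays zero tax
weekly_tax <- function(earned_weekly, brackets) {
  annual <- earned_weekly * 52
  tax <- numeric(length(annual))
  thr <- brackets$threshold
  rate <- brackets$rate
  for (b in seq_along(thr)) {
    upper <- if (b < length(thr)) thr[b + 1] else Inf
    tax <- tax + rate[b] * pmax(0, pmin(annual, upper) - thr[b])
  }
  tax / 52
}

# mean-parameterized gamma draw with configured coefficient of variation;
# zero mean gives exact zeros
rgamma_mean <- function(n, mean, cv) {
  out <- numeric(n)
  pos <- mean > 0
  if (any(pos)) {
    shape <- 1 / cv^2
    out[pos] <- stats::rgamma(sum(pos), shape = shape,
                              scale = mean[pos] / shape)
  }
  out
}

# draw the five economic attributes for records with known matching cells
draw_economics <- function(df, config) {
  n <- nrow(df)
  ip <- config$income_params
  wp <- config$welfare_params

  edu_mean <- ip$ft_mean_by_education[df$education]
  age_idx <- match(df$age_band, config$age_bands)
  lf_factor <- c(employed_ft = 1, employed_pt = ip$pt_factor,
                 unemployed = 0, nilf = 0)[df$lf_status]
  cell_mean <- edu_mean * ip$age_multipliers[age_idx] * lf_factor
  earned <- numeric(n)
  pos <- cell_mean > 0
  if (any(pos)) {
    meanlog <- log(cell_mean[pos]) - ip$sdlog^2 / 2
    earned[pos] <- stats::rlnorm(sum(pos), meanlog = meanlog, sdlog = ip$sdlog)
  }

  nilf <- df$lf_status == "nilf"
  cp_mean <- ifelse(nilf & df$is_primary_carer, wp$carer_payment_mean, 0)
  on_dsp <- nilf & !df$is_primary_carer & stats::runif(n) < wp$dsp_share
  dsp_mean <- ifelse(on_dsp, wp$dsp_mean, 0)
  other_mean <- wp$other_mean[df$lf_status]

  out <- data.frame(
    earned_income = earned,
    welfare_carer_payment = rgamma_mean(n, cp_mean, wp$cv),
    welfare_dsp = rgamma_mean(n, dsp_mean, wp$cv),
    welfare_other = rgamma_mean(n, other_mean, wp$cv),
    income_tax = numeric(n)
  )
  out$income_tax <- weekly_tax(out$earned_income, config$tax_brackets)
  out
}

#' Recompute derived economic totals
#'
#' Adds/overwrites `total_welfare` (sum of the three welfare components)
#' and `total_income` (earned income plus total welfare) on a data.frame
#' carrying the five economic attribute columns.
#'
#' @param df data.frame with the economic attribute columns.
#' @return `df` with `total_welfare` and `total_income` recomputed.
#' @export
economics_totals <- function(df) {
  miss <- setdiff(ECON_COLS, names(df))
  if (length(miss))
    stop("missing economic columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$total_welfare <- df$welfare_carer_payment + df$welfare_dsp +
    df$welfare_other
  df$total_income <- df$earned_income + df$total_welfare
  df
}

#' Generate a synthetic economic donor pool
#'
#' Emulates the output file of a static tax/transfer microsimulation: one
#' record per donor with the matching variables (`age_band`, `sex`,
#' `education`, `lf_status`, `is_primary_carer`), the five weekly economic
#' attributes drawn from the configured income/welfare/tax rules, and a
#' `donor_weight`. Every matching cell the population generator can
#' produce is guaranteed at least one donor; the remaining donors are
#' drawn with cell probabilities that approximate the population's joint
#' distribution.
#'
#' @param config a [pop_config()].
#' @param n_donors number of donor records; must be at least the number of
#'   distinct matching cells.
#' @param seed integer seed; defaults to `config$rng_seed`.
#' @return a data.frame of donors with economic attributes and derived
#'   totals.
#' @export
generate_donor_pool <- function(config, n_donors = 20000,
                                seed = config$rng_seed) {
  validate_pop_config(config)
  if (is.null(seed))
    stop("a seed is required: set config$rng_seed or pass seed=", call. = FALSE)
  cells <- expand.grid(age_band = config$age_bands,
                       sex = SEX_LEVELS,
                       education = names(config$education_distribution),
                       lf_status = LF_LEVELS,
                       is_primary_carer = c(FALSE, TRUE),
                       stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  if (n_donors < nrow(cells))
    stop(sprintf(paste0("n_donors = %d cannot cover all %d matching cells; ",
                        "%d cells would be empty (first: %s)"),
                 n_donors, nrow(cells), nrow(cells) - n_donors,
                 paste(cells[min(n_donors + 1, nrow(cells)), ],
                       collapse = "|")), call. = FALSE)
  set.seed(seed)

  # approximate joint cell probabilities from the configured marginals
  p_sex <- ifelse(cells$sex == "female",
                  ifelse(cells$is_primary_carer, config$female_share_carers,
                         config$female_share_non_carers),
                  ifelse(cells$is_primary_carer,
                         1 - config$female_share_carers,
                         1 - config$female_share_non_carers))
  lf_carer <- config$lf_status_distribution$carer
  # fold the nilf-due-to-caring share into the carer nilf probability
  p_lf_carer <- config$nilf_carer_share * (names(lf_carer) == "nilf") +
    (1 - config$nilf_carer_share) * lf_carer
  p_lf <- ifelse(cells$is_primary_carer,
                 p_lf_carer[cells$lf_status],
                 config$lf_status_distribution$non_carer[cells$lf_status])
  p_cell <- (1 / length(config$age_bands)) * p_sex *
    config$education_distribution[cells$education] * p_lf *
    ifelse(cells$is_primary_carer, config$carer_share, 1 - config$carer_share)

  extra <- sample.int(nrow(cells), n_donors - nrow(cells), replace = TRUE,
                      prob = p_cell)
  donors <- cells[c(seq_len(nrow(cells)), extra), , drop = FALSE]
  rownames(donors) <- NULL
  donors <- cbind(donor_id = sprintf("D%07d", seq_len(nrow(donors))), donors,
                  stringsAsFactors = FALSE)
  donors <- cbind(donors, draw_economics(donors, config))
  donors$donor_weight <- 1
  economics_totals(donors)
}

#' Project demographic benchmarks by compound growth
#'
#' Builds the per-year calibration targets for static ageing: for each
#' constraint family (a set of record fields, e.g. `age_band` x `sex`),
#' the weighted base-file total of every complete cell is grown at a
#' compound annual rate to each projection year:
#' `target = base_total * (1 + g)^(year - base_year)`. Records with a
#' missing value in any family field do not form cells, so a family such
#' as `is_primary_carer` x `cared_condition` yields carer-only cells and
#' carer targets grow with the same rate as their demographic cells unless
#' `growth` overrides them — carers keep the same propensity to care over
#' the projection horizon.
#'
#' @param base data.frame of person records with a `weight` column.
#' @param years projection years, all `>= base_year`.
#' @param growth annual growth rate: a single number applied to every
#'   cell, or a function `(variable, category) -> rate` for per-cell
#'   control.
#' @param families list of character vectors of record fields; each
#'   defines one mutually-exclusive constraint family.
#' @param base_year base calendar year.
#' @return a data.frame with columns `year`, `variable` (family fields
#'   joined by `|`), `category` (cell values joined by `|`), `target`.
#' @examples
#' cfg <- pop_config(n_records = 500, rng_seed = 1)
#' pop <- generate_population(cfg)
#' bm <- generate_benchmarks(pop, c(2015, 2030), growth = 0.011)
#' @export
generate_benchmarks <- function(base, years, growth = 0,
                                families = list(c("age_band", "sex"),
                                                c("is_primary_carer",
                                                  "cared_condition")),
                                base_year = 2015) {
  if (nrow(base) == 0) stop("base microdata is empty", call. = FALSE)
  if (any(years < base_year))
    stop("projection years must not precede the base year", call. = FALSE)
  rate_fun <- if (is.function(growth)) growth else {
    if (!is.finite(growth)) stop("growth rate must be finite", call. = FALSE)
    function(variable, category) growth
  }
  out <- list()
  for (fam in families) {
    miss <- setdiff(fam, names(base))
    if (length(miss))
      stop("unknown benchmark field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    complete <- !Reduce(`|`, lapply(base[fam], is.na))
    if (!any(complete)) next
    sub <- base[complete, , drop = FALSE]
    key <- do.call(paste, c(lapply(sub[fam], as.character), sep = "|"))
    totals <- tapply(sub$weight, key, sum)
    variable <- paste(fam, collapse = "|")
    for (y in years) {
      g <- vapply(names(totals), function(cat) rate_fun(variable, cat),
                  numeric(1))
      out[[length(out) + 1]] <- data.frame(
        year = y, variable = variable, category = names(totals),
        target = as.numeric(totals) * (1 + g)^(y - base_year),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$year, res$variable, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}
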