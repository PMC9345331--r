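#' Canonical category labels
#'
#' The survey-style categorical vocabulary used throughout the package.
#' Category strings are always compared case-insensitively after whitespace
#' normalization (see [norm_cat()]), so files written with different
#' capitalisation survive a round trip.
#'
#' @name categories
#' @keywords internal
NULL

# labour-force statuses
LF_LEVELS <- c("employed_ft", "employed_pt", "unemployed", "nilf")
# education, ordered low to high
EDU_LEVELS <- c("below_secondary", "secondary", "diploma", "degree")
SEX_LEVELS <- c("female", "male")

#' Main reason for being out of the labour force that identifies a carer
#' whose non-participation is attributable to caring.
#' @export
REASON_CARE <- "someone else's ill health or disability"

# other main reasons a respondent can give for being out of the labour force
REASON_OTHER <- c("own ill health or disability", "home duties", "retired",
                  "studying")

#' Care-recipient main condition label for mental and behavioural disorders.
#' @export
CONDITION_MENTAL <- "mental and behavioural disorders"

CONDITION_OTHER <- c("physical conditions", "other conditions")

ECON_COLS <- c("earned_income", "welfare_carer_payment", "welfare_dsp",
               "welfare_other", "income_tax")

#' Normalize a category string for matching
#'
#' Lower-cases, trims, and collapses internal whitespace. All categorical
#' comparisons in the package go through this helper so that survey-file
#' dialects (stray capitals, double spaces) do not break cohort selection,
#' constraint building or cell matching.
#'
#' @param x character vector (or anything coercible to character).
#' @return normalized character vector; `NA` stays `NA`.
#' @export
norm_cat <- function(x) {
  x <- as.character(x)
  tolower(trimws(gsub("\\s+", " ", x)))
}

default_age_bands <- function() {
  lo <- seq(15, 60, by = 5)
  paste(lo, lo + 4, sep = "-")
}

default_income_params <- function() {
  # mean weekly earned income of full-time employees by education, chosen so
  # that the education-weighted mean (1526) plus the mean full-time
  # other-benefit amount (18) gives a full-time non-carer mean total income
  # of AU$1544/week in 2015 real terms
  raw_age <- c(0.60, 0.85, 1.00, 1.05, 1.10, 1.10, 1.08, 1.05, 1.00, 0.90)
  list(
    ft_mean_by_education = c(below_secondary = 1120, secondary = 1380,
                             diploma = 1590, degree = 2056),
    pt_factor = 0.45,          # part-time earnings relative to full-time
    sdlog = 0.45,              # log-scale spread of the lognormal incomes
    # life-cycle earnings profile, normalized to mean 1 over uniform ages so
    # the education-level calibration above is preserved
    age_multipliers = raw_age / mean(raw_age)
  )
}

default_welfare_params <- function() {
  list(
    carer_payment_mean = 320,  # AU$/week, nilf primary carers
    dsp_mean = 340,            # AU$/week, Disability Support Pension
    dsp_share = 0.35,          # share of nilf non-carers on the DSP
    # residual "other benefits" by labour-force status; nilf carers receive
    # 23 on top of the Carer Payment so their mean total welfare is 343
    other_mean = c(employed_ft = 18, employed_pt = 60, unemployed = 250,
                   nilf = 23),
    cv = 0.2                   # coefficient of variation of welfare draws
  )
}

default_tax_brackets <- function() {
  # synthetic piecewise-linear progressive schedule on annual earned income;
  # deliberately not any real statutory scale
  data.frame(threshold = c(0, 20000, 60000, 180000),
             rate = c(0, 0.20, 0.34, 0.45))
}

#' Population generator configuration
#'
#' Bundles every tunable of the synthetic-microdata generator: demographic
#' composition, carer prevalence, labour-force structure, and the economic
#' parameters (income, welfare, tax) used for the donor pool. Defaults
#' emulate the magnitudes of an Australian working-age (15-64) carer survey
#' in 2015 real dollars: 75% of primary carers are women, about 24% of
#' mental-illness carers are out of the labour force because of caring
#' (12 900 of 53 700 persons), full-time non-carers average AU$1544/week in
#' total income, and nilf carers average AU$343/week in welfare.
#'
#' @param n_records number of survey records to generate.
#' @param base_year calendar base year of the file (economic values are in
#'   this year's real dollars).
#' @param age_bands ordered 5-year bands partitioning ages 15-64.
#' @param female_share_carers proportion of primary carers who are female.
#' @param female_share_non_carers proportion of non-carers who are female.
#' @param carer_share proportion of the population who are primary carers.
#' @param nilf_carer_share proportion of carers who are out of the labour
#'   force because of their caring role.
#' @param mental_illness_care_share proportion of carers whose care
#'   recipient's main condition is a mental or behavioural disorder.
#' @param education_distribution named probabilities over education levels.
#' @param lf_status_distribution list with elements `non_carer` and `carer`,
#'   each a named probability vector over labour-force statuses (for carers,
#'   conditional on *not* being out of the labour force due to caring).
#' @param nilf_reason_distribution list with elements `non_carer` and
#'   `carer`: probabilities over the non-caring main reasons given by
#'   respondents out of the labour force.
#' @param income_params lognormal weekly-earnings parameters per
#'   (labour-force status, education, age) cell; see
#'   `default_income_params()` in the source.
#' @param welfare_params rule-based weekly welfare amounts (Carer Payment,
#'   Disability Support Pension, other benefits).
#' @param tax_brackets piecewise-linear progressive schedule applied to
#'   annualized earned income (columns `threshold`, `rate`).
#' @param carer_population_total weighted number of mental-illness primary
#'   carers the generated file should represent; record weights are scaled
#'   so the weighted carer count matches this total.
#' @param rng_seed integer seed used when a `seed` argument is not supplied
#'   to the generator functions.
#' @return an object of class `pop_config` (a validated list).
#' @examples
#' cfg <- pop_config(n_records = 1000, rng_seed = 1)
#' pop <- generate_population(cfg)
#' @export
pop_config <- function(n_records = 50000,
                       base_year = 2015,
                       age_bands = default_age_bands(),
                       female_share_carers = 0.75,
                       female_share_non_carers = 0.50,
                       carer_share = 0.03,
                       nilf_carer_share = 12900 / 53700,
                       mental_illness_care_share = 0.13,
                       education_distribution = c(below_secondary = 0.25,
                                                  secondary = 0.30,
                                                  diploma = 0.20,
                                                  degree = 0.25),
                       lf_status_distribution = list(
                         non_carer = c(employed_ft = 0.45, employed_pt = 0.20,
                                       unemployed = 0.05, nilf = 0.30),
                         carer = c(employed_ft = 0.30, employed_pt = 0.30,
                                   unemployed = 0.06, nilf = 0.34)),
                       nilf_reason_distribution = list(
                         non_carer = c("own ill health or disability" = 0.25,
                                       "home duties" = 0.35,
                                       "retired" = 0.15,
                                       "studying" = 0.25),
                         carer = c("own ill health or disability" = 0.30,
                                   "home duties" = 0.40,
                                   "retired" = 0.10,
                                   "studying" = 0.20)),
                       income_params = default_income_params(),
                       welfare_params = default_welfare_params(),
                       tax_brackets = default_tax_brackets(),
                       carer_population_total = 53700,
                       rng_seed = NULL) {
  cfg <- structure(mget(names(formals())), class = "pop_config")
  validate_pop_config(cfg)
  cfg
}

check_prob <- function(p, field) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop(sprintf("configuration error: '%s' must be a proportion in [0, 1]",
                 field), call. = FALSE)
}

check_dist <- function(d, field) {
  if (!is.numeric(d) || length(d) == 0 || any(is.na(d)) || any(d < 0))
    stop(sprintf("configuration error: '%s' must be non-negative probabilities",
                 field), call. = FALSE)
  if (abs(sum(d) - 1) > 1e-9)
    stop(sprintf("configuration error: '%s' must sum to 1 (got %.12f)",
                 field, sum(d)), call. = FALSE)
}

validate_pop_config <- function(cfg) {
  if (!is.numeric(cfg$n_records) || cfg$n_records < 1)
    stop("configuration error: 'n_records' must be a positive integer",
         call. = FALSE)
  for (f in c("female_share_carers", "female_share_non_carers", "carer_share",
              "nilf_carer_share", "mental_illness_care_share"))
    check_prob(cfg[[f]], f)
  check_dist(cfg$education_distribution, "education_distribution")
  for (g in names(cfg$lf_status_distribution))
    check_dist(cfg$lf_status_distribution[[g]],
               paste0("lf_status_distribution$", g))
  for (g in names(cfg$nilf_reason_distribution))
    check_dist(cfg$nilf_reason_distribution[[g]],
               paste0("nilf_reason_distribution$", g))
  bands <- parse_age_bands(cfg$age_bands)
  if (bands$lo[1] != 15 || bands$hi[length(bands$hi)] != 64 ||
      any(bands$lo[-1] != bands$hi[-length(bands$hi)] + 1))
    stop("configuration error: 'age_bands' must partition ages 15-64 without gaps or overlap",
         call. = FALSE)
  invisible(cfg)
}

parse_age_bands <- function(bands) {
  if (length(bands) == 0)
    stop("configuration error: 'age_bands' is empty", call. = FALSE)
  parts <- strsplit(as.character(bands), "-", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("configuration error: 'age_bands' entries must look like '15-19'",
         call. = FALSE)
  lo <- as.numeric(vapply(parts, `[`, "", 1))
  hi <- as.numeric(vapply(parts, `[`, "", 2))
  if (any(is.na(lo)) || any(is.na(hi)) || any(hi < lo))
    stop("configuration error: 'age_bands' entries must be numeric ranges",
         call. = FALSE)
  list(lo = lo, hi = hi)
}

#' Read a generator configuration from a YAML file
#'
#' Every [pop_config()] field is addressable by name; unspecified fields
#' keep their defaults. Nested lists (e.g. `lf_status_distribution`)
#' override element-wise.
#'
#' @param path path to a YAML file.
#' @return a validated `pop_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- pop_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("configuration error: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (is.list(v) && !is.data.frame(v) && !is.list(base[[nm]]))
      v <- unlist(v)
    if (is.list(base[[nm]]) && !is.data.frame(base[[nm]])) {
      v <- utils::modifyList(base[[nm]], lapply(v, function(e)
        if (is.list(e)) unlist(e) else e))
    }
    if (nm == "tax_brackets") v <- as.data.frame(v)
    base[[nm]] <- v
  }
  validate_pop_config(base)
  base
}
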