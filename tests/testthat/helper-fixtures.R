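# Small hand-built fixtures shared across test files.

# Ten-record survey fixture: exactly three records qualify as nilf carers
# (primary carer, out of the labour force, main reason = caring, cared
# condition = mental/behavioural), and the non-carers provide pools of
# 4 full-time, 2 part-time and 1 unemployed member.
fixture_records <- function() {
  data.frame(
    record_id = sprintf("R%02d", 1:10),
    age_band = c("25-29", "30-34", "25-29", "40-44", "25-29",
                 "30-34", "40-44", "25-29", "30-34", "50-54"),
    sex = c("female", "female", "male", "female", "male",
            "female", "male", "female", "male", "female"),
    education = c("secondary", "degree", "secondary", "diploma", "degree",
                  "secondary", "secondary", "degree", "diploma", "secondary"),
    lf_status = c("nilf", "nilf", "nilf", "nilf", "nilf",
                  "employed_ft", "employed_ft", "employed_ft", "employed_ft",
                  "employed_pt"),
    is_primary_carer = c(TRUE, TRUE, TRUE, TRUE, FALSE,
                         FALSE, FALSE, FALSE, FALSE, FALSE),
    nilf_main_reason = c(rep("someone else's ill health or disability", 3),
                         "own ill health or disability",
                         "studying", rep(NA, 5)),
    cared_condition = c(rep("mental and behavioural disorders", 3),
                        "mental and behavioural disorders",
                        rep(NA, 6)),
    weight = rep(1, 10),
    stringsAsFactors = FALSE
  )
}

# add the unemployed and part-time members needed for pool-size counts
fixture_records_pools <- function() {
  df <- fixture_records()
  extra <- df[rep(10, 2), ]
  extra$record_id <- c("R11", "R12")
  extra$lf_status <- c("employed_pt", "unemployed")
  rbind(df, extra)
}

# minimal economics columns with chosen values
with_econ <- function(df, earned = 0, cp = 0, dsp = 0, other = 0, tax = 0) {
  df$earned_income <- rep_len(earned, nrow(df))
  df$welfare_carer_payment <- rep_len(cp, nrow(df))
  df$welfare_dsp <- rep_len(dsp, nrow(df))
  df$welfare_other <- rep_len(other, nrow(df))
  df$income_tax <- rep_len(tax, nrow(df))
  economics_totals(df)
}

# tiny config for fast generator tests
small_config <- function(...) {
  pop_config(n_records = 2000, rng_seed = 42, ...)
}

# single-cell carer/pool pair with chosen incomes
cell_people <- function(n, income, weight = 1, carer = TRUE) {
  df <- data.frame(
    record_id = sprintf("%s%04d", if (carer) "c" else "p", seq_len(n)),
    age_band = "35-39", sex = "female", education = "secondary",
    lf_status = if (carer) "nilf" else "employed_ft",
    is_primary_carer = carer,
    weight = rep_len(weight, n),
    stringsAsFactors = FALSE)
  with_econ(df, earned = if (carer) 0 else income,
            cp = if (carer) income else 0)
}

random_instance <- function(seed, n = NULL, fams = NULL) {
  # random small calibration instance over two categorical fields
  set.seed(seed)
  if (is.null(n)) n <- sample(10:30, 1)
  rec <- data.frame(
    f1 = sample(letters[1:3], n, replace = TRUE),
    f2 = sample(c("x", "y"), n, replace = TRUE),
    weight = stats::runif(n, 0.5, 3),
    stringsAsFactors = FALSE)
  if (is.null(fams)) fams <- sample(1:2, 1)
  # perturb achieved totals into feasible targets; drop one cell from the
  # first family so the two families are not jointly collinear
  bm <- list()
  t1 <- tapply(rec$weight, rec$f1, sum)
  t1 <- t1 * stats::runif(length(t1), 0.8, 1.2)
  bm[[1]] <- data.frame(variable = "f1", category = names(t1)[-1],
                        target = as.numeric(t1)[-1],
                        stringsAsFactors = FALSE)
  if (fams == 2) {
    t2 <- tapply(rec$weight, rec$f2, sum)
    t2 <- t2 * stats::runif(length(t2), 0.8, 1.2)
    bm[[2]] <- data.frame(variable = "f2", category = names(t2),
                          target = as.numeric(t2),
                          stringsAsFactors = FALSE)
  }
  list(records = rec, benchmarks = do.call(rbind, bm))
}
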