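#' Statistical-matching specification
#'
#' Controls the hot-deck fusion of economic attributes onto the survey
#' file: the matching variables, the order in which they are dropped when
#' a recipient's exact cell holds no donor, and how a donor is sampled
#' within a cell.
#'
#' @param match_variables ordered character vector of matching fields.
#' @param fallback_order variables dropped one at a time (cumulatively)
#'   when a cell is empty; must be a strict subset of `match_variables`
#'   so at least one variable is always retained.
#' @param donor_sampling `"weight_proportional"` (probability proportional
#'   to `donor_weight`, the default — respects the donor file's
#'   population representativity) or `"uniform"`.
#' @return an object of class `match_spec`.
#' @export
match_spec <- function(match_variables = c("age_band", "sex", "education",
                                           "lf_status", "is_primary_carer"),
                       fallback_order = c("education", "lf_status",
                                          "age_band"),
                       donor_sampling = c("weight_proportional", "uniform")) {
  donor_sampling <- match.arg(donor_sampling)
  if (!all(fallback_order %in% match_variables))
    stop("fallback_order must be a subset of match_variables", call. = FALSE)
  if (length(fallback_order) >= length(match_variables))
    stop("at least one matching variable must always be retained",
         call. = FALSE)
  structure(list(match_variables = match_variables,
                 fallback_order = fallback_order,
                 donor_sampling = donor_sampling),
            class = "match_spec")
}

match_key <- function(df, vars) {
  do.call(paste, c(lapply(df[vars], function(col) norm_cat(col)),
                   sep = "\r"))
}

#' Hot-deck synthetic matching of economic attributes
#'
#' Attaches the five weekly economic attributes (earned income, the three
#' welfare components, income tax) to each recipient by copying them
#' verbatim from one donor drawn from the finest non-empty matching cell.
#' When a recipient's exact cell holds no donor, matching variables are
#' dropped cumulatively in `spec$fallback_order` until a donor is found;
#' the coarsening level used is recorded per recipient (`match_level`,
#' 0 = exact cell). Nothing is ever synthesised: every imputed attribute
#' set equals some donor's attributes exactly.
#'
#' @param recipients person-level data.frame.
#' @param donors donor pool from [generate_donor_pool()] (or any
#'   data.frame with the matching variables, economic attributes and a
#'   `donor_weight` column).
#' @param spec a [match_spec()].
#' @param seed integer seed; assignments are deterministic given the seed.
#' @return `recipients` with the economic columns, derived totals,
#'   `donor_id` and `match_level` attached. The audit trail
#'   (recipient_id, donor_id, match_level) is these three columns.
#' @export
synthetic_match <- function(recipients, donors, spec = match_spec(), seed) {
  stopifnot(inherits(spec, "match_spec"))
  if (nrow(donors) == 0) stop("donor pool is empty", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for donor sampling", call. = FALSE)
  miss <- setdiff(c(spec$match_variables, ECON_COLS), names(donors))
  if (length(miss))
    stop("donor pool lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  set.seed(seed)
  n <- nrow(recipients)
  assigned <- rep(NA_integer_, n)
  level <- rep(NA_integer_, n)
  dweight <- if (spec$donor_sampling == "weight_proportional")
    donors$donor_weight else rep(1, nrow(donors))

  for (l in 0:length(spec$fallback_order)) {
    todo <- which(is.na(assigned))
    if (!length(todo)) break
    vars <- setdiff(spec$match_variables,
                    spec$fallback_order[seq_len(l)])
    rkey <- match_key(recipients[todo, , drop = FALSE], vars)
    dkey <- match_key(donors, vars)
    dsplit <- split(seq_len(nrow(donors)), dkey)
    for (key in sort(unique(rkey))) {
      pool <- dsplit[[key]]
      if (is.null(pool)) next
      idx <- todo[rkey == key]
      pick <- pool[sample.int(length(pool), length(idx), replace = TRUE,
                              prob = dweight[pool])]
      assigned[idx] <- pick
      level[idx] <- l
    }
  }
  if (anyNA(assigned)) {
    bad <- recipients$record_id[is.na(assigned)]
    stop("no donor found at any fallback level for recipient(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10),
         call. = FALSE)
  }

  out <- recipients
  out[ECON_COLS] <- donors[assigned, ECON_COLS]
  out$donor_id <- if (!is.null(donors$donor_id)) donors$donor_id[assigned]
                  else as.character(assigned)
  out$match_level <- level
  economics_totals(out)
}

#' Write the imputation audit trail
#'
#' @param matched output of [synthetic_match()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_match_audit <- function(matched, path) {
  utils::write.csv(matched[, c("record_id", "donor_id", "match_level")],
                   path, row.names = FALSE)
  invisible(path)
}
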