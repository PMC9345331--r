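#' Select carers out of the labour force because of caring for someone
#' with mental illness
#'
#' The analysis cohort: primary informal carers who are out of the labour
#' force, whose main reason for non-participation is someone else's ill
#' health or disability, and whose care recipient's main condition is a
#' mental or behavioural disorder. Records giving any other main reason
#' for being out of the labour force are excluded. Matching is
#' case-insensitive after whitespace normalization.
#'
#' @param records person-level data.frame (see [generate_population()]).
#' @return the qualifying subset of `records` (possibly empty).
#' @export
select_nilf_carers <- function(records) {
  keep <- records$is_primary_carer %in% TRUE &
    norm_cat(records$lf_status) == "nilf" &
    !is.na(records$nilf_main_reason) &
    norm_cat(records$nilf_main_reason) == norm_cat(REASON_CARE) &
    !is.na(records$cared_condition) &
    norm_cat(records$cared_condition) == norm_cat(CONDITION_MENTAL)
  records[which(keep), , drop = FALSE]
}

#' Select a non-carer comparison pool
#'
#' The pools from which counterfactual records are drawn. All pools
#' contain non-carers only and are therefore disjoint from
#' [select_nilf_carers()]:
#' \describe{
#'   \item{`labour_force_all`}{non-carers in full-time or part-time
#'     employment or unemployed (the labour force).}
#'   \item{`ft_only`}{full-time employed non-carers.}
#'   \item{`pt_only`}{part-time employed non-carers.}
#' }
#' Unemployed pool members carry their recorded (typically low) incomes
#' into comparisons unadjusted.
#'
#' @param records person-level data.frame.
#' @param pool_kind one of `"labour_force_all"`, `"ft_only"`, `"pt_only"`.
#' @return the qualifying subset of `records`.
#' @export
select_pool <- function(records,
                        pool_kind = c("labour_force_all", "ft_only",
                                      "pt_only")) {
  pool_kind <- match.arg(pool_kind)
  status <- norm_cat(records$lf_status)
  wanted <- switch(pool_kind,
                   labour_force_all = c("employed_ft", "employed_pt",
                                        "unemployed"),
                   ft_only = "employed_ft",
                   pt_only = "employed_pt")
  keep <- !(records$is_primary_carer %in% TRUE) & status %in% wanted
  records[which(keep), , drop = FALSE]
}

#' Export cohort membership
#'
#' Writes a CSV of `record_id` plus a cohort label, one row per member.
#'
#' @param cohorts named list of record data.frames (names become labels).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cohorts <- function(cohorts, path) {
  rows <- lapply(names(cohorts), function(nm)
    data.frame(record_id = cohorts[[nm]]$record_id, cohort = nm,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
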