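#' Read and write delimited microdata
#'
#' Microdata and donor pools travel as plain CSV with a documented
#' header; missing categorical values are encoded as empty strings.
#'
#' @param df data.frame to write.
#' @param path CSV path.
#' @return `write_microdata` returns the path invisibly;
#'   `read_microdata` returns a data.frame with `NA` restored in the
#'   categorical columns and logical carer flags re-typed.
#' @name microdata_io
NULL

#' @rdname microdata_io
#' @export
write_microdata <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname microdata_io
#' @export
read_microdata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if ("is_primary_carer" %in% names(df))
    df$is_primary_carer <- as.logical(df$is_primary_carer)
  df
}

#' Read and write benchmark tables
#'
#' Benchmarks travel as CSV with columns `year`, `variable`, `category`,
#' `target`.
#'
#' @param benchmarks benchmark data.frame.
#' @param path CSV path.
#' @name benchmark_io
NULL

#' @rdname benchmark_io
#' @export
write_benchmarks <- function(benchmarks, path) {
  utils::write.csv(benchmarks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname benchmark_io
#' @export
read_benchmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "variable", "category", "target")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("benchmark file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Write calibration diagnostics
#'
#' @param diagnostics a [verify_benchmarks()] table.
#' @param path CSV path.
#' @export
write_diagnostics <- function(diagnostics, path) {
  utils::write.csv(diagnostics, path, row.names = FALSE)
  invisible(path)
}
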