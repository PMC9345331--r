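#' Build the calibration constraint matrix
#'
#' Assembles the 0/1 cell-membership matrix linking person records to
#' benchmark cells, together with the target vector and the initial
#' (design) weights. A benchmark row with `variable = "age_band|sex"` and
#' `category = "15-19|female"` contributes one column whose entries are 1
#' for records matching every field/value pair (after category
#' normalization). Records matching no cell at all are flagged; the GREG
#' solution leaves their weights at the design weights.
#'
#' @param records person-level data.frame with a `weight` column.
#' @param benchmarks data.frame with columns `variable`, `category`,
#'   `target` (a single projection year's rows; a `year` column, if
#'   present, must be constant).
#' @return an object of class `constraint_matrix`: list with the
#'   indicator matrix `X` (records x cells), `targets`, design weights
#'   `d`, cell labels `cells`, and the logical `unconstrained` flag per
#'   record.
#' @export
build_constraints <- function(records, benchmarks) {
  if (!is.null(benchmarks$year) && length(unique(benchmarks$year)) > 1)
    stop("benchmarks span multiple years; filter to one year first",
         call. = FALSE)
  if (any(!is.finite(benchmarks$target)) || any(benchmarks$target < 0))
    stop("benchmark targets must be finite and non-negative", call. = FALSE)
  X <- membership_matrix(records, benchmarks)
  infeasible <- colSums(X) == 0 & benchmarks$target > 0
  if (any(infeasible))
    stop("infeasible benchmark cell(s) with no matching records: ",
         paste(colnames(X)[infeasible], collapse = "; "), call. = FALSE)
  structure(list(X = X,
                 targets = as.numeric(benchmarks$target),
                 d = as.numeric(records$weight),
                 cells = colnames(X),
                 unconstrained = rowSums(X) == 0),
            class = "constraint_matrix")
}

# records x cells 0/1 matrix; shared by build_constraints and
# verify_benchmarks (which must not error on empty cells)
membership_matrix <- function(records, benchmarks) {
  k <- nrow(benchmarks)
  X <- matrix(0, nrow(records), k)
  labels <- character(k)
  for (j in seq_len(k)) {
    fields <- strsplit(benchmarks$variable[j], "|", fixed = TRUE)[[1]]
    cats <- strsplit(benchmarks$category[j], "|", fixed = TRUE)[[1]]
    if (length(fields) != length(cats))
      stop(sprintf("benchmark row %d: %d fields but %d category values",
                   j, length(fields), length(cats)), call. = FALSE)
    miss <- setdiff(fields, names(records))
    if (length(miss))
      stop("benchmark references unknown field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    ind <- rep(TRUE, nrow(records))
    for (i in seq_along(fields)) {
      v <- norm_cat(records[[fields[i]]])
      ind <- ind & !is.na(v) & v == norm_cat(cats[i])
    }
    X[, j] <- as.numeric(ind)
    labels[j] <- paste0(benchmarks$variable[j], "=", benchmarks$category[j])
  }
  colnames(X) <- labels
  X
}

#' Generalized-regression (GREGWT-style) weight calibration
#'
#' Finds new record weights `w` as close as possible to the design
#' weights `d` in the chi-square distance `sum((w - d)^2 / d)` subject to
#' the weighted totals hitting the benchmark targets, `X'w = T`. The
#' unbounded solution is the classical linear GREG closed form
#' `w = d * (1 + X lambda)` with `lambda` solving
#' `(X' D X) lambda = T - X'd`, `D = diag(d)`. With bounds, weights that
#' violate them are clamped, removed from the free set, and the residual
#' targets re-solved until no new violations occur.
#'
#' By default negative weights are not allowed: if the unbounded solution
#' produces any, the run is repeated with a lower bound of zero. Pass
#' `allow_negative = TRUE` to accept the raw GREG solution.
#'
#' @param cm a [build_constraints()] result.
#' @param tolerance convergence threshold on the maximum relative gap
#'   `|achieved - target| / max(1, target)`.
#' @param max_iter maximum clamp/re-solve iterations.
#' @param bounds optional two-column matrix (or length-2 vector recycled)
#'   of per-record `[lower, upper]` weight limits; must bracket `d`.
#' @param allow_negative allow negative weights in the unbounded solution.
#' @return an object of class `weight_solution`: list with `weights`,
#'   `converged`, `iterations`, `max_relative_gap`, `bounded_count`, and
#'   the regression multipliers `lambda`.
#' @references Singh, A.C. & Mohl, C.A. (1996) Understanding calibration
#'   estimators in survey sampling. Survey Methodology 22, 107-115.
#' @examples
#' rec <- data.frame(sex = c("f", "f", "m"), weight = 1)
#' bm <- data.frame(variable = "sex", category = c("f", "m"),
#'                  target = c(4, 2))
#' sol <- gregwt_solve(build_constraints(rec, bm))
#' sol$weights  # 2 2 2
#' @export
gregwt_solve <- function(cm, tolerance = 1e-6, max_iter = 100, bounds = NULL,
                         allow_negative = FALSE) {
  stopifnot(inherits(cm, "constraint_matrix"))
  d <- cm$d
  X <- cm$X
  T_ <- cm$targets
  n <- length(d)
  if (any(d < 0)) stop("design weights must be non-negative", call. = FALSE)

  if (!is.null(bounds)) {
    if (is.null(dim(bounds))) bounds <- matrix(bounds, n, 2, byrow = TRUE)
    if (any(bounds[, 1] > d) || any(bounds[, 2] < d))
      stop("bounds must satisfy lower <= d <= upper", call. = FALSE)
  }

  solve_free <- function(free, w, graceful) {
    # residual targets net of clamped records
    T_free <- T_ - if (all(free)) 0 else
      drop(crossprod(X[!free, , drop = FALSE], w[!free]))
    Xf <- X[free, , drop = FALSE]
    df <- d[free]
    M <- crossprod(Xf, Xf * df)
    rhs <- T_free - drop(crossprod(Xf, df))
    lambda <- tryCatch(solve(M, rhs), error = function(e) {
      if (graceful) return(NULL)
      stop(paste0("singular calibration system (collinear constraints); ",
                  "drop a redundant constraint family"), call. = FALSE)
    })
    if (is.null(lambda)) return(NULL)
    w[free] <- df * (1 + drop(Xf %*% lambda))
    list(w = w, lambda = lambda)
  }

  run <- function(bounds) {
    free <- rep(TRUE, n)
    w <- d
    lambda <- rep(0, ncol(X))
    iter <- 0L
    repeat {
      iter <- iter + 1L
      # clamping can strip a constraint of all free members; the residual
      # system then becomes singular and the run ends unconverged
      sol <- solve_free(free, w, graceful = iter > 1L)
      if (is.null(sol)) break
      w <- sol$w
      lambda <- sol$lambda
      if (is.null(bounds)) break
      lo_viol <- free & w < bounds[, 1]
      hi_viol <- free & w > bounds[, 2]
      if (!any(lo_viol) && !any(hi_viol)) break
      w[lo_viol] <- bounds[lo_viol, 1]
      w[hi_viol] <- bounds[hi_viol, 2]
      free <- free & !lo_viol & !hi_viol
      if (iter >= max_iter || !any(free)) break
    }
    list(w = w, lambda = lambda, iterations = iter,
         bounded_count = sum(!free))
  }

  res <- run(bounds)
  if (is.null(bounds) && !allow_negative && any(res$w < 0)) {
    bounds <- cbind(pmin(0, d), Inf)
    res <- run(bounds)
  }

  achieved <- drop(crossprod(X, res$w))
  gap <- max(abs(achieved - T_) / pmax(1, abs(T_)))
  structure(list(weights = res$w,
                 converged = gap <= tolerance,
                 iterations = res$iterations,
                 max_relative_gap = gap,
                 bounded_count = res$bounded_count,
                 lambda = res$lambda),
            class = "weight_solution")
}

#' @export
print.weight_solution <- function(x, ...) {
  cat(sprintf(
    "GREG weight solution: %d records, %s (max relative gap %.3g, %d iteration%s, %d bounded)\n",
    length(x$weights), if (x$converged) "converged" else "NOT converged",
    x$max_relative_gap, x$iterations, if (x$iterations == 1) "" else "s",
    x$bounded_count))
  invisible(x)
}

#' Compare weighted totals against benchmarks
#'
#' Per-cell diagnostics after (or before) calibration: achieved weighted
#' total, target, absolute gap, and relative gap with denominator
#' `max(1, target)`.
#'
#' @param records person-level data.frame.
#' @param benchmarks benchmark data.frame (`variable`, `category`,
#'   `target`).
#' @param weights weights to evaluate; defaults to `records$weight`.
#' @return data.frame with columns `cell`, `target`, `achieved`, `gap`,
#'   `relative_gap` (empty if `benchmarks` has no rows).
#' @export
verify_benchmarks <- function(records, benchmarks,
                              weights = records$weight) {
  if (is.null(benchmarks) || nrow(benchmarks) == 0)
    return(data.frame(cell = character(), target = numeric(),
                      achieved = numeric(), gap = numeric(),
                      relative_gap = numeric(), stringsAsFactors = FALSE))
  X <- membership_matrix(records, benchmarks)
  achieved <- drop(crossprod(X, weights))
  gap <- achieved - benchmarks$target
  data.frame(cell = colnames(X),
             target = benchmarks$target,
             achieved = achieved,
             gap = gap,
             relative_gap = gap / pmax(1, abs(benchmarks$target)),
             stringsAsFactors = FALSE, row.names = NULL)
}
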