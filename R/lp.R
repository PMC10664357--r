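#' Solve a bounded linear program
#'
#' Thin contract over the package's built-in bounded-variable two-phase
#' simplex: maximize (or minimize) `obj %*% x` subject to `A x = b` and
#' `lb <= x <= ub`. Infinite bounds are allowed.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), dense or `Matrix` sparse.
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds (length n); may contain `-Inf`/`Inf`.
#' @param maximize logical; maximize when `TRUE` (default).
#' @param maxit simplex iteration cap.
#' @return list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"iteration_limit"`), `objective` and the primal
#'   solution `x` (`NULL` unless optimal).
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE, maxit = 100000L) {
  A <- as.matrix(A)
  stopifnot(length(obj) == ncol(A), length(b) == nrow(A),
            length(lb) == ncol(A), length(ub) == ncol(A))
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  res <- .simplex_cpp(A, as.numeric(b), as.numeric(obj),
                      as.numeric(lb), as.numeric(ub),
                      isTRUE(maximize), as.integer(maxit))
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "iteration_limit")
  x <- if (status == "optimal") as.numeric(res$x) else NULL
  list(status = status,
       objective = if (status == "optimal") res$objective else NA_real_,
       x = x)
}
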