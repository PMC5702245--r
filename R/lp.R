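#' @useDynLib mitoflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Solve a linear programme
#'
#' Thin interface over the package's bounded-variable two-phase simplex.
#' Rows with `rowlb == rowub` are equalities; other rows are converted to
#' equalities with internally added slack variables.
#'
#' @param obj numeric objective coefficients (length `n`).
#' @param mat constraint matrix (dense or `Matrix` sparse, `m x n`).
#' @param rowlb,rowub row activity bounds (length `m`).
#' @param lb,ub variable bounds (length `n`); `Inf` allowed.
#' @param maximise logical; maximise (default) or minimise.
#' @param max_iter simplex iteration cap.
#'
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"iteration_limit"`), `objective` and the primal solution `x`.
#' @keywords internal
lp_solve <- function(obj, mat, rowlb, rowub, lb, ub,
                     maximise = TRUE, max_iter = 50000L) {
  mat <- as.matrix(mat)
  m <- nrow(mat)
  n <- ncol(mat)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(rowlb) == m, length(rowub) == m)
  slack <- which(rowub - rowlb > 0)
  b <- as.numeric(rowlb)
  if (length(slack)) {
    sl <- matrix(0, m, length(slack))
    sl[cbind(slack, seq_along(slack))] <- -1
    mat <- cbind(mat, sl)
    obj <- c(obj, rep(0, length(slack)))
    lb <- c(lb, rowlb[slack])
    ub <- c(ub, rowub[slack])
    b[slack] <- 0
  }
  res <- .simplex_solve(mat, b, as.numeric(obj), as.numeric(lb),
                        as.numeric(ub), isTRUE(maximise), as.integer(max_iter))
  status <- c("optimal", "infeasible", "unbounded", "iteration_limit")[res$status + 1L]
  list(status = status,
       objective = if (status == "optimal") res$objective else NA_real_,
       x = res$x[seq_len(n)])
}

# fast path for the pure steady-state system S v = 0, no slack construction
lp_solve_eq <- function(obj, S, lb, ub, maximise = TRUE) {
  res <- .simplex_solve(S, rep(0, nrow(S)), as.numeric(obj), as.numeric(lb),
                        as.numeric(ub), isTRUE(maximise), 50000L)
  status <- c("optimal", "infeasible", "unbounded", "iteration_limit")[res$status + 1L]
  list(status = status,
       objective = if (status == "optimal") res$objective else NA_real_,
       x = res$x)
}
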