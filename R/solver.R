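# Linear and mixed-integer programming backend.
#
# All LPs and MILPs in the package go through these two entry points, which
# drive the HiGHS solver shipped with scipy (scipy.optimize.linprog / milp)
# through reticulate. HiGHS is deterministic for a fixed problem, which the
# curation module relies on for reproducible gap fills.

scipy_optimize <- function() {
  if (!is.null(.backend$sp)) return(.backend$sp)
  if (!reticulate::py_available(initialize = FALSE)) {
    py <- Sys.getenv("RETICULATE_PYTHON", unset = "")
    if (!nzchar(py)) py <- Sys.which("python3")
    if (!nzchar(py)) py <- Sys.which("python")
    if (nzchar(py)) {
      try(reticulate::use_python(py, required = TRUE), silent = TRUE)
    }
  }
  .backend$np <- reticulate::import("numpy", convert = FALSE)
  .backend$sp <- reticulate::import("scipy.optimize", convert = TRUE)
  .backend$sparse <- reticulate::import("scipy.sparse", convert = FALSE)
  .backend$sp
}

# sparse constraint matrices go to python as scipy.sparse; dense as numpy
as_py_matrix <- function(A) {
  if (inherits(A, "sparseMatrix")) methods::as(A, "CsparseMatrix") else as.matrix(A)
}

lp_status <- function(code) {
  switch(as.character(code),
         "0" = "optimal", "2" = "infeasible", "3" = "unbounded",
         "1" = "iteration_limit", "4" = "numerical", "error")
}

#' Solve a linear program (internal backend)
#'
#' Maximize `obj' x` subject to `A_eq x = b_eq`, `A_ub x <= b_ub`,
#' `lb <= x <= ub`.
#'
#' @param obj objective coefficients.
#' @param A_eq,b_eq equality constraints (matrix may be NULL).
#' @param A_ub,b_ub inequality constraints (matrix may be NULL).
#' @param lb,ub variable bounds (recycled; may contain -Inf/Inf).
#' @param maximize maximize (default) or minimize.
#' @return list with `status` ("optimal", "infeasible", "unbounded", ...),
#'   `objective` and `x`.
#' @keywords internal
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb = 0, ub = Inf, maximize = TRUE) {
  sp <- scipy_optimize()
  n <- length(obj)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  bounds <- lapply(seq_len(n), function(i) {
    reticulate::tuple(
      if (is.finite(lb[i])) lb[i] else NULL,
      if (is.finite(ub[i])) ub[i] else NULL
    )
  })
  cvec <- if (maximize) -obj else obj
  args <- list(c = cvec, bounds = bounds, method = "highs")
  if (!is.null(A_eq) && nrow(A_eq) > 0) {
    args$A_eq <- as_py_matrix(A_eq); args$b_eq <- as.numeric(b_eq)
  }
  if (!is.null(A_ub) && nrow(A_ub) > 0) {
    args$A_ub <- as_py_matrix(A_ub); args$b_ub <- as.numeric(b_ub)
  }
  res <- do.call(sp$linprog, args)
  status <- lp_status(res$status)
  x <- if (status == "optimal") as.numeric(res$x) else rep(NA_real_, n)
  objective <- if (status == "optimal") {
    if (maximize) -res$fun else res$fun
  } else NA_real_
  list(status = status, objective = objective, x = x)
}

#' Solve a mixed-integer linear program (internal backend)
#'
#' Maximize `obj' x` subject to `A_eq x = b_eq`, `A_ub x <= b_ub`, bounds,
#' and integrality on the flagged variables.
#'
#' @inheritParams solve_lp
#' @param integer logical vector marking integer variables.
#' @keywords internal
solve_milp <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL,
                       b_ub = NULL, lb = 0, ub = Inf, integer = FALSE,
                       maximize = TRUE) {
  sp <- scipy_optimize()
  n <- length(obj)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  integer <- rep_len(integer, n)
  cons <- list()
  if (!is.null(A_ub) && nrow(A_ub) > 0) {
    cons <- c(cons, list(sp$LinearConstraint(
      as_py_matrix(A_ub), rep(-Inf, nrow(A_ub)), as.numeric(b_ub))))
  }
  if (!is.null(A_eq) && nrow(A_eq) > 0) {
    cons <- c(cons, list(sp$LinearConstraint(
      as_py_matrix(A_eq), as.numeric(b_eq), as.numeric(b_eq))))
  }
  res <- sp$milp(
    c = if (maximize) -obj else obj,
    constraints = cons,
    integrality = as.numeric(integer),
    bounds = sp$Bounds(lb, ub)
  )
  status <- lp_status(res$status)
  x <- if (!is.null(res$x)) as.numeric(res$x) else rep(NA_real_, n)
  objective <- if (status == "optimal") {
    if (maximize) -res$fun else res$fun
  } else NA_real_
  list(status = status, objective = objective, x = x)
}
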