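# Minimal sparse-LP interface. The only backend is HiGHS, reached through
# scipy.optimize.linprog in a python subprocess; problems are exchanged as
# JSON triplet files. Deterministic and single-threaded.

find_python <- function() {
  for (cand in c(Sys.getenv("TRAJFLOW_PYTHON", ""), "python", "python3")) {
    if (!nzchar(cand)) next
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no 'python' found on PATH (required for the HiGHS LP backend)")
}

#' Solve a sparse linear program
#'
#' Minimizes `c'x` subject to `A_eq x = b_eq`, `A_ub x <= b_ub`,
#' `lb <= x <= ub`. Matrices are given as 1-based triplet lists
#' `list(i=, j=, v=)`. Backend: HiGHS via scipy.
#'
#' @param c objective coefficients.
#' @param A_eq,b_eq equality constraints (triplets), or `NULL`.
#' @param A_ub,b_ub inequality constraints (triplets), or `NULL`.
#' @param lb,ub variable bounds (recycled).
#' @param solver backend name; only `"highs"` is available.
#' @return list with `status` ("optimal"/"infeasible"), `objective`, `x`,
#'   `message`.
#' @keywords internal
lp_solve <- function(c, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb = 0, ub = 1, solver = "highs") {
  if (!identical(solver, "highs"))
    stop("unknown solver backend: ", solver, " (available: highs)")
  n <- length(c)
  prob <- list(
    c = as.numeric(c),
    lb = rep_len(as.numeric(lb), n),
    ub = rep_len(as.numeric(ub), n),
    A_eq = A_eq, b_eq = as.numeric(b_eq),
    A_ub = A_ub, b_ub = as.numeric(b_ub))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(prob, fin, auto_unbox = FALSE, digits = NA, null = "null")
  script <- system.file("python", "lp_solve.py", package = "trajflow",
                        mustWork = TRUE)
  st <- system2(find_python(), c(shQuote(script), shQuote(fin), shQuote(fout)),
                stdout = TRUE, stderr = TRUE)
  code <- attr(st, "status")
  if (!is.null(code) && code != 0)
    stop("LP backend failed:\n", paste(st, collapse = "\n"))
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "2" = "infeasible",
                   stop("LP solver did not converge: ", res$message))
  list(status = status, objective = res$objective, x = res$x,
       message = res$message)
}
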