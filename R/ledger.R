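#' Evaluation ledger: the budget accountant
#'
#' Every convergence claim made by the package is stated in units of
#' objective-function evaluations, so evaluations are metered through a
#' single mutable ledger. The ledger holds the budget `N`, the number of
#' evaluations consumed so far, and the best-so-far trace (one entry per
#' evaluation, monotone non-increasing). Calling the objective past the
#' budget raises a `dopsr_budget_exhausted` condition, which the phase
#' drivers use as their hard stop.
#'
#' @param budget Positive integer: the maximum number of objective
#'   evaluations `N`.
#'
#' @return An environment of class `eval_ledger` with fields `budget`,
#'   `consumed`, `best` and `trace`.
#' @examples
#' led <- eval_ledger(100)
#' led$consumed
#' @export
eval_ledger <- function(budget) {
  budget <- as.integer(budget)
  if (is.na(budget) || budget < 1L) {
    stop("`budget` must be a positive integer", call. = FALSE)
  }
  e <- new.env(parent = emptyenv())
  e$budget <- budget
  e$consumed <- 0L
  e$best <- Inf
  e$trace <- numeric(budget)
  class(e) <- "eval_ledger"
  e
}

#' @export
print.eval_ledger <- function(x, ...) {
  cat("<eval_ledger>", x$consumed, "of", x$budget, "evaluations used;",
      "best =", format(x$best), "\n")
  invisible(x)
}

ledger_remaining <- function(ledger) ledger$budget - ledger$consumed

ledger_record <- function(ledger, value) {
  if (ledger$consumed >= ledger$budget) {
    stop(structure(
      class = c("dopsr_budget_exhausted", "error", "condition"),
      list(message = sprintf("evaluation budget of %d exhausted",
                             ledger$budget),
           call = NULL)
    ))
  }
  ledger$consumed <- ledger$consumed + 1L
  if (value < ledger$best) ledger$best <- value
  ledger$trace[ledger$consumed] <- ledger$best
  invisible(value)
}

#' Evaluate an objective under budget accounting
#'
#' Calls the objective exactly once, increments the ledger and extends the
#' best-so-far trace. This is the only route through which the optimizer
#' phases touch the objective, so the trace length always equals the number
#' of objective calls.
#'
#' @param spec An [objective_spec()].
#' @param x Numeric vector of length `spec$bounds$dimension`.
#' @param ledger An [eval_ledger()] with at least one evaluation remaining.
#'
#' @return The objective value at `x` (scalar).
#' @export
evaluate_with_budget <- function(spec, x, ledger) {
  stopifnot(inherits(spec, "objective_spec"), inherits(ledger, "eval_ledger"))
  if (length(x) != spec$bounds$dimension) {
    stop(sprintf("dimension mismatch: x has length %d, objective expects %d",
                 length(x), spec$bounds$dimension), call. = FALSE)
  }
  if (ledger$consumed >= ledger$budget) {
    # raise before calling the objective so budgets are never overdrawn
    ledger_record(ledger, Inf)
  }
  value <- spec$evaluate(x)
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    stop("objective returned a non-scalar or NA value", call. = FALSE)
  }
  ledger_record(ledger, value)
  value
}

#' Scale a best-so-far trace by its initial value
#'
#' Convergence curves are reported as scaled error: the best-so-far objective
#' divided by the starting best of the same trial, so every trial begins at
#' exactly 1.0 and curves from different problems share a common scale.
#'
#' @param trace Numeric vector of best-so-far values; the first entry is the
#'   trial's initial best and must be strictly positive.
#'
#' @return Numeric vector of the same length, starting at 1.0.
#' @examples
#' scaled_error(c(10, 5, 1))
#' @export
scaled_error <- function(trace) {
  trace <- as.numeric(trace)
  if (length(trace) < 1L) stop("`trace` must be non-empty", call. = FALSE)
  if (!is.finite(trace[1]) || trace[1] <= 0) {
    stop("the initial trace value must be finite and > 0; scaling undefined",
         call. = FALSE)
  }
  trace / trace[1]
}
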