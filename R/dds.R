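#' Settings for the dynamically dimensioned search phase
#'
#' @param r Scalar perturbation size R; the per-dimension perturbation
#'   standard deviation is `r * (upper - lower)` (default 0.2).
#' @param prob_formula Which perturbation-probability schedule to use.
#'   `"reference"` (default) is the original dynamically dimensioned search
#'   schedule `1 - ln(i)/ln(n_dds)`, which decreases monotonically from 1 to
#'   0 over the phase. `"as-printed"` is the alternative form
#'   `1 - log(i/n_dds)` clamped to \[0, 1\]; it equals 1 over the whole
#'   horizon and is retained for auditability only.
#'
#' @return An object of class `dds_settings`.
#' @export
dds_settings <- function(r = 0.2, prob_formula = c("reference", "as-printed")) {
  prob_formula <- match.arg(prob_formula)
  if (r <= 0) stop("`r` must be positive", call. = FALSE)
  structure(list(r = r, prob_formula = prob_formula), class = "dds_settings")
}

#' Perturbation-inclusion probability schedule
#'
#' The probability that any given dimension is perturbed at iteration `i` of
#' a dynamically dimensioned search phase with `n_dds` total iterations.
#' Under the default `"reference"` schedule it is
#' `1 - ln(i)/ln(n_dds)`: 1 at the first iteration (perturb everything,
#' global search) and 0 at the last (perturb a single dimension, local
#' search).
#'
#' @param i Current phase iteration, `1 <= i <= n_dds`.
#' @param n_dds Total iterations of the phase (>= 2).
#' @param prob_formula See [dds_settings()].
#'
#' @return Scalar in `[0, 1]`, monotone non-increasing in `i`.
#' @examples
#' perturb_probability(1, 1000)     # 1
#' perturb_probability(1000, 1000)  # 0
#' @export
perturb_probability <- function(i, n_dds,
                                prob_formula = c("reference", "as-printed")) {
  prob_formula <- match.arg(prob_formula)
  if (n_dds < 2) stop("`n_dds` must be at least 2", call. = FALSE)
  p <- switch(prob_formula,
    "reference"  = 1 - log(i) / log(n_dds),
    "as-printed" = 1 - log(i / n_dds)
  )
  min(max(p, 0), 1)
}

#' Choose the subset of dimensions to perturb
#'
#' Each dimension is included independently with probability `p_include`
#' (a uniform draw per dimension, included when below the threshold). At
#' least one dimension is always perturbed: when the draw leaves the set
#' empty, one dimension is picked uniformly at random.
#'
#' @param p_include Inclusion probability in `[0, 1]`.
#' @param dimension Number of dimensions K.
#'
#' @return Integer vector of selected dimension indices (never empty).
#' @export
select_dimensions <- function(p_include, dimension) {
  stopifnot(p_include >= 0, p_include <= 1, dimension >= 1)
  j <- which(runif(dimension) < p_include)
  if (length(j) == 0L) j <- sample.int(dimension, 1L)
  j
}

#' Generate a dynamically dimensioned search candidate
#'
#' Copies the incumbent and perturbs the selected dimensions with
#' independent zero-mean normal draws whose standard deviation is
#' `sigma = r * (upper - lower)` per dimension, then reflects the result
#' into the box. Unselected dimensions are untouched.
#'
#' @param incumbent Current best vector.
#' @param j_set Non-empty integer vector of dimensions to perturb.
#' @param settings A [dds_settings()].
#' @param bounds A [bounds_box()].
#'
#' @return A feasible candidate vector.
#' @export
dds_candidate <- function(incumbent, j_set, settings, bounds) {
  if (length(j_set) == 0L) {
    stop("`j_set` must contain at least one dimension", call. = FALSE)
  }
  sigma <- settings$r * (bounds$upper - bounds$lower)
  cand <- incumbent
  cand[j_set] <- cand[j_set] + rnorm(length(j_set), 0, sigma[j_set])
  reflect_bounds(cand, bounds)
}

#' One greedy dynamically dimensioned search step
#'
#' Draws the perturbation probability for the current iteration, selects the
#' dimension subset, generates and evaluates one candidate (one ledger
#' evaluation), and replaces the incumbent only on strict improvement.
#'
#' @param state List with `incumbent`, `incumbent_value`, `iteration` and
#'   `n_dds` (total phase iterations).
#' @param spec An [objective_spec()].
#' @param ledger An [eval_ledger()].
#' @param settings A [dds_settings()].
#'
#' @return The updated state.
#' @export
dds_step <- function(state, spec, ledger, settings = dds_settings()) {
  if (ledger_remaining(ledger) < 1L) {
    stop("insufficient budget for a dynamically dimensioned search step",
         call. = FALSE)
  }
  p_i <- if (state$n_dds < 2) 1 else {
    perturb_probability(state$iteration, state$n_dds, settings$prob_formula)
  }
  j_set <- select_dimensions(p_i, spec$bounds$dimension)
  cand <- dds_candidate(state$incumbent, j_set, settings, spec$bounds)
  value <- evaluate_with_budget(spec, cand, ledger)
  if (value < state$incumbent_value) {
    state$incumbent <- cand
    state$incumbent_value <- value
  }
  state$iteration <- state$iteration + 1L
  state
}
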