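#' Define a black-box objective over a bounded box
#'
#' An `objective_spec` packages the minimization target: a deterministic
#' function from a real parameter vector to a scalar, the box bounds of the
#' search, and a display name. Stochastic objectives are out of scope; all
#' randomness lives in the optimizer.
#'
#' @param evaluate Function taking a numeric vector of length
#'   `bounds$dimension` and returning a finite scalar.
#' @param bounds A [bounds_box()].
#' @param name Identifier used in printing and result metadata.
#'
#' @return An object of class `objective_spec`.
#' @examples
#' sphere <- objective_spec(function(x) sum(x^2),
#'                          bounds_box(rep(-5, 3), rep(5, 3)), "sphere")
#' @export
objective_spec <- function(evaluate, bounds, name = "objective") {
  stopifnot(is.function(evaluate), inherits(bounds, "bounds_box"))
  structure(
    list(evaluate = evaluate, bounds = bounds, name = as.character(name)),
    class = "objective_spec"
  )
}

#' @export
print.objective_spec <- function(x, ...) {
  cat("<objective_spec>", x$name, "- dimension", x$bounds$dimension, "\n")
  invisible(x)
}

#' Construct a benchmark test-function objective by name
#'
#' Builds an [objective_spec()] for one of the bundled analytic test
#' functions, with the conventional search domain for each:
#' Ackley on \[-15, 30\], Rastrigin on \[-5.12, 5.12\],
#' Styblinski-Tang on \[-5, 5\] (any dimension), and the two-dimensional
#' Eggholder on \[-512, 512\].
#'
#' @param name One of `"ackley"`, `"rastrigin"`, `"eggholder"`,
#'   `"styblinski_tang"`.
#' @param dimension Positive integer; must be 2 for `"eggholder"`.
#' @param bounds Optional [bounds_box()] overriding the conventional domain.
#'
#' @return An [objective_spec()].
#' @examples
#' make_test_objective("rastrigin", 10)
#' @export
make_test_objective <- function(name = c("ackley", "rastrigin", "eggholder",
                                         "styblinski_tang"),
                                dimension = 10L, bounds = NULL) {
  name <- match.arg(name)
  dimension <- as.integer(dimension)
  if (name == "eggholder" && dimension != 2L) {
    stop("the Eggholder function is defined in 2 dimensions", call. = FALSE)
  }
  default_box <- switch(name,
    ackley          = c(-15, 30),
    rastrigin       = c(-5.12, 5.12),
    eggholder       = c(-512, 512),
    styblinski_tang = c(-5, 5)
  )
  if (is.null(bounds)) {
    bounds <- bounds_box(rep(default_box[1], dimension),
                         rep(default_box[2], dimension))
  }
  fn <- switch(name,
    ackley = ackley,
    rastrigin = rastrigin,
    eggholder = eggholder,
    styblinski_tang = styblinski_tang
  )
  objective_spec(fn, bounds, name = sprintf("%s-%dd", name, dimension))
}
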