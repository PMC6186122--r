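#' Analytic benchmark test functions
#'
#' Standard multimodal minimization benchmarks used to exercise the
#' optimizer. All are stated in their conventional literature forms:
#'
#' * **Ackley** (`a = 20`, `b = 0.2`, `c = 2*pi`): global minimum 0 at the
#'   origin; a nearly flat outer region with a deep central funnel.
#' * **Rastrigin** (`A = 10`): `10*K + sum(x^2 - 10*cos(2*pi*x))`; global
#'   minimum 0 at the origin with a regular lattice of local minima.
#' * **Eggholder** (2-D): strongly multimodal over \[-512, 512\]^2; global
#'   minimum about -959.6407 near (512, 404.23).
#' * **Styblinski-Tang**: `sum(x^4 - 16*x^2 + 5*x)/2`; separable, with the
#'   K-dimensional minimum equal to K times the one-dimensional minimum
#'   (about -39.166 per dimension at x = -2.9035).
#'
#' @param x Numeric vector (length 2 for `eggholder`).
#' @return Scalar function value.
#' @name test_functions
#' @examples
#' ackley(rep(0, 10))
#' rastrigin(rep(1, 10))
NULL

#' @rdname test_functions
#' @export
ackley <- function(x) {
  if (length(x) == 0L) stop("`x` must be non-empty", call. = FALSE)
  a <- 20; b <- 0.2; cc <- 2 * pi
  -a * exp(-b * sqrt(mean(x^2))) - exp(mean(cos(cc * x))) + a + exp(1)
}

#' @rdname test_functions
#' @export
rastrigin <- function(x) {
  if (length(x) == 0L) stop("`x` must be non-empty", call. = FALSE)
  10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))
}

#' @rdname test_functions
#' @export
eggholder <- function(x) {
  if (length(x) != 2L) {
    stop("the Eggholder function takes a vector of length 2", call. = FALSE)
  }
  eggholder_xy(x[1], x[2])
}

# vectorized core used by both the scalar wrapper and the grid search
eggholder_xy <- function(x1, x2) {
  -(x2 + 47) * sin(sqrt(abs(x2 + x1 / 2 + 47))) -
    x1 * sin(sqrt(abs(x1 - (x2 + 47))))
}

#' @rdname test_functions
#' @export
styblinski_tang <- function(x) {
  if (length(x) == 0L) stop("`x` must be non-empty", call. = FALSE)
  sum(x^4 - 16 * x^2 + 5 * x) / 2
}

#' Locate the Eggholder global minimum by grid search plus refinement
#'
#' Evaluates the Eggholder function on a dense regular grid over
#' \[-512, 512\]^2 and polishes the best grid point with a bounded
#' quasi-Newton local search. With the default grid this recovers the known
#' global minimum, approximately -959.6407 at (512, 404.23).
#'
#' @param n_grid Number of grid points per axis (default 2049).
#'
#' @return A list with `value` (the minimum), `par` (its location) and
#'   `grid_value` (the best value on the raw grid).
#' @export
eggholder_minimum <- function(n_grid = 2049L) {
  g <- seq(-512, 512, length.out = n_grid)
  vals <- outer(g, g, eggholder_xy)
  idx <- arrayInd(which.min(vals), dim(vals))
  start <- c(g[idx[1]], g[idx[2]])
  ref <- optim(start, function(p) eggholder_xy(p[1], p[2]),
               method = "L-BFGS-B",
               lower = c(-512, -512), upper = c(512, 512))
  list(value = ref$value, par = ref$par, grid_value = min(vals))
}
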