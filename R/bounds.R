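#' Box constraints on the parameter vector
#'
#' A `bounds_box` holds the lower and upper parameter bounds that define the
#' rectangular search domain. Every candidate the optimizer evaluates lies
#' inside this box; proposals that leave it are folded back by
#' [reflect_bounds()].
#'
#' @param lower Numeric vector of lower bounds.
#' @param upper Numeric vector of upper bounds, same length as `lower`, with
#'   `lower[d] < upper[d]` in every dimension.
#'
#' @return An object of class `bounds_box` with fields `lower`, `upper` and
#'   `dimension`.
#' @examples
#' b <- bounds_box(rep(-5.12, 10), rep(5.12, 10))
#' b$dimension
#' @export
bounds_box <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) < 1L || length(lower) != length(upper)) {
    stop("`lower` and `upper` must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (anyNA(lower) || anyNA(upper)) {
    stop("bounds must not contain NA", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("every lower bound must be strictly below its upper bound",
         call. = FALSE)
  }
  structure(
    list(lower = lower, upper = upper, dimension = length(lower)),
    class = "bounds_box"
  )
}

#' @export
print.bounds_box <- function(x, ...) {
  cat("<bounds_box> dimension", x$dimension, "\n")
  k <- min(x$dimension, 6L)
  cat("  lower:", paste(signif(x$lower[seq_len(k)], 4), collapse = ", "),
      if (x$dimension > k) "..." else "", "\n")
  cat("  upper:", paste(signif(x$upper[seq_len(k)], 4), collapse = ", "),
      if (x$dimension > k) "..." else "", "\n")
  invisible(x)
}

#' Reflect a candidate vector back into the search box
#'
#' Bound violations are handled by reflection: a coordinate that exceeds its
#' upper bound by a distance d is mapped to `upper - d`, and symmetrically at
#' the lower bound. If the overshoot is wider than the box, so that the
#' reflected value still lies outside, the coordinate is clamped to the bound
#' that was originally violated. In-bounds coordinates are returned unchanged,
#' and the output always lies inside the box.
#'
#' @param x Numeric vector, possibly outside the box.
#' @param bounds A [bounds_box()] with the same dimension as `x`.
#'
#' @return A numeric vector inside `bounds`.
#' @examples
#' b <- bounds_box(0, 10)
#' reflect_bounds(12, b)  # 8
#' @export
reflect_bounds <- function(x, bounds) {
  stopifnot(inherits(bounds, "bounds_box"))
  if (length(x) != bounds$dimension) {
    stop("dimension mismatch between `x` and `bounds`", call. = FALSE)
  }
  lo <- bounds$lower
  hi <- bounds$upper
  out <- x
  over <- x > hi
  under <- x < lo
  out[over] <- 2 * hi[over] - x[over]
  out[under] <- 2 * lo[under] - x[under]
  # double violation: reflection overshot the opposite face
  clamp_hi <- over & out < lo
  clamp_lo <- under & out > hi
  out[clamp_hi] <- hi[clamp_hi]
  out[clamp_lo] <- lo[clamp_lo]
  out
}

# uniform draw inside the box; one row per sample
runif_box <- function(n, bounds) {
  k <- bounds$dimension
  m <- matrix(runif(n * k), nrow = n, ncol = k)
  sweep(sweep(m, 2, bounds$upper - bounds$lower, "*"), 2, bounds$lower, "+")
}
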