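# shared fixtures: cheap objectives with call counting

sphere_spec <- function(dimension = 2, lo = -5, hi = 5, shift = 0) {
  objective_spec(function(x) sum((x - shift)^2) ,
                 bounds_box(rep(lo, dimension), rep(hi, dimension)),
                 name = "sphere")
}

# wraps a spec so the true number of objective calls is observable
counting_spec <- function(spec) {
  counter <- new.env(parent = emptyenv())
  counter$calls <- 0L
  wrapped <- objective_spec(
    function(x) {
      counter$calls <- counter$calls + 1L
      spec$evaluate(x)
    },
    spec$bounds, name = paste0(spec$name, "-counted")
  )
  list(spec = wrapped, counter = counter)
}

expect_within_bounds <- function(x, bounds) {
  expect_true(all(x >= bounds$lower - 1e-12 & x <= bounds$upper + 1e-12))
}
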