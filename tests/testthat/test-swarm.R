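test_that("inertia weight is the linear schedule with the study endpoints", {
  expect_equal(inertia_weight(1, 4000), 0.9)
  expect_equal(inertia_weight(4000, 4000), 0.4)
  n <- 4001  # odd: exact midpoint
  expect_equal(inertia_weight((n + 1) / 2, n), 0.65)
  w <- vapply(1:100, inertia_weight, numeric(1), n_total = 100)
  expect_true(all(diff(w) < 0))
  expect_equal(max(abs(diff(w, differences = 2))), 0, tolerance = 1e-12)
  expect_error(inertia_weight(1, 1), "at least 2")
})

test_that("the velocity-free update has the contracting fixed-point structure", {
  z <- rep(0, 4)
  expect_equal(update_particle(z, z, z, theta1 = 0.9), rep(0, 4))
  # at consensus the attraction terms vanish and the position contracts
  v <- c(1, -2, 3)
  expect_equal(update_particle(v, v, v, theta1 = 0.9), 0.9 * v)
  expect_error(update_particle(v, c(1, 2), v, 0.9), "dimension")
})

test_that("reflection folds violations back into the box", {
  b <- bounds_box(c(0, 0), c(10, 1))
  expect_equal(reflect_bounds(c(5, 0.5), b), c(5, 0.5))
  expect_equal(reflect_bounds(c(12, 0.5), b), c(8, 0.5))
  # overshoot wider than the box clamps to the violated bound
  expect_equal(reflect_bounds(c(5, 5), b), c(5, 1))
  expect_equal(reflect_bounds(c(-30, -5), b), c(0, 0))
  set.seed(11)
  for (i in 1:50) {
    x <- runif(2, -40, 40)
    expect_within_bounds(reflect_bounds(x, b), b)
  }
})

test_that("initialization draws in-bounds particles in equal sub-swarms", {
  spec <- sphere_spec(3)
  set.seed(5)
  led <- eval_ledger(100)
  st <- initialize_swarm(spec, swarm_settings(np = 40, k = 5), led)
  expect_equal(led$consumed, 40L)
  expect_equal(as.integer(table(st$assignment)), rep(8L, 5))
  expect_within_bounds(st$positions, spec$bounds)
  expect_equal(st$global_best_value, min(st$pbest_value))
  expect_error(swarm_settings(np = 40, k = 7), "multiple")
  expect_error(initialize_swarm(spec, swarm_settings(np = 40, k = 5),
                                eval_ledger(10)), "insufficient budget")
})

test_that("an iteration costs NP evaluations and never loses the best", {
  spec <- sphere_spec(2)
  set.seed(9)
  led <- eval_ledger(500)
  sw <- swarm_settings(np = 20, k = 4)
  st <- initialize_swarm(spec, sw, led)
  prev_best <- st$global_best_value
  for (i in 1:10) {
    before <- led$consumed
    st <- swarm_iteration(st, spec, sw, led)
    expect_equal(led$consumed - before, 20L)
    expect_lte(st$global_best_value, prev_best)
    prev_best <- st$global_best_value
    expect_within_bounds(st$positions, spec$bounds)
    expect_within_bounds(st$pbest, spec$bounds)
  }
  # personal bests cache their own objective value
  expect_equal(st$pbest_value,
               apply(st$pbest, 1, spec$evaluate))
})

test_that("repeated iterations beat random search on the sphere", {
  spec <- sphere_spec(1, lo = -10, hi = 10)
  set.seed(21)
  led <- eval_ledger(500)
  sw <- swarm_settings(np = 8, k = 2)
  st <- initialize_swarm(spec, sw, led)
  init_best <- st$global_best_value
  while (led$budget - led$consumed >= 8) {
    st <- swarm_iteration(st, spec, sw, led)
  }
  expect_lt(st$global_best_value, init_best)
  # random search at the identical budget, same generator
  set.seed(21)
  rand_best <- min(vapply(seq_len(led$consumed),
                          function(i) spec$evaluate(runif(1, -10, 10)),
                          numeric(1)))
  expect_lt(st$global_best_value, rand_best)
})

test_that("regrouping permutes membership without touching memories", {
  spec <- sphere_spec(4)
  set.seed(13)
  led <- eval_ledger(200)
  sw <- swarm_settings(np = 12, k = 3)
  st <- initialize_swarm(spec, sw, led)
  st <- swarm_iteration(st, spec, sw, led)
  before_pb <- sort(st$pbest_value)
  before_gb <- st$global_best_value
  set.seed(99)
  st2 <- regroup(st)
  expect_equal(sort(st2$pbest_value), before_pb)
  expect_equal(st2$global_best_value, before_gb)
  expect_equal(as.integer(table(st2$assignment)), rep(4L, 3))
  set.seed(99)
  st3 <- regroup(st)
  expect_identical(st2$assignment, st3$assignment)
})

test_that("stagnation needs a full quiet window", {
  expect_true(detect_stagnation(c(100, 99.9, 99.85, 99.84, 99.84),
                                tolerance = 0.01, limit = 4))
  expect_false(detect_stagnation(c(100, 50, 25, 12, 6),
                                 tolerance = 0.01, limit = 4))
  expect_false(detect_stagnation(c(100, 100, 100), limit = 4))
  # slow but steady cumulative improvement is not stagnation
  expect_false(detect_stagnation(c(100, 99.4, 98.8, 98.2, 97.6),
                                 tolerance = 0.01, limit = 4))
  # flat at zero counts as stagnant
  expect_true(detect_stagnation(c(0, 0, 0, 0, 0), limit = 4))
})

test_that("one sub-swarm reduces to single-swarm search", {
  spec <- sphere_spec(3)
  set.seed(44)
  led <- eval_ledger(300)
  sw <- swarm_settings(np = 10, k = 1)
  st <- initialize_swarm(spec, sw, led)
  expect_equal(as.integer(table(st$assignment)), 10L)
  # the sub-swarm best IS the global best at all times
  for (i in 1:5) {
    st <- swarm_iteration(st, spec, sw, led)
    expect_equal(st$swarm_best_value, st$global_best_value)
  }
})
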