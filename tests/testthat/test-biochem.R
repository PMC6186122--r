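test_that("simulation honours initial conditions and degenerate kinetics", {
  m <- demo_cascade_model()
  times <- seq(0, 5, length.out = 11)
  out <- simulate_model(m, times = times)
  expect_equal(unname(out[1, ]), unname(m$initial_state))
  # all rate constants zero: nothing moves
  frozen <- simulate_model(m, p = rep(0, 8), times = times)
  expect_equal(frozen, matrix(rep(m$initial_state, each = 11), nrow = 11,
                              dimnames = dimnames(frozen)),
               tolerance = 1e-10)
  # trajectories stay non-negative under mass action
  expect_true(all(out >= -1e-8))
})

test_that("single first-order decay matches the analytic exponential", {
  decay <- mass_action_model(
    species = c("A", "B"),
    reactions = list(list(reactants = c(A = 1), products = c(B = 1))),
    rate_constants = c(k = 0.7),
    initial_state = c(A = 2, B = 0)
  )
  times <- seq(0, 4, length.out = 21)
  out <- simulate_model(decay, times = times)
  expect_equal(out[, "A"], 2 * exp(-0.7 * times), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(out[, "B"], 2 - 2 * exp(-0.7 * times), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("the error objective is an exact sum of squared residuals", {
  m <- demo_cascade_model()
  ds <- demo_datasets(m)
  spec <- sse_objective(m, ds)
  # noiseless data: the generating parameters give exactly zero error
  expect_equal(spec$evaluate(m$rate_constants), 0, tolerance = 1e-10)
  # hand-built residual: perturb one measurement by 2 -> SSE contribution 4
  ds2 <- ds
  ds2[[1]]$measurements[3, 1] <- ds2[[1]]$measurements[3, 1] + 2
  spec2 <- sse_objective(m, ds2)
  expect_equal(spec2$evaluate(m$rate_constants), 4, tolerance = 1e-6)
  # closed-form cross-check on the analytic decay model
  decay <- mass_action_model(
    species = c("A", "B"),
    reactions = list(list(reactants = c(A = 1), products = c(B = 1))),
    rate_constants = c(k = 0.5),
    initial_state = c(A = 1, B = 0)
  )
  tt <- c(0, 1)
  d <- generate_synthetic_data(decay, times = tt, observed_species = "A")
  d$measurements[, 1] <- c(1, 0.5)  # truth is exp(-0.5) = 0.6065
  s <- sse_objective(decay, d, bounds = bounds_box(0.1, 2))
  expect_equal(s$evaluate(0.5), (exp(-0.5) - 0.5)^2, tolerance = 1e-4)
})

test_that("synthetic noise has the advertised second moment", {
  m <- demo_cascade_model()
  times <- seq(0, 10, length.out = 20)
  sd0 <- 0.05
  set.seed(1234)
  sses <- vapply(1:200, function(i) {
    d <- generate_synthetic_data(m, times = times,
                                 observed_species = c("Xa", "Ya"),
                                 noise_sd = sd0)
    spec <- sse_objective(m, d)
    spec$evaluate(m$rate_constants)
  }, numeric(1))
  n_resid <- 20 * 2
  # chi-square expectation: E[SSE at truth] = n * sd^2
  expect_equal(mean(sses), n_resid * sd0^2, tolerance = 0.1)
  d <- generate_synthetic_data(m, times = times,
                               observed_species = c("Xa", "Ya"),
                               noise_sd = sd0)
  expect_equal(dim(d$measurements), c(20L, 2L))
})

test_that("every rate constant leaves a fingerprint on the observables", {
  m <- demo_cascade_model()
  ds <- demo_datasets(m)
  sens <- parameter_sensitivities(m, ds)
  expect_length(sens, 8)
  expect_true(all(sens > 0))
})

test_that("failed integrations become a large finite sentinel, not an abort", {
  m <- demo_cascade_model()
  ds <- demo_datasets(m)
  spec <- sse_objective(m, ds)
  ok <- spec$evaluate(m$rate_constants * 2)   # prime the cache
  expect_true(is.finite(ok))
  # absurd rate constants blow up the integrator; value must stay finite
  bad <- spec$evaluate(rep(1e12, 8))
  expect_true(is.finite(bad))
  expect_gt(bad, ok)
})

test_that("model JSON and dataset CSV round-trip faithfully", {
  m <- demo_cascade_model()
  f1 <- tempfile(fileext = ".json")
  write_model_json(m, f1)
  m2 <- read_model_json(f1)
  expect_equal(m2$rate_constants, m$rate_constants, ignore_attr = TRUE)
  expect_equal(m2$initial_state, m$initial_state)
  expect_equal(m2$net, m$net)
  set.seed(77)
  d <- generate_synthetic_data(m, times = seq(0, 10, length.out = 20),
                               observed_species = c("Xa", "Ya"),
                               noise_sd = 0.1)
  f2 <- tempfile(fileext = ".csv")
  write_dataset_csv(d, m, f2)
  back <- read_dataset_csv(f2)
  expect_identical(back$time, d$times)
  expect_identical(back$Xa, unname(d$measurements[, 1]))
  expect_identical(back$Ya, unname(d$measurements[, 2]))
})

test_that("the recovery report has one scored row per trial", {
  cfg <- dops_config(total_budget = 400,
                     swarm = swarm_settings(np = 20, k = 4))
  rep <- recovery_experiment(config = cfg, trials = 2, base_seed = 42)
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$final_sse <= rep$initial_best))
  expect_true(all(rep$scaled_error >= 0 & rep$scaled_error <= 1))
  expect_true(all(is.finite(rep$param_rel_error)))
  expect_equal(rep$seed, c(42L, 43L))
})
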