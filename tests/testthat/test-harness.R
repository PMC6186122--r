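batch_cfg <- dops_config(total_budget = 200,
                         swarm = swarm_settings(np = 20, k = 4))

test_that("batches are seeded deterministically and trial-wise distinct", {
  spec <- make_test_objective("rastrigin", 3)
  b1 <- run_batch("dops", spec, batch_cfg, trials = 4, base_seed = 50)
  b2 <- run_batch("dops", spec, batch_cfg, trials = 4, base_seed = 50)
  expect_equal(length(b1$results), 4L)
  expect_false(any(duplicated(b1$seeds)))
  for (t in 1:4) {
    expect_identical(b1$results[[t]]$trace, b2$results[[t]]$trace)
  }
  # a single trial reduces to one plain run
  single <- run_batch("dops", spec, batch_cfg, trials = 1, base_seed = 50)
  cfg1 <- batch_cfg
  cfg1$seed <- 50L
  expect_identical(single$results[[1]]$trace, run_dops(spec, cfg1)$trace)
})

test_that("trial failures are recorded rather than dropped", {
  flaky <- objective_spec(function(x) {
    if (x[1] > 0.99) stop("bad region") else sum(x^2)
  }, bounds_box(c(-1, -1), c(1, 1)), "flaky")
  b <- run_batch("dds", flaky, batch_cfg, trials = 6, base_seed = 1)
  n_ok <- sum(!vapply(b$results, is.null, logical(1)))
  n_err <- sum(!is.na(b$errors))
  expect_equal(n_ok + n_err, 6L)
})

test_that("aggregated curves are monotone, pinned at 1, ordered by trial count", {
  spec <- make_test_objective("ackley", 4)
  b <- run_batch("dops", spec, batch_cfg, trials = 5, base_seed = 9)
  curve <- aggregate_convergence(b)
  expect_equal(nrow(curve), 200L)
  np <- batch_cfg$swarm$np
  expect_true(all(curve$mean_scaled_error[seq_len(np)] == 1))
  expect_true(all(diff(curve$mean_scaled_error) <= 1e-12))
  expect_true(all(curve$sd_scaled_error >= 0))
  # identical trials have a zero-sd curve
  b1 <- run_batch("dops", spec, batch_cfg, trials = 1, base_seed = 3)
  b1$results <- rep(b1$results, 3)
  b1$trials <- 3L
  curve1 <- aggregate_convergence(b1)
  expect_true(all(curve1$sd_scaled_error == 0))
})

test_that("trace CSV and result JSON survive a round trip", {
  spec <- sphere_spec(2)
  cfg <- batch_cfg
  cfg$seed <- 4L
  res <- run_dops(spec, cfg)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(res, f)
  back <- read_trace_csv(f)
  expect_equal(back$best_value, res$trace)
  expect_equal(back$evaluation_index, seq_along(res$trace))

  fj <- tempfile(fileext = ".json")
  write_result_json(res, fj)
  payload <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(payload$best_value, res$best_value, tolerance = 1e-12)
  expect_equal(unlist(payload$best_vector), unname(res$best_vector),
               tolerance = 1e-12)
  expect_equal(payload$seed, res$seed)
})

test_that("config files define runs in either YAML or JSON", {
  fy <- tempfile(fileext = ".yaml")
  writeLines(c(
    "total_budget: 500",
    "seed: 12",
    "swarm:",
    "  np: 10",
    "  k: 2",
    "dds:",
    "  r: 0.3"
  ), fy)
  cfg <- read_dops_config(fy)
  expect_equal(cfg$total_budget, 500L)
  expect_equal(cfg$swarm$np, 10L)
  expect_equal(cfg$dds$r, 0.3)

  fj <- tempfile(fileext = ".json")
  writeLines('{"total_budget": 300, "seed": 2, "swarm": {"np": 20, "k": 5}}',
             fj)
  cfg2 <- read_dops_config(fj)
  expect_equal(cfg2$total_budget, 300L)
  expect_equal(cfg2$swarm$k, 5L)
  # defaults fill the unstated fields
  expect_equal(cfg2$dds$r, 0.2)
})

test_that("tidiers expose runs and batches as tibbles", {
  spec <- sphere_spec(2)
  cfg <- batch_cfg
  cfg$seed <- 6L
  res <- run_dops(spec, cfg)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), res$evaluations)
  expect_true(all(td$phase %in% c("swarm", "dds")))
  gl <- glance(res)
  expect_equal(gl$best_value, res$best_value)

  b <- run_batch("dops", spec, batch_cfg, trials = 3, base_seed = 2)
  tb <- tidy(b)
  expect_equal(nrow(tb), 3L)
  gb <- glance(b)
  expect_equal(gb$completed, 3L)
  expect_true(gb$mean_scaled_final_error >= 0)

  p1 <- autoplot(res)
  p2 <- autoplot(b)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
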