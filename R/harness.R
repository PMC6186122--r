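#' Run a batch of independent seeded trials
#'
#' Performance claims are averages over repeated trials: each trial runs the
#' chosen variant with its own seed derived from `base_seed` (trial t uses
#' `base_seed + t - 1`), so trials are reproducible individually and in
#' aggregate. Failing trials are recorded with their error message, never
#' silently dropped.
#'
#' @param variant One of `"dops"`, `"msdops"`, `"mspso"`, `"dds"`.
#' @param spec An [objective_spec()].
#' @param config A [dops_config()]; its `seed` field is overridden per trial.
#' @param trials Number of independent trials T (default 25).
#' @param base_seed Integer from which per-trial seeds are derived.
#'
#' @return An object of class `trial_batch`: the per-trial results, any
#'   trial errors, and the batch metadata.
#' @examples
#' spec <- make_test_objective("rastrigin", 2)
#' b <- run_batch("dops", spec, dops_config(total_budget = 200),
#'                trials = 3, base_seed = 11)
#' glance(b)
#' @export
run_batch <- function(variant, spec, config = dops_config(),
                      trials = 25L, base_seed = 1L) {
  trials <- as.integer(trials)
  if (trials < 1L) stop("`trials` must be at least 1", call. = FALSE)
  seeds <- as.integer(base_seed) + seq_len(trials) - 1L
  results <- vector("list", trials)
  errors <- rep(NA_character_, trials)
  for (t in seq_len(trials)) {
    cfg <- config
    cfg$seed <- seeds[t]
    results[[t]] <- tryCatch(
      run_variant(variant, spec, cfg),
      error = function(e) {
        errors[t] <<- conditionMessage(e)
        NULL
      }
    )
  }
  structure(
    list(variant = variant, objective = spec$name,
         dimension = spec$bounds$dimension, trials = trials,
         base_seed = as.integer(base_seed), seeds = seeds,
         results = results, errors = errors),
    class = "trial_batch"
  )
}

#' @export
print.trial_batch <- function(x, ...) {
  ok <- sum(!vapply(x$results, is.null, logical(1)))
  cat("<trial_batch>", x$variant, "on", x$objective, "-",
      ok, "of", x$trials, "trials completed\n")
  fin <- batch_final_scaled_errors(x)
  if (length(fin)) {
    cat("  mean scaled final error:", format(mean(fin)),
        " sd:", format(sd(fin)), "\n")
  }
  invisible(x)
}

batch_final_scaled_errors <- function(batch) {
  vapply(Filter(Negate(is.null), batch$results), scaled_final_error,
         numeric(1))
}

# per-trial scaled trace on the full evaluation grid; evaluations up to the
# scaling baseline (the initialization block) are pinned at 1.0
scaled_trace_on_grid <- function(result) {
  s <- result$trace / result$trace[result$baseline_eval]
  s[seq_len(result$baseline_eval)] <- 1
  s
}

#' Aggregate convergence curves over a batch
#'
#' Scales every trial's best-so-far trace by that trial's initial best, pins
#' the initialization block at 1.0, aligns the step-function traces on the
#' common evaluation grid 1..N (best-so-far traces carry the last
#' observation forward by construction), and returns the pointwise mean and
#' standard deviation.
#'
#' @param batch A [run_batch()] result.
#'
#' @return A tibble with columns `evaluation`, `mean_scaled_error`,
#'   `sd_scaled_error`, and `n_trials`.
#' @export
aggregate_convergence <- function(batch) {
  stopifnot(inherits(batch, "trial_batch"))
  ok <- Filter(Negate(is.null), batch$results)
  if (length(ok) == 0L) stop("no completed trials in the batch", call. = FALSE)
  mat <- vapply(ok, scaled_trace_on_grid, numeric(length(ok[[1]]$trace)))
  tibble::tibble(
    evaluation = seq_len(nrow(mat)),
    mean_scaled_error = rowMeans(mat),
    sd_scaled_error = apply(mat, 1, sd),
    n_trials = length(ok)
  )
}

#' Export a single run's trace as a tidy table or CSV
#'
#' @param result A `dops_result`.
#' @param path Optional file path; when given the table is also written as
#'   CSV with columns `evaluation_index`, `best_value`,
#'   `scaled_best_value`.
#'
#' @return (Invisibly, when writing) the tibble of the trace.
#' @export
write_trace_csv <- function(result, path = NULL) {
  stopifnot(inherits(result, "dops_result"))
  tab <- tibble::tibble(
    evaluation_index = seq_along(result$trace),
    best_value = result$trace,
    scaled_best_value = scaled_trace_on_grid(result)
  )
  if (!is.null(path)) {
    write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' @param path File path.
#' @return A tibble with the trace columns.
#' @export
read_trace_csv <- function(path) {
  tibble::as_tibble(read.csv(path))
}

#' Write a run summary as JSON
#'
#' Serializes the best vector, best value, phase log, variant, objective
#' and seed of a run. Numbers are written at full precision.
#'
#' @param result A `dops_result`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "dops_result"))
  payload <- list(
    variant = result$variant,
    objective = result$objective,
    dimension = result$dimension,
    seed = result$seed,
    evaluations = result$evaluations,
    best_value = result$best_value,
    best_vector = result$best_vector,
    phase_log = result$phase_log
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an optimizer configuration from a YAML or JSON file
#'
#' The file may define any subset of the fields of [dops_config()],
#' [swarm_settings()] (under `swarm`) and [dds_settings()] (under `dds`);
#' missing fields keep the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [dops_config()].
#' @export
read_dops_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sw_args <- raw$swarm %||% list()
  dds_args <- raw$dds %||% list()
  top <- raw[setdiff(names(raw), c("swarm", "dds"))]
  args <- c(top, list(swarm = do.call(swarm_settings, sw_args),
                      dds = do.call(dds_settings, dds_args)))
  do.call(dops_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
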