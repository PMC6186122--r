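#' Configuration for a budgeted hybrid optimization run
#'
#' Collects every tunable of the optimizer in one object. The defaults are
#' the study settings used throughout the package: a budget of 4000
#' evaluations, 40 particles in 5 sub-swarms, inertia schedule 0.9 to 0.4,
#' attraction coefficients 1.5, regrouping every 10 swarm iterations,
#' stagnation at four consecutive iterations with under 1% relative
#' improvement, perturbation size R = 0.2, and a 90% switch-back ratio for
#' the multi-switch variant.
#'
#' @param total_budget Total objective evaluations N (default 4000).
#' @param swarm A [swarm_settings()].
#' @param dds A [dds_settings()].
#' @param phase1_cap Maximum fraction of the (remaining) budget a swarm
#'   phase may consume before the switch is forced. The default of 1 leaves
#'   the swarm phase bounded only by stagnation and the budget, matching
#'   the adaptive switching rule; set it below 1 to guarantee the
#'   refinement phase a budget share even on problems where the swarm
#'   never stagnates.
#' @param multiswitch Logical: allow switching back from refinement to a
#'   fresh swarm phase (default `FALSE`).
#' @param switchback_ratio The multi-switch variant returns to a swarm phase
#'   once the refinement phase has reduced the objective to this fraction of
#'   its phase-entry value (default 0.9). A ratio of 0 makes the threshold
#'   unreachable.
#' @param seed Integer seed; every run is fully reproducible given the seed.
#'
#' @return An object of class `dops_config`.
#' @examples
#' cfg <- dops_config(total_budget = 1000, seed = 42)
#' @export
dops_config <- function(total_budget = 4000L,
                        swarm = swarm_settings(),
                        dds = dds_settings(),
                        phase1_cap = 1,
                        multiswitch = FALSE,
                        switchback_ratio = 0.9,
                        seed = 1L) {
  total_budget <- as.integer(total_budget)
  stopifnot(inherits(swarm, "swarm_settings"), inherits(dds, "dds_settings"))
  if (total_budget < swarm$np) {
    stop("`total_budget` must cover at least one swarm initialization (np)",
         call. = FALSE)
  }
  if (phase1_cap <= 0 || phase1_cap > 1) {
    stop("`phase1_cap` must lie in (0, 1]", call. = FALSE)
  }
  if (switchback_ratio < 0 || switchback_ratio >= 1) {
    stop("`switchback_ratio` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(total_budget = total_budget, swarm = swarm, dds = dds,
         phase1_cap = phase1_cap, multiswitch = isTRUE(multiswitch),
         switchback_ratio = switchback_ratio, seed = as.integer(seed)),
    class = "dops_config"
  )
}

new_dops_result <- function(best_vector, best_value, ledger, phase_log,
                            config, variant, spec, baseline_eval) {
  structure(
    list(
      best_vector = best_vector,
      best_value = best_value,
      trace = ledger$trace[seq_len(ledger$consumed)],
      evaluations = ledger$consumed,
      phase_log = dplyr::bind_rows(phase_log),
      seed = config$seed,
      variant = variant,
      objective = spec$name,
      dimension = spec$bounds$dimension,
      baseline_eval = as.integer(baseline_eval),
      config = config
    ),
    class = "dops_result"
  )
}

#' @export
print.dops_result <- function(x, ...) {
  cat("<dops_result>", x$variant, "on", x$objective, "\n")
  cat("  evaluations:", x$evaluations,
      " best value:", format(x$best_value), "\n")
  cat("  scaled final error:", format(scaled_final_error(x)),
      " phases:", nrow(x$phase_log), " seed:", x$seed, "\n")
  invisible(x)
}

#' Final scaled error of a run
#'
#' The best objective value at the end of the budget divided by the trial's
#' initial best (the best value among the randomly initialized particles;
#' for the single-solution baseline, the value of the random starting
#' point).
#'
#' @param result A `dops_result`.
#' @return Scalar scaled error.
#' @export
scaled_final_error <- function(result) {
  stopifnot(inherits(result, "dops_result"))
  baseline <- result$trace[result$baseline_eval]
  if (!is.finite(baseline) || baseline <= 0) return(NA_real_)
  result$trace[length(result$trace)] / baseline
}

# one swarm phase: initialization (unless state supplied), iterations with
# periodic regrouping, stopping on stagnation, the phase cap, or budget.
run_swarm_phase <- function(spec, config, ledger, cap_evals,
                            seed_particle = NULL, seed_value = NULL) {
  sw <- config$swarm
  state <- initialize_swarm(spec, sw, ledger, seed_particle, seed_value)
  history <- state$global_best_value
  iters_this_phase <- 0L
  repeat {
    if (detect_stagnation(history, sw$stagnation_tolerance,
                          sw$stagnation_limit)) {
      stagnated <- TRUE
      break
    }
    if (ledger$consumed + sw$np > cap_evals ||
        ledger_remaining(ledger) < sw$np) {
      stagnated <- FALSE
      break
    }
    state <- swarm_iteration(state, spec, sw, ledger)
    iters_this_phase <- iters_this_phase + 1L
    if (iters_this_phase %% sw$regroup_interval == 0L) {
      state <- regroup(state)
    }
    history <- c(history, state$global_best_value)
  }
  list(state = state, history = history, stagnated = stagnated)
}

# one refinement phase: up to n_dds greedy steps; optionally stop early when
# the incumbent reaches switchback_value (multi-switch), provided at least
# min_remaining evaluations would be left for a new swarm phase.
run_dds_phase <- function(spec, config, ledger, incumbent, incumbent_value,
                          switchback_value = NULL, min_remaining = 0L) {
  n_dds <- ledger_remaining(ledger)
  state <- list(incumbent = incumbent, incumbent_value = incumbent_value,
                iteration = 1L, n_dds = n_dds)
  switched <- FALSE
  while (ledger_remaining(ledger) > 0L && state$iteration <= n_dds) {
    state <- dds_step(state, spec, ledger, config$dds)
    if (!is.null(switchback_value) &&
        state$incumbent_value <= switchback_value &&
        ledger_remaining(ledger) >= min_remaining) {
      switched <- TRUE
      break
    }
  }
  list(state = state, switched = switched)
}

phase_row <- function(phase, start_eval, end_eval) {
  tibble::tibble(phase = phase, start_eval = as.integer(start_eval),
                 end_eval = as.integer(end_eval))
}

#' Run the hybrid swarm-then-refinement optimizer
#'
#' The full method: a velocity-free multi-swarm particle swarm phase runs
#' from random initialization until the global best stagnates (or the phase
#' cap is hit), then the remaining budget is spent on greedy dynamically
#' dimensioned search started from the overall best particle. The run
#' consumes exactly `config$total_budget` objective evaluations.
#'
#' @param spec An [objective_spec()].
#' @param config A [dops_config()].
#'
#' @return A `dops_result` with the best vector and value, the best-so-far
#'   trace, a phase log, and the seed.
#' @examples
#' spec <- make_test_objective("rastrigin", 2)
#' res <- run_dops(spec, dops_config(total_budget = 400, seed = 7))
#' res$best_value
#' @export
run_dops <- function(spec, config = dops_config()) {
  stopifnot(inherits(spec, "objective_spec"), inherits(config, "dops_config"))
  set.seed(config$seed)
  ledger <- eval_ledger(config$total_budget)
  cap <- config$phase1_cap * config$total_budget
  phase_log <- list()

  sw <- run_swarm_phase(spec, config, ledger, cap_evals = cap)
  phase_log[[1]] <- phase_row("swarm", 1L, ledger$consumed)

  dds_start <- ledger$consumed + 1L
  dd <- run_dds_phase(spec, config, ledger,
                      incumbent = sw$state$global_best,
                      incumbent_value = sw$state$global_best_value)
  if (ledger$consumed >= dds_start) {
    phase_log[[2]] <- phase_row("dds", dds_start, ledger$consumed)
  }

  new_dops_result(dd$state$incumbent, dd$state$incumbent_value, ledger,
                  phase_log, config, "dops", spec, config$swarm$np)
}

#' Run the multi-switch variant
#'
#' Identical to [run_dops()] except that each refinement phase records its
#' entry value and, once the incumbent falls to
#' `switchback_ratio` times that value (default 90%), control returns to a
#' fresh swarm phase seeded with the incumbent (particle 1 set to it with
#' its cached value; the other particles re-drawn uniformly). If no
#' refinement phase ever meets the ratio, the trace is identical to
#' [run_dops()] at the same seed. Switch-back applies only to
#' positive-valued objectives, where "reduced to 90% of the entry value" is
#' well defined.
#'
#' @inheritParams run_dops
#' @return A `dops_result`.
#' @export
run_msdops <- function(spec, config = dops_config(multiswitch = TRUE)) {
  stopifnot(inherits(spec, "objective_spec"), inherits(config, "dops_config"))
  set.seed(config$seed)
  np <- config$swarm$np
  ledger <- eval_ledger(config$total_budget)
  phase_log <- list()
  seed_particle <- NULL
  seed_value <- NULL
  best <- NULL
  best_value <- Inf

  repeat {
    # swarm phase, capped at half the budget remaining at entry
    entry <- ledger$consumed
    cap <- entry + config$phase1_cap * (config$total_budget - entry)
    sw <- run_swarm_phase(spec, config, ledger, cap_evals = cap,
                          seed_particle = seed_particle,
                          seed_value = seed_value)
    phase_log[[length(phase_log) + 1L]] <-
      phase_row("swarm", entry + 1L, ledger$consumed)
    best <- sw$state$global_best
    best_value <- sw$state$global_best_value
    if (ledger_remaining(ledger) == 0L) break

    # refinement phase with the 90% switch-back rule
    entry <- ledger$consumed
    entry_value <- best_value
    switchback <- if (config$switchback_ratio > 0 && entry_value > 0) {
      config$switchback_ratio * entry_value
    } else {
      NULL  # unreachable threshold: behave exactly like run_dops
    }
    dd <- run_dds_phase(spec, config, ledger, best, best_value,
                        switchback_value = switchback,
                        min_remaining = np + 1L)
    phase_log[[length(phase_log) + 1L]] <-
      phase_row("dds", entry + 1L, ledger$consumed)
    best <- dd$state$incumbent
    best_value <- dd$state$incumbent_value
    if (!dd$switched || ledger_remaining(ledger) == 0L) break
    seed_particle <- best
    seed_value <- best_value
  }

  new_dops_result(best, best_value, ledger, phase_log, config,
                  "msdops", spec, np)
}

#' Run the multi-swarm particle swarm baseline (no refinement phase)
#'
#' Ablation baseline: the swarm phase runs for the entire budget with
#' periodic regrouping and no phase switch. When the budget is not a
#' multiple of the particle count, a final partial sweep over the first
#' remaining particles lands the run exactly on the budget.
#'
#' @inheritParams run_dops
#' @return A `dops_result` whose phase log has a single swarm phase.
#' @export
run_mspso_only <- function(spec, config = dops_config()) {
  stopifnot(inherits(spec, "objective_spec"), inherits(config, "dops_config"))
  set.seed(config$seed)
  sw <- config$swarm
  ledger <- eval_ledger(config$total_budget)
  state <- initialize_swarm(spec, sw, ledger)
  iters <- 0L
  while (ledger_remaining(ledger) >= sw$np) {
    state <- swarm_iteration(state, spec, sw, ledger)
    iters <- iters + 1L
    if (iters %% sw$regroup_interval == 0L) state <- regroup(state)
  }
  leftover <- ledger_remaining(ledger)
  if (leftover > 0L) {
    state <- swarm_iteration(state, spec, sw, ledger, n_update = leftover)
  }
  new_dops_result(state$global_best, state$global_best_value, ledger,
                  list(phase_row("swarm", 1L, ledger$consumed)),
                  config, "mspso", spec, sw$np)
}

#' Run the dynamically dimensioned search baseline
#'
#' Ablation baseline: greedy dynamically dimensioned search from a single
#' uniformly random starting point, for the full budget, with no swarm
#' phase.
#'
#' @inheritParams run_dops
#' @return A `dops_result`; its scaled-error baseline is the starting
#'   point's value (evaluation 1).
#' @export
run_dds_only <- function(spec, config = dops_config()) {
  stopifnot(inherits(spec, "objective_spec"), inherits(config, "dops_config"))
  set.seed(config$seed)
  ledger <- eval_ledger(config$total_budget)
  x0 <- drop(runif_box(1L, spec$bounds))
  v0 <- evaluate_with_budget(spec, x0, ledger)
  dd <- run_dds_phase(spec, config, ledger, x0, v0)
  new_dops_result(dd$state$incumbent, dd$state$incumbent_value, ledger,
                  list(phase_row("dds", 1L, ledger$consumed)),
                  config, "dds", spec, 1L)
}

#' Dispatch an optimizer variant by name
#'
#' @param variant One of `"dops"`, `"msdops"`, `"mspso"`, `"dds"`.
#' @inheritParams run_dops
#' @return A `dops_result`.
#' @export
run_variant <- function(variant = c("dops", "msdops", "mspso", "dds"),
                        spec, config = dops_config()) {
  variant <- match.arg(variant)
  switch(variant,
    dops   = run_dops(spec, config),
    msdops = run_msdops(spec, config),
    mspso  = run_mspso_only(spec, config),
    dds    = run_dds_only(spec, config)
  )
}
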