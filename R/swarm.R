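#' Settings for the multi-swarm particle swarm phase
#'
#' @param np Total number of particles NP (default 40).
#' @param k Number of sub-swarms; `np` must be divisible by `k` (default 5).
#' @param w_max,w_min Maximum and minimum inertia weights for the linearly
#'   decreasing position-inertia schedule (defaults 0.9 and 0.4).
#' @param theta2,theta3 Attraction coefficients toward the personal best and
#'   the sub-swarm best (defaults 1.5 and 1.5).
#' @param regroup_interval Sub-swarm membership is reshuffled every this many
#'   swarm iterations (default 10).
#' @param stagnation_tolerance Relative improvement of the global best below
#'   which an iteration counts as stagnant (default 0.01, i.e. 1%).
#' @param stagnation_limit Number of consecutive stagnant iterations that
#'   triggers the phase switch (default 4).
#'
#' @return An object of class `swarm_settings`.
#' @export
swarm_settings <- function(np = 40L, k = 5L, w_max = 0.9, w_min = 0.4,
                           theta2 = 1.5, theta3 = 1.5,
                           regroup_interval = 10L,
                           stagnation_tolerance = 0.01,
                           stagnation_limit = 4L) {
  np <- as.integer(np); k <- as.integer(k)
  if (np < 1L || k < 1L || np %% k != 0L) {
    stop("`np` must be a positive multiple of `k`", call. = FALSE)
  }
  if (!(0 < w_min && w_min < w_max)) {
    stop("need 0 < w_min < w_max", call. = FALSE)
  }
  if (theta2 <= 0 || theta3 <= 0) {
    stop("`theta2` and `theta3` must be positive", call. = FALSE)
  }
  structure(
    list(np = np, k = k, w_max = w_max, w_min = w_min,
         theta2 = theta2, theta3 = theta3,
         regroup_interval = as.integer(regroup_interval),
         stagnation_tolerance = stagnation_tolerance,
         stagnation_limit = as.integer(stagnation_limit)),
    class = "swarm_settings"
  )
}

#' Linearly decreasing inertia weight
#'
#' The coefficient on a particle's current position decays linearly with the
#' evaluation counter, from `w_max` at the first evaluation to `w_min` at
#' the last, so the swarm moves from exploration to contraction over the
#' budget: `(N - j) * (w_max - w_min) / (N - 1) + w_min`.
#'
#' @param j Current evaluation index, `1 <= j <= n_total`.
#' @param n_total Total evaluation budget N (must be >= 2).
#' @param w_max,w_min Endpoints of the schedule.
#'
#' @return Scalar weight in `[w_min, w_max]`.
#' @examples
#' inertia_weight(1, 4000)    # 0.9
#' inertia_weight(4000, 4000) # 0.4
#' @export
inertia_weight <- function(j, n_total, w_max = 0.9, w_min = 0.4) {
  if (n_total < 2) stop("`n_total` must be at least 2", call. = FALSE)
  (n_total - j) * (w_max - w_min) / (n_total - 1) + w_min
}

#' Velocity-free particle position update
#'
#' Proposes a new position from the current one without a velocity term:
#' `theta1 * z + theta2 * r1 * (L - z) + theta3 * r2 * (G - z)`, where `L`
#' is the particle's personal best, `G` the best of its sub-swarm, and
#' `r1`, `r2` fresh elementwise uniform(0, 1) vectors. The caller reflects
#' the proposal into bounds and evaluates it. Note the rule has no velocity
#' memory: at consensus (`z = L = G`) the expected update contracts the
#' position by `theta1`.
#'
#' @param position Current position `z`.
#' @param personal_best Personal best `L`.
#' @param swarm_best Sub-swarm best `G`.
#' @param theta1 Inertia weight for this iteration (see [inertia_weight()]).
#' @param theta2,theta3 Attraction coefficients.
#'
#' @return Proposed (unreflected, unevaluated) position vector.
#' @export
update_particle <- function(position, personal_best, swarm_best,
                            theta1, theta2 = 1.5, theta3 = 1.5) {
  kk <- length(position)
  if (length(personal_best) != kk || length(swarm_best) != kk) {
    stop("dimension mismatch among position, personal best and swarm best",
         call. = FALSE)
  }
  r1 <- runif(kk)
  r2 <- runif(kk)
  theta1 * position +
    theta2 * r1 * (personal_best - position) +
    theta3 * r2 * (swarm_best - position)
}

# random equal partition of np particles into k sub-swarms
random_assignment <- function(np, k) {
  sample(rep.int(seq_len(k), np / k))
}

# recompute per-sub-swarm bests and the global best from personal bests
refresh_bests <- function(state) {
  k <- state$settings$k
  best_idx <- integer(k)
  for (s in seq_len(k)) {
    members <- which(state$assignment == s)
    best_idx[s] <- members[which.min(state$pbest_value[members])]
  }
  state$swarm_best <- state$pbest[best_idx, , drop = FALSE]
  state$swarm_best_value <- state$pbest_value[best_idx]
  g <- which.min(state$swarm_best_value)
  cand_val <- state$swarm_best_value[g]
  if (is.null(state$global_best_value) || cand_val < state$global_best_value) {
    state$global_best <- state$swarm_best[g, ]
    state$global_best_value <- cand_val
  }
  state
}

#' Initialize the multi-swarm state
#'
#' Draws `np` positions uniformly inside the box (one objective evaluation
#' each), partitions them uniformly at random into `k` equal sub-swarms, and
#' populates personal, sub-swarm and global bests.
#'
#' @param spec An [objective_spec()].
#' @param settings A [swarm_settings()].
#' @param ledger An [eval_ledger()] with at least `np` evaluations remaining
#'   (or `np - 1` when a seed particle with a cached value is supplied).
#' @param seed_particle Optional numeric vector used as particle 1's position
#'   (the multi-switch variant re-seeds the swarm with the search incumbent).
#' @param seed_value Cached objective value of `seed_particle`; when given,
#'   the seed particle is not re-evaluated.
#'
#' @return A list of class `swarm_state` with the particle matrix, personal
#'   bests, sub-swarm assignment, bests and the iteration counter.
#' @export
initialize_swarm <- function(spec, settings, ledger,
                             seed_particle = NULL, seed_value = NULL) {
  np <- settings$np
  kdim <- spec$bounds$dimension
  need <- if (!is.null(seed_particle) && !is.null(seed_value)) np - 1L else np
  if (ledger_remaining(ledger) < need) {
    stop("insufficient budget to initialize the swarm", call. = FALSE)
  }
  positions <- runif_box(np, spec$bounds)
  values <- numeric(np)
  start <- 1L
  if (!is.null(seed_particle)) {
    positions[1L, ] <- seed_particle
    if (!is.null(seed_value)) {
      values[1L] <- seed_value
      start <- 2L
    }
  }
  for (i in seq.int(start, np)) {
    values[i] <- evaluate_with_budget(spec, positions[i, ], ledger)
  }
  state <- list(
    positions = positions,
    pbest = positions,
    pbest_value = values,
    assignment = random_assignment(np, settings$k),
    iteration = 0L,
    settings = settings,
    global_best = NULL,
    global_best_value = NULL
  )
  class(state) <- "swarm_state"
  refresh_bests(state)
}

#' Advance the swarm by one iteration
#'
#' Each particle proposes a move under the velocity-free update rule, the
#' proposal is reflected into bounds and evaluated (one ledger evaluation
#' per particle), and personal bests are replaced only on strict
#' improvement. Sub-swarm and global bests are refreshed after the sweep.
#'
#' @inheritParams initialize_swarm
#' @param state A `swarm_state` from [initialize_swarm()].
#' @param n_update Number of particles to update this sweep (defaults to all
#'   `np`; the multi-swarm-only baseline uses a final partial sweep to land
#'   exactly on the budget).
#'
#' @return The updated `swarm_state`.
#' @export
swarm_iteration <- function(state, spec, settings, ledger,
                            n_update = settings$np) {
  if (ledger_remaining(ledger) < n_update) {
    stop("insufficient budget for a swarm iteration", call. = FALSE)
  }
  # position inertia is scheduled on the global evaluation counter
  j <- min(ledger$consumed + 1L, ledger$budget)
  theta1 <- inertia_weight(j, ledger$budget, settings$w_max, settings$w_min)
  for (i in seq_len(n_update)) {
    s <- state$assignment[i]
    proposal <- update_particle(
      state$positions[i, ], state$pbest[i, ], state$swarm_best[s, ],
      theta1, settings$theta2, settings$theta3
    )
    proposal <- reflect_bounds(proposal, spec$bounds)
    value <- evaluate_with_budget(spec, proposal, ledger)
    state$positions[i, ] <- proposal
    if (value < state$pbest_value[i]) {
      state$pbest[i, ] <- proposal
      state$pbest_value[i] <- value
    }
  }
  state$iteration <- state$iteration + 1L
  refresh_bests(state)
}

#' Randomly regroup particles into new sub-swarms
#'
#' Re-partitions the particles uniformly at random into `k` equal sub-swarms,
#' keeping every personal best; sub-swarm bests are recomputed from the new
#' membership and the global best is unchanged. Periodic regrouping mixes
#' information across sub-swarms and preserves search diversity.
#'
#' @param state A `swarm_state`.
#'
#' @return The regrouped `swarm_state`.
#' @export
regroup <- function(state) {
  state$assignment <- random_assignment(state$settings$np, state$settings$k)
  refresh_bests(state)
}

#' Detect stagnation of the global best
#'
#' Returns `TRUE` when the global best changed by no more than `tolerance`
#' (relative) in total over the last `limit` iterations, i.e. the search
#' has genuinely flattened rather than merely paused for a single step.
#' A full window is required: with fewer than `limit + 1` recorded values
#' the answer is `FALSE`.
#'
#' @param recent Numeric vector of per-iteration global best values, oldest
#'   first.
#' @param tolerance Relative-change threshold over the window (default
#'   0.01, i.e. 1%).
#' @param limit Window length in iterations (default 4).
#'
#' @return Logical scalar.
#' @examples
#' detect_stagnation(c(100, 99.9, 99.85, 99.84, 99.84))  # TRUE
#' detect_stagnation(c(100, 50, 25, 12, 6))              # FALSE
#' @export
detect_stagnation <- function(recent, tolerance = 0.01, limit = 4L) {
  n <- length(recent)
  if (n < limit + 1L) return(FALSE)
  ref <- recent[n - limit]
  denom <- max(abs(ref), .Machine$double.eps)
  abs(ref - recent[n]) / denom <= tolerance
}
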