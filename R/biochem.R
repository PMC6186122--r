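#' Define a mass-action reaction network
#'
#' A small container for ordinary-differential-equation models with
#' mass-action kinetics: each reaction proceeds at a rate equal to its rate
#' constant times the product of its reactant concentrations (raised to
#' their stoichiometric coefficients). The rate-constant vector is the
#' estimation target in parameter-recovery studies.
#'
#' @param species Character vector of species names.
#' @param reactions List of reactions; each a list with named integer
#'   vectors `reactants` and `products` giving stoichiometric coefficients
#'   keyed by species name (either may be empty for source/sink reactions).
#' @param rate_constants Named numeric vector, one non-negative rate
#'   constant per reaction.
#' @param initial_state Named numeric vector of non-negative initial
#'   concentrations, one per species.
#'
#' @return An object of class `mass_action_model`.
#' @export
mass_action_model <- function(species, reactions, rate_constants,
                              initial_state) {
  species <- as.character(species)
  n_s <- length(species)
  n_r <- length(reactions)
  if (length(rate_constants) != n_r) {
    stop("need one rate constant per reaction", call. = FALSE)
  }
  if (any(rate_constants < 0) || any(initial_state < 0)) {
    stop("rate constants and initial concentrations must be non-negative",
         call. = FALSE)
  }
  if (!setequal(names(initial_state), species)) {
    stop("`initial_state` must be named by the species", call. = FALSE)
  }
  initial_state <- initial_state[species]
  net <- matrix(0, nrow = n_r, ncol = n_s,
                dimnames = list(NULL, species))
  sre <- matrix(0, nrow = n_r, ncol = n_s,
                dimnames = list(NULL, species))
  reactant_idx <- vector("list", n_r)
  reactant_stoich <- vector("list", n_r)
  for (j in seq_len(n_r)) {
    rx <- reactions[[j]]
    re <- rx$reactants %||% integer()
    pr <- rx$products %||% integer()
    bad <- setdiff(c(names(re), names(pr)), species)
    if (length(bad)) {
      stop("unknown species in reaction ", j, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (length(re)) {
      net[j, names(re)] <- net[j, names(re)] - re
      sre[j, names(re)] <- re
    }
    if (length(pr)) net[j, names(pr)] <- net[j, names(pr)] + pr
    reactant_idx[[j]] <- match(names(re), species)
    reactant_stoich[[j]] <- as.numeric(re)
  }
  structure(
    list(species = species, reactions = reactions,
         rate_constants = as.numeric(rate_constants),
         initial_state = initial_state,
         net = net, net_t = t(net), reactant_stoich_matrix = sre,
         reactant_idx = reactant_idx, reactant_stoich = reactant_stoich),
    class = "mass_action_model"
  )
}

#' @export
print.mass_action_model <- function(x, ...) {
  cat("<mass_action_model>", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

mass_action_rhs <- function(model) {
  idx <- model$reactant_idx
  sto <- model$reactant_stoich
  net_t <- model$net_t
  n_r <- length(idx)
  function(t, x, p) {
    xc <- pmax(x, 0)  # guard tiny negative excursions from the integrator
    rates <- numeric(n_r)
    for (j in seq_len(n_r)) {
      rates[j] <- p[j] * prod(xc[idx[[j]]]^sto[[j]])
    }
    list(as.vector(net_t %*% rates))
  }
}

#' Integrate a mass-action model
#'
#' Solves the mass-action system numerically (via [deSolve::lsoda()]) at
#' the requested times. The first requested time is the initial time and the
#' first row of the returned matrix equals the initial state exactly.
#'
#' @param model A [mass_action_model()].
#' @param p Rate-constant vector (defaults to the model's).
#' @param times Increasing numeric vector of output times.
#' @param initial_state Optional replacement initial state (named like the
#'   species).
#' @param rtol,atol Integrator tolerances.
#' @param engine `"compiled"` evaluates the derivative in C (the default
#'   whenever the network fits the compiled parameter block); `"r"` uses
#'   the plain R derivative, kept as the reference implementation.
#'
#' @return Numeric matrix, `length(times)` rows by species columns. Throws
#'   a condition of class `dopsr_integration_failure` if the integrator
#'   fails or returns non-finite states.
#' @export
simulate_model <- function(model, p = model$rate_constants, times,
                           initial_state = NULL, rtol = 1e-6, atol = 1e-8,
                           engine = c("auto", "compiled", "r")) {
  stopifnot(inherits(model, "mass_action_model"))
  engine <- match.arg(engine)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  x0 <- if (is.null(initial_state)) model$initial_state else {
    initial_state[model$species]
  }
  n_r <- nrow(model$net)
  n_s <- ncol(model$net)
  fits <- 2 + n_r + 2 * n_r * n_s <= 4096
  if (engine == "auto") engine <- if (fits) "compiled" else "r"
  if (engine == "compiled" && !fits) {
    stop("network too large for the compiled parameter block; use engine = 'r'",
         call. = FALSE)
  }
  out <- tryCatch(
    suppressWarnings(
      if (engine == "compiled") {
        parms <- numeric(4096)
        parms[1:2] <- c(n_r, n_s)
        parms[2 + seq_len(n_r)] <- p
        parms[2 + n_r + seq_len(n_r * n_s)] <-
          as.vector(t(model$reactant_stoich_matrix))
        parms[2 + n_r + n_r * n_s + seq_len(n_r * n_s)] <-
          as.vector(t(model$net))
        deSolve::lsoda(y = x0, times = times, func = "dopsr_derivs",
                       dllname = "dopsr", initfunc = "dopsr_initmod",
                       parms = parms, rtol = rtol, atol = atol,
                       maxsteps = 2000)
      } else {
        deSolve::lsoda(y = x0, times = times, func = mass_action_rhs(model),
                       parms = p, rtol = rtol, atol = atol, maxsteps = 2000)
      }
    ),
    error = function(e) NULL
  )
  if (is.null(out) || nrow(out) != length(times) ||
      any(!is.finite(out[, -1, drop = FALSE]))) {
    stop(structure(
      class = c("dopsr_integration_failure", "error", "condition"),
      list(message = "ODE integration failed", call = NULL, parameters = p)
    ))
  }
  states <- out[, -1, drop = FALSE]
  states[1, ] <- x0  # exact initial condition, untouched by the solver
  colnames(states) <- model$species
  states
}

#' Generate a synthetic noisy time-course dataset
#'
#' Simulates the model at known nominal rate constants, keeps the observed
#' species, and adds independent zero-mean Gaussian measurement noise. This
#' emulates the standard validation protocol for estimation methods:
#' training data generated from the model itself so the true parameters are
#' known.
#'
#' @param model A [mass_action_model()].
#' @param p_nom Nominal rate constants used to generate the data.
#' @param times Observation times (first entry is the initial time).
#' @param observed_species Character or integer vector of observed species.
#' @param noise_sd Measurement noise standard deviation (>= 0, concentration
#'   units).
#' @param initial_state Optional replacement initial state.
#'
#' @return An object of class `experiment_dataset` with `times`,
#'   `observed`, `measurements` (times x observed matrix), `noise_sd` and
#'   the initial state used.
#' @export
generate_synthetic_data <- function(model, p_nom = model$rate_constants,
                                    times, observed_species,
                                    noise_sd = 0, initial_state = NULL) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.character(observed_species)) {
    observed_species <- match(observed_species, model$species)
  }
  states <- simulate_model(model, p_nom, times, initial_state)
  meas <- states[, observed_species, drop = FALSE]
  if (noise_sd > 0) {
    meas <- meas + matrix(rnorm(length(meas), 0, noise_sd),
                          nrow = nrow(meas))
  }
  structure(
    list(times = times, observed = observed_species, measurements = meas,
         noise_sd = noise_sd,
         initial_state = if (is.null(initial_state)) model$initial_state
                         else initial_state[model$species]),
    class = "experiment_dataset"
  )
}

#' Sum-of-squared-error objective for parameter estimation
#'
#' Builds an [objective_spec()] whose value at a rate-constant vector `p`
#' is the sum over all datasets, time points and observed species of the
#' squared residual between the model simulation at `p` and the
#' measurement. Multiple datasets (e.g. experiments started from different
#' trigger concentrations) are summed unweighted. Integration failures are
#' mapped to a large sentinel value (1e6 times the first finite objective
#' value seen) so the optimizer's budget accounting is unaffected.
#'
#' @param model A [mass_action_model()].
#' @param datasets A single `experiment_dataset` or a list of them.
#' @param bounds Optional [bounds_box()]; defaults to the multiplicative box
#'   `0.2 * nominal` to `5 * nominal`.
#' @param nominal Nominal rate constants defining the default bounds
#'   (defaults to the model's rate constants).
#' @param name Objective name.
#'
#' @return An [objective_spec()] with attribute `nominal`.
#' @export
sse_objective <- function(model, datasets, bounds = NULL,
                          nominal = model$rate_constants,
                          name = "sse") {
  if (inherits(datasets, "experiment_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "experiment_dataset")))
  if (is.null(bounds)) {
    bounds <- bounds_box(0.2 * nominal, 5 * nominal)
  }
  cache <- new.env(parent = emptyenv())
  cache$first_finite <- NULL
  fn <- function(p) {
    total <- tryCatch({
      sse <- 0
      for (d in datasets) {
        states <- simulate_model(model, p, d$times, d$initial_state)
        resid <- states[, d$observed, drop = FALSE] - d$measurements
        sse <- sse + sum(resid^2)
      }
      sse
    }, dopsr_integration_failure = function(e) NA_real_)
    if (is.na(total) || !is.finite(total)) {
      return(if (is.null(cache$first_finite)) 1e30
             else 1e6 * cache$first_finite)
    }
    if (is.null(cache$first_finite)) cache$first_finite <- max(total, 1e-12)
    total
  }
  spec <- objective_spec(fn, bounds, name = name)
  attr(spec, "nominal") <- nominal
  spec
}

#' The bundled demonstration cascade
#'
#' A six-species, eight-reaction mass-action cascade with the
#' initiation/amplification/inhibition architecture typical of protease
#' networks such as coagulation: a trigger `TRIG` activates zymogen `X` to
#' `Xa`; `Xa` activates a second zymogen `Y` to `Ya`; `Ya` feeds back
#' positively by also activating `X`; a stoichiometric inhibitor `INH`
#' neutralizes both active species; both active species decay; and `Ya`
#' closes a negative feedback loop by consuming the trigger. The eight rate
#' constants are the estimation target of the parameter-recovery
#' demonstration; two species (`Xa`, `Ya`) are observed.
#'
#' @return A [mass_action_model()] with nominal rate constants.
#' @examples
#' m <- demo_cascade_model()
#' m$rate_constants
#' @export
demo_cascade_model <- function() {
  species <- c("TRIG", "X", "Xa", "Y", "Ya", "INH")
  reactions <- list(
    list(reactants = c(TRIG = 1, X = 1), products = c(TRIG = 1, Xa = 1)),
    list(reactants = c(Xa = 1, Y = 1),   products = c(Xa = 1, Ya = 1)),
    list(reactants = c(Ya = 1, X = 1),   products = c(Ya = 1, Xa = 1)),
    list(reactants = c(Xa = 1, INH = 1), products = integer()),
    list(reactants = c(Ya = 1, INH = 1), products = integer()),
    list(reactants = c(Xa = 1),          products = integer()),
    list(reactants = c(Ya = 1),          products = integer()),
    list(reactants = c(Ya = 1, TRIG = 1), products = c(Ya = 1))
  )
  k_nom <- c(k_act = 2.0, k_amp = 1.5, k_fb = 0.8, k_inh_x = 1.0,
             k_inh_y = 0.6, k_deg_x = 0.2, k_deg_y = 0.1, k_neg = 0.5)
  x0 <- c(TRIG = 1, X = 5, Xa = 0, Y = 5, Ya = 0, INH = 2)
  mass_action_model(species, reactions, k_nom, x0)
}

#' Training datasets for the demonstration cascade
#'
#' Two experiments differing in the initial trigger concentration (1.0 and
#' 0.2), each observed at 20 time points over \[0, 10\] for the two active
#' species, combined unweighted in the objective.
#'
#' @param model The demonstration model (default [demo_cascade_model()]).
#' @param noise_sd Measurement noise standard deviation (default 0:
#'   noiseless training data, so the nominal parameters give objective 0).
#' @param times Observation times.
#'
#' @return A list of two `experiment_dataset` objects.
#' @export
demo_datasets <- function(model = demo_cascade_model(), noise_sd = 0,
                          times = seq(0, 10, length.out = 20)) {
  obs <- c("Xa", "Ya")
  x0_low <- model$initial_state
  x0_low["TRIG"] <- 0.2
  list(
    generate_synthetic_data(model, times = times, observed_species = obs,
                            noise_sd = noise_sd),
    generate_synthetic_data(model, times = times, observed_species = obs,
                            noise_sd = noise_sd, initial_state = x0_low)
  )
}

#' Finite-difference output sensitivities of a model
#'
#' For each rate constant, perturbs it by a relative step and reports the
#' root-sum-square change of the observed trajectories across the supplied
#' datasets. A strictly positive value for every parameter indicates each
#' parameter has a detectable effect on the observables (a necessary
#' condition for recovery).
#'
#' @param model A [mass_action_model()].
#' @param datasets List of `experiment_dataset` objects.
#' @param p Parameter vector at which to probe (default nominal).
#' @param rel_step Relative perturbation (default 0.01).
#'
#' @return Named numeric vector, one sensitivity per parameter.
#' @export
parameter_sensitivities <- function(model, datasets,
                                    p = model$rate_constants,
                                    rel_step = 0.01) {
  if (inherits(datasets, "experiment_dataset")) datasets <- list(datasets)
  base <- lapply(datasets, function(d) {
    simulate_model(model, p, d$times, d$initial_state)[, d$observed,
                                                       drop = FALSE]
  })
  out <- numeric(length(p))
  for (j in seq_along(p)) {
    pj <- p
    pj[j] <- pj[j] * (1 + rel_step)
    delta <- 0
    for (i in seq_along(datasets)) {
      d <- datasets[[i]]
      pert <- simulate_model(model, pj, d$times,
                             d$initial_state)[, d$observed, drop = FALSE]
      delta <- delta + sum((pert - base[[i]])^2)
    }
    out[j] <- sqrt(delta)
  }
  names(out) <- names(model$rate_constants)
  out
}

#' Parameter-recovery experiment on the demonstration cascade
#'
#' Runs the full optimizer repeatedly against synthetic training data from
#' the bundled cascade, with the multiplicative bounds `0.2 x nominal` to
#' `5 x nominal`, and reports per-trial recovery quality: the final
#' sum-of-squared-error, the final error scaled by the trial's initial
#' best, and the relative parameter error
#' `||p_hat - p_nom|| / ||p_nom||`.
#'
#' @param config A [dops_config()] (its seed is overridden per trial).
#' @param noise_sd Measurement noise of the training data (default 0).
#' @param trials Number of independent trials (default 10).
#' @param base_seed Base seed; trial t uses `base_seed + t - 1`.
#' @param variant Optimizer variant to test (default `"dops"`).
#'
#' @return A tibble with one row per trial: `trial`, `seed`,
#'   `initial_best`, `final_sse`, `scaled_error`, `param_rel_error`.
#' @export
recovery_experiment <- function(config = dops_config(), noise_sd = 0,
                                trials = 10L, base_seed = 1L,
                                variant = "dops") {
  model <- demo_cascade_model()
  if (noise_sd > 0) set.seed(base_seed)  # reproducible noisy training data
  datasets <- demo_datasets(model, noise_sd = noise_sd)
  spec <- sse_objective(model, datasets, name = "demo-cascade-sse")
  p_nom <- model$rate_constants
  rows <- vector("list", trials)
  for (t in seq_len(trials)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed) + t - 1L
    res <- run_variant(variant, spec, cfg)
    rows[[t]] <- tibble::tibble(
      trial = t,
      seed = cfg$seed,
      initial_best = res$trace[res$baseline_eval],
      final_sse = res$best_value,
      scaled_error = scaled_final_error(res),
      param_rel_error = sqrt(sum((res$best_vector - p_nom)^2)) /
        sqrt(sum(p_nom^2))
    )
  }
  dplyr::bind_rows(rows)
}

#' Serialize a mass-action model to JSON (and back)
#'
#' @param model A [mass_action_model()].
#' @param path Output path.
#' @return `write_model_json()` returns the path invisibly;
#'   `read_model_json()` returns the model.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "mass_action_model"))
  payload <- list(
    species = model$species,
    reactions = lapply(model$reactions, function(rx) {
      list(reactants = as.list(rx$reactants %||% integer()),
           products = as.list(rx$products %||% integer()))
    }),
    rate_constants = as.list(model$rate_constants),
    initial_state = as.list(model$initial_state)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  reactions <- lapply(raw$reactions, function(rx) {
    list(reactants = unlist(rx$reactants) %||% integer(),
         products = unlist(rx$products) %||% integer())
  })
  mass_action_model(
    species = unlist(raw$species),
    reactions = reactions,
    rate_constants = unlist(raw$rate_constants),
    initial_state = unlist(raw$initial_state)
  )
}

#' Write or read a time-course dataset as CSV
#'
#' Columns: `time`, then one column per observed species. Values are
#' written with 17 significant digits so a round trip reproduces them
#' exactly.
#'
#' @param dataset An `experiment_dataset`.
#' @param model The model the dataset belongs to (for species names).
#' @param path File path.
#' @return `write_dataset_csv()` returns the path invisibly;
#'   `read_dataset_csv()` returns a tibble.
#' @export
write_dataset_csv <- function(dataset, model, path) {
  stopifnot(inherits(dataset, "experiment_dataset"))
  tab <- data.frame(time = dataset$times, dataset$measurements)
  names(tab) <- c("time", model$species[dataset$observed])
  formatted <- as.data.frame(lapply(tab, function(col) {
    formatC(col, digits = 17, format = "g")
  }))
  names(formatted) <- names(tab)
  write.csv(formatted, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  tibble::as_tibble(read.csv(path))
}
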