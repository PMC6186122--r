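#' Tidy the best-so-far trace of a run
#'
#' @param x A `dops_result`.
#' @param ... Unused.
#'
#' @return A tibble with one row per objective evaluation: `evaluation`,
#'   `best_value`, `scaled_best_value` and the `phase` active at that
#'   evaluation.
#' @method tidy dops_result
#' @export
tidy.dops_result <- function(x, ...) {
  phase <- character(length(x$trace))
  for (i in seq_len(nrow(x$phase_log))) {
    idx <- seq.int(x$phase_log$start_eval[i], x$phase_log$end_eval[i])
    phase[idx] <- x$phase_log$phase[i]
  }
  tibble::tibble(
    evaluation = seq_along(x$trace),
    best_value = x$trace,
    scaled_best_value = scaled_trace_on_grid(x),
    phase = phase
  )
}

#' One-row summary of a run
#'
#' @param x A `dops_result`.
#' @param ... Unused.
#'
#' @return A tibble with `variant`, `objective`, `dimension`,
#'   `evaluations`, `best_value`, `scaled_final_error`, `n_phases`, `seed`.
#' @method glance dops_result
#' @export
glance.dops_result <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    objective = x$objective,
    dimension = x$dimension,
    evaluations = x$evaluations,
    best_value = x$best_value,
    scaled_final_error = scaled_final_error(x),
    n_phases = nrow(x$phase_log),
    seed = x$seed
  )
}

#' Per-trial summaries of a batch
#'
#' @param x A `trial_batch`.
#' @param ... Unused.
#'
#' @return A tibble with one row per completed trial ([glance.dops_result()]
#'   columns plus `trial`).
#' @method tidy trial_batch
#' @export
tidy.trial_batch <- function(x, ...) {
  rows <- purrr::imap(x$results, function(res, t) {
    if (is.null(res)) return(NULL)
    dplyr::mutate(glance(res), trial = t, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a batch
#'
#' @param x A `trial_batch`.
#' @param ... Unused.
#'
#' @return A tibble with the batch metadata and the mean, standard
#'   deviation and median of the per-trial final scaled errors.
#' @method glance trial_batch
#' @export
glance.trial_batch <- function(x, ...) {
  fin <- batch_final_scaled_errors(x)
  tibble::tibble(
    variant = x$variant,
    objective = x$objective,
    dimension = x$dimension,
    trials = x$trials,
    completed = length(fin),
    mean_scaled_final_error = mean(fin),
    sd_scaled_final_error = if (length(fin) > 1) sd(fin) else NA_real_,
    median_scaled_final_error = median(fin),
    base_seed = x$base_seed
  )
}

#' Convergence plot for a single run
#'
#' Scaled best-so-far error versus evaluations on a log axis, colored by the
#' active phase so the switch points are visible.
#'
#' @param object A `dops_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dops_result
#' @export
autoplot.dops_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$evaluation,
                                    y = .data$scaled_best_value,
                                    color = .data$phase, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "function evaluations", y = "scaled error",
                  color = "phase",
                  title = sprintf("%s on %s (seed %d)", object$variant,
                                  object$objective, object$seed)) +
    ggplot2::theme_minimal()
}

#' Mean convergence plot for a batch
#'
#' Pointwise mean scaled error across trials with a +/- one standard
#' deviation ribbon.
#'
#' @param object A `trial_batch`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_batch
#' @export
autoplot.trial_batch <- function(object, ...) {
  curve <- aggregate_convergence(object)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$evaluation,
                                      y = .data$mean_scaled_error)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = pmax(.data$mean_scaled_error - .data$sd_scaled_error,
                    .Machine$double.xmin),
        ymax = .data$mean_scaled_error + .data$sd_scaled_error
      ),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "function evaluations", y = "mean scaled error",
                  title = sprintf("%s on %s (%d trials)", object$variant,
                                  object$objective, object$trials)) +
    ggplot2::theme_minimal()
}
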