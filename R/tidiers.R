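#' Tidy the round-by-round history of an M-training run
#'
#' One row per (round, slot): the error bounds `e_prev` / `e_t`, proposal
#' and sub-sample sizes, the decision taken, training-pool sizes before
#' and after, and the noise-utility diagnostics `u_prev` / `u_t`.
#'
#' @param x an `mtrain_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.mtrain_fit <- function(x, ...) {
  x$history
}

#' One-row summary of an M-training run
#'
#' @param x an `mtrain_fit`.
#' @param ... unused.
#' @return tibble with ensemble configuration, pool sizes, number of
#'   rounds, refit count and termination reason.
#' @export
glance.mtrain_fit <- function(x, ...) {
  tibble::tibble(
    M = x$config$M, theta = x$config$theta,
    base = x$config$base_spec$kind,
    n_L = x$n_L, n_U = x$n_U,
    rounds = x$rounds,
    n_refits = sum(x$history$decision != "skip"),
    termination = x$termination
  )
}

#' Label each sample of a feature table with the ensemble prediction
#'
#' @param x an `mtrain_fit`.
#' @param data feature table to predict.
#' @param ... unused.
#' @return `data` with `.fitted` (final) and `.fitted_initial` columns.
#' @export
augment.mtrain_fit <- function(x, data, ...) {
  dplyr::mutate(data,
                .fitted = predict(x, data, stage = "final"),
                .fitted_initial = predict(x, data, stage = "initial"))
}

#' Plot an M-training run history
#'
#' Two panels per slot: the committee error bound e_i(t) and the size of
#' the slot's training pool across rounds.
#'
#' @param object an `mtrain_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mtrain_fit <- function(object, ...) {
  h <- object$history |>
    dplyr::select("round", "slot", "e_t", "pool_after") |>
    tidyr::pivot_longer(c("e_t", "pool_after"), names_to = "quantity") |>
    dplyr::mutate(quantity = dplyr::recode(.data$quantity,
                                           e_t = "committee error e_i(t)",
                                           pool_after = "training pool size"))
  ggplot(h, aes(x = .data$round, y = .data$value,
                colour = factor(.data$slot))) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "round", y = NULL, colour = "slot",
         title = "M-training refinement history") +
    theme_minimal()
}

#' Plot accuracy against unlabeled rate for an experiment grid
#'
#' Shows median initial and final ensemble test accuracy per unlabeled
#' rate (and per ensemble size if several were run).
#'
#' @param reports output of [run_experiment()].
#' @return a ggplot object.
#' @export
plot_experiment <- function(reports) {
  s <- summarize_experiment(reports) |>
    tidyr::pivot_longer(c("initial_accuracy", "final_accuracy"),
                        names_to = "stage", values_to = "accuracy") |>
    dplyr::mutate(stage = sub("_accuracy", "", .data$stage))
  ggplot(s, aes(x = factor(.data$unlabeled_rate), y = .data$accuracy,
                fill = .data$stage)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~M, labeller = "label_both") +
    labs(x = "unlabeled rate", y = "median test accuracy (%)",
         fill = NULL) +
    theme_minimal()
}

#' Plot a response curve
#'
#' @param object a [response_curve()].
#' @param ... unused.
#' @return a ggplot object with phase boundaries marked.
#' @export
autoplot.response_curve <- function(object, ...) {
  ph <- curve_phases(object)
  d <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_s",
                           names_to = "channel", values_to = "response")
  ggplot(d, aes(x = .data$time_s, y = .data$response,
                colour = .data$channel)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = c(ph$baseline_end, ph$exposure_end),
                        linetype = "dashed", colour = "grey40") +
    labs(x = "time (s)", y = "sensor response",
         title = "baseline | exposure | recovery") +
    theme_minimal()
}
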