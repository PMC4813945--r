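#' Evaluate one M-training run on a benchmark split
#'
#' Runs [mtrain()] on a split and measures initial (ensemble fitted on L
#' only) and final (after refinement) test accuracies, the relative
#' improvement, per-class accuracies and per-slot pool sizes.
#'
#' @param bench list with `L`, `U`, `test` tibbles (e.g.
#'   [benchmark_split()]).
#' @param config an [mtrain_config()].
#' @return one-row tibble: `M`, `theta`, `unlabeled_rate`, `seed`,
#'   `initial_accuracy`, `final_accuracy`, `impro`, `rounds`,
#'   `termination`, plus list-columns `per_class` (tibble with initial
#'   and final per-class accuracy), `pool_sizes` (initial/final per
#'   slot) and `fit` (the `mtrain_fit`).
#' @export
evaluate_run <- function(bench, config) {
  fit <- mtrain(bench$L, bench$U, config)
  pred0 <- predict(fit, bench$test, stage = "initial")
  pred1 <- predict(fit, bench$test, stage = "final")
  acc0 <- accuracy(pred0, bench$test$label)
  acc1 <- accuracy(pred1, bench$test$label)
  pc <- dplyr::left_join(
    dplyr::rename(per_class_accuracy(pred0, bench$test$label),
                  initial = "accuracy"),
    dplyr::rename(per_class_accuracy(pred1, bench$test$label),
                  final = "accuracy"),
    by = c("label", "n")
  )
  pools <- tibble::tibble(
    slot = seq_along(fit$slots),
    initial = vapply(fit$initial_slots, function(s) nrow(s$pool), numeric(1)),
    final = vapply(fit$slots, function(s) {
      if (is.null(s$train_pool)) nrow(s$pool) else nrow(s$train_pool)
    }, numeric(1))
  )
  tibble::tibble(
    M = config$M, theta = config$theta,
    unlabeled_rate = nrow(bench$U) / (nrow(bench$L) + nrow(bench$U)),
    seed = config$seed,
    initial_accuracy = acc0, final_accuracy = acc1,
    impro = impro(acc0, acc1),
    rounds = fit$rounds, termination = fit$termination,
    per_class = list(pc), pool_sizes = list(pools), fit = list(fit)
  )
}

#' Run a grid of semi-supervised experiments
#'
#' For every combination of ensemble size, unlabeled rate and seed,
#' builds the default synthetic benchmark split, runs M-training and
#' evaluates it with [evaluate_run()]. Cell seeds are derived from the
#' root seed and the cell index so cells are independent and
#' reproducible; a failing cell is recorded (`error` column) without
#' aborting the grid.
#'
#' @param M integer vector of ensemble sizes (each >= 3).
#' @param unlabeled_rate numeric vector of rates in \[0, 1).
#' @param seeds number of replicate seeds per cell, or an explicit
#'   integer vector of seeds.
#' @param seed root seed from which cell seeds are derived.
#' @param base_spec base [classifier_spec()].
#' @param spec benchmark [cluster_spec()].
#' @param theta,init_fraction,max_rounds passed to [mtrain_config()].
#' @param keep_fits keep the full `mtrain_fit` objects in the result
#'   (default `FALSE`; they are large).
#' @return tibble, one row per (M, rate, seed) cell, as in
#'   [evaluate_run()], plus an `error` column (`NA` when the cell ran).
#' @export
run_experiment <- function(M = 4L, unlabeled_rate = 0.5, seeds = 5L,
                           seed = 1L,
                           base_spec = classifier_spec("svm_rbf"),
                           spec = default_cluster_spec(),
                           theta = 2 / 3, init_fraction = 0.75,
                           max_rounds = 50L, keep_fits = FALSE) {
  if (length(seeds) == 1 && seeds == as.integer(seeds)) {
    seeds <- seq_len(seeds)
  }
  grid <- expand.grid(M = M, rate = unlabeled_rate, rep = seeds)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cell_seed <- derive_seed(seed, grid$M[g], round(1000 * grid$rate[g]),
                             grid$rep[g])
    res <- tryCatch({
      bench <- benchmark_split(cell_seed, grid$rate[g], spec)
      cfg <- mtrain_config(M = grid$M[g], theta = theta,
                           init_fraction = init_fraction,
                           max_rounds = max_rounds, seed = cell_seed,
                           base_spec = base_spec)
      out <- evaluate_run(bench, cfg)
      out$error <- NA_character_
      out
    }, error = function(e) {
      tibble::tibble(M = grid$M[g], theta = theta,
                     unlabeled_rate = grid$rate[g],
                     seed = cell_seed, initial_accuracy = NA_real_,
                     final_accuracy = NA_real_, impro = NA_real_,
                     rounds = NA_integer_, termination = NA_character_,
                     per_class = list(NULL), pool_sizes = list(NULL),
                     fit = list(NULL), error = conditionMessage(e))
    })
    res$replicate <- grid$rep[g]
    if (!keep_fits) res$fit <- NULL
    res
  })
  dplyr::bind_rows(rows)
}

#' Summarize an experiment grid
#'
#' Median initial/final accuracy and improvement per (M, unlabeled_rate)
#' cell, with the fraction of seeds in which refinement did not hurt.
#'
#' @param reports output of [run_experiment()].
#' @return summary tibble.
#' @export
summarize_experiment <- function(reports) {
  reports |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$M, .data$unlabeled_rate) |>
    dplyr::summarise(
      n_seeds = dplyr::n(),
      frac_improved = mean(.data$final_accuracy >= .data$initial_accuracy),
      initial_accuracy = stats::median(.data$initial_accuracy),
      final_accuracy = stats::median(.data$final_accuracy),
      impro = stats::median(.data$impro),
      .groups = "drop"
    )
}
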