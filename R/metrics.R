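#' Classification accuracy
#'
#' @param predicted,truth character vectors of equal, positive length.
#' @return percent correct, `100 * matches / total`.
#' @examples
#' accuracy(c("a", "a", "b"), c("a", "b", "b"))
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("predicted and truth have different lengths")
  }
  if (length(truth) == 0) abort("empty label vectors")
  100 * mean(predicted == truth)
}

#' Relative improvement of final over initial accuracy
#'
#' `100 * (final - initial) / initial`, the headline refinement metric;
#' reports are conventionally shown at 2 decimal places
#' ([round_half_up()]).
#'
#' @param initial,final accuracies in percent; `initial` must be > 0.
#' @return the relative improvement in percent (unrounded).
#' @examples
#' round_half_up(impro(73.48, 91.67), 2)
#' @export
impro <- function(initial, final) {
  if (any(initial <= 0)) abort("initial accuracy must be positive")
  100 * (final - initial) / initial
}

#' Per-class (class-conditional) accuracy
#'
#' @param predicted,truth character vectors of equal length; every class
#'   of `label_set` must occur in `truth`.
#' @param label_set classes to report (default: classes in `truth`).
#' @return tibble with `label`, `n` and `accuracy` (percent). The
#'   size-weighted mean of the per-class accuracies equals
#'   [accuracy()].
#' @export
per_class_accuracy <- function(predicted, truth,
                               label_set = label_order(truth)) {
  if (length(predicted) != length(truth)) {
    abort("predicted and truth have different lengths")
  }
  missing <- setdiff(label_set, truth)
  if (length(missing) > 0) {
    abort(sprintf("class absent from truth: %s",
                  paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    label = label_set,
    n = vapply(label_set, function(cl) sum(truth == cl), integer(1),
               USE.NAMES = FALSE),
    accuracy = vapply(label_set, function(cl) {
      accuracy(predicted[truth == cl], truth[truth == cl])
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Leave-one-out accuracy of a base classifier
#'
#' Fits `nrow(data)` models, each with one sample held out, and reports
#' the percentage of held-out samples predicted correctly — the standard
#' way to compare candidate base classifiers on a small labeled dataset.
#'
#' @param data labeled feature table with at least 2 samples; every class
#'   needs at least 2 samples so each fold keeps all classes.
#' @param spec a [classifier_spec()].
#' @return percent of held-out samples classified correctly.
#' @export
loo_accuracy <- function(data, spec) {
  validate_feature_table(data)
  if (nrow(data) < 2) abort("leave-one-out needs at least 2 samples")
  sizes <- table(data$label)
  if (any(sizes < 2)) {
    abort(sprintf("class `%s` has a single sample; a fold would lose it",
                  names(sizes)[sizes < 2][1]))
  }
  hits <- vapply(seq_len(nrow(data)), function(i) {
    model <- fit_classifier(data[-i, ], spec)
    predict(model, data[i, ]) == data$label[i]
  }, logical(1))
  100 * mean(hits)
}
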