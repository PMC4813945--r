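#' Train/test split of a labeled feature table
#'
#' Splits a fully labeled feature table into training and test parts.
#' With `stratified = TRUE` (the default, matching the usual per-gas
#' protocol) each class contributes `round_half_up(train_fraction * class
#' size)` samples to the training part; otherwise the count is taken over
#' the whole table. The split is a uniform random draw without
#' replacement, deterministic under `seed`.
#'
#' @param data labeled feature table (no `NA` labels).
#' @param train_fraction fraction assigned to the training part, in (0, 1).
#' @param seed integer seed.
#' @param stratified split per class (default `TRUE`).
#' @return list with tibbles `train` and `test`; disjoint and exhaustive.
#' @examples
#' d <- simulate_feature_clusters(seed = 1)
#' s <- split_train_test(d, 0.75, seed = 1)
#' nrow(s$train); nrow(s$test)
#' @export
split_train_test <- function(data, train_fraction = 0.75, seed = 1,
                             stratified = TRUE) {
  validate_feature_table(data)
  if (any(is.na(data$label))) {
    abort("split_train_test() needs a fully labeled table")
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("`train_fraction` must be in (0, 1)")
  }
  pick <- function(d, s) {
    k <- round_half_up(train_fraction * nrow(d))
    idx <- with_seed(s, sample.int(nrow(d), k))
    list(train = d[idx, ], test = d[-idx, ])
  }
  if (stratified) {
    classes <- label_order(data$label)
    sizes <- table(data$label)
    if (any(sizes < 2)) {
      abort(sprintf("class `%s` has fewer than 2 samples; cannot stratify",
                    names(sizes)[sizes < 2][1]))
    }
    parts <- lapply(seq_along(classes), function(i) {
      pick(dplyr::filter(data, .data$label == classes[i]),
           derive_seed(seed, i))
    })
    list(train = dplyr::bind_rows(lapply(parts, `[[`, "train")),
         test  = dplyr::bind_rows(lapply(parts, `[[`, "test")))
  } else {
    pick(data, derive_seed(seed, 0L))
  }
}

#' Labeled/unlabeled split of a training pool
#'
#' Withholds labels from a fraction of the training data to form the
#' unlabeled pool U. `|L| = round_half_up((1 - unlabeled_rate) * n)`. The
#' draw is simple random by default; a stratified option draws the L part
#' per class. The withheld ground-truth labels are returned separately in
#' `truth` for pseudo-label diagnostics and are never seen by the learner
#' (the `U` tibble carries `NA` labels).
#'
#' If the drawn L part misses a class entirely the draw is retried with a
#' derived seed (up to 100 times, with a message).
#'
#' @param train labeled feature table.
#' @param unlabeled_rate fraction of `train` whose labels are withheld,
#'   in \[0, 1).
#' @param seed integer seed.
#' @param stratified draw L per class (default `FALSE`).
#' @return list with `L` (labeled tibble), `U` (tibble, `label` all `NA`)
#'   and `truth` (tibble `sample_id`, `true_label` for the U rows).
#' @export
split_labeled_unlabeled <- function(train, unlabeled_rate, seed = 1,
                                    stratified = FALSE) {
  validate_feature_table(train)
  if (any(is.na(train$label))) {
    abort("split_labeled_unlabeled() needs a fully labeled training table")
  }
  if (!(unlabeled_rate >= 0 && unlabeled_rate < 1)) {
    abort("`unlabeled_rate` must be in [0, 1)")
  }
  classes <- label_order(train$label)
  draw <- function(s) {
    if (stratified) {
      idx <- unlist(lapply(seq_along(classes), function(i) {
        rows <- which(train$label == classes[i])
        k <- round_half_up((1 - unlabeled_rate) * length(rows))
        with_seed(derive_seed(s, i), sample(rows, k))
      }))
      sort(idx)
    } else {
      k <- round_half_up((1 - unlabeled_rate) * nrow(train))
      sort(with_seed(derive_seed(s, 0L), sample.int(nrow(train), k)))
    }
  }
  idx <- draw(seed)
  tries <- 0
  while (!all(classes %in% train$label[idx]) && tries < 100) {
    tries <- tries + 1
    idx <- draw(derive_seed(seed, 997L, tries))
  }
  if (!all(classes %in% train$label[idx])) {
    abort("labeled part misses a class entirely after 100 redraws")
  }
  if (tries > 0) {
    inform(sprintf("labeled part redrawn %d time(s) to cover every class",
                   tries))
  }
  L <- train[idx, ]
  U_rows <- if (length(idx) > 0) train[-idx, ] else train
  truth <- tibble::tibble(sample_id = U_rows$sample_id,
                          true_label = U_rows$label)
  U <- dplyr::mutate(U_rows, label = NA_character_)
  list(L = L, U = U, truth = truth)
}
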