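#' Ensemble configuration for M-training
#'
#' @param M number of base classifiers, integer >= 3. With `M = 3` and
#'   `theta = 2/3` the algorithm degenerates to tri-training (a sample is
#'   pseudo-labeled for one classifier exactly when the other two agree).
#' @param theta agreement threshold: minimum fraction of the `M - 1`
#'   co-classifier votes the modal label must reach for a sample to be
#'   pseudo-labeled. Must lie in (0.5, 1] so the accepted label is the
#'   unique strict majority; default 2/3.
#' @param init_fraction fraction of L drawn (without replacement,
#'   independently per slot) as each classifier's initial training pool;
#'   default 0.75. This sampling is what makes the base classifiers
#'   diverse.
#' @param max_rounds safety cap on refinement rounds; default 50.
#' @param seed root seed; all per-slot/per-round randomness is derived
#'   from it by a fixed scheme, so runs are reproducible for any `M`.
#' @param base_spec a [classifier_spec()] for the base classifiers
#'   (default: RBF-kernel SVM at the tuned operating point).
#' @param eta_L assumed classification noise rate of the labeled pool L,
#'   in \[0, 0.5); default 0. Only used in the noise-rate diagnostics.
#' @param scheduling `"synchronous"` (default): all decisions of a round
#'   are computed against the start-of-round models, so the result does
#'   not depend on slot order; `"sequential"`: each slot's refit is
#'   visible to the later slots of the same round.
#' @param refit_pool `"slot"` (default): a refit trains on the slot's
#'   own diversified pool plus its pseudo-labels; `"full_L"`: on all of
#'   L plus the pseudo-labels.
#' @param error_on `"agreed"` (default): the committee error bound is
#'   measured on the committee-agreed part of L; `"all"`: on all of L.
#' @return an `mtrain_config` object.
#' @export
mtrain_config <- function(M = 4L, theta = 2 / 3, init_fraction = 0.75,
                          max_rounds = 50L, seed = 1L,
                          base_spec = classifier_spec("svm_rbf"),
                          eta_L = 0,
                          scheduling = c("synchronous", "sequential"),
                          refit_pool = c("slot", "full_L"),
                          error_on = c("agreed", "all")) {
  scheduling <- match.arg(scheduling)
  refit_pool <- match.arg(refit_pool)
  error_on <- match.arg(error_on)
  M <- as.integer(M)
  if (M < 3) abort("`M` must be at least 3")
  if (!(theta > 0.5 && theta <= 1)) abort("`theta` must be in (0.5, 1]")
  if (!(init_fraction > 0 && init_fraction <= 1)) {
    abort("`init_fraction` must be in (0, 1]")
  }
  if (!(eta_L >= 0 && eta_L < 0.5)) abort("`eta_L` must be in [0, 0.5)")
  stopifnot(inherits(base_spec, "classifier_spec"))
  structure(list(M = M, theta = theta, init_fraction = init_fraction,
                 max_rounds = as.integer(max_rounds),
                 seed = as.integer(seed), base_spec = base_spec,
                 eta_L = eta_L, scheduling = scheduling,
                 refit_pool = refit_pool, error_on = error_on),
            class = "mtrain_config")
}

#' @export
print.mtrain_config <- function(x, ...) {
  cat(sprintf(
    "<mtrain_config> M = %d, theta = %.4f, init_fraction = %.2f, max_rounds = %d, seed = %d, base = %s\n",
    x$M, x$theta, x$init_fraction, x$max_rounds, x$seed, x$base_spec$kind))
  invisible(x)
}

#' Initialize the ensemble
#'
#' Creates the `M` classifier slots. Each slot's initial training pool is
#' an independent draw without replacement of
#' `round_half_up(init_fraction * |L|)` samples of L (redrawn with a
#' derived seed, with a message, if a class is missing); each model is
#' fitted on its pool. Per-round error bounds start at the worst case
#' `e_prev = 0.5` with `size_prev = 0`.
#'
#' @param L labeled feature table.
#' @param config an [mtrain_config()].
#' @return list of `M` slot objects (index, pool, model, e_prev,
#'   size_prev).
#' @export
init_ensemble <- function(L, config) {
  validate_feature_table(L)
  classes <- label_order(L$label)
  k <- round_half_up(config$init_fraction * nrow(L))
  if (k < length(classes)) {
    abort(sprintf("initial pool size %d is smaller than the number of classes %d",
                  k, length(classes)))
  }
  lapply(seq_len(config$M), function(i) {
    idx <- NULL
    for (try in 0:100) {
      idx <- with_seed(derive_seed(config$seed, 11L, i, try),
                       sort(sample.int(nrow(L), k)))
      if (all(classes %in% L$label[idx])) break
      if (try == 100) abort("could not draw an initial pool covering every class")
    }
    if (!all(classes %in% L$label[idx])) {
      abort("could not draw an initial pool covering every class")
    }
    pool <- L[idx, ]
    spec <- config$base_spec
    spec$seed <- derive_seed(config$seed, 13L, i)
    list(index = i, pool = pool, spec = spec,
         model = fit_classifier(pool, spec),
         e_prev = 0.5, size_prev = 0L)
  })
}

# Votes of the co-classifier committee of slot i (all slots but i) on
# `data`; matrix rows = samples, cols = committee members.
committee_votes <- function(slots, i, data) {
  others <- slots[-i]
  vapply(others, function(s) predict(s$model, data),
         character(nrow(data)))
}

#' Propose pseudo-labels for one classifier
#'
#' For every unlabeled sample, collects the votes of the `M - 1`
#' co-classifiers of slot `i`; if the modal label's vote share reaches
#' `theta`, the sample is pseudo-labeled with that label. Because
#' `theta > 0.5`, an accepted label is always the unique strict majority.
#' The whole of U is re-examined every round: pseudo-labels from earlier
#' rounds are conceptually returned to U and never accumulate.
#'
#' @param slots slot list from [init_ensemble()].
#' @param i index of the main classifier (excluded from the vote).
#' @param U unlabeled feature table (labels ignored).
#' @param theta agreement threshold in (0.5, 1].
#' @return feature table of the accepted samples with `label` set to the
#'   agreed label and an `.agreement` column holding the vote share.
#' @export
propose_labels <- function(slots, i, U, theta) {
  empty <- dplyr::mutate(U[0, ], .agreement = numeric(0))
  if (nrow(U) == 0) return(empty)
  levels <- slots[[i]]$model$label_set
  votes <- committee_votes(slots, i, U)
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(U))
  vs <- vote_share(votes, levels)
  keep <- vs$share >= theta
  if (!any(keep)) return(empty)
  out <- U[keep, ]
  out$label <- vs$label[keep]
  out$.agreement <- vs$share[keep]
  out
}

#' Estimate the committee error bound e_i(t)
#'
#' The classification error of the committee on the unlabeled pool cannot
#' be measured, so it is estimated on the labeled pool L under the
#' assumption that L and U share one distribution: over the samples of L
#' on which the committee reaches agreement `>= theta`, the fraction
#' whose agreed label differs from the true label. If the committee never
#' reaches agreement, the worst-case value 0.5 is returned with attribute
#' `no_evidence = TRUE` (the caller must then skip the update). With
#' `on = "all"` the committee's modal label is scored on all of L
#' instead.
#'
#' @inheritParams propose_labels
#' @param L labeled feature table.
#' @param on `"agreed"` (default) or `"all"`.
#' @return the error estimate in \[0, 1\], with attributes `n_agreed` and
#'   `no_evidence`.
#' @export
estimate_error <- function(slots, i, L, theta, on = c("agreed", "all")) {
  on <- match.arg(on)
  levels <- slots[[i]]$model$label_set
  votes <- committee_votes(slots, i, L)
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(L))
  vs <- vote_share(votes, levels)
  use <- if (on == "agreed") vs$share >= theta else rep(TRUE, nrow(L))
  if (!any(use)) {
    return(structure(0.5, n_agreed = 0L, no_evidence = TRUE))
  }
  e <- mean(vs$label[use] != L$label[use])
  structure(e, n_agreed = sum(use), no_evidence = FALSE)
}

#' Refit decision with noise compensation
#'
#' Decides whether a classifier may be refit with its freshly
#' pseudo-labeled set, so that the injected classification noise strictly
#' decreases: a refit requires `e_t < e_prev`, a non-empty proposal, a
#' growing pseudo-labeled set (`size_prev < size_t`) and
#' `e_t * size_t < e_prev * size_prev`. When the last product condition
#' fails but `size_prev > e_t / (e_prev - e_t)`, the proposal can be
#' sub-sampled to `s_i = ceiling(e_prev * size_prev / e_t - 1)` entries,
#' which restores the product condition while keeping `s_i > size_prev`.
#'
#' On the first productive round (`size_prev = 0`) a virtual previous
#' size `floor(e_t / (e_prev - e_t) + 1)` is adopted (the tri-training
#' bootstrap convention) and the rules re-evaluated against it; the
#' decision is then labeled `update_with_bootstrap_prev`. `e_t = 0`
#' pseudo-labels carry no measured noise, so the sub-sampling division is
#' short-circuited to a plain update.
#'
#' @param e_t committee error bound of the current round.
#' @param e_prev error bound at the previous refit (0.5 initially).
#' @param size_t number of proposed pseudo-labels.
#' @param size_prev pseudo-label count at the previous refit (0 initially).
#' @return list with `decision` (one of `"skip"`, `"update"`,
#'   `"update_after_subsample"`, `"update_with_bootstrap_prev"`), `s_i`
#'   (subsample size or `NA`) and `virtual_prev` (the bootstrapped
#'   previous size or `NA`).
#' @examples
#' should_update(e_t = 0.1, e_prev = 0.2, size_t = 30, size_prev = 10)
#' @export
should_update <- function(e_t, e_prev, size_t, size_prev) {
  stopifnot(e_t >= 0, e_prev >= 0, size_t >= 0, size_prev >= 0)
  res <- list(decision = "skip", s_i = NA_integer_,
              virtual_prev = NA_integer_)
  if (!(e_t < e_prev) || size_t <= 0) return(res)
  bootstrap <- size_prev == 0
  if (bootstrap) {
    size_prev <- floor(e_t / (e_prev - e_t) + 1)
    res$virtual_prev <- as.integer(size_prev)
  }
  if (!(size_prev < size_t)) return(res)
  ok_label <- if (bootstrap) "update_with_bootstrap_prev" else "update"
  if (e_t == 0 || e_t * size_t < e_prev * size_prev) {
    res$decision <- ok_label
    return(res)
  }
  if (size_prev > e_t / (e_prev - e_t)) {
    res$decision <- if (bootstrap) ok_label else "update_after_subsample"
    res$s_i <- as.integer(ceiling(e_prev * size_prev / e_t - 1))
  }
  res
}

#' Randomly sub-sample a pseudo-labeled set
#'
#' Uniform draw without replacement of exactly `s_i` entries,
#' deterministic under `seed`.
#'
#' @param pseudo pseudo-labeled feature table (from [propose_labels()]).
#' @param s_i target size, `0 < s_i < nrow(pseudo)`.
#' @param seed integer seed.
#' @return the sub-sampled tibble.
#' @export
subsample_pseudo <- function(pseudo, s_i, seed) {
  if (!(s_i > 0 && s_i < nrow(pseudo))) {
    abort(sprintf("s_i must satisfy 0 < s_i < %d (got %s)",
                  nrow(pseudo), s_i))
  }
  idx <- with_seed(seed, sort(sample.int(nrow(pseudo), s_i)))
  pseudo[idx, ]
}

#' Refine one classifier slot
#'
#' Refits the slot's model on the union of its own initial pool and the
#' pseudo-labeled set (deduplicated by `sample_id`; the labeled copy
#' wins) and rolls the slot's `e_prev` / `size_prev` state forward.
#'
#' @param slot one slot of [init_ensemble()].
#' @param pseudo pseudo-labeled feature table (possibly sub-sampled).
#' @param e_t the error estimate used for this round's decision.
#' @param pool_base labeled table the pseudo-labels are joined to;
#'   defaults to the slot's own diversified pool.
#' @return the updated slot.
#' @export
refine_slot <- function(slot, pseudo, e_t, pool_base = NULL) {
  if (is.null(pool_base)) pool_base <- slot$pool
  add <- dplyr::select(pseudo, -dplyr::any_of(".agreement"))
  add <- dplyr::filter(add, !.data$sample_id %in% pool_base$sample_id)
  pool <- dplyr::bind_rows(pool_base, add)
  slot$model <- fit_classifier(pool, slot$spec)
  slot$train_pool <- pool
  slot$e_prev <- as.numeric(e_t)
  slot$size_prev <- nrow(pseudo)
  slot
}

#' Run M-training
#'
#' Executes the full semi-supervised loop: initialize `M` diversified
#' base classifiers on L, then repeat rounds in which each classifier's
#' committee error is estimated on L, unlabeled samples are
#' pseudo-labeled by committee agreement, the noise-compensation decision
#' of [should_update()] is taken (with optional sub-sampling), and the
#' accepted slots are refit. All decisions of a round are computed
#' against the start-of-round models (synchronous update). The loop stops
#' at the first round with no refit (fixed point) or at
#' `config$max_rounds`.
#'
#' @param L labeled feature table (the pool the learner may trust).
#' @param U unlabeled feature table (labels, if any, are ignored).
#' @param config an [mtrain_config()].
#' @return an object of class `mtrain_fit` with elements `slots` (final),
#'   `initial_slots`, `history` (one row per round and slot; see
#'   [tidy.mtrain_fit()]), `termination` (`"fixed_point"` or
#'   `"max_rounds"`), `rounds`, `label_set` and `config`.
#' @examples
#' bench <- benchmark_split(seed = 1, unlabeled_rate = 0.5)
#' cfg <- mtrain_config(M = 3, seed = 1,
#'                      base_spec = classifier_spec("nearest_centroid"))
#' fit <- mtrain(bench$L, bench$U, cfg)
#' glance(fit)
#' @export
mtrain <- function(L, U, config = mtrain_config()) {
  stopifnot(inherits(config, "mtrain_config"))
  validate_feature_table(L)
  if (nrow(U) > 0) {
    U <- dplyr::mutate(U, label = NA_character_)
    if (any(U$sample_id %in% L$sample_id)) {
      abort("L and U share sample_id values")
    }
  }
  label_set <- label_order(L$label)
  slots <- init_ensemble(L, config)
  initial_slots <- slots
  history <- list()
  termination <- "max_rounds"
  rounds <- 0L
  for (t in seq_len(config$max_rounds)) {
    rounds <- t
    snapshot <- slots
    run_slot <- function(i) {
      # synchronous: decisions read the start-of-round models, so the
      # outcome is invariant to slot order
      ref <- if (config$scheduling == "synchronous") snapshot else slots
      slot <- slots[[i]]
      e_info <- estimate_error(ref, i, L, config$theta,
                               on = config$error_on)
      e_t <- as.numeric(e_info)
      pseudo <- if (e_t < slot$e_prev) {
        propose_labels(ref, i, U, config$theta)
      } else {
        U[0, ]
      }
      dec <- should_update(e_t, slot$e_prev, nrow(pseudo), slot$size_prev)
      list(i = i, e_t = e_t, no_evidence = attr(e_info, "no_evidence"),
           pseudo = pseudo, dec = dec)
    }
    changed <- FALSE
    for (i in seq_len(config$M)) {
      p <- run_slot(i)
      slot <- slots[[p$i]]
      pool_before <- if (is.null(slot$train_pool)) nrow(slot$pool) else nrow(slot$train_pool)
      e_prev <- slot$e_prev
      size_prev_eff <- if (!is.na(p$dec$virtual_prev)) {
        p$dec$virtual_prev
      } else {
        slot$size_prev
      }
      size_used <- NA_integer_
      pool_after <- pool_before
      if (p$dec$decision != "skip") {
        ps <- p$pseudo
        if (!is.na(p$dec$s_i)) {
          ps <- subsample_pseudo(ps, p$dec$s_i,
                                 derive_seed(config$seed, 31L, t, p$i))
        }
        base <- if (config$refit_pool == "full_L") L else slot$pool
        slots[[p$i]] <- refine_slot(slot, ps, p$e_t, pool_base = base)
        size_used <- nrow(ps)
        pool_after <- nrow(slots[[p$i]]$train_pool)
        changed <- TRUE
      }
      u_prev <- utility_u(nrow(L) + size_prev_eff,
                          noise_rate(config$eta_L, nrow(L), e_prev,
                                     size_prev_eff))
      u_t <- if (is.na(size_used)) NA_real_ else {
        utility_u(nrow(L) + size_used,
                  noise_rate(config$eta_L, nrow(L), p$e_t, size_used))
      }
      size_prev_real <- slot$size_prev
      history[[length(history) + 1]] <- tibble::tibble(
        round = t, slot = p$i, e_prev = e_prev,
        size_prev = size_prev_real, virtual_prev = p$dec$virtual_prev,
        e_t = p$e_t, no_evidence = p$no_evidence,
        size_proposed = nrow(p$pseudo), decision = p$dec$decision,
        s_i = p$dec$s_i, size_used = size_used,
        pool_before = pool_before, pool_after = pool_after,
        u_prev = u_prev, u_t = u_t
      )
    }
    if (!changed) {
      termination <- "fixed_point"
      break
    }
  }
  structure(list(slots = slots, initial_slots = initial_slots,
                 history = dplyr::bind_rows(history),
                 termination = termination, rounds = rounds,
                 label_set = label_set, config = config,
                 n_L = nrow(L), n_U = nrow(U)),
            class = "mtrain_fit")
}

#' Predict with the ensemble
#'
#' Plurality vote over all `M` base classifiers; ties are broken by the
#' lowest label in the fixed (sorted) label ordering.
#'
#' @param object an `mtrain_fit`.
#' @param newdata feature table.
#' @param stage `"final"` (default, after refinement) or `"initial"`
#'   (the ensemble as fitted on L only).
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.mtrain_fit <- function(object, newdata,
                               stage = c("final", "initial"), ...) {
  stage <- match.arg(stage)
  slots <- if (stage == "final") object$slots else object$initial_slots
  if (nrow(newdata) == 0) return(character(0))
  votes <- vapply(slots, function(s) predict(s$model, newdata),
                  character(nrow(newdata)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(newdata))
  vote_modal(votes, object$label_set)
}

#' @export
print.mtrain_fit <- function(x, ...) {
  cat(sprintf(
    "<mtrain_fit> M = %d (%s), |L| = %d, |U| = %d, %d round(s), %s\n",
    x$config$M, x$config$base_spec$kind, x$n_L, x$n_U, x$rounds,
    x$termination))
  pools <- vapply(x$slots, function(s) {
    if (is.null(s$train_pool)) nrow(s$pool) else nrow(s$train_pool)
  }, numeric(1))
  cat("final training pools:", paste(pools, collapse = ", "), "\n")
  invisible(x)
}

#' Combined classification noise rate of a training pool
#'
#' Mixes the assumed label-noise rate of the labeled pool with the
#' measured pseudo-label error of the added set:
#' `(eta_L * size_L + e * size_pseudo) / (size_L + size_pseudo)`.
#'
#' @param eta_L assumed noise rate of L.
#' @param size_L size of L.
#' @param e pseudo-label error bound of the round.
#' @param size_pseudo number of pseudo-labeled samples.
#' @return the combined noise rate.
#' @export
noise_rate <- function(eta_L, size_L, e, size_pseudo) {
  if (size_L + size_pseudo <= 0) abort("empty pool has no noise rate")
  (eta_L * size_L + e * size_pseudo) / (size_L + size_pseudo)
}

#' Training utility under classification noise
#'
#' The quantity `u = m * (1 - 2 * eta)^2` for a pool of `m` samples with
#' noise rate `eta`: by the worst-case error bound for learning under
#' classification noise, a refit helps exactly when `u` increases, so the
#' run history records it per round as a diagnostic.
#'
#' @param m training pool size.
#' @param eta classification noise rate.
#' @return the utility value.
#' @export
utility_u <- function(m, eta) {
  stopifnot(m >= 0)
  m * (1 - 2 * eta)^2
}
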