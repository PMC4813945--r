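# Small programmatic fixtures shared across test files.

# A labeled feature table of `n` samples per class, classes at the given
# 2-D means with isotropic Gaussian noise.
make_blobs <- function(means, n = 10, sd = 0.3, seed = 1,
                       prefix = "s") {
  labs <- names(means)
  withr::with_seed(seed, {
    rows <- lapply(labs, function(l) {
      mu <- means[[l]]
      tibble::tibble(
        sample_id = paste0(prefix, "_", l, "_", seq_len(n)),
        x1 = rnorm(n, mu[1], sd), x2 = rnorm(n, mu[2], sd),
        label = l, concentration = NA_real_
      )
    })
    dplyr::bind_rows(rows)
  })
}

# Two well-separated classes; any sensible classifier fits them exactly.
separable_blobs <- function(n = 10, seed = 1) {
  make_blobs(list(a = c(0, 0), b = c(8, 8)), n = n, seed = seed)
}

# A feature table with explicit feature values and labels (4-D default).
make_table <- function(features, labels, ids = NULL) {
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(features)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = ids),
    tibble::as_tibble(features),
    tibble::tibble(label = labels, concentration = NA_real_)
  )
}

# Slots whose models emit scripted predictions (sample_id -> label),
# for exact control over committee votes.
fixed_slots <- function(vote_maps, label_set) {
  lapply(seq_along(vote_maps), function(i) {
    list(index = i,
         model = mtraining:::fixed_classifier(vote_maps[[i]], label_set))
  })
}

# An unlabeled pool with the given ids (features irrelevant for fixed
# slots but present for schema validity).
make_U <- function(ids) {
  tibble::tibble(sample_id = ids, f1 = seq_along(ids) * 1.0,
                 label = NA_character_, concentration = NA_real_)
}

# Independent brute-force oracle for tri-training pseudo-labeling: with
# three classifiers, sample u is labeled for classifier i exactly when
# the other two agree, with their common label.
tritrain_oracle <- function(votes_others) {
  agree <- votes_others[, 1] == votes_others[, 2]
  list(accept = agree, label = ifelse(agree, votes_others[, 1], NA))
}
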