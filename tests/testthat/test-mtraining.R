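test_that("initial pools have round-half-up size and every slot is fitted", {
  bench <- benchmark_split(seed = 2, unlabeled_rate = 0.5)
  cfg <- mtrain_config(M = 4, seed = 3,
                       base_spec = classifier_spec("nearest_centroid"))
  slots <- init_ensemble(bench$L, cfg)
  expect_length(slots, 4)
  for (s in slots) {
    expect_equal(nrow(s$pool), 149)  # 0.75 * 198 = 148.5 -> 149
    expect_length(label_order(s$pool$label), 3)
    expect_s3_class(s$model, "mtrain_classifier")
    expect_equal(s$e_prev, 0.5)
    expect_equal(s$size_prev, 0L)
  }
  # pools are diversified: not all identical
  ids <- lapply(slots, function(s) sort(s$pool$sample_id))
  expect_gt(length(unique(ids)), 1)

  small <- benchmark_split(seed = 2, unlabeled_rate = 0.75)
  slots99 <- init_ensemble(small$L, cfg)
  expect_equal(nrow(slots99[[1]]$pool), 74)  # 0.75 * 99 = 74.25 -> 74
})

test_that("init_fraction 1 gives every slot the full labeled pool", {
  d <- separable_blobs(n = 10, seed = 4)
  cfg <- mtrain_config(M = 3, init_fraction = 1, seed = 1,
                       base_spec = classifier_spec("nearest_centroid"))
  slots <- init_ensemble(d, cfg)
  for (s in slots) expect_setequal(s$pool$sample_id, d$sample_id)
})

test_that("pseudo-labels follow the committee agreement threshold", {
  U <- make_U(c("u1"))
  # M = 4: committee of slot 1 is slots 2-4 voting {1, 2, 1}: share 2/3
  slots4 <- fixed_slots(list(c(u1 = "9"), c(u1 = "1"), c(u1 = "2"),
                             c(u1 = "1")), label_set = c("1", "2", "9"))
  p <- propose_labels(slots4, 1, U, theta = 2 / 3)
  expect_equal(nrow(p), 1)
  expect_equal(p$label, "1")
  expect_equal(p$.agreement, 2 / 3)

  # M = 3: committee {1, 2} disagrees: max share 1/2 < 2/3 -> rejected,
  # which is exactly tri-training's unanimity-of-two rule
  slots3 <- fixed_slots(list(c(u1 = "9"), c(u1 = "1"), c(u1 = "2")),
                        label_set = c("1", "2", "9"))
  expect_equal(nrow(propose_labels(slots3, 1, U, theta = 2 / 3)), 0)

  # identical constant co-classifiers accept everything with share 1
  U5 <- make_U(paste0("u", 1:5))
  const <- setNames(rep("2", 5), U5$sample_id)
  slotsC <- fixed_slots(list(const, const, const, const),
                        label_set = c("1", "2"))
  pC <- propose_labels(slotsC, 2, U5, theta = 1)
  expect_equal(nrow(pC), 5)
  expect_true(all(pC$.agreement == 1))
  expect_true(all(pC$label == "2"))

  # empty U proposes nothing
  expect_equal(nrow(propose_labels(slots4, 1, U5[0, ], 2 / 3)), 0)
})

test_that("raising theta never enlarges the accepted set", {
  withr::local_seed(5)
  for (rep in 1:10) {
    n <- 40
    ids <- paste0("u", 1:n)
    U <- make_U(ids)
    maps <- lapply(1:4, function(i) {
      setNames(sample(c("a", "b", "c"), n, replace = TRUE), ids)
    })
    slots <- fixed_slots(maps, label_set = c("a", "b", "c"))
    sizes <- vapply(c(0.55, 2 / 3, 0.9, 1), function(th) {
      nrow(propose_labels(slots, 1, U, th))
    }, numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("committee error is counted over agreed samples only", {
  # L of 10; committee (2 voters, theta 2/3 -> unanimity) agrees on 6,
  # and 2 of those agreed labels are wrong -> e = 2/6
  ids <- paste0("l", 1:10)
  truth <- setNames(rep(c("a", "b"), each = 5), ids)
  v1 <- truth
  v1[c("l7", "l8")] <- "a"     # wrong but agreed
  v1[c("l1", "l2", "l3", "l4")] <- c("a", "a", "a", "a")
  v2 <- v1
  v2[c("l1", "l2", "l3", "l4")] <- c("b", "b", "b", "b")  # disagree on 4
  L <- make_table(matrix(seq_len(20), ncol = 2), labels = unname(truth),
                  ids = ids)
  slots <- fixed_slots(list(setNames(rep("a", 10), ids), v1, v2),
                       label_set = c("a", "b"))
  e <- estimate_error(slots, 1, L, theta = 2 / 3)
  expect_equal(as.numeric(e), 2 / 6)
  expect_equal(attr(e, "n_agreed"), 6L)
  expect_false(attr(e, "no_evidence"))

  # perfect committee -> 0
  perfect <- fixed_slots(list(v1, truth, truth), label_set = c("a", "b"))
  expect_equal(as.numeric(estimate_error(perfect, 1, L, 2 / 3)), 0)

  # committee that never agrees -> worst case 0.5 with no-evidence marker
  opp <- setNames(ifelse(truth == "a", "b", "a"), ids)
  never <- fixed_slots(list(v1, truth, opp), label_set = c("a", "b"))
  e0 <- estimate_error(never, 1, L, 2 / 3)
  expect_equal(as.numeric(e0), 0.5)
  expect_true(attr(e0, "no_evidence"))
})

test_that("the refit decision implements the noise-compensation rules", {
  # direct evaluation of the sub-sampling size rule
  d1 <- should_update(e_t = 0.1, e_prev = 0.2, size_t = 30, size_prev = 10)
  expect_equal(d1$decision, "update_after_subsample")
  expect_equal(d1$s_i, 19L)  # ceiling(0.2 * 10 / 0.1 - 1)

  # product condition satisfied outright
  d2 <- should_update(e_t = 0.05, e_prev = 0.2, size_t = 30, size_prev = 10)
  expect_equal(d2$decision, "update")
  expect_true(is.na(d2$s_i))

  # error did not decrease -> skip
  expect_equal(should_update(0.2, 0.2, 30, 10)$decision, "skip")
  expect_equal(should_update(0.3, 0.2, 30, 10)$decision, "skip")
  # nothing proposed -> skip
  expect_equal(should_update(0.1, 0.2, 0, 10)$decision, "skip")
  # pseudo-set must grow
  expect_equal(should_update(0.1, 0.2, 10, 10)$decision, "skip")

  # first productive round: virtual previous size, then re-evaluated
  d3 <- should_update(e_t = 0.1, e_prev = 0.5, size_t = 100, size_prev = 0)
  expect_equal(d3$decision, "update_with_bootstrap_prev")
  expect_equal(d3$virtual_prev, 1L)  # floor(0.1/0.4 + 1)
  expect_equal(d3$s_i, 4L)           # ceiling(0.5 * 1 / 0.1 - 1)

  # zero measured error short-circuits the division guard
  d4 <- should_update(e_t = 0, e_prev = 0.5, size_t = 100, size_prev = 0)
  expect_equal(d4$decision, "update_with_bootstrap_prev")
  expect_true(is.na(d4$s_i))
})

test_that("sub-sampling sizes satisfy the two-sided noise bound", {
  withr::local_seed(6)
  for (rep in 1:200) {
    e_prev <- runif(1, 0.02, 0.5)
    e_t <- runif(1, 0.001, e_prev * 0.999)
    size_prev <- sample(1:60, 1)
    size_t <- size_prev + sample(1:300, 1)
    d <- should_update(e_t, e_prev, size_t, size_prev)
    if (d$decision == "update_after_subsample") {
      expect_lt(e_t * d$s_i, e_prev * size_prev)      # noise decreases
      expect_gt(d$s_i, size_prev)                     # set still grows
      expect_lt(d$s_i, size_t)                        # real sub-sample
    }
    if (d$decision == "update") {
      expect_true(e_t == 0 || e_t * size_t < e_prev * size_prev)
    }
  }
})

test_that("subsample_pseudo draws exact, reproducible subsets", {
  pseudo <- make_U(paste0("u", 1:30))
  pseudo$label <- "a"
  pseudo$.agreement <- 1
  s <- subsample_pseudo(pseudo, 19, seed = 7)
  expect_equal(nrow(s), 19)
  expect_true(all(s$sample_id %in% pseudo$sample_id))
  expect_identical(subsample_pseudo(pseudo, 19, seed = 7), s)
  expect_false(identical(subsample_pseudo(pseudo, 19, seed = 8), s))
  expect_equal(nrow(subsample_pseudo(pseudo, 29, seed = 1)), 29)
  expect_error(subsample_pseudo(pseudo, 30, seed = 1), "s_i")
  expect_error(subsample_pseudo(pseudo, 0, seed = 1), "s_i")
})

test_that("refinement unions the slot pool with the pseudo-labels", {
  withr::local_seed(8)
  pool <- make_table(matrix(rnorm(149 * 4), ncol = 4),
                     labels = sample(c("a", "b", "c"), 149, replace = TRUE),
                     ids = paste0("p", 1:149))
  slot <- list(index = 1, pool = pool,
               spec = classifier_spec("nearest_centroid"),
               model = fit_classifier(pool, classifier_spec("nearest_centroid")),
               e_prev = 0.5, size_prev = 0L)
  pseudo <- make_table(matrix(rnorm(454 * 4), ncol = 4),
                       labels = sample(c("a", "b", "c"), 454, replace = TRUE),
                       ids = paste0("u", 1:454))
  pseudo$.agreement <- 1
  refined <- refine_slot(slot, pseudo, e_t = 0.05)
  expect_equal(nrow(refined$train_pool), 603)  # 149 + 454
  expect_equal(refined$e_prev, 0.05)
  expect_equal(refined$size_prev, 454L)

  # duplicated sample_id: the labeled copy from the pool wins
  dup <- pseudo[1:10, ]
  dup$sample_id <- pool$sample_id[1:10]
  dup$label <- "c"
  refined2 <- refine_slot(slot, dplyr::bind_rows(pseudo[11:20, ], dup), 0.1)
  expect_equal(nrow(refined2$train_pool), 159)
  kept <- dplyr::filter(refined2$train_pool,
                        .data$sample_id %in% pool$sample_id[1:10])
  expect_identical(kept$label, pool$label[1:10])
})

test_that("noise rate and utility follow their closed forms", {
  expect_equal(noise_rate(0, 100, 0, 50), 0)
  expect_equal(noise_rate(0, 100, 0.1, 50), 5 / 150)
  expect_equal(noise_rate(0.2, 10, 0.1, 0), 0.2)
  expect_error(noise_rate(0, 0, 0.1, 0), "empty")
  expect_equal(utility_u(123, 0.5), 0)
  expect_equal(utility_u(100, 0), 100)
  # compound form: utility of the mixed pool equals m(1 - 2 eta)^2 with
  # eta from the mixture formula, checked on random inputs
  withr::local_seed(9)
  for (rep in 1:20) {
    nL <- sample(10:200, 1); np <- sample(0:200, 1)
    etaL <- runif(1, 0, 0.4); e <- runif(1, 0, 0.5)
    eta <- noise_rate(etaL, nL, e, np)
    m <- nL + np
    expect_equal(utility_u(m, eta),
                 m * (1 - 2 * (etaL * nL + e * np) / m)^2)
  }
})

test_that("a run with no unlabeled data is a fixed point after one round", {
  d <- separable_blobs(n = 12, seed = 10)
  cfg <- mtrain_config(M = 3, seed = 1,
                       base_spec = classifier_spec("nearest_centroid"))
  fit <- mtrain(d, d[0, ], cfg)
  expect_equal(fit$rounds, 1L)
  expect_equal(fit$termination, "fixed_point")
  expect_true(all(fit$history$decision == "skip"))
  probe <- separable_blobs(n = 5, seed = 77)
  expect_identical(predict(fit, probe, stage = "final"),
                   predict(fit, probe, stage = "initial"))
})

test_that("runs are deterministic and the last round is all-skip", {
  bench <- benchmark_split(seed = 4, unlabeled_rate = 0.5)
  cfg <- mtrain_config(M = 4, seed = 4)
  f1 <- mtrain(bench$L, bench$U, cfg)
  f2 <- mtrain(bench$L, bench$U, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, bench$test), predict(f2, bench$test))
  if (f1$termination == "fixed_point") {
    last <- dplyr::filter(f1$history, .data$round == max(.data$round))
    expect_true(all(last$decision == "skip"))
  }
})

test_that("ensemble voting is plurality with lowest-label tie-break", {
  ids <- c("q1", "q2", "q3")
  maps <- list(c(q1 = "a", q2 = "a", q3 = "x"),
               c(q1 = "a", q2 = "a", q3 = "x"),
               c(q1 = "b", q2 = "b", q3 = "x"),
               c(q1 = "c", q2 = "b", q3 = "x"))
  fit <- structure(list(
    slots = fixed_slots(maps, c("a", "b", "c", "x")),
    initial_slots = NULL, label_set = c("a", "b", "c", "x")
  ), class = "mtrain_fit")
  got <- predict(fit, make_U(ids))
  expect_equal(got[1], "a")  # (a,a,b,c) -> strict plurality
  expect_equal(got[2], "a")  # (a,a,b,b) -> tie, lowest label
  expect_equal(got[3], "x")  # unanimous
})

test_that("the full loop runs with any base classifier kind", {
  bench <- benchmark_split(seed = 6, unlabeled_rate = 0.5)
  for (kind in c("nearest_centroid", "svm_rbf")) {
    cfg <- mtrain_config(M = 3, seed = 2,
                         base_spec = classifier_spec(kind))
    fit <- mtrain(bench$L, bench$U, cfg)
    expect_s3_class(fit, "mtrain_fit")
    expect_true(fit$termination %in% c("fixed_point", "max_rounds"))
    refits <- dplyr::filter(fit$history, .data$decision != "skip")
    if (nrow(refits) > 0) {
      prev_eff <- ifelse(is.na(refits$virtual_prev), refits$size_prev,
                         refits$virtual_prev)
      expect_true(all(refits$e_t * refits$size_used <
                        refits$e_prev * prev_eff))
    }
  }
})

test_that("configuration invariants are enforced", {
  expect_error(mtrain_config(M = 2), "at least 3")
  expect_error(mtrain_config(theta = 0.5), "theta")
  expect_error(mtrain_config(theta = 1.1), "theta")
  expect_error(mtrain_config(init_fraction = 0), "init_fraction")
  expect_error(mtrain_config(eta_L = 0.5), "eta_L")
})

test_that("alternative scheduling, refit-pool and estimator options work", {
  bench <- benchmark_split(seed = 12, unlabeled_rate = 0.5)
  base <- classifier_spec("nearest_centroid")

  seq_cfg <- mtrain_config(M = 3, seed = 12, base_spec = base,
                           scheduling = "sequential")
  f_seq <- mtrain(bench$L, bench$U, seq_cfg)
  expect_true(f_seq$termination %in% c("fixed_point", "max_rounds"))
  expect_identical(mtrain(bench$L, bench$U, seq_cfg)$history, f_seq$history)

  full_cfg <- mtrain_config(M = 3, seed = 12, base_spec = base,
                            refit_pool = "full_L")
  f_full <- mtrain(bench$L, bench$U, full_cfg)
  refits <- dplyr::filter(f_full$history, .data$decision != "skip")
  if (nrow(refits) > 0) {
    # L and U are id-disjoint, so the refit pool is |L| + pseudo-labels
    expect_equal(refits$pool_after, nrow(bench$L) + refits$size_used)
  }

  slots <- init_ensemble(bench$L, mtrain_config(M = 3, seed = 12,
                                                base_spec = base))
  e_all <- estimate_error(slots, 1, bench$L, theta = 2 / 3, on = "all")
  votes <- mtraining:::committee_votes(slots, 1, bench$L)
  modal <- mtraining:::vote_modal(votes, slots[[1]]$model$label_set)
  expect_equal(as.numeric(e_all), mean(modal != bench$L$label))
  expect_equal(attr(e_all, "n_agreed"), nrow(bench$L))
})
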