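test_that("pseudo-count and schedule arithmetic match hand computation", {
  expect_identical(n_pseudo(460, 0.1), 46L)
  expect_identical(n_pseudo(12345, 0), 0L)
  expect_identical(n_pseudo(100, 0.333), 33L)
  expect_error(n_pseudo(10, 1.2), class = "hsal_error_validation")

  expect_equal(update_p(0.05, 0, 0.02), 0.05)
  expect_equal(update_p(0.11, 3, 0.02), 0.17)
  expect_equal(update_p(0.94, 5, 0.1, p_max = 0.95), 0.95)

  # grid check against direct arithmetic
  for (n in c(10, 57, 460)) {
    for (p in c(0, 0.17, 0.5, 1)) {
      expect_identical(n_pseudo(n, p), as.integer(floor(n * p)))
    }
  }
  for (p in c(0, 0.3)) {
    for (k in 0:4) {
      for (delta in c(0, 0.01, 0.2)) {
        expect_equal(update_p(p, k, delta, 1), min(p + delta * k, 1))
      }
    }
  }
})

test_that("initialization seeds the labeled set reproducibly", {
  w <- scripted_world(n_train = 60, n_test = 6)
  cfg <- loop_config(K = 5, seed = 11, max_iterations = 0)
  run1 <- run_active_learning(w$manifest, cfg, w$oracle, w$backend, w$cubes)
  expect_identical(length(run1$XM), 5L)
  expect_identical(nrow(run1$history), 1L)
  expect_identical(run1$history$n_unlabeled, 55L)
  expect_identical(run1$manual_count, 5L)

  run2 <- run_active_learning(w$manifest, cfg, scripted_world(60, 6)$oracle,
                              w$backend, w$cubes)
  expect_identical(names(run1$XM), names(run2$XM))

  expect_error(
    run_active_learning(w$manifest, loop_config(K = 61), w$oracle,
                        w$backend, w$cubes),
    class = "hsal_error_validation"
  )
})

test_that("algorithm 1 bookkeeping follows the per-pass contract", {
  w <- scripted_world(n_train = 50, n_test = 6)
  cfg <- loop_config(K = 5, p0 = 0.2, delta = 0.01, criterion = "entropy",
                     algorithm = "alg1", seed = 3, max_iterations = 4)
  run <- run_active_learning(w$manifest, cfg, w$oracle, w$backend, w$cubes)
  h <- run$history
  expect_identical(h$iteration, 0:4)
  # manual_count after t passes is K * (t + 1): no free labels in alg 1
  expect_identical(h$manual_count, 5L * (1:5))
  expect_identical(h$n_manual_total, h$manual_count)
  # XU shrinks by exactly K per pass; pool unused
  expect_identical(h$n_unlabeled, 45L - 5L * (0:4))
  expect_true(all(h$n_pool == 0L))
  # test accuracy column is populated from the scripted predictions
  expect_true(all(h$accuracy >= 0 & h$accuracy <= 1))
})

test_that("identical scripted probabilities give identical traces", {
  w <- scripted_world(n_train = 40, n_test = 8)
  cfg <- loop_config(K = 4, algorithm = "alg1", seed = 9,
                     max_iterations = 5)
  t1 <- run_active_learning(w$manifest, cfg, w$oracle, w$backend, w$cubes)
  t2 <- run_active_learning(w$manifest, cfg, scripted_world(40, 8)$oracle,
                            w$backend, w$cubes)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$XM, t2$XM)
})

test_that("pseudo-labeled ids are transient and return to the unlabeled set", {
  w <- scripted_world(n_train = 30, n_test = 6)
  cfg <- loop_config(K = 3, p0 = 0.3, algorithm = "alg1", seed = 2,
                     max_iterations = 3)
  run <- run_active_learning(w$manifest, cfg, w$oracle, w$backend, w$cubes)
  h <- run$history
  # every pass pseudo-labels floor(n_train * p) (capped), yet XU only loses K
  expect_true(all(h$n_pseudo[-1] > 0))
  expect_identical(h$n_unlabeled, 27L - 3L * (0:3))
})

test_that("algorithm 2 banks associates and draws from the pool for free", {
  # 24 train ids in groups of 6, scripted predictions
  w <- scripted_world(n_train = 24, n_test = 6, group_size = 6, seed = 13)
  cfg <- loop_config(K = 4, p0 = 0, delta = 0, algorithm = "alg2",
                     criterion = "entropy", seed = 5, max_iterations = 1)
  run <- run_active_learning(w$manifest, cfg, w$oracle, w$backend, w$cubes)
  h <- run$history
  # pass 1: pool below K, so manual annotation happened; all four groups
  # were touched at init or now, associates banked at zero charge
  expect_identical(h$n_pool[1], 0L)
  expect_gt(h$n_pool[2], 0L)
  expect_identical(
    h$n_pool[2] + h$n_manual_total[2] + h$n_unlabeled[2], 24L
  )
  # charges never exceed the algorithm-1 schedule
  expect_lte(h$manual_count[2], 8L)

  # when the pool holds at least K, a draw replaces annotation: no charge
  cfg2 <- loop_config(K = 2, p0 = 0, delta = 0, algorithm = "alg2",
                      criterion = "entropy", seed = 5, max_iterations = 6)
  run2 <- run_active_learning(w$manifest, cfg2, scripted_world(
    n_train = 24, n_test = 6, group_size = 6, seed = 13)$oracle,
    w$backend, w$cubes)
  h2 <- run2$history
  draw_passes <- which(diff(h2$n_pool) < 0 & diff(h2$manual_count) == 0)
  expect_gt(length(draw_passes), 0)
  # pool draws enlarge the labeled set without touching the charge ledger
  for (t in draw_passes) {
    expect_identical(h2$n_manual_total[t + 1] - h2$n_manual_total[t],
                     h2$n_pool[t] - h2$n_pool[t + 1])
  }
})

test_that("a single physical sample's variants cost one annotation in alg 2", {
  # one group of 6 whose variants tie in certainty: the batch is the group,
  # charged once, remaining variants banked
  w <- scripted_world(n_train = 12, n_test = 4, group_size = 6, seed = 21)
  # constant probabilities: every id ties, ranking falls back to id order
  const <- matrix(0.5, nrow = 16, ncol = 2,
                  dimnames = list(w$manifest$sample_id, NULL))
  backend <- scripted_backend(const)
  cfg <- loop_config(K = 6, p0 = 0, delta = 0, algorithm = "alg2",
                     criterion = "entropy", seed = 1, max_iterations = 1)
  run <- run_active_learning(w$manifest, cfg, w$oracle, backend, w$cubes)
  h <- run$history
  # a group's label is paid at most once: init charges one annotation per
  # distinct physical sample drawn, the pass only pays for groups not
  # already known
  init_ids <- names(run$XM)[1:6]
  train_ids <- w$manifest$sample_id[w$manifest$split == "train"]
  group_of <- setNames(w$manifest$group_id, w$manifest$sample_id)
  init_groups <- unique(unname(group_of[init_ids]))
  expect_identical(h$manual_count[1], length(init_groups))
  batch <- setdiff(train_ids, init_ids)
  new_groups <- setdiff(unique(unname(group_of[batch])), init_groups)
  expect_identical(h$manual_count[2],
                   length(init_groups) + length(new_groups))
  expect_identical(h$n_manual_total[2], 12L)
  # the whole 12-image training set (2 physical samples) cost at most 2
  expect_lte(h$manual_count[2], 2L)
})

test_that("partition and cost invariants hold across a long synthetic run", {
  w <- scripted_world(n_train = 60, n_test = 10, group_size = 6, seed = 17)
  train_ids <- w$manifest$sample_id[w$manifest$split == "train"]
  for (alg in c("alg1", "alg2")) {
    cfg <- loop_config(K = 3, p0 = 0.1, delta = 0.02, algorithm = alg,
                       criterion = "least_confidence", seed = 23,
                       max_iterations = 20)
    run <- run_active_learning(w$manifest, cfg, scripted_world(
      n_train = 60, n_test = 10, group_size = 6, seed = 17)$oracle,
      w$backend, w$cubes)
    h <- run$history
    # manual + pool + unlabeled always partition the training set
    expect_true(all(h$n_manual_total + h$n_pool + h$n_unlabeled == 60L))
    # charges and labeled set are monotone; pool never overlaps them
    expect_true(all(diff(h$manual_count) >= 0))
    expect_true(all(diff(h$n_manual_total) >= 0))
    expect_identical(length(run$XM) + run$history$n_unlabeled[nrow(h)] +
                       run$history$n_pool[nrow(h)], 60L)
    expect_true(all(names(run$XM) %in% train_ids))
    if (alg == "alg1") {
      expect_identical(h$manual_count, h$n_manual_total)
      alg1_cost <- h$manual_count
    } else {
      # cost dominance under identical seeds and predictions
      shared <- seq_len(min(length(alg1_cost), nrow(h)))
      expect_true(all(h$manual_count[shared] <= alg1_cost[shared]))
    }
  }
})

test_that("schedule is non-decreasing and capped during a run", {
  w <- scripted_world(n_train = 40, n_test = 6)
  cfg <- loop_config(K = 2, p0 = 0.5, delta = 0.2, p_max = 0.9,
                     algorithm = "alg1", seed = 2, max_iterations = 10)
  run <- run_active_learning(w$manifest, cfg, w$oracle, w$backend, w$cubes)
  p <- run$history$p
  expect_true(all(diff(p) >= 0))
  expect_true(all(p <= 0.9 + 1e-12))
})

test_that("runs terminate on exhaustion with the full set annotated", {
  w <- scripted_world(n_train = 20, n_test = 4)
  cfg <- loop_config(K = 3, algorithm = "alg1", seed = 8,
                     max_iterations = 100)
  run <- run_active_learning(w$manifest, cfg, w$oracle, w$backend, w$cubes)
  expect_identical(run$history$n_unlabeled[nrow(run$history)], 0L)
  expect_identical(length(run$XM), 20L)
  # final partial pass annotated the remainder (20 = 3 * 6 + 2)
  expect_identical(run$manual_count, 20L)

  # the pool is drained too under alg2 before stopping
  w2 <- scripted_world(n_train = 24, n_test = 4, group_size = 6, seed = 3)
  run2 <- run_active_learning(w2$manifest,
                              loop_config(K = 3, algorithm = "alg2",
                                          seed = 8, max_iterations = 100),
                              w2$oracle, w2$backend, w2$cubes)
  last <- run2$history[nrow(run2$history), ]
  expect_identical(last$n_unlabeled, 0L)
  expect_identical(last$n_pool, 0L)
  expect_identical(length(run2$XM), 24L)
  expect_lt(run2$manual_count, 24L)
})

test_that("evaluation reports accuracy and conserved confusion counts", {
  probs <- rbind(diag(2)[rep(1:2, 10), ])
  ids <- sprintf("e%02d", 1:20)
  rownames(probs) <- ids
  b <- scripted_backend(probs)
  st <- classifier_fit(b, NULL, setNames(vector("list", 2), ids[1:2]),
                       setNames(0:1, ids[1:2]))
  cubes <- setNames(vector("list", 20), ids)
  truth <- setNames(rep(0:1, 10), ids)
  ev <- evaluate_classifier(b, st, cubes, truth)
  expect_identical(ev$accuracy, 1)
  expect_identical(sum(ev$confusion), 20L)

  # an all-one-class predictor on a balanced set scores 0.5
  onecls <- matrix(rep(c(1, 0), each = 20), ncol = 2,
                   dimnames = list(ids, NULL))
  b2 <- scripted_backend(onecls)
  ev2 <- evaluate_classifier(b2, classifier_fit(b2, NULL, cubes[1:2],
                                                setNames(0:1, ids[1:2])),
                             cubes, truth)
  expect_identical(ev2$accuracy, 0.5)
  expect_identical(sum(ev2$confusion), 20L)

  expect_error(evaluate_classifier(b, st, list(), integer(0)),
               class = "hsal_error_validation")
})

test_that("annotation curves convert charges to monotone percentages", {
  w <- scripted_world(n_train = 30, n_test = 5, group_size = 6, seed = 29)
  cfg1 <- loop_config(K = 3, algorithm = "alg1", seed = 4,
                      max_iterations = 5)
  run1 <- run_active_learning(w$manifest, cfg1, w$oracle, w$backend,
                              w$cubes)
  curve1 <- annotation_curve(run1)
  # alg1 increments are a constant K / n_train_original per pass
  expect_equal(unique(diff(curve1$manual_pct)), 100 * 3 / 5,
               tolerance = 1e-9)
  expect_true(all(diff(curve1$manual_pct) >= 0))

  # alg2 curves show zero-increment steps on pool-draw passes
  run2 <- run_active_learning(w$manifest,
                              loop_config(K = 3, algorithm = "alg2",
                                          seed = 4, max_iterations = 8),
                              scripted_world(30, 5, group_size = 6,
                                             seed = 29)$oracle,
                              w$backend, w$cubes)
  curve2 <- annotation_curve(run2)
  expect_true(any(diff(curve2$manual_pct) == 0))
  expect_true(all(diff(curve2$manual_pct) >= 0))

  # direct arithmetic: 46 charges of 460 originals is 10%
  h <- tibble::tibble(iteration = 0L, manual_count = 46L, accuracy = 0.9)
  expect_equal(annotation_curve(h, n_train_original = 460)$manual_pct, 10)

  expect_identical(reach_percentage(curve1, 0), min(curve1$manual_pct))
  expect_identical(reach_percentage(curve1, 2), Inf)
})

test_that("tidy, glance and autoplot expose the run", {
  w <- scripted_world(n_train = 20, n_test = 4)
  run <- run_active_learning(w$manifest,
                             loop_config(K = 4, seed = 1,
                                         max_iterations = 2),
                             w$oracle, w$backend, w$cubes)
  td <- tidy(run)
  expect_true(all(c("iteration", "manual_pct", "accuracy") %in% names(td)))
  gl <- glance(run)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$iterations, 2L)
  expect_s3_class(autoplot(run), "ggplot")
})
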