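#' Active-learning loop configuration
#'
#' Parameters of the annotation-budget loop shared by both algorithm
#' variants: plain uncertainty-driven annotation plus pseudo-labeling
#' (`"alg1"`), and the same loop with an augmentation-aware image pool that
#' converts the associated (augmented) variants of each paid annotation into
#' free labels (`"alg2"`).
#'
#' Each pass ranks the unlabeled set by the chosen certainty criterion,
#' pseudo-labels the `floor(n_train * p)` most certain samples with the
#' model's own predictions, sends the `K` least certain to the annotator
#' (or, under `"alg2"`, draws `K` free labels from the pool once it holds at
#' least `K`), refits the classifier on the union of manual and pseudo
#' labels, and grows `p` by `delta * k`, capped at `p_max`.
#'
#' @param K manual annotations per pass; defaults to
#'   `ceiling(0.05 * n_train)` at run time when `NULL`.
#' @param p0 initial pseudo-label fraction, in `[0, 1)`.
#' @param delta stride of the pseudo-fraction schedule (`p` grows by
#'   `delta * k` after pass `k`).
#' @param p_max cap on the pseudo-label fraction.
#' @param max_iterations maximum number of loop passes after
#'   initialization.
#' @param manual_budget stop once this many annotations have been charged.
#' @param criterion acquisition criterion: `"least_confidence"`,
#'   `"margin"`, `"entropy"`, or `"random"` (the control arm, which replaces
#'   the certainty scores by a seeded random permutation).
#' @param algorithm `"alg1"` (no pool) or `"alg2"` (image pool).
#' @param warm_start warm-start each refit from the previous state.
#' @param seed integer seed; all loop randomness (initial draw, pool draws,
#'   random-criterion scores) flows from one generator seeded with it.
#' @return A `loop_config` list.
#' @export
loop_config <- function(K = NULL, p0 = 0.05, delta = 0.01, p_max = 0.95,
                        max_iterations = 1000L, manual_budget = Inf,
                        criterion = c("entropy", "least_confidence",
                                      "margin", "random"),
                        algorithm = c("alg1", "alg2"),
                        warm_start = TRUE, seed = 1L) {
  criterion <- match.arg(criterion)
  algorithm <- match.arg(algorithm)
  if (p0 < 0 || p0 >= 1) abort("`p0` must be in [0, 1).",
                               class = "hsal_error_validation")
  if (delta < 0) abort("`delta` must be >= 0.", class = "hsal_error_validation")
  if (p_max < p0) abort("`p_max` must be >= `p0`.",
                        class = "hsal_error_validation")
  if (!is.null(K) && K < 1) abort("`K` must be >= 1.",
                                  class = "hsal_error_validation")
  structure(
    list(K = if (is.null(K)) NULL else as.integer(K), p0 = p0, delta = delta,
         p_max = p_max, max_iterations = as.integer(max_iterations),
         manual_budget = manual_budget, criterion = criterion,
         algorithm = algorithm, warm_start = isTRUE(warm_start),
         seed = as.integer(seed)),
    class = "loop_config"
  )
}

#' Pseudo-label count for one pass
#'
#' `floor(n_train * p)`: the number of most-certain unlabeled samples
#' earmarked for pseudo-labeling, as a growing fraction of the full
#' training-set size.
#'
#' @param n_train training-set size (fixed over the run).
#' @param p current pseudo-label fraction in `[0, 1]`.
#' @return Integer count.
#' @export
n_pseudo <- function(n_train, p) {
  if (p < 0 || p > 1) abort("`p` must be in [0, 1].",
                            class = "hsal_error_validation")
  as.integer(floor(n_train * p))
}

#' Pseudo-fraction schedule update
#'
#' After pass `k` the fraction grows by `delta * k` (accelerating
#' increments), capped at `p_max`:
#' `p(k+1) = min(p(k) + delta * k, p_max)`.
#'
#' @param p current fraction.
#' @param k index of the pass just completed (0 leaves `p` unchanged).
#' @param delta stride length.
#' @param p_max cap.
#' @return Updated fraction.
#' @export
update_p <- function(p, k, delta, p_max = 0.95) {
  min(p + delta * k, p_max)
}

# association map: group_id -> member ids, from the training manifest
build_groups <- function(manifest) {
  train <- manifest[manifest$split == "train", ]
  split(train$sample_id, train$group_id)
}

associates_of <- function(groups, id, group_of) {
  setdiff(groups[[group_of[[id]]]], id)
}

#' Initialize the active-learning loop
#'
#' Draws `K` training samples at random, has the oracle annotate them
#' (charged), fits the classifier once on that seed set, and records the
#' first history row. The unlabeled set is the rest of the training split;
#' the pseudo-label set and the pool start empty.
#'
#' @param manifest preprocessed `sample_manifest` (train and test rows).
#' @param config a [loop_config()].
#' @param oracle an annotation oracle (see [make_oracle()]).
#' @param backend a classifier backend (see [reference_backend()]).
#' @param cubes named list of preprocessed cubes covering the manifest.
#' @return A `loop_state` list. Part of the lower-level interface; most
#'   callers want [run_active_learning()].
#' @export
al_initialize <- function(manifest, config, oracle, backend, cubes) {
  train_ids <- manifest$sample_id[manifest$split == "train"]
  if (length(train_ids) == 0) {
    abort("training split is empty.", class = "hsal_error_validation")
  }
  K <- config$K %||% as.integer(ceiling(0.05 * length(train_ids)))
  if (K > length(train_ids)) {
    abort(sprintf("K = %d exceeds the training-set size %d.",
                  K, length(train_ids)),
          class = "hsal_error_validation")
  }
  n_classes <- infer_n_classes(manifest)
  seed_ids <- sample(train_ids, K)
  train <- manifest[manifest$split == "train", ]
  seed_groups <- train$group_id[match(seed_ids, train$sample_id)]
  if (config$algorithm == "alg2") {
    # association-aware: one charge per distinct physical sample
    charged_ids <- seed_ids[!duplicated(seed_groups)]
    free_ids <- setdiff(seed_ids, charged_ids)
    seed_labels <- c(
      vapply(charged_ids, oracle$label, integer(1)),
      if (length(free_ids) > 0) {
        vapply(free_ids, oracle$free_label, integer(1))
      } else {
        integer(0)
      }
    )[seed_ids]
    init_charges <- length(charged_ids)
  } else {
    seed_labels <- vapply(seed_ids, oracle$label, integer(1))
    init_charges <- K
  }
  state <- classifier_fit(backend, state = NULL,
                          cubes = cubes[seed_ids], labels = seed_labels,
                          n_classes = n_classes,
                          warm_start = FALSE, seed = config$seed)
  st <- list(
    k = 0L,
    p = config$p0,
    K = K,
    XM = seed_labels,
    XP = setNames(integer(0), character(0)),
    XU = setdiff(train_ids, seed_ids),
    Pool = setNames(integer(0), character(0)),
    known_groups = unique(seed_groups),
    manual_count = init_charges,
    n_train = length(train_ids),
    n_classes = n_classes,
    model = state,
    history = list()
  )
  class(st) <- "loop_state"
  st
}

infer_n_classes <- function(manifest) {
  labs <- manifest$label[!is.na(manifest$label)]
  if (length(labs) == 0) {
    abort("manifest carries no labels; cannot infer the class count.",
          class = "hsal_error_validation")
  }
  max(labs) + 1L
}

# one loop pass; branches on config$algorithm for the pool logic
loop_pass <- function(st, config, oracle, backend, cubes, groups, group_of) {
  k <- st$k + 1L
  probs <- NULL
  ranking <- NULL
  if (length(st$XU) > 0) {
    probs <- predict_proba(backend, st$model, cubes[st$XU])
    random_scores <- if (config$criterion == "random") {
      stats::runif(length(st$XU))
    } else {
      NULL
    }
    ranking <- rank_by_certainty(probs, st$XU, config$criterion,
                                 random_scores = random_scores)
  }
  pool_draw <- config$algorithm == "alg2" &&
    (length(st$Pool) >= st$K ||
       (length(st$XU) == 0 && length(st$Pool) > 0))
  n_manual <- if (pool_draw) 0L else min(st$K, length(st$XU))
  np_quota <- n_pseudo(st$n_train, st$p)
  sel <- if (!is.null(ranking)) {
    split_selection(ranking, np_quota, n_manual)
  } else {
    list(pseudo = character(), manual = character())
  }
  st$XP <- if (length(sel$pseudo) > 0) {
    pseudo_label(probs, sel$pseudo)
  } else {
    setNames(integer(0), character(0))
  }

  if (pool_draw) {
    drawn <- sample(names(st$Pool), min(st$K, length(st$Pool)))
    st$XM <- c(st$XM, st$Pool[drawn])
    st$Pool <- st$Pool[setdiff(names(st$Pool), drawn)]
  } else if (length(sel$manual) > 0) {
    if (config$algorithm == "alg2") {
      # association-aware annotation: a physical sample's label is paid at
      # most once; batch members whose group is already known (annotated
      # earlier, or co-present in this batch) get their labels for free
      batch_groups <- unlist(group_of[sel$manual])
      is_new <- !duplicated(batch_groups) &
        !(batch_groups %in% st$known_groups)
      charged <- sel$manual[is_new]
      free_in_batch <- setdiff(sel$manual, charged)
      new_labels <- c(
        vapply(charged, oracle$label, integer(1)),
        if (length(free_in_batch) > 0) {
          vapply(free_in_batch, oracle$free_label, integer(1))
        } else {
          integer(0)
        }
      )
      st$manual_count <- st$manual_count + length(charged)
      st$known_groups <- union(st$known_groups, batch_groups)
    } else {
      new_labels <- vapply(sel$manual, oracle$label, integer(1))
      st$manual_count <- st$manual_count + length(sel$manual)
    }
    st$XM <- c(st$XM, new_labels)
    st$XU <- setdiff(st$XU, sel$manual)
    if (config$algorithm == "alg2") {
      assoc <- unique(unlist(lapply(sel$manual, associates_of,
                                    groups = groups, group_of = group_of)))
      # bank associates that are still unlabeled; a pseudo-labeled associate
      # is banked too (pseudo labels are transient, pool membership is not)
      assoc <- intersect(assoc, st$XU)
      if (length(assoc) > 0) {
        st$Pool <- c(st$Pool, vapply(assoc, oracle$free_label, integer(1)))
        st$XU <- setdiff(st$XU, assoc)
      }
    }
  }

  train_labels <- c(st$XM, st$XP)
  st$model <- classifier_fit(backend,
                             state = if (config$warm_start) st$model else NULL,
                             cubes = cubes[names(train_labels)],
                             labels = train_labels, n_classes = st$n_classes,
                             warm_start = config$warm_start,
                             seed = config$seed)
  st$k <- k
  st$p_used <- st$p
  st$p <- update_p(st$p, k, config$delta, config$p_max)
  # pseudo labels are transient: their ids stay in XU for the next ranking
  st$XP <- setNames(integer(0), character(0))
  st$n_pseudo_last <- length(sel$pseudo)
  st
}

history_row <- function(st, accuracy, p_used, n_pseudo_used) {
  tibble::tibble(
    iteration = st$k,
    p = p_used,
    n_pseudo = n_pseudo_used,
    n_manual_total = length(st$XM),
    n_unlabeled = length(st$XU),
    n_pool = length(st$Pool),
    manual_count = st$manual_count,
    accuracy = accuracy
  )
}

#' Run an active-learning experiment
#'
#' Orchestrates the full loop: initialization, repeated passes
#' (rank, pseudo-label, annotate or draw from the pool, refit, advance the
#' pseudo-fraction schedule), and per-pass evaluation on the test split.
#' Stops when the unlabeled set (and, under `"alg2"`, the pool) is
#' exhausted, when the manual budget is reached, or after
#' `config$max_iterations` passes.
#'
#' @inheritParams al_initialize
#' @return An `al_run` object: a list with `history` (one tibble row per
#'   pass, including the post-initialization row at iteration 0), the final
#'   classifier `model`, the manually annotated set `XM`, `manual_count`,
#'   `n_train`, `n_train_original` (distinct augmentation groups in the
#'   training split), and the `config`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' \donttest{
#' cfg <- synth_config(n_per_class = 6, height = c(24, 28), width = c(24, 28),
#'                     n_channels = 40)
#' ds <- generate_cubes(cfg)
#' pre <- preprocess_config(first_channel = 5, last_channel = 35, step = 3,
#'                          target_size = 16)
#' prep <- preprocess_cubes(ds$manifest, ds$cubes, pre, augment_train = TRUE)
#' oracle <- make_oracle(ds$manifest, seed = 1)
#' run <- run_active_learning(prep$manifest, loop_config(K = 4, seed = 1),
#'                            oracle, reference_backend(), prep$cubes)
#' tail(tidy(run), 3)
#' }
#' @export
run_active_learning <- function(manifest, config, oracle, backend, cubes) {
  stopifnot(inherits(config, "loop_config"))
  test_ids <- manifest$sample_id[manifest$split == "test"]
  if (length(test_ids) == 0) {
    abort("test split is empty.", class = "hsal_error_validation")
  }
  test_labels <- manifest_labels(manifest, test_ids)
  groups <- build_groups(manifest)
  train <- manifest[manifest$split == "train", ]
  group_of <- setNames(as.list(train$group_id), train$sample_id)

  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  st <- al_initialize(manifest, config, oracle, backend, cubes)
  acc <- evaluate_classifier(backend, st$model, cubes[test_ids],
                             test_labels)$accuracy
  st$history[[1]] <- history_row(st, acc, p_used = st$p, n_pseudo_used = 0L)

  repeat {
    exhausted <- length(st$XU) == 0 &&
      (config$algorithm == "alg1" || length(st$Pool) == 0)
    if (exhausted) break
    if (st$k >= config$max_iterations) break
    if (st$manual_count >= config$manual_budget) break
    st <- loop_pass(st, config, oracle, backend, cubes, groups, group_of)
    acc <- evaluate_classifier(backend, st$model, cubes[test_ids],
                               test_labels)$accuracy
    st$history[[st$k + 1L]] <- history_row(st, acc, st$p_used,
                                           st$n_pseudo_last)
  }

  structure(
    list(
      history = bind_rows(st$history),
      model = st$model,
      XM = st$XM,
      manual_count = st$manual_count,
      n_train = st$n_train,
      n_train_original = length(unique(train$group_id)),
      n_classes = st$n_classes,
      config = config
    ),
    class = "al_run"
  )
}

#' @export
print.al_run <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<al_run> %s / %s | %d passes | manual %d of %d original train (%.1f%%) | final accuracy %.3f\n",
    x$config$algorithm, x$config$criterion, max(h$iteration),
    x$manual_count, x$n_train_original,
    100 * x$manual_count / x$n_train_original,
    h$accuracy[nrow(h)]
  ))
  invisible(x)
}

#' Evaluate a classifier state on labeled cubes
#'
#' @param backend,state classifier backend and fitted state.
#' @param cubes named list of cubes to classify.
#' @param labels named integer vector of 0-based true labels.
#' @return List with `accuracy`, the `confusion` table
#'   (rows = true class, columns = predicted class, counts summing to the
#'   number of cubes), and `n`.
#' @export
evaluate_classifier <- function(backend, state, cubes, labels) {
  if (length(cubes) == 0) {
    abort("empty evaluation set.", class = "hsal_error_validation")
  }
  probs <- predict_proba(backend, state, cubes)
  predicted <- apply(probs, 1, which.max) - 1L
  truth <- labels[names(cubes)]
  lev <- 0:(ncol(probs) - 1L)
  confusion <- table(
    true = factor(truth, levels = lev),
    predicted = factor(predicted, levels = lev)
  )
  list(accuracy = mean(predicted == truth), confusion = confusion,
       n = length(cubes))
}

#' Annotation-cost learning curve
#'
#' Converts a run history into the (manual-annotation percentage, accuracy)
#' curve used to compare acquisition strategies. The percentage is charged
#' annotations over the *original, pre-augmentation* training-set size:
#' labels drawn from the image pool were already paid for by the annotation
#' of their group mate, so they add cost 0. Under `"alg1"` (where every
#' augmented variant must be paid for individually) the percentage can
#' therefore exceed 100.
#'
#' @param run an `al_run`, or a history tibble (then `n_train_original`
#'   must be given).
#' @param n_train_original distinct physical samples in the training split.
#' @return Tibble with `iteration`, `manual_count`, `manual_pct`
#'   (non-decreasing), and `accuracy`.
#' @export
annotation_curve <- function(run, n_train_original = NULL) {
  if (inherits(run, "al_run")) {
    history <- run$history
    n_train_original <- run$n_train_original
  } else {
    history <- run
    if (is.null(n_train_original)) {
      abort("`n_train_original` is required when passing a bare history.",
            class = "hsal_error_validation")
    }
  }
  if (nrow(history) == 0) {
    abort("empty history.", class = "hsal_error_validation")
  }
  history %>%
    mutate(manual_pct = 100 * manual_count / n_train_original) %>%
    select(iteration, manual_count, manual_pct, accuracy)
}

#' Smallest annotation percentage reaching a target accuracy
#'
#' @param curve output of [annotation_curve()].
#' @param target accuracy to reach (typically the full-annotation
#'   baseline's).
#' @return The smallest `manual_pct` whose accuracy is `>= target`, or
#'   `Inf` when the run never reaches it.
#' @export
reach_percentage <- function(curve, target) {
  hit <- curve$manual_pct[curve$accuracy >= target]
  if (length(hit) == 0) Inf else min(hit)
}
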