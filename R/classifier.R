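#' Default residual-network architecture specification
#'
#' The classification network is a small-image residual network: a first
#' convolution that mixes the spectral channels, 27 residual blocks, then
#' global average pooling and a softmax fully-connected head. Block widths
#' and strides are not uniquely determined by that description; the default
#' here is the canonical small-input layout of 3 stages of 9 blocks
#' (16/32/64 filters, stride 2 at stage boundaries), which is consistent
#' with 27 blocks on 32 x 32 inputs. Batch normalization precedes every ReLU
#' activation; training uses cross-entropy loss with a momentum optimizer.
#'
#' The spec is a buildable description (consumable by any deep-learning
#' framework), not a trained model; the in-package training backends are
#' [reference_backend()] and [scripted_backend()].
#'
#' @param input_channels number of spectral channels entering the first
#'   convolution (71 after default preprocessing).
#' @param classes softmax output width.
#' @param n_residual_blocks number of residual blocks.
#' @return An `architecture_spec` list.
#' @examples
#' build_default_spec(input_channels = 71, classes = 2)$n_residual_blocks
#' @export
build_default_spec <- function(input_channels, classes,
                               n_residual_blocks = 27L) {
  if (input_channels < 1 || classes < 1) {
    abort("`input_channels` and `classes` must be >= 1.",
          class = "hsal_error_validation")
  }
  if (n_residual_blocks < 1) {
    abort("`n_residual_blocks` must be >= 1.", class = "hsal_error_validation")
  }
  n_stages <- 3L
  per_stage <- rep(n_residual_blocks %/% n_stages, n_stages)
  per_stage[seq_len(n_residual_blocks %% n_stages)] <-
    per_stage[seq_len(n_residual_blocks %% n_stages)] + 1L
  structure(
    list(
      first_conv = list(in_channels = as.integer(input_channels),
                        out_channels = 16L, kernel = 3L, stride = 1L,
                        purpose = "mix spectral channels"),
      n_residual_blocks = as.integer(n_residual_blocks),
      stages = list(blocks = per_stage, filters = c(16L, 32L, 64L),
                    stride_at_stage_boundary = 2L),
      head = list(pooling = "global_average", fc = "softmax",
                  out_width = as.integer(classes)),
      activation = "relu",
      batch_norm = "before_activation",
      loss = "cross_entropy",
      optimizer = list(type = "momentum", momentum = 0.9,
                       learning_rate = 0.1, lr_schedule = "step_decay",
                       batch_size = 32L, epochs_per_iteration = 10L),
      input_spatial = 32L
    ),
    class = "architecture_spec"
  )
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<architecture_spec> first conv %d -> %d channels | ",
           "%d residual blocks (stages %s, filters %s) | GAP + softmax(%d)\n"),
    x$first_conv$in_channels, x$first_conv$out_channels,
    x$n_residual_blocks, paste(x$stages$blocks, collapse = "/"),
    paste(x$stages$filters, collapse = "/"), x$head$out_width
  ))
  invisible(x)
}

# ---- backend contract -------------------------------------------------------

#' Classifier backends
#'
#' Both active-learning algorithms only ever see a probabilistic-classifier
#' contract: `classifier_fit()` produces an opaque state from labeled cubes,
#' `predict_proba()` maps cubes to a prediction matrix whose rows sum to 1.
#' Any object honoring the contract can drive the loop; the package ships
#'
#' * [reference_backend()] — a deterministic nearest-centroid model on
#'   per-channel summary spectra with a softmax over negative distances;
#'   fast, CPU-only, used throughout the tests and benchmarks;
#' * [scripted_backend()] — replays externally supplied probability tables,
#'   so loop bookkeeping is testable with no training at all.
#'
#' @param backend a backend object.
#' @param state a previous state (or `NULL` to fit from scratch).
#' @param cubes named list of [hyper_cube()]s (names are sample ids); the
#'   scripted backend only consumes the names.
#' @param labels named integer vector of 0-based class labels for `cubes`
#'   (names matching cube ids).
#' @param n_classes total number of classes. When `NULL`, inferred from
#'   `labels`, in which case fewer than two observed classes is a validation
#'   error. When supplied explicitly, classes absent from the training set
#'   get zero probability instead.
#' @param warm_start logical; continue from `state`'s parameters. The
#'   reference model's fit is closed-form (its optimum does not depend on
#'   the starting point), so warm and cold starts coincide except for the
#'   training-iteration metadata.
#' @param seed integer seed for any stochastic component of the backend
#'   (the shipped backends are deterministic).
#' @return `classifier_fit()` returns a new state; `predict_proba()` an
#'   N x m matrix with row names = cube ids, rows summing to 1.
#' @name classifier-backend
NULL

#' @rdname classifier-backend
#' @export
classifier_fit <- function(backend, state = NULL, cubes, labels,
                           n_classes = NULL, warm_start = TRUE, seed = NULL) {
  UseMethod("classifier_fit")
}

#' @rdname classifier-backend
#' @export
predict_proba <- function(backend, state, cubes) {
  UseMethod("predict_proba")
}

# ---- reference backend ------------------------------------------------------

#' Deterministic nearest-centroid reference classifier
#'
#' Summarizes each cube by a per-channel summary spectrum and classifies by
#' distance to class centroids, with class probabilities from a softmax over
#' negative squared distances. The summary of channel `c` is the
#' foreground-background contrast: the mean of channel `c` over foreground
#' pixels minus its mean over background pixels, the foreground being the
#' pixels whose across-channel mean exceeds the cube's spatial median. On
#' raw or log-stage cubes this is a monotone proxy of the plain mean
#' spectrum; unlike the plain mean (identically zero after per-channel
#' normalization) it survives the full preprocessing chain. For a cube with
#' no spatial variation the summary falls back to the plain per-channel
#' mean.
#'
#' Spectral channels carry very unequal feature variances, so distances are
#' computed on z-scored features (per-channel mean/sd taken from the
#' training batch — a diagonal-covariance nearest centroid) and further
#' scaled by the mean within-class training distance. `temperature` is
#' therefore unitless; scaling it reshapes the probabilities monotonically
#' without changing any per-sample class ranking.
#'
#' @param temperature positive softmax sharpness.
#' @return A backend object for [classifier_fit()] / [predict_proba()].
#' @export
reference_backend <- function(temperature = 1) {
  if (temperature <= 0) {
    abort("`temperature` must be > 0.", class = "hsal_error_validation")
  }
  structure(
    list(temperature = temperature, feature_cache = new.env(parent = emptyenv())),
    class = c("reference_backend", "hsal_backend")
  )
}

#' Per-channel summary spectrum of a cube
#'
#' The feature vector consumed by [reference_backend()]; exposed for
#' inspection and testing.
#'
#' @param cube a [hyper_cube()].
#' @return Numeric vector, one value per channel.
#' @export
summary_spectrum <- function(cube) {
  assert_cube(cube)
  d <- dim(cube$pixels)
  m <- matrix(cube$pixels, nrow = d[1] * d[2], ncol = d[3])
  px_mean <- rowMeans(m)
  fg <- px_mean > stats::median(px_mean)
  if (sum(fg) == 0 || sum(!fg) == 0) {
    return(colMeans(m))
  }
  colMeans(m[fg, , drop = FALSE]) - colMeans(m[!fg, , drop = FALSE])
}

backend_features <- function(backend, cubes) {
  ids <- names(cubes)
  feats <- lapply(ids, function(id) {
    cached <- backend$feature_cache[[id]]
    if (is.null(cached)) {
      cached <- summary_spectrum(cubes[[id]])
      assign(id, cached, envir = backend$feature_cache)
    }
    cached
  })
  do.call(rbind, feats)
}

#' @export
classifier_fit.reference_backend <- function(backend, state = NULL, cubes,
                                             labels, n_classes = NULL,
                                             warm_start = TRUE, seed = NULL) {
  if (length(cubes) == 0) {
    abort("empty training set.", class = "hsal_error_validation")
  }
  if (is.null(names(cubes))) {
    abort("`cubes` must be a named list (names = sample ids).",
          class = "hsal_error_validation")
  }
  labels <- labels[names(cubes)]
  if (anyNA(labels)) {
    abort("every training cube needs a label.", class = "hsal_error_validation")
  }
  observed <- sort(unique(as.integer(labels)))
  if (is.null(n_classes)) {
    if (length(observed) < 2L) {
      abort("training set contains a single class; declare `n_classes` or supply both classes.",
            class = "hsal_error_validation")
    }
    n_classes <- max(observed) + 1L
  }
  feats <- backend_features(backend, cubes)
  centroids_raw <- matrix(NA_real_, nrow = n_classes, ncol = ncol(feats))
  for (cl in observed) {
    centroids_raw[cl + 1L, ] <- colMeans(feats[labels == cl, , drop = FALSE])
  }
  # diagonal-covariance standardization: spectral channels have very
  # different feature variances, so distances are taken in z-score space
  feat_center <- colMeans(feats)
  feat_scale <- sqrt(colMeans(sweep(feats, 2, feat_center)^2))
  feat_scale[feat_scale < 1e-8] <- 1e-8
  z <- sweep(sweep(feats, 2, feat_center), 2, feat_scale, "/")
  centroids <- sweep(sweep(centroids_raw, 2, feat_center), 2, feat_scale, "/")
  # within-class scale: mean distance of training samples to their centroid
  own <- centroids[as.integer(labels) + 1L, , drop = FALSE]
  scale <- mean(sqrt(rowSums((z - own)^2)))
  if (!is.finite(scale) || scale < 1e-8) scale <- 1e-8
  structure(
    list(
      centroids = centroids,
      centroids_raw = centroids_raw,
      feat_center = feat_center,
      feat_scale = feat_scale,
      scale = scale,
      n_classes = as.integer(n_classes),
      input_channels = ncol(feats),
      temperature = backend$temperature,
      iterations = if (warm_start && !is.null(state)) state$iterations + 1L else 1L
    ),
    class = "reference_state"
  )
}

#' @export
predict_proba.reference_backend <- function(backend, state, cubes) {
  if (length(cubes) == 0) {
    abort("no cubes to predict on.", class = "hsal_error_validation")
  }
  feats <- backend_features(backend, cubes)
  if (ncol(feats) != state$input_channels) {
    abort(sprintf("cube channel count %d does not match the fitted state (%d).",
                  ncol(feats), state$input_channels),
          class = "hsal_error_validation")
  }
  z <- sweep(sweep(feats, 2, state$feat_center), 2, state$feat_scale, "/")
  d2 <- sapply(seq_len(state$n_classes), function(j) {
    ctr <- state$centroids[j, ]
    if (anyNA(ctr)) return(rep(Inf, nrow(feats)))
    rowSums(sweep(z, 2, ctr)^2)
  })
  d2 <- matrix(d2, nrow = nrow(feats))
  logits <- -state$temperature * d2 / (2 * state$scale^2)
  probs <- t(apply(logits, 1, function(l) {
    l <- l - max(l[is.finite(l)])
    e <- exp(l)
    e[!is.finite(l) & l < 0] <- 0
    e / sum(e)
  }))
  rownames(probs) <- names(cubes)
  probs
}

# ---- scripted backend -------------------------------------------------------

#' Scripted (replay) classifier backend
#'
#' Emits externally fixed class probabilities, keyed by sample id and,
#' optionally, by training iteration. Fitting only advances an iteration
#' counter. This makes every piece of acquisition and loop bookkeeping
#' testable without any training: identical probability tables must produce
#' identical loop traces whatever "model" stands behind them.
#'
#' @param probs either a fixed numeric matrix with sample ids as row names,
#'   or a function `(ids, iteration) -> matrix` returning one row per id.
#' @param n_classes number of classes the table covers (inferred from a
#'   matrix argument).
#' @return A backend object.
#' @export
scripted_backend <- function(probs, n_classes = NULL) {
  if (is.matrix(probs)) {
    validate_prediction_matrix(probs)
    if (is.null(rownames(probs))) {
      abort("a scripted probability matrix needs sample ids as row names.",
            class = "hsal_error_validation")
    }
    n_classes <- ncol(probs)
    table <- probs
    fn <- function(ids, iteration) {
      idx <- match(ids, rownames(table))
      if (anyNA(idx)) {
        abort(sprintf("scripted backend has no probabilities for: %s.",
                      paste(ids[is.na(idx)], collapse = ", ")),
              class = "hsal_error_lookup")
      }
      table[idx, , drop = FALSE]
    }
  } else if (is.function(probs)) {
    if (is.null(n_classes)) {
      abort("`n_classes` is required when `probs` is a function.",
            class = "hsal_error_validation")
    }
    fn <- probs
  } else {
    abort("`probs` must be a matrix or a function.",
          class = "hsal_error_validation")
  }
  structure(
    list(prob_fn = fn, n_classes = as.integer(n_classes)),
    class = c("scripted_backend", "hsal_backend")
  )
}

#' @export
classifier_fit.scripted_backend <- function(backend, state = NULL, cubes,
                                            labels, n_classes = NULL,
                                            warm_start = TRUE, seed = NULL) {
  if (length(cubes) == 0) {
    abort("empty training set.", class = "hsal_error_validation")
  }
  structure(
    list(
      n_classes = backend$n_classes,
      iterations = if (warm_start && !is.null(state)) state$iterations + 1L else 1L
    ),
    class = "scripted_state"
  )
}

#' @export
predict_proba.scripted_backend <- function(backend, state, cubes) {
  ids <- names(cubes)
  probs <- backend$prob_fn(ids, state$iterations)
  probs <- matrix(as.numeric(probs), nrow = length(ids),
                  dimnames = list(ids, NULL))
  validate_prediction_matrix(probs)
  probs
}
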