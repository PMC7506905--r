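#' Prediction matrices
#'
#' A prediction matrix holds one row of class probabilities per unlabeled
#' sample (rows sum to 1, at least two classes). Row names carry the sample
#' ids. `validate_prediction_matrix()` checks these invariants and is called
#' by every acquisition function.
#'
#' @param probs numeric matrix, N x m, nonnegative, rows summing to 1
#'   within `1e-6`.
#' @param tol row-sum tolerance.
#' @return `probs`, invisibly, after validation.
#' @export
validate_prediction_matrix <- function(probs, tol = 1e-6) {
  if (!is.matrix(probs) || !is.numeric(probs)) {
    abort("`probs` must be a numeric matrix.", class = "hsal_error_validation")
  }
  if (ncol(probs) < 2L) {
    abort("`probs` needs at least 2 class columns.",
          class = "hsal_error_validation")
  }
  if (any(probs < -tol)) {
    abort("`probs` contains negative probabilities.",
          class = "hsal_error_validation")
  }
  rs <- rowSums(probs)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad) > 0) {
    abort(sprintf("prediction row(s) %s do not sum to 1.",
                  paste(head(bad, 5), collapse = ", ")),
          class = "hsal_error_validation")
  }
  invisible(probs)
}

#' Least-confidence certainty score
#'
#' The probability of the most likely class, `max_j p_ij`: the model's
#' confidence in its top prediction. Ranges over `[1/m, 1]`; low scores mark
#' the samples the model is least sure about.
#'
#' @param probs a validated prediction matrix (see
#'   [validate_prediction_matrix()]).
#' @return Numeric score per row.
#' @export
certainty_least_confidence <- function(probs) {
  validate_prediction_matrix(probs)
  apply(probs, 1, max)
}

#' Margin-sampling certainty score
#'
#' The gap between the two most probable classes,
#' `p_i,(1) - p_i,(2)`. Ranges over `[0, 1]`; a small margin means the model
#' cannot separate its top two candidate classes.
#'
#' @inheritParams certainty_least_confidence
#' @return Numeric score per row.
#' @export
certainty_margin <- function(probs) {
  validate_prediction_matrix(probs)
  apply(probs, 1, function(p) {
    top2 <- sort(p, decreasing = TRUE)[1:2]
    top2[1] - top2[2]
  })
}

#' Entropy-based certainty score
#'
#' The signed sum `sum_j p_ij * ln(p_ij)` with the convention
#' `0 * ln(0) = 0`, i.e. the negative Shannon entropy in nats. Larger (closer
#' to 0) means more certain; the minimum `-ln(m)` is reached on the uniform
#' row. Using the negative entropy keeps one uniform rule for all three
#' criteria: sort certainty high to low, pseudo-label the top, annotate the
#' bottom.
#'
#' @inheritParams certainty_least_confidence
#' @return Numeric score per row in `[-ln(m), 0]`.
#' @export
certainty_entropy <- function(probs) {
  validate_prediction_matrix(probs)
  plogp <- probs * log(probs)
  plogp[probs == 0] <- 0
  rowSums(plogp)
}

criterion_names <- function() c("least_confidence", "margin", "entropy", "random")

certainty_scores <- function(probs, criterion) {
  switch(criterion,
    least_confidence = certainty_least_confidence(probs),
    margin = certainty_margin(probs),
    entropy = certainty_entropy(probs),
    abort(sprintf("unknown criterion '%s'.", criterion),
          class = "hsal_error_validation")
  )
}

#' Rank samples by certainty
#'
#' Sorts samples high-to-low by the chosen criterion's certainty score with
#' a stable sort: ties keep their original id order, so rankings are
#' reproducible. The `"random"` criterion replaces the scores by a seeded
#' random permutation (the random-selection control arm).
#'
#' @param probs prediction matrix with rows aligned to `ids`.
#' @param ids character vector of sample ids, one per row.
#' @param criterion one of `"least_confidence"`, `"margin"`, `"entropy"`,
#'   `"random"`.
#' @param random_scores optional numeric vector used as scores when
#'   `criterion = "random"` (supplied by the loop from its seeded RNG).
#' @return A `certainty_ranking` tibble with columns `sample_id` and
#'   `certainty`, ordered non-increasing in `certainty`.
#' @export
rank_by_certainty <- function(probs, ids,
                              criterion = c("least_confidence", "margin",
                                            "entropy", "random"),
                              random_scores = NULL) {
  criterion <- match.arg(criterion)
  if (length(ids) != nrow(probs)) {
    abort(sprintf("%d ids supplied for %d prediction rows.",
                  length(ids), nrow(probs)),
          class = "hsal_error_validation")
  }
  scores <- if (criterion == "random") {
    validate_prediction_matrix(probs)
    random_scores %||% stats::runif(nrow(probs))
  } else {
    certainty_scores(probs, criterion)
  }
  ord <- order(-scores)  # radix sort: stable, ties keep input order
  out <- tibble::tibble(sample_id = as.character(ids)[ord],
                        certainty = as.numeric(scores)[ord])
  attr(out, "criterion") <- criterion
  class(out) <- c("certainty_ranking", class(out))
  out
}

#' Split a certainty ranking into pseudo-label and manual-annotation sets
#'
#' The top `n_pseudo` (most certain) ids are earmarked for pseudo-labeling;
#' the bottom `n_manual` (least certain) for manual annotation. The two sets
#' are always disjoint: when `n_pseudo + n_manual` exceeds the ranking
#' length, `n_pseudo` is reduced — the manual quota has priority, since paid
#' annotation is the budgeted resource.
#'
#' @param ranking a `certainty_ranking` from [rank_by_certainty()].
#' @param n_pseudo number of top-ranked ids to pseudo-label.
#' @param n_manual number of bottom-ranked ids to annotate.
#' @return A list with character vectors `pseudo` and `manual`.
#' @export
split_selection <- function(ranking, n_pseudo, n_manual) {
  n <- nrow(ranking)
  if (n_pseudo < 0 || n_manual < 0) {
    abort("`n_pseudo` and `n_manual` must be >= 0.",
          class = "hsal_error_validation")
  }
  if (n_manual > n) {
    abort(sprintf("n_manual = %d exceeds the ranking length %d.",
                  n_manual, n),
          class = "hsal_error_validation")
  }
  n_pseudo <- min(n_pseudo, n - n_manual)
  list(
    pseudo = head(ranking$sample_id, n_pseudo),
    manual = if (n_manual > 0) tail(ranking$sample_id, n_manual) else character()
  )
}

#' Pseudo-label samples from the model's predictions
#'
#' Assigns each selected sample the argmax class of its prediction row; ties
#' break toward the smaller class index. Class indices are 0-based, matching
#' the labels used throughout.
#'
#' @param probs prediction matrix with row names (or `ids` aligned by
#'   position).
#' @param ids ids to label; must be a subset of the matrix's row ids.
#' @return Named integer vector of 0-based class labels.
#' @export
pseudo_label <- function(probs, ids) {
  validate_prediction_matrix(probs)
  row_ids <- rownames(probs)
  if (is.null(row_ids)) {
    abort("`probs` must carry sample ids as row names.",
          class = "hsal_error_validation")
  }
  idx <- match(ids, row_ids)
  if (anyNA(idx)) {
    abort(sprintf("unknown sample id(s): %s.",
                  paste(ids[is.na(idx)], collapse = ", ")),
          class = "hsal_error_lookup")
  }
  labels <- apply(probs[idx, , drop = FALSE], 1, which.max) - 1L
  setNames(as.integer(labels), ids)
}
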