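#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an active-learning run
#'
#' One row per loop pass (including the post-initialization row at
#' iteration 0): the pseudo-fraction in force, set sizes, cumulative
#' annotation charges, the annotation percentage, and test accuracy.
#'
#' @param x an `al_run` from [run_active_learning()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.al_run <- function(x, ...) {
  x$history %>%
    mutate(manual_pct = 100 * manual_count / x$n_train_original)
}

#' One-row summary of an active-learning run
#'
#' @param x an `al_run`.
#' @param ... unused.
#' @return A one-row tibble: algorithm, criterion, passes, total charges,
#'   annotation percentage, peak and final accuracy.
#' @export
glance.al_run <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    algorithm = x$config$algorithm,
    criterion = x$config$criterion,
    iterations = max(h$iteration),
    n_train = x$n_train,
    n_train_original = x$n_train_original,
    manual_count = x$manual_count,
    manual_pct = 100 * x$manual_count / x$n_train_original,
    peak_accuracy = max(h$accuracy),
    final_accuracy = h$accuracy[nrow(h)]
  )
}
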