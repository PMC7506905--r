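#' Sample manifests
#'
#' A sample manifest is a tibble registry of samples with columns
#' `sample_id`, `file_path`, `label` (integer class index or `NA` when
#' unlabeled), `split` (`"train"` or `"test"`), and `group_id` (shared by a
#' sample and its augmented variants). Invariants: sample ids are unique,
#' every augmentation group carries exactly one label, and the splits are
#' disjoint by construction.
#'
#' @param path CSV file with columns `sample_id`, `file_path`, `split`;
#'   `label` and `group_id` are optional. A missing `group_id` defaults to
#'   the sample id (a group of size one, pre-augmentation).
#' @return A tibble with class `sample_manifest`, row order preserved from
#'   the file.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,file_path,label,split",
#'              "a,ignored,0,train", "b,ignored,1,test"), f)
#' load_manifest(f)
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("manifest file '%s' does not exist.", path),
          class = "hsal_error_io")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_sample_manifest(df)
}

#' Coerce a data frame to a validated sample manifest
#'
#' @param df data frame with at least `sample_id`, `file_path`, `split`.
#' @return A `sample_manifest` tibble.
#' @export
as_sample_manifest <- function(df) {
  required <- c("sample_id", "file_path", "split")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("manifest is missing required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "hsal_error_validation")
  }
  out <- tibble::as_tibble(df)
  out$sample_id <- as.character(out$sample_id)
  out$file_path <- as.character(out$file_path)
  if (!"label" %in% names(out)) out$label <- NA_integer_
  out$label <- as.integer(out$label)
  if (!"group_id" %in% names(out) ) out$group_id <- out$sample_id
  out$group_id <- dplyr::coalesce(as.character(out$group_id), out$sample_id)
  out$split <- as.character(out$split)
  out <- out[, c("sample_id", "file_path", "label", "split", "group_id")]

  dup <- out$sample_id[duplicated(out$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated sample_id in manifest: %s.",
                  paste(unique(dup), collapse = ", ")),
          class = "hsal_error_validation")
  }
  bad_split <- setdiff(unique(out$split), c("train", "test"))
  if (length(bad_split) > 0) {
    abort(sprintf("unknown split token(s): %s (expected 'train' or 'test').",
                  paste(bad_split, collapse = ", ")),
          class = "hsal_error_validation")
  }
  labels_per_group <- out %>%
    filter(!is.na(label)) %>%
    group_by(group_id) %>%
    summarise(n_labels = dplyr::n_distinct(label), .groups = "drop") %>%
    filter(n_labels > 1)
  if (nrow(labels_per_group) > 0) {
    abort(sprintf(
      "augmentation group(s) with conflicting labels: %s.",
      paste(labels_per_group$group_id, collapse = ", ")
    ), class = "hsal_error_validation")
  }
  class(out) <- c("sample_manifest", class(out))
  out
}

#' Write a sample manifest to CSV
#'
#' @param manifest a `sample_manifest` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Query the ground-truth label of a manifest row
#'
#' Raises an "unlabeled" condition when the sample carries no label, so that
#' unlabeled data cannot silently leak into supervised code paths.
#'
#' @param manifest a `sample_manifest`.
#' @param ids character vector of sample ids.
#' @return Integer labels, named by id.
#' @export
manifest_labels <- function(manifest, ids) {
  idx <- match(ids, manifest$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("unknown sample id(s): %s.",
                  paste(ids[is.na(idx)], collapse = ", ")),
          class = "hsal_error_lookup")
  }
  labels <- manifest$label[idx]
  if (anyNA(labels)) {
    abort(sprintf("sample(s) %s are unlabeled.",
                  paste(ids[is.na(labels)], collapse = ", ")),
          class = "hsal_error_unlabeled")
  }
  setNames(labels, ids)
}

#' Split sizes of a manifest
#'
#' @param manifest a `sample_manifest`.
#' @return Named integer vector with the number of train and test rows.
#' @export
split_sizes <- function(manifest) {
  c(train = sum(manifest$split == "train"),
    test = sum(manifest$split == "test"))
}
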