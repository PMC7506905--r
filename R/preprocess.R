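#' Preprocessing configuration
#'
#' Parameters of the hyperspectral preprocessing chain. The defaults follow
#' the blueberry transmittance protocol: keep channels 470..820 of the
#' 1002-channel cube with a stride of 5 (71 channels), log10-transform,
#' zero-mean/unit-variance normalize each channel of each cube, and resize
#' spatially to 32 x 32 before augmentation.
#'
#' @param first_channel 1-based index of the first retained channel.
#' @param last_channel 1-based index of the last retained channel (inclusive).
#' @param step channel stride; every `step`-th channel in
#'   `first_channel:last_channel` is kept.
#' @param target_size spatial side length (pixels) after resizing.
#' @param log_floor positive clip floor applied before the log10 transform;
#'   values below it (including sensor zeros) map to `log10(log_floor)`.
#' @param augmentations ordered character vector of deterministic
#'   augmentations, a subset of
#'   `c("vflip", "hflip", "rot90", "rot180", "rot270")`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(first_channel = 470L, last_channel = 820L,
                              step = 5L, target_size = 32L, log_floor = 1,
                              augmentations = c("vflip", "hflip", "rot90",
                                                "rot180", "rot270")) {
  first_channel <- as.integer(first_channel)
  last_channel <- as.integer(last_channel)
  step <- as.integer(step)
  target_size <- as.integer(target_size)
  if (first_channel < 1L || last_channel < first_channel) {
    abort("need 1 <= first_channel <= last_channel.",
          class = "hsal_error_validation")
  }
  if (step < 1L) abort("`step` must be >= 1.", class = "hsal_error_validation")
  if (target_size < 1L) {
    abort("`target_size` must be >= 1.", class = "hsal_error_validation")
  }
  if (log_floor <= 0) {
    abort("`log_floor` must be > 0.", class = "hsal_error_validation")
  }
  bad <- setdiff(augmentations, c("vflip", "hflip", "rot90", "rot180", "rot270"))
  if (length(bad) > 0) {
    abort(sprintf("unknown augmentation(s): %s.", paste(bad, collapse = ", ")),
          class = "hsal_error_validation")
  }
  structure(
    list(first_channel = first_channel, last_channel = last_channel,
         step = step, target_size = target_size, log_floor = log_floor,
         augmentations = augmentations),
    class = "preprocess_config"
  )
}

#' Subset and stride the spectral channels of a cube
#'
#' Keeps the 1-based channels `first, first+step, ..., <= last`, so the
#' output channel count is `floor((last - first) / step) + 1`. With the
#' defaults (470, 820, 5) a 1002-channel cube becomes a 71-channel cube.
#'
#' @param cube a [hyper_cube()] at stage `"raw"`.
#' @param cfg a [preprocess_config()].
#' @return The cube restricted to the selected channels, stage
#'   `"channel_selected"`, wavelengths subset accordingly.
#' @export
select_channels <- function(cube, cfg = preprocess_config()) {
  assert_cube(cube)
  n_ch <- dim(cube$pixels)[3]
  if (cfg$last_channel > n_ch) {
    abort(sprintf("last_channel = %d exceeds the cube's %d channels.",
                  cfg$last_channel, n_ch),
          class = "hsal_error_index")
  }
  idx <- seq.int(cfg$first_channel, cfg$last_channel, by = cfg$step)
  cube$pixels <- cube$pixels[, , idx, drop = FALSE]
  if (!is.null(cube$wavelengths)) cube$wavelengths <- cube$wavelengths[idx]
  advance_stage(cube, "raw", "channel_selected")
}

#' Log10 intensity transform
#'
#' Replaces every pixel `v` by `log10(max(v, log_floor))`, compressing the
#' extreme transmittance counts of reflective hot pixels. Clipping at the
#' floor makes the transform total: sensor zeros map to `log10(log_floor)`
#' (0 with the default floor of 1).
#'
#' @inheritParams select_channels
#' @return The transformed cube at stage `"log"`.
#' @export
log_transform <- function(cube, cfg = preprocess_config()) {
  assert_cube(cube)
  cube$pixels[] <- log10(pmax(cube$pixels, cfg$log_floor))
  advance_stage(cube, "channel_selected", "log")
}

#' Per-channel zero-mean, unit-variance normalization
#'
#' Standardizes each wavelength channel of this cube by its own spatial mean
#' and standard deviation (population moments). Channels with variance below
#' `1e-12` (spatially constant channels) map to all zeros.
#'
#' @inheritParams select_channels
#' @return The normalized cube at stage `"normalized"`.
#' @export
normalize_cube <- function(cube) {
  assert_cube(cube)
  d <- dim(cube$pixels)
  m <- matrix(cube$pixels, nrow = d[1] * d[2], ncol = d[3])
  mu <- colMeans(m)
  centered <- sweep(m, 2, mu)
  v <- colMeans(centered^2)
  sd_safe <- ifelse(v < 1e-12, Inf, sqrt(v))
  out <- sweep(centered, 2, sd_safe, "/")
  cube$pixels <- array(out, dim = d)
  advance_stage(cube, "log", "normalized")
}

#' Bilinear spatial resizing
#'
#' Resizes the two spatial axes to `target_size` x `target_size` with plain
#' bilinear interpolation (no anti-aliasing), applied independently per
#' channel; the channel count is unchanged.
#'
#' @inheritParams select_channels
#' @return The resized cube at stage `"resized"`.
#' @export
resize_spatial <- function(cube, cfg = preprocess_config()) {
  assert_cube(cube)
  s <- cfg$target_size
  if (s < 1L) abort("`target_size` must be >= 1.", class = "hsal_error_validation")
  d <- dim(cube$pixels)
  if (d[1] == s && d[2] == s) {
    return(advance_stage(cube, "normalized", "resized"))
  }
  resized <- EBImage::resize(cube$pixels, w = s, h = s, filter = "bilinear",
                             antialias = FALSE)
  cube$pixels <- array(resized, dim = c(s, s, d[3]))
  advance_stage(cube, "normalized", "resized")
}

#' Deterministic augmentation of a square cube
#'
#' Returns the original cube plus its five deterministic spatial transforms
#' (vertical flip, horizontal flip, rotations by 90/180/270 degrees), all
#' sharing the input's `group_id` so their labels are tied to one physical
#' sample. Variant ids are derived from the original's
#' (`<id>#vflip`, ...).
#'
#' @param cube a [hyper_cube()] at stage `"resized"` with square spatial
#'   shape (rotations would otherwise change the shape).
#' @param cfg a [preprocess_config()]; `cfg$augmentations` selects and orders
#'   the transforms.
#' @return A named list of `1 + length(cfg$augmentations)` cubes, the
#'   original first.
#' @export
augment_cube <- function(cube, cfg = preprocess_config()) {
  assert_cube(cube)
  if (cube$stage != "resized") {
    abort("`augment_cube` expects a cube at stage 'resized'.",
          class = "hsal_error_stage")
  }
  d <- dim(cube$pixels)
  if (d[1] != d[2]) {
    abort("augmentation requires a square spatial shape.",
          class = "hsal_error_validation")
  }
  variants <- lapply(cfg$augmentations, function(tr) {
    v <- cube
    v$pixels <- apply_transform(cube$pixels, tr)
    v$sample_id <- paste0(cube$sample_id, "#", tr)
    v
  })
  out <- c(list(cube), variants)
  names(out) <- map_chr(out, "sample_id")
  out
}

# spatial transforms on an (H, W, C) array; square input assumed for rotations
apply_transform <- function(px, transform) {
  h <- dim(px)[1]
  w <- dim(px)[2]
  switch(transform,
    vflip = px[h:1, , , drop = FALSE],
    hflip = px[, w:1, , drop = FALSE],
    rot90 = rotate90(px),
    rot180 = px[h:1, w:1, , drop = FALSE],
    rot270 = rotate90(rotate90(rotate90(px))),
    abort(sprintf("unknown transform '%s'.", transform),
          class = "hsal_error_validation")
  )
}

# clockwise quarter turn of each channel
rotate90 <- function(px) {
  h <- dim(px)[1]
  aperm(px, c(2, 1, 3))[, h:1, , drop = FALSE]
}

#' Run the full preprocessing chain on one cube
#'
#' `select_channels()`, [log_transform()], [normalize_cube()] and
#' [resize_spatial()] in pipeline order.
#'
#' @inheritParams select_channels
#' @return The preprocessed cube at stage `"resized"`.
#' @export
preprocess_cube <- function(cube, cfg = preprocess_config()) {
  cube %>%
    select_channels(cfg) %>%
    log_transform(cfg) %>%
    normalize_cube() %>%
    resize_spatial(cfg)
}

#' Preprocess every sample of an in-memory dataset
#'
#' In-memory counterpart of [preprocess_dataset()]: takes a manifest plus a
#' named list of raw cubes, pushes every cube through the preprocessing
#' chain, and (optionally) augments the training split. Test samples are
#' never augmented. Augmented rows inherit their parent's `group_id` and
#' (hidden) label.
#'
#' @param manifest a `sample_manifest`.
#' @param cubes named list of raw [hyper_cube()]s covering
#'   `manifest$sample_id`.
#' @param cfg a [preprocess_config()].
#' @param augment_train logical; expand the training split
#'   `1 + length(cfg$augmentations)`-fold?
#' @return A list with the expanded `manifest` and the named `cubes` list of
#'   preprocessed cubes.
#' @export
preprocess_cubes <- function(manifest, cubes, cfg = preprocess_config(),
                             augment_train = TRUE) {
  missing <- setdiff(manifest$sample_id, names(cubes))
  if (length(missing) > 0) {
    abort(sprintf("no cube supplied for sample(s): %s.",
                  paste(head(missing, 5), collapse = ", ")),
          class = "hsal_error_validation")
  }
  out_rows <- vector("list", nrow(manifest))
  out_cubes <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    cube <- tryCatch(
      preprocess_cube(cubes[[row$sample_id]], cfg),
      error = function(e) {
        abort(sprintf("preprocessing failed for sample '%s': %s",
                      row$sample_id, conditionMessage(e)),
              class = "hsal_error_preprocess", parent = e)
      }
    )
    if (augment_train && row$split == "train") {
      fam <- augment_cube(cube, cfg)
      rows <- row[rep(1L, length(fam)), ]
      rows$sample_id <- names(fam)
      out_rows[[i]] <- rows
      out_cubes <- c(out_cubes, fam)
    } else {
      out_rows[[i]] <- row
      out_cubes[[row$sample_id]] <- cube
    }
  }
  new_manifest <- bind_rows(out_rows)
  class(new_manifest) <- class(manifest)
  list(manifest = new_manifest, cubes = out_cubes)
}

#' Preprocess a dataset on disk
#'
#' Reads every cube named by the manifest, applies the preprocessing chain
#' (channel subset, log10, per-channel normalization, resize), augments
#' the training split when requested, writes the results under `out_dir`,
#' and returns the new manifest (also written as `manifest.csv`). A failure
#' on any sample aborts with that sample named.
#'
#' @inheritParams preprocess_cubes
#' @param out_dir output directory.
#' @param format on-disk cube layout, `"array_dir"` or `"envi"`.
#' @return The new `sample_manifest`, with `file_path` pointing into
#'   `out_dir`.
#' @export
preprocess_dataset <- function(manifest, cfg = preprocess_config(),
                               augment_train = TRUE, out_dir,
                               format = c("array_dir", "envi")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cubes <- lapply(setNames(manifest$file_path, manifest$sample_id), read_cube)
  res <- preprocess_cubes(manifest, cubes, cfg, augment_train)
  res$manifest$file_path <- map_chr(res$manifest$sample_id, function(id) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", id)
    target <- file.path(out_dir, safe)
    write_cube(res$cubes[[id]], target, format = format)
    if (format == "envi") paste0(target, ".hdr") else target
  })
  write_manifest(res$manifest, file.path(out_dir, "manifest.csv"))
  res$manifest
}
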