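#' Synthetic hyperspectral dataset configuration
#'
#' Describes a synthetic two-class transmittance-cube collection with the
#' statistical shape of a hyperspectral fruit-sorting study: per-class
#' smooth spectral profiles, a dome-shaped spatial transmittance mask
#' (bright center, dim rim, near-zero background), multiplicative lognormal
#' pixel noise, per-acquisition spectral gain jitter, and sparse reflective
#' hot pixels tens to hundreds of times brighter than their surroundings.
#' Ground-truth labels are carried by the manifest but are meant to be read
#' only through the simulated annotation oracle ([make_oracle()]) and for
#' test-set scoring.
#'
#' `separation` is the single task-difficulty knob: it scales the
#' between-class difference of the log10 spectral profiles. 0 means the
#' classes are identical (chance-level task); the default 3 gives a
#' well-separated but not saturated task.
#'
#' @param n_per_class samples per class.
#' @param classes number of classes.
#' @param height,width integer range (min, max) of the spatial extents in
#'   pixels; each cube draws its own height and width.
#' @param n_channels spectral channels per cube.
#' @param wavelength_range wavelength endpoints in nm, linearly spaced
#'   across the channels.
#' @param separation nonnegative scale of the between-class profile
#'   difference.
#' @param noise_sd sd of the multiplicative lognormal pixel noise (natural
#'   log scale).
#' @param gain_sd sd of the per-sample, per-channel lognormal gain jitter
#'   (natural log scale); models between-acquisition illumination/detector
#'   drift and biological variability, the component that keeps per-sample
#'   spectra from being noise-free after averaging thousands of pixels.
#' @param hot_pixel_rate fraction of pixels turned into reflective hot
#'   pixels.
#' @param hot_pixel_gain multiplicative intensity range (min, max) of hot
#'   pixels.
#' @param mask_log_range decades of transmittance falloff from the dome's
#'   center to its rim.
#' @param label_noise probability that the oracle returns a flipped label.
#' @param train_frac fraction of samples assigned to the training split
#'   (stratified by class).
#' @param class_profiles optional function
#'   `(wavelengths, classes, separation) -> matrix` (channels x classes) of
#'   log10 mean-intensity profiles; the default is a smooth base curve plus
#'   class-shifted Gaussian bumps.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_per_class = 60L, classes = 2L,
                         height = c(100L, 130L), width = c(100L, 130L),
                         n_channels = 1002L,
                         wavelength_range = c(328.82, 1113.54),
                         separation = 3, noise_sd = 0.1, gain_sd = 0.42,
                         hot_pixel_rate = 0.002,
                         hot_pixel_gain = c(50, 200),
                         mask_log_range = 2, label_noise = 0,
                         train_frac = 0.8, class_profiles = NULL,
                         seed = 1L) {
  if (n_per_class < 1) abort("`n_per_class` must be >= 1.",
                             class = "hsal_error_validation")
  if (classes < 2) abort("`classes` must be >= 2.",
                         class = "hsal_error_validation")
  if (separation < 0) abort("`separation` must be >= 0.",
                            class = "hsal_error_validation")
  for (r in list(hot_pixel_rate, label_noise)) {
    if (r < 0 || r > 1) abort("rates must be in [0, 1].",
                              class = "hsal_error_validation")
  }
  structure(
    list(n_per_class = as.integer(n_per_class), classes = as.integer(classes),
         height = as.integer(height), width = as.integer(width),
         n_channels = as.integer(n_channels),
         wavelength_range = wavelength_range, separation = separation,
         noise_sd = noise_sd, gain_sd = gain_sd,
         hot_pixel_rate = hot_pixel_rate, hot_pixel_gain = hot_pixel_gain,
         mask_log_range = mask_log_range, label_noise = label_noise,
         train_frac = train_frac, class_profiles = class_profiles,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Default class spectral profiles
#'
#' A smooth log10 base transmittance curve (broad Gaussian window peaking
#' mid-range) plus a fixed sum of three Gaussian bumps whose sign alternates
#' along the wavelength axis. Classes receive the bump term with offsets
#' spread over `[-1/2, +1/2] * separation`, so `separation` directly scales
#' every between-class log10 profile gap.
#'
#' @param wavelengths numeric vector of channel wavelengths (nm).
#' @param classes number of classes.
#' @param separation between-class scale.
#' @return Matrix `length(wavelengths)` x `classes` of log10 intensities.
#' @export
default_class_profiles <- function(wavelengths, classes, separation) {
  lo <- min(wavelengths)
  span <- max(wavelengths) - lo
  if (span <= 0) span <- 1
  u <- (wavelengths - lo) / span
  base <- 1.0 + 2.5 * exp(-((u - 0.6) / 0.23)^2)
  bump <- function(center, width, amp) amp * exp(-((u - center) / width)^2)
  diff_curve <- bump(0.48, 0.05, 1) + bump(0.63, 0.06, -0.8) +
    bump(0.78, 0.055, 0.6)
  diff_curve <- 0.08 * diff_curve
  offsets <- if (classes == 1) 0 else
    (seq_len(classes) - 1 - (classes - 1) / 2) / max(1, classes - 1)
  vapply(offsets, function(o) base + separation * o * diff_curve,
         numeric(length(wavelengths)))
}

# dome-shaped transmittance mask: 10^0 at the center falling to
# 10^-mask_log_range at the rim, hard zero outside the ellipse
dome_mask <- function(h, w, mask_log_range) {
  u <- (seq_len(h) - (h + 1) / 2) / (0.48 * h)
  v <- (seq_len(w) - (w + 1) / 2) / (0.48 * w)
  r2 <- outer(u^2, v^2, "+")
  mask <- 10^(-mask_log_range * r2)
  mask[r2 > 1] <- 0
  mask
}

#' Generate a synthetic dataset in memory
#'
#' Draws every cube as
#' `pixel(x, y, c) = mask(x, y) * 10^profile_class(c) * gain(i, c) * exp(noise)`
#' with hot pixels injected afterwards, assigns stratified train/test
#' splits, and quantizes intensities to float32 (the precision cubes carry
#' on disk). Bit-identical output for identical configs.
#'
#' @param config a [synth_config()].
#' @return List with `manifest` (a `sample_manifest`; `file_path` is `NA`
#'   until written) and `cubes` (named list of raw [hyper_cube()]s).
#' @seealso [generate_dataset()] for the on-disk variant.
#' @export
generate_cubes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  wavelengths <- seq(config$wavelength_range[1], config$wavelength_range[2],
                     length.out = config$n_channels)
  profile_fn <- config$class_profiles %||% default_class_profiles
  profiles <- profile_fn(wavelengths, config$classes, config$separation)
  stopifnot(nrow(profiles) == config$n_channels,
            ncol(profiles) == config$classes)

  cubes <- list()
  rows <- list()
  idx <- 0L
  for (cl in seq_len(config$classes) - 1L) {
    profile_lin <- 10^profiles[, cl + 1L]
    for (i in seq_len(config$n_per_class)) {
      idx <- idx + 1L
      id <- sprintf("c%d_%03d", cl, i)
      h <- sample(config$height[1]:config$height[2], 1)
      w <- sample(config$width[1]:config$width[2], 1)
      mask <- dome_mask(h, w, config$mask_log_range)
      gain <- exp(rnorm(config$n_channels, 0, config$gain_sd))
      noise <- exp(array(rnorm(h * w * config$n_channels, 0, config$noise_sd),
                         dim = c(h, w, config$n_channels)))
      px <- outer(mask, profile_lin * gain) * noise
      n_hot <- rbinom(1, h * w * config$n_channels, config$hot_pixel_rate)
      if (n_hot > 0) {
        hot_idx <- sample.int(length(px), n_hot)
        px[hot_idx] <- px[hot_idx] *
          runif(n_hot, config$hot_pixel_gain[1], config$hot_pixel_gain[2])
      }
      cubes[[id]] <- hyper_cube(quantize_float32(px), sample_id = id,
                                wavelengths = wavelengths)
      rows[[idx]] <- tibble::tibble(sample_id = id, file_path = NA_character_,
                                    label = cl, split = NA_character_,
                                    group_id = id)
    }
  }
  manifest <- bind_rows(rows)
  # stratified train/test split within each class
  for (cl in unique(manifest$label)) {
    members <- which(manifest$label == cl)
    n_tr <- round(config$train_frac * length(members))
    tr <- sample(members, n_tr)
    manifest$split[members] <- "test"
    manifest$split[tr] <- "train"
  }
  list(manifest = as_sample_manifest(manifest), cubes = cubes)
}

#' Generate a synthetic dataset on disk
#'
#' [generate_cubes()] plus serialization: writes every cube under `out_dir`
#' (ENVI or array-dir layout) and the manifest as `manifest.csv`.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @param format cube layout, `"array_dir"` or `"envi"`.
#' @return The `sample_manifest` with `file_path` filled in.
#' @export
generate_dataset <- function(config, out_dir,
                             format = c("array_dir", "envi")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory '%s'.", out_dir),
          class = "hsal_error_io")
  }
  ds <- generate_cubes(config)
  ds$manifest$file_path <- map_chr(ds$manifest$sample_id, function(id) {
    target <- file.path(out_dir, id)
    write_cube(ds$cubes[[id]], target, format = format)
    if (format == "envi") paste0(target, ".hdr") else target
  })
  write_manifest(ds$manifest, file.path(out_dir, "manifest.csv"))
  ds$manifest
}

#' Simulated annotation oracle
#'
#' Plays the human annotator: `label(id)` returns the ground-truth class
#' (flipped with probability `label_noise`, the flips drawn once at
#' creation so every query is deterministic) and charges one annotation;
#' `free_label(id)` returns the same value without charging — it models the
#' labels implied for pool-banked associated images whose group mate was
#' already paid for. `charges()` reports the running annotation cost.
#'
#' @param manifest a `sample_manifest` with ground-truth labels.
#' @param label_noise per-sample flip probability.
#' @param seed seed for the flip draws.
#' @return An `annotation_oracle`: list of functions `label`, `free_label`,
#'   `charges`.
#' @export
make_oracle <- function(manifest, label_noise = 0, seed = 1L) {
  truth <- setNames(manifest$label, manifest$sample_id)
  if (all(is.na(truth))) {
    abort("manifest carries no ground-truth labels.",
          class = "hsal_error_validation")
  }
  n_classes <- max(truth, na.rm = TRUE) + 1L
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  set.seed(seed)
  flipped <- stats::rbinom(length(truth), 1, label_noise) == 1
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  served <- truth
  served[flipped] <- (served[flipped] + 1L) %% n_classes
  charge_count <- 0L
  lookup <- function(id) {
    if (!id %in% names(served)) {
      abort(sprintf("unknown sample id '%s'.", id),
            class = "hsal_error_lookup")
    }
    val <- served[[id]]
    if (is.na(val)) {
      abort(sprintf("sample '%s' has no ground-truth label.", id),
            class = "hsal_error_unlabeled")
    }
    val
  }
  structure(
    list(
      label = function(id) {
        val <- lookup(id)
        charge_count <<- charge_count + 1L
        val
      },
      free_label = function(id) lookup(id),
      charges = function() charge_count
    ),
    class = "annotation_oracle"
  )
}

#' A preprocessing configuration matched to a channel count
#'
#' The standard channel window (470..820 step 5) presumes 1002-channel
#' cubes. For cubes with fewer channels this helper keeps the same
#' proportions: the middle ~70% of the spectrum, strided to roughly 71
#' output channels.
#'
#' @param n_channels channel count of the cubes.
#' @param target_size spatial side length after resizing.
#' @return A [preprocess_config()].
#' @export
auto_preprocess_config <- function(n_channels, target_size = 32L) {
  if (n_channels >= 820L) {
    return(preprocess_config(target_size = target_size))
  }
  first <- max(1L, round(0.15 * n_channels))
  step <- max(1L, floor((n_channels - first) / 70))
  last <- first + 70L * step
  while (last > n_channels && step > 1L) {
    step <- step - 1L
    last <- first + 70L * step
  }
  if (last > n_channels) {
    first <- 1L
    step <- 1L
    last <- n_channels
  }
  preprocess_config(first_channel = first, last_channel = last, step = step,
                    target_size = target_size)
}

#' Baseline-accuracy sweep over task difficulty
#'
#' For each separation value, generates a dataset, trains the reference
#' classifier on the fully annotated training split (the full-annotation
#' baseline), and records the test accuracy, optionally averaged over
#' several seeds. Accuracy is non-decreasing in separation up to Monte
#' Carlo noise; at separation 0 the classes are identical and accuracy sits
#' at chance.
#'
#' @param config a [synth_config()]; its `separation` is overridden.
#' @param separations numeric vector of separation values.
#' @param n_seeds Monte Carlo replicates per separation.
#' @param pre_cfg preprocessing configuration; defaults to
#'   [auto_preprocess_config()] for the config's channel count.
#' @return Tibble with `separation` and mean `baseline_accuracy`.
#' @export
degrade_separation_sweep <- function(config, separations, n_seeds = 1L,
                                     pre_cfg = NULL) {
  if (length(separations) == 0) {
    return(tibble::tibble(separation = numeric(0),
                          baseline_accuracy = numeric(0)))
  }
  pre_cfg <- pre_cfg %||% auto_preprocess_config(config$n_channels)
  rows <- lapply(separations, function(sep) {
    accs <- vapply(seq_len(n_seeds), function(s) {
      cfg <- config
      cfg$separation <- sep
      cfg$seed <- config$seed + s - 1L
      ds <- generate_cubes(cfg)
      prep <- preprocess_cubes(ds$manifest, ds$cubes, pre_cfg,
                               augment_train = FALSE)
      fit_full_baseline(prep$manifest, prep$cubes,
                        reference_backend())$accuracy
    }, numeric(1))
    tibble::tibble(separation = sep, baseline_accuracy = mean(accs))
  })
  bind_rows(rows)
}

#' Full-annotation baseline
#'
#' Trains a backend on the entire training split with its true labels and
#' scores it on the test split: the accuracy reference all annotation-cost
#' curves are compared against.
#'
#' @param manifest preprocessed `sample_manifest`.
#' @param cubes named cube list covering the manifest.
#' @param backend classifier backend.
#' @return List with `accuracy`, `model`, and the test `confusion` table.
#' @export
fit_full_baseline <- function(manifest, cubes, backend) {
  train_ids <- manifest$sample_id[manifest$split == "train"]
  test_ids <- manifest$sample_id[manifest$split == "test"]
  labels <- manifest_labels(manifest, train_ids)
  model <- classifier_fit(backend, NULL, cubes[train_ids], labels,
                          n_classes = infer_n_classes(manifest),
                          warm_start = FALSE)
  ev <- evaluate_classifier(backend, model, cubes[test_ids],
                            manifest_labels(manifest, test_ids))
  list(accuracy = ev$accuracy, model = model, confusion = ev$confusion)
}
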