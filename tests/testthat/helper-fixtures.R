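# tiny in-code fixtures shared across the suite

# float32-representable random cube (values survive the on-disk encoding)
make_cube <- function(h = 4, w = 4, c = 6, id = "s1", seed = 42,
                      wavelengths = NULL, stage = "raw") {
  set.seed(seed)
  px <- quantize_float32(array(runif(h * w * c, 0, 1000), dim = c(h, w, c)))
  hyper_cube(px, sample_id = id, wavelengths = wavelengths, stage = stage)
}

# small synthetic dataset config: cheap but structurally faithful
tiny_synth_config <- function(n_per_class = 8, n_channels = 60, seed = 1,
                              ...) {
  synth_config(
    n_per_class = n_per_class,
    height = c(20L, 24L), width = c(20L, 24L),
    n_channels = n_channels,
    seed = seed,
    ...
  )
}

tiny_pre_config <- function(n_channels = 60, target_size = 16L) {
  auto_preprocess_config(n_channels, target_size = target_size)
}

# manifest + scripted backend for loop bookkeeping tests (no real cubes)
scripted_world <- function(n_train = 24, n_test = 6, n_classes = 2,
                           group_size = 1, seed = 7) {
  set.seed(seed)
  n <- n_train + n_test
  ids <- sprintf("s%02d", seq_len(n))
  groups <- if (group_size > 1) {
    rep(sprintf("g%02d", seq_len(ceiling(n_train / group_size))),
        each = group_size)[seq_len(n_train)]
  } else {
    ids[seq_len(n_train)]
  }
  # labels constant within each augmentation group
  train_labels <- (as.integer(factor(groups, levels = unique(groups))) - 1L) %%
    n_classes
  manifest <- as_sample_manifest(tibble::tibble(
    sample_id = ids,
    file_path = NA_character_,
    label = c(train_labels,
              rep_len(seq_len(n_classes) - 1L, n_test)),
    split = c(rep("train", n_train), rep("test", n_test)),
    group_id = c(groups, ids[n_train + seq_len(n_test)])
  ))
  probs <- matrix(runif(n * n_classes), ncol = n_classes)
  probs <- probs / rowSums(probs)
  rownames(probs) <- ids
  cubes <- setNames(vector("list", n), ids)
  list(manifest = manifest, backend = scripted_backend(probs),
       cubes = cubes, probs = probs,
       oracle = make_oracle(manifest, seed = seed))
}

random_prob_matrix <- function(n, m, seed = 1) {
  set.seed(seed)
  p <- matrix(stats::rexp(n * m), ncol = m)
  p <- p / rowSums(p)
  rownames(p) <- sprintf("r%03d", seq_len(n))
  p
}
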