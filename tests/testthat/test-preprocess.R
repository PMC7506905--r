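test_that("channel selection matches the closed-form count on a small domain", {
  # exhaustive oracle: enumerate selected indices for all (first, last, step)
  for (last in c(5L, 17L, 50L)) {
    cube <- make_cube(2, 2, last)
    for (first in c(1L, 3L, last)) {
      if (first > last) next
      for (step in c(1L, 2L, 5L, 7L)) {
        cfg <- preprocess_config(first_channel = first, last_channel = last,
                                 step = step)
        got <- select_channels(cube, cfg)
        idx <- seq(first, last, by = step)  # brute-force enumeration
        expect_identical(dim(got$pixels)[3], length(idx))
        expect_identical(dim(got$pixels)[3],
                         as.integer(floor((last - first) / step) + 1))
        expect_identical(got$pixels, cube$pixels[, , idx, drop = FALSE])
      }
    }
  }
})

test_that("default channel window reduces 1002 channels to 71", {
  cube <- make_cube(2, 2, 1002, wavelengths = seq(328.82, 1113.54,
                                                  length.out = 1002))
  out <- select_channels(cube, preprocess_config())
  expect_identical(dim(out$pixels)[3], 71L)
  expect_identical(length(out$wavelengths), 71L)
  expect_identical(out$stage, "channel_selected")
  expect_error(select_channels(make_cube(2, 2, 100), preprocess_config()),
               class = "hsal_error_index")
})

test_that("log transform maps known values and clips at the floor", {
  px <- array(c(100, 1, 0, 1000, 10, 0.5), dim = c(1, 2, 3))
  cube <- hyper_cube(px, "s", stage = "channel_selected")
  out <- log_transform(cube)
  expect_equal(as.numeric(out$pixels), c(2, 0, 0, 3, 1, 0), tolerance = 1e-12)
  expect_identical(out$stage, "log")
})

test_that("normalization yields zero-mean unit-variance channels", {
  cube <- make_cube(6, 5, 4, stage = "log")
  out <- normalize_cube(cube)
  m <- matrix(out$pixels, nrow = 30)
  expect_true(all(abs(colMeans(m)) < 1e-9))
  expect_true(all(abs(colMeans(m^2) - 1) < 1e-6))
  expect_identical(out$stage, "normalized")

  # constant channel maps to all zeros
  px <- array(1, c(3, 3, 2))
  px[, , 2] <- matrix(1:9, 3)
  const <- normalize_cube(hyper_cube(px, "s", stage = "log"))
  expect_true(all(const$pixels[, , 1] == 0))

  # re-standardizing an already standardized cube changes nothing
  again <- out
  again$stage <- "log"
  expect_equal(normalize_cube(again)$pixels, out$pixels, tolerance = 1e-6)
})

test_that("log-then-normalize is invariant to per-channel rescaling", {
  # values kept above the clip floor for every tested scale, so the log
  # turns the rescaling into an exact per-channel shift
  set.seed(8)
  cube <- hyper_cube(array(runif(75, 10, 1000), c(5, 5, 3)), "s")
  cfg <- preprocess_config(first_channel = 1, last_channel = 3, step = 1)
  scaled <- cube
  for (a in c(0.25, 7)) {
    scaled$pixels <- cube$pixels * a
    ref <- normalize_cube(log_transform(select_channels(cube, cfg), cfg))
    got <- normalize_cube(log_transform(select_channels(scaled, cfg), cfg))
    expect_equal(got$pixels, ref$pixels, tolerance = 1e-6)
  }
})

test_that("spatial resize hits the target shape and preserves structure", {
  set.seed(3)
  px <- array(rnorm(100 * 120 * 4), dim = c(100, 120, 4))
  cube <- hyper_cube(px, "s", stage = "normalized")
  out <- resize_spatial(cube, preprocess_config())
  expect_identical(dim(out$pixels), c(32L, 32L, 4L))
  expect_identical(out$stage, "resized")

  # identity resize leaves values untouched
  sq <- hyper_cube(array(rnorm(32 * 32 * 2), c(32, 32, 2)), "s",
                   stage = "normalized")
  same <- resize_spatial(sq, preprocess_config())
  expect_equal(same$pixels, sq$pixels, tolerance = 1e-6)

  # bilinear interpolation preserves constants
  const <- hyper_cube(array(4.5, c(7, 9, 2)), "s", stage = "normalized")
  expect_equal(range(resize_spatial(const, preprocess_config())$pixels),
               c(4.5, 4.5), tolerance = 1e-9)
})

test_that("augmentation produces 6 label-sharing variants with exact symmetries", {
  cube <- make_cube(8, 8, 3, stage = "resized")
  fam <- augment_cube(cube)
  expect_length(fam, 6L)
  expect_identical(unique(vapply(fam, `[[`, "", "group_id")),
                   cube$group_id)
  expect_identical(length(unique(names(fam))), 6L)

  # transforms permute pixels within channels: multisets of values match
  for (v in fam) {
    for (ch in 1:3) {
      expect_identical(sort(as.numeric(v$pixels[, , ch])),
                       sort(as.numeric(cube$pixels[, , ch])))
    }
  }

  # vflip is an involution, rot90 has order 4
  vflip2 <- hsal:::apply_transform(
    hsal:::apply_transform(cube$pixels, "vflip"), "vflip")
  expect_identical(vflip2, cube$pixels)
  r <- cube$pixels
  for (i in 1:4) r <- hsal:::apply_transform(r, "rot90")
  expect_identical(r, cube$pixels)
  # rot270 undoes rot90
  expect_identical(
    hsal:::apply_transform(hsal:::apply_transform(cube$pixels, "rot90"),
                           "rot270"),
    cube$pixels
  )

  expect_error(
    augment_cube(hyper_cube(array(1, c(4, 5, 2)), "s", stage = "resized")),
    class = "hsal_error_validation"
  )
})

test_that("stage discipline rejects out-of-order operations", {
  raw <- make_cube(4, 4, 5)
  expect_error(log_transform(raw), class = "hsal_error_stage")
  expect_error(normalize_cube(raw), class = "hsal_error_stage")
  expect_error(augment_cube(raw), class = "hsal_error_stage")
})

test_that("dataset preprocessing augments the training split only", {
  cfg <- tiny_synth_config(n_per_class = 5)
  ds <- generate_cubes(cfg)
  pre <- tiny_pre_config()
  res <- preprocess_cubes(ds$manifest, ds$cubes, pre, augment_train = TRUE)
  sizes <- split_sizes(res$manifest)
  orig <- split_sizes(ds$manifest)
  expect_identical(unname(sizes["train"]), unname(orig["train"]) * 6L)
  expect_identical(unname(sizes["test"]), unname(orig["test"]))

  # augmented rows inherit the parent's group and label
  aug <- res$manifest[grepl("#", res$manifest$sample_id), ]
  parent <- sub("#.*$", "", aug$sample_id)
  expect_identical(aug$group_id, parent)
  expect_identical(aug$label,
                   ds$manifest$label[match(parent, ds$manifest$sample_id)])

  # with augmentation off, row counts are unchanged
  res2 <- preprocess_cubes(ds$manifest, ds$cubes, pre, augment_train = FALSE)
  expect_identical(nrow(res2$manifest), nrow(ds$manifest))
})

test_that("disk-based dataset preprocessing names the failing sample", {
  cfg <- tiny_synth_config(n_per_class = 2)
  dir_in <- withr::local_tempdir()
  manifest <- generate_dataset(cfg, dir_in, format = "array_dir")
  dir_out <- withr::local_tempdir()
  out <- preprocess_dataset(manifest, tiny_pre_config(),
                            augment_train = FALSE, out_dir = dir_out)
  expect_identical(nrow(out), nrow(manifest))
  pre <- tiny_pre_config()
  n_kept <- as.integer(
    floor((pre$last_channel - pre$first_channel) / pre$step) + 1
  )
  cube <- read_cube(out$file_path[1])
  expect_identical(dim(cube$pixels), c(16L, 16L, n_kept))
  expect_identical(cube$stage, "resized")

  bad <- manifest
  bad_pre <- preprocess_config(first_channel = 1, last_channel = 5000)
  expect_error(
    preprocess_dataset(bad, bad_pre, out_dir = withr::local_tempdir()),
    manifest$sample_id[1]
  )
})
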