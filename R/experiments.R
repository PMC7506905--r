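#' Annotation-budget benchmark across acquisition strategies
#'
#' The package's end-to-end experiment: for each replicate seed it generates
#' a synthetic two-class dataset, preprocesses and augments the training
#' split, fits the full-annotation baseline, and runs a set of
#' active-learning arms with identical seeds and budgets. For every arm it
#' records the smallest manual-annotation percentage at which the arm's
#' test accuracy reaches the baseline's ([reach_percentage()]), plus the
#' arm's peak accuracy.
#'
#' The default arms mirror the study design: Algorithm 1 with entropy
#' (no pool), and Algorithm 2 (image pool) with entropy, least confidence,
#' margin, and the random-selection control.
#'
#' @param n_seeds number of replicate datasets.
#' @param seed base seed; replicate `i` uses `seed + i - 1`.
#' @param synth a [synth_config()] describing one replicate (its `seed` is
#'   overridden per replicate). The default is a reduced-size dataset (60
#'   samples per class, 44-52 px cubes, 240 channels) that preserves the
#'   spatial/spectral structure at benchmark-friendly cost.
#' @param pre_cfg preprocessing configuration; default
#'   [auto_preprocess_config()] (71 channels, 32 x 32).
#' @param K manual annotations per pass (default 5, about 5% of the
#'   distinct training samples under the default config).
#' @param arms data frame with columns `arm`, `algorithm`, `criterion`.
#' @param max_iterations cap on loop passes per run.
#' @return Tibble with one row per (seed, arm): `seed`,
#'   `baseline_accuracy`, `arm`, `algorithm`, `criterion`, `reach_pct`,
#'   `peak_accuracy`, `final_accuracy`, `manual_count`.
#' @seealso [benchmark_outcomes()] for the derived win rates.
#' @export
annotation_benchmark <- function(n_seeds = 10L, seed = 1L,
                                 synth = benchmark_synth_config(),
                                 pre_cfg = NULL, K = 5L,
                                 arms = benchmark_arms(),
                                 max_iterations = 500L) {
  pre_cfg <- pre_cfg %||% auto_preprocess_config(synth$n_channels)
  out <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    s <- seed + i - 1L
    cfg <- synth
    cfg$seed <- s
    ds <- generate_cubes(cfg)
    prep <- preprocess_cubes(ds$manifest, ds$cubes, pre_cfg,
                             augment_train = TRUE)
    backend <- reference_backend()
    baseline <- fit_full_baseline(prep$manifest, prep$cubes, backend)
    rows <- lapply(seq_len(nrow(arms)), function(a) {
      oracle <- make_oracle(prep$manifest, label_noise = synth$label_noise,
                            seed = s)
      run <- run_active_learning(
        prep$manifest,
        loop_config(K = K, criterion = arms$criterion[a],
                    algorithm = arms$algorithm[a],
                    max_iterations = max_iterations, seed = s),
        oracle, backend, prep$cubes
      )
      curve <- annotation_curve(run)
      tibble::tibble(
        seed = s,
        baseline_accuracy = baseline$accuracy,
        arm = arms$arm[a],
        algorithm = arms$algorithm[a],
        criterion = arms$criterion[a],
        reach_pct = reach_percentage(curve, baseline$accuracy),
        peak_accuracy = max(curve$accuracy),
        final_accuracy = curve$accuracy[nrow(curve)],
        manual_count = run$manual_count
      )
    })
    out[[i]] <- bind_rows(rows)
  }
  bind_rows(out)
}

#' Default benchmark arms
#'
#' @return Tibble of (arm, algorithm, criterion) rows.
#' @export
benchmark_arms <- function() {
  tibble::tribble(
    ~arm,           ~algorithm, ~criterion,
    "alg1_entropy", "alg1",     "entropy",
    "alg2_entropy", "alg2",     "entropy",
    "alg2_lc",      "alg2",     "least_confidence",
    "alg2_margin",  "alg2",     "margin",
    "alg2_random",  "alg2",     "random"
  )
}

#' Default benchmark dataset configuration
#'
#' The study-shaped task at benchmark scale: 2 classes, 60 samples per
#' class, separation 3, with the spatial extent and channel count reduced
#' (44-52 px, 240 channels) so full multi-seed benchmarks stay cheap while
#' every preprocessing stage remains non-trivial (the channel window is
#' strided down to 71 channels, cubes are resized to 32 x 32, training is
#' augmented 6-fold).
#'
#' @param n_per_class samples per class.
#' @param separation task separation.
#' @return A [synth_config()].
#' @export
benchmark_synth_config <- function(n_per_class = 60L, separation = 3) {
  synth_config(
    n_per_class = n_per_class,
    height = c(44L, 52L), width = c(44L, 52L),
    n_channels = 240L,
    separation = separation
  )
}

#' Win rates derived from a benchmark table
#'
#' Summarizes [annotation_benchmark()] output into the two headline
#' comparisons: how often the image pool (Algorithm 2, entropy) reaches the
#' baseline strictly cheaper than Algorithm 1, and how often each
#' uncertainty criterion reaches it no later than the random-selection
#' control.
#'
#' @param bench output of [annotation_benchmark()].
#' @return List with `n_seeds`, `alg2_beats_alg1` (count of seeds with a
#'   strictly smaller reach percentage), `criteria_beat_random` (named
#'   counts of seeds with reach percentage <= random's), and the
#'   mean `baseline_accuracy`.
#' @export
benchmark_outcomes <- function(bench) {
  wide <- bench %>%
    select(seed, arm, reach_pct) %>%
    tidyr::pivot_wider(names_from = arm, values_from = reach_pct)
  crit_arms <- c("alg2_entropy", "alg2_lc", "alg2_margin")
  crit_wins <- vapply(crit_arms, function(a) {
    sum(wide[[a]] <= wide$alg2_random)
  }, integer(1))
  list(
    n_seeds = nrow(wide),
    alg2_beats_alg1 = sum(wide$alg2_entropy < wide$alg1_entropy),
    criteria_beat_random = crit_wins,
    mean_baseline_accuracy = mean(
      bench$baseline_accuracy[!duplicated(bench$seed)]
    )
  )
}
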