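#' Specify an augmentation-comparison experiment
#'
#' Describes a full, reproducible experiment comparing augmentation regimes
#' on synthetic streams: one low-artifact training stream (plus a
#' validation stream from the same regime), and test groups that include
#' artifact regimes absent from training — by default a `highly_visible`
#' group resembling the training data, a `wave_like` group with strong
#' wave artifacts, and a `particle_free` wave-artifact group for
#' false-positive rates. Each regime is trained `repeats` times; the model
#' with the median overall F1 across repeats represents the regime.
#'
#' All randomness is fanned out deterministically from `seed`: data seeds
#' depend only on the repeat (so every regime sees identical streams) and
#' training seeds on regime and repeat.
#'
#' @param regimes augmentation regimes to compare (see [augment_config()]).
#' @param repeats training runs per regime.
#' @param seed master seed.
#' @param width,height frame extent in pixels.
#' @param n_train_frames,n_val_frames,n_test_frames frames per stream.
#' @param n_particles particles per particle-bearing stream.
#' @param noise_sigma uncorrelated noise level of all streams.
#' @param waves [wave_intervals()] for the wave-artifact test group, the
#'   reference streams and the procedural-wave augmentation.
#' @param tile_size tile side length for tile-based overlays, in pixels.
#' @param n_reference_frames frames in the artifact reference stream.
#' @param lr,batch_size,max_epochs,depth,base_filters training settings
#'   (see [train_config()]); the defaults here are desk-scale.
#' @param mask_threshold binarisation threshold for predicted masks.
#' @param detect_args list of overrides for [detect_blobs()].
#' @param link_threshold,overlap_threshold linking and matching IoUs.
#' @return an `experiment_spec` object.
#' @export
experiment_spec <- function(regimes = c("none", "waves", "real_tiles"),
                            repeats = 3L, seed = 1L,
                            width = 64L, height = 64L,
                            n_train_frames = 12L, n_val_frames = 4L,
                            n_test_frames = 6L, n_particles = 4L,
                            noise_sigma = 0.02,
                            waves = wave_intervals(gamma_range = c(0.15, 0.3)),
                            tile_size = 32L, n_reference_frames = 12L,
                            lr = 1e-3, batch_size = 2L, max_epochs = 10L,
                            depth = 5L, base_filters = 16L,
                            mask_threshold = 0.5,
                            detect_args = list(),
                            link_threshold = 0.3,
                            overlap_threshold = 0.3) {
  spec <- as.list(environment())
  known <- c("none", "size_only", "waves", "real_tiles", "generated_tiles")
  if (length(regimes) == 0 || !all(regimes %in% known)) {
    stop("regimes must be a non-empty subset of: ",
         paste(known, collapse = ", "))
  }
  stopifnot(repeats >= 1)
  structure(spec, class = "experiment_spec")
}

# Deterministic seed fan-out from the master seed. Returns a function
# seed_for(kind, rep) -> integer.
make_seeder <- function(master) {
  function(kind, rep = 0L, extra = 0L) {
    key <- sum(utf8ToInt(kind)) %% 1000L
    (as.integer(master) %% 100000L) * 17L + key * 131L + rep * 7919L +
      extra * 104729L
  }
}

# Simulate all streams for one repeat (identical across regimes).
simulate_repeat_data <- function(spec, rep) {
  seed_for <- make_seeder(spec$seed)
  base <- list(width = spec$width, height = spec$height,
               n_particles = spec$n_particles,
               noise_sigma = spec$noise_sigma)
  cfg <- function(..., seed) {
    args <- c(list(...), list(seed = seed))
    args <- c(args, base[!names(base) %in% names(args)])
    do.call(sim_config, args)
  }
  train_stream <- simulate_stream(
    cfg(n_frames = spec$n_train_frames, seed = seed_for("train", rep)))
  val_stream <- simulate_stream(
    cfg(n_frames = spec$n_val_frames, seed = seed_for("val", rep)))
  tests <- list(
    list(group = "highly_visible", stream = simulate_stream(
      cfg(n_frames = spec$n_test_frames, seed = seed_for("test_hv", rep)))),
    list(group = "wave_like", stream = simulate_stream(
      cfg(n_frames = spec$n_test_frames, artifacts = spec$waves,
          seed = seed_for("test_wave", rep)))),
    list(group = "particle_free", stream = simulate_stream(
      cfg(n_frames = spec$n_test_frames, n_particles = 0L,
          artifacts = spec$waves, seed = seed_for("test_free", rep))))
  )
  reference <- simulate_reference_stream(
    cfg(n_frames = spec$n_reference_frames, artifacts = spec$waves,
        seed = seed_for("reference", rep)))
  list(train = train_stream, val = val_stream, tests = tests,
       reference = reference)
}

# Build the augment_config for a regime, given this repeat's data.
build_augmentation <- function(spec, regime, data, tile_dir = NULL) {
  if (regime == "none") {
    return(augment_config("none"))
  }
  particle_streams <- c(list(data$train, data$val),
                        lapply(Filter(function(tt) tt$group != "particle_free",
                                      data$tests), `[[`, "stream"))
  medians <- vapply(particle_streams,
                    function(s) median_particle_area(s$traces), numeric(1))
  size_iv <- size_factor_interval(medians, medians[1])
  switch(regime,
    size_only = augment_config("size_only",
                               size_interval = size_iv),
    waves = augment_config("waves", size_interval = size_iv,
                           waves = spec$waves),
    real_tiles = augment_config(
      "real_tiles", size_interval = size_iv,
      tiles = real_cutout_source(data$reference, spec$tile_size,
                                 spec$tile_size)),
    generated_tiles = {
      dir <- tile_dir %||% file.path(tempdir(),
                                     paste0("tiles_", Sys.getpid()))
      make_tiles(data$reference, dir, n = 64, v = spec$tile_size,
                 w = spec$tile_size)
      augment_config("generated_tiles", size_interval = size_iv,
                     tiles = directory_tile_source(dir, spec$tile_size,
                                                   spec$tile_size))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Train one regime on one repeat's data and evaluate on its test groups.
run_single <- function(spec, regime, rep, data, verbose = FALSE) {
  seed_for <- make_seeder(spec$seed)
  aug <- build_augmentation(spec, regime, data)
  cfg <- train_config(lr = spec$lr, batch_size = spec$batch_size,
                      max_epochs = spec$max_epochs, depth = spec$depth,
                      base_filters = spec$base_filters, augment = aug,
                      seed = seed_for(paste0("train_", regime), rep))
  model <- train(data$train, data$val, cfg, verbose = verbose)
  rows <- lapply(data$tests, function(tt) {
    stream <- tt$stream
    masks <- lapply(stream$frames, function(fr) {
      predict_mask(model, fr, threshold = spec$mask_threshold)
    })
    predicted <- do.call(detect_traces,
                         c(list(masks), spec$detect_args,
                           list(link_threshold = spec$link_threshold)))
    ev <- evaluate_stream(predicted, stream$traces,
                          n_frames = length(stream$frames),
                          overlap_threshold = spec$overlap_threshold)
    data.frame(stream = tt$group, group = tt$group, f1 = ev$f1,
               count_exactness = ev$count_exactness,
               fp_per_image = ev$fp_per_image,
               tp = ev$tp, fp = ev$fp, fn = ev$fn)
  })
  results <- do.call(rbind, rows)
  particle <- results[results$group != "particle_free", ]
  list(regime = regime, rep = rep, results = results,
       f1_overall = mean(particle$f1), model = model)
}

#' Run an augmentation-comparison experiment
#'
#' For every regime and repeat: simulate (or reuse) the repeat's streams,
#' train under the regime, detect and link traces on every test stream and
#' evaluate them. Per regime the repeat with the median overall F1 (mean F1
#' across particle-bearing test streams) is selected as the representative
#' model, and its grouped results form the comparison table. A failing
#' regime is recorded with a diagnostic and does not abort the others.
#'
#' @param spec an [experiment_spec()].
#' @param outdir optional directory; when given, the comparison table, the
#'   per-run results and the resolved spec are written there.
#' @param verbose print training progress.
#' @return an `experiment_report`: list with `comparison` (one row per
#'   regime and test group), `runs` (per regime x repeat summaries),
#'   `selected` (chosen repeat per regime), `errors` and `spec`.
#' @export
run_experiment <- function(spec, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  data_per_rep <- lapply(seq_len(spec$repeats),
                         function(r) simulate_repeat_data(spec, r))
  runs <- list()
  errors <- list()
  selected <- list()
  comparison <- list()
  for (regime in spec$regimes) {
    regime_runs <- list()
    failed <- FALSE
    for (r in seq_len(spec$repeats)) {
      run <- tryCatch(
        run_single(spec, regime, r, data_per_rep[[r]], verbose = verbose),
        error = function(e) e)
      if (inherits(run, "error")) {
        errors[[regime]] <- conditionMessage(run)
        warning("regime ", regime, " failed: ", conditionMessage(run),
                call. = FALSE)
        failed <- TRUE
        break
      }
      regime_runs[[r]] <- run
      runs[[length(runs) + 1L]] <-
        data.frame(regime = regime, rep = r, f1_overall = run$f1_overall)
    }
    if (failed) next
    f1s <- vapply(regime_runs, `[[`, numeric(1), "f1_overall")
    sel <- which(rank(f1s, ties.method = "first") ==
                 ceiling(length(f1s) / 2))  # median run (lower on even n)
    selected[[regime]] <- list(rep = sel,
                               results = regime_runs[[sel]]$results,
                               f1_overall = f1s[sel], all_f1 = f1s)
    res <- regime_runs[[sel]]$results
    res$regime <- regime
    comparison[[regime]] <- res
  }
  report <- structure(
    list(comparison = if (length(comparison)) do.call(rbind, comparison),
         runs = if (length(runs)) do.call(rbind, runs),
         selected = selected, errors = errors, spec = spec),
    class = "experiment_report")
  if (!is.null(outdir)) {
    write_experiment_report(report, outdir)
  }
  report
}

write_experiment_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$comparison)) {
    write.csv(report$comparison, file.path(outdir, "comparison.csv"),
              row.names = FALSE)
  }
  if (!is.null(report$runs)) {
    write.csv(report$runs, file.path(outdir, "runs.csv"), row.names = FALSE)
  }
  resolved <- report$spec
  resolved$waves <- unclass(resolved$waves)
  resolved[c("detect_args")] <- NULL
  yaml::write_yaml(lapply(unclass(resolved), function(x)
    if (is.function(x)) NULL else x), file.path(outdir, "spec.yaml"))
  invisible(outdir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Augmentation comparison (median-F1 model per regime)\n")
  if (!is.null(x$comparison)) {
    cols <- c("regime", "group", "f1", "count_exactness", "fp_per_image")
    print(x$comparison[, cols], digits = 3, row.names = FALSE)
  }
  if (length(x$errors)) {
    cat("Failed regimes:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load an experiment specification from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_spec()]; the nested
#' key `waves` (a list of [wave_intervals()] arguments) is converted
#' automatically.
#'
#' @param path YAML file.
#' @return an `experiment_spec`.
#' @export
read_experiment_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$waves)) {
    raw$waves <- do.call(wave_intervals, lapply(raw$waves, unlist))
  }
  do.call(experiment_spec, raw)
}
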