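test_that("a particle-free configuration yields empty masks and traces", {
  str <- simulate_stream(tiny_config(n_particles = 0L))
  expect_true(all(vapply(str$masks, function(m) all(m == 0), TRUE)))
  expect_equal(nrow(str$traces), 0)
})

test_that("streams are bit-identical for a fixed seed", {
  cfg <- tiny_config(artifacts = wave_intervals(), noise_sigma = 0.03)
  a <- simulate_stream(cfg)
  b <- simulate_stream(cfg)
  expect_identical(a$frames, b$frames)
  expect_identical(a$traces, b$traces)
  expect_identical(a$decomposition, b$decomposition)
})

test_that("a single particle produces one trace over its whole lifetime", {
  cfg <- sim_config(width = 40L, height = 40L, n_frames = 8L,
                    n_particles = 1L, particle_radius = c(3, 3),
                    particle_intensity = c(0.3, 0.3),
                    particle_lifetime = c(5L, 5L), noise_sigma = 0,
                    seed = 42L)
  str <- simulate_stream(cfg)
  expect_equal(length(unique(str$traces$trace_id)), 1)
  frames_seen <- sort(str$traces$frame)
  expect_length(frames_seen, 5)
  expect_equal(frames_seen, seq(min(frames_seen), by = 1, length.out = 5))

  # mask support equals the analytic pixel disc of radius 3 at the centre
  t0 <- frames_seen[1] + 1L
  mask <- str$masks[[t0]]
  on <- which(mask == 1, arr.ind = TRUE)
  # recover the centre from the particle grid's maximum
  P <- str$decomposition[[t0]]$particle
  peak <- which(P == max(P), arr.ind = TRUE)[1, ]
  # analytic support count: pixels within distance 3 of the true centre;
  # compare against a brute-force count around the peak pixel
  d <- sqrt((on[, 1] - peak[1])^2 + (on[, 2] - peak[2])^2)
  expect_true(all(d <= 3 + 1))            # support confined to the disc
  expect_gte(nrow(on), 20)                # lower bound on the disc area
  # mask equals positive particle support exactly
  expect_identical((P > 0) * 1L, mask)
  # all frames of the trace share the same box, which bounds the support
  box <- unique(str$traces[, c("x_min", "y_min", "x_max", "y_max")])
  expect_equal(nrow(box), 1)
  expect_true(all(on[, 2] - 1 >= box$x_min & on[, 2] - 1 < box$x_max))
  expect_true(all(on[, 1] - 1 >= box$y_min & on[, 1] - 1 < box$y_max))
})

test_that("frames reconstruct exactly from their decomposition", {
  str <- simulate_stream(tiny_config(artifacts = wave_intervals(),
                                     noise_sigma = 0.05))
  for (t in seq_along(str$frames)) {
    d <- str$decomposition[[t]]
    rebuilt <- pmin(pmax(d$particle + d$background + d$correlated +
                           d$uncorrelated, 0), 1)
    expect_equal(rebuilt, str$frames[[t]])
    expect_identical((d$particle > 0) * 1L, str$masks[[t]])
  }
})

test_that("reference streams carry no particle signal", {
  str <- simulate_reference_stream(tiny_config(n_particles = 5L))
  expect_true(all(vapply(str$decomposition,
                         function(d) all(d$particle == 0), TRUE)))
  expect_equal(nrow(str$traces), 0)

  # noiseless, artifact-free reference is exactly the constant background
  flat <- simulate_reference_stream(sim_config(
    width = 16L, height = 12L, n_frames = 3L, noise_sigma = 0,
    background = c(0.5, 0.5), seed = 1L))
  for (f in flat$frames) expect_equal(f, matrix(0.5, 12, 16))
})

test_that("wave artifacts stay within the configured strength bound", {
  iv <- wave_intervals(gamma_range = c(0.2, 0.2))
  cfg <- sim_config(width = 48L, height = 48L, n_frames = 6L,
                    noise_sigma = 0.02, artifacts = iv, seed = 9L)
  str <- simulate_reference_stream(cfg)
  frac_ok <- vapply(seq_along(str$frames), function(t) {
    d <- str$decomposition[[t]]
    dev <- abs(str$frames[[t]] - d$background)
    mean(dev <= 0.2 + 3 * cfg$noise_sigma)
  }, numeric(1))
  expect_true(all(frac_ok >= 0.99))
})

test_that("line artifacts render a static softened band", {
  cfg <- sim_config(width = 32L, height = 32L, n_frames = 3L,
                    noise_sigma = 0,
                    artifacts = line_artifact_spec(orientation = 0,
                                                   line_width = 2,
                                                   amplitude = 0.2),
                    seed = 3L)
  str <- simulate_reference_stream(cfg)
  C1 <- str$decomposition[[1]]$correlated
  expect_equal(max(C1), 0.2, tolerance = 0.05)
  # static across frames
  expect_identical(C1, str$decomposition[[3]]$correlated)
  # horizontal orientation: constant along x
  expect_equal(C1[, 1], C1[, 32])
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(width = 0), "positive area")
  expect_error(sim_config(n_frames = 0), "at least one frame")
  expect_error(sim_config(particle_radius = c(4, 2)), "empty range")
  expect_error(simulate_stream(sim_config(width = 8L, height = 8L,
                                          particle_radius = c(4, 4),
                                          seed = 1L)),
               "too small")
})

test_that("streams, masks and traces survive a file round trip", {
  str <- simulate_stream(tiny_config())
  dir <- withr::local_tempdir()

  tif <- file.path(dir, "stream.tif")
  write_stream(str, tif)
  back <- read_stream(tif)
  expect_length(back, length(str$frames))
  expect_equal(back[[2]], str$frames[[2]], tolerance = 1e-6)

  pngdir <- file.path(dir, "frames")
  write_stream(str, pngdir, format = "png")
  back2 <- read_stream(pngdir)
  expect_equal(back2[[1]], str$frames[[1]], tolerance = 0.01)

  mdir <- file.path(dir, "masks")
  write_masks(str$masks, mdir)
  masks <- read_masks(mdir)
  expect_identical(masks[[3]], str$masks[[3]])

  csv <- file.path(dir, "traces.csv")
  write_traces(str$traces, csv)
  expect_equal(read_traces(csv), str$traces)
})
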