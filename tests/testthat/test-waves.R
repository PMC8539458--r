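test_that("wave amplitude follows the sine of scaled distance", {
  # at the wave centre the distance is 0, so only the phase remains
  expect_equal(wave_amplitude(10, 10, c_w = c(10, 10), sigma = 0.7,
                              omega = pi / 2), 1)
  expect_equal(wave_amplitude(10, 10, c_w = c(10, 10), sigma = 0.7,
                              omega = 0), 0)
  # one pixel away with sigma = pi/2 and no phase: sin(pi/2) = 1
  expect_equal(wave_amplitude(11, 10, c_w = c(10, 10), sigma = pi / 2,
                              omega = 0), 1)
})

test_that("wave amplitude is radially symmetric about the centre", {
  c_w <- c(7, 3)
  # two grid points at the same exact distance from the centre
  a1 <- wave_amplitude(c_w[1] + 3, c_w[2] + 4, c_w, 0.37, 1.1)
  a2 <- wave_amplitude(c_w[1] - 4, c_w[2] + 3, c_w, 0.37, 1.1)
  a3 <- wave_amplitude(c_w[1] + 5, c_w[2], c_w, 0.37, 1.1)
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("fade factor is 1 at the centre and 0 at the farthest grid point", {
  dom <- c(11, 11)
  expect_equal(fade_factor(3, 5, c_f = c(3, 5), beta = 1, domain = dom), 1)
  # centre at the (1,1) corner: farthest grid point is (11,11)
  expect_equal(fade_factor(11, 11, c_f = c(1, 1), beta = 1, domain = dom), 0)
})

test_that("fade factor matches a brute-force grid maximum", {
  dom <- c(11, 11)
  c_f <- c(1, 1)
  grid <- expand.grid(x = 1:11, y = 1:11)
  for (beta in c(0.4, 0.7, 1)) {
    dmax_pow <- max((sqrt((grid$x - 1)^2 + (grid$y - 1)^2))^beta)
    # point at half the maximum distance along the diagonal
    p <- c(6, 6)
    d <- sqrt(50)
    expect_equal(fade_factor(p[1], p[2], c_f, beta, dom),
                 1 - d^beta / dmax_pow)
  }
  # beta = 1, half distance -> exactly 0.5
  expect_equal(fade_factor(6, 6, c_f, 1, dom), 0.5)
})

test_that("fade factor stays in [0,1] over the grid for sampled settings", {
  set.seed(42)
  for (i in 1:25) {
    dom <- c(sample(2:17, 1), sample(2:17, 1))
    c_f <- c(runif(1, -5, dom[1] + 5), runif(1, -5, dom[2] + 5))
    beta <- runif(1, 0.05, 1)
    g <- expand.grid(x = seq_len(dom[1]), y = seq_len(dom[2]))
    e <- fade_factor(g$x, g$y, c_f, beta, dom)
    expect_true(all(e >= 0 - 1e-12) && all(e <= 1 + 1e-12))
  }
})

test_that("a faded wave is the product of amplitude and fade", {
  dom <- c(15, 15)
  # both centres coincide with the evaluated point: h = sin(pi/2) = 1, e = 1
  expect_equal(faded_wave(4, 4, c(4, 4), c(4, 4), 0.5, pi / 2, 1, dom), 1)
  # any point at fade 0 yields 0 regardless of the wave
  expect_equal(faded_wave(15, 15, c(2, 2), c(1, 1), 0.9, 0.3, 1, dom), 0)
  # generic point: product of the two factors
  h <- wave_amplitude(9, 5, c(3, 3), 0.4, 0.2)
  e <- fade_factor(9, 5, c(12, 2), 0.6, dom)
  expect_equal(faded_wave(9, 5, c(3, 3), c(12, 2), 0.4, 0.2, 0.6, dom),
               h * e)
})

test_that("composing waves perturbs no pixel by more than gamma", {
  set.seed(7)
  img <- matrix(runif(32 * 24), 24, 32)
  iv <- wave_intervals()
  for (i in 1:100) {
    p <- sample_wave_params(iv, c(32, 24))
    out <- compose_waves(img, p)
    expect_lte(max(abs(out - img)), p$gamma + 1e-12)
  }
})

test_that("wave composition special cases", {
  img <- matrix(runif(20 * 20), 20, 20)
  p0 <- one_wave(gamma = 0)
  expect_identical(compose_waves(img, p0), img)
  # single wave: difference equals gamma * faded wave pointwise
  p1 <- one_wave(c_w = c(5, 7), c_f = c(15, 3), sigma = 0.4, omega = 0.9,
                 beta = 0.8, gamma = 0.17)
  out <- compose_waves(img, p1)
  xg <- matrix(1:20, 20, 20, byrow = TRUE)
  yg <- matrix(1:20, 20, 20)
  expected <- 0.17 * faded_wave(xg, yg, c(5, 7), c(15, 3), 0.4, 0.9, 0.8,
                                c(20, 20))
  expect_equal(out - img, expected)
})

test_that("wave parameters are sampled inside their intervals", {
  iv <- wave_intervals(n_w = c(2L, 3L), sigma_range = c(0.1, 0.2),
                       omega_range = c(1, 2), beta_range = c(0.2, 0.8),
                       gamma_range = c(0.05, 0.1))
  set.seed(99)
  draws <- replicate(1000, sample_wave_params(iv, c(30, 30)),
                     simplify = FALSE)
  betas <- unlist(lapply(draws, `[[`, "beta"))
  expect_gte(min(betas), 0.2)
  expect_lte(max(betas), 0.8)
  expect_true(all(vapply(draws, `[[`, numeric(1), "gamma") >= 0.05))
  expect_true(all(vapply(draws, `[[`, integer(1), "n_w") %in% 2:3))

  # degenerate intervals reproduce the point values exactly
  ivd <- wave_intervals(n_w = c(1L, 1L), sigma_range = c(0.3, 0.3),
                        omega_range = c(1.5, 1.5), beta_range = c(0.5, 0.5),
                        gamma_range = c(0.2, 0.2), centre_margin = 0)
  d <- sample_wave_params(ivd, c(10, 10))
  expect_equal(d$sigma, 0.3)
  expect_equal(d$omega, 1.5)
  expect_equal(d$beta, 0.5)
  expect_equal(d$gamma, 0.2)

  # fixed seed gives identical draws
  set.seed(5); a <- sample_wave_params(iv, c(30, 30))
  set.seed(5); b <- sample_wave_params(iv, c(30, 30))
  expect_identical(a, b)
})

test_that("empty sampling intervals are rejected", {
  expect_error(wave_intervals(sigma_range = c(0.5, 0.1)), "empty interval")
  expect_error(compose_waves(matrix(0, 4, 4),
                             one_wave(gamma = 0.1))[1, 1], NA)
  expect_error(compose_waves(matrix(0, 4, 6),
                             structure(list(), class = "wave_params")))
})
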