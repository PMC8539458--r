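#' Procedural fading sine-wave artifacts
#'
#' Correlated wave artifacts in preprocessed SPR sensor images look like
#' concentric sine waves radiating from a centre, with an intensity that
#' fades away from a second, independent centre. These functions generate
#' such patterns procedurally so they can be superimposed on clean training
#' images, or used by the stream simulator as a correlated-artifact recipe.
#'
#' A single wave is `h(x, y) = sin(d(x, y, c_w) * sigma + omega)` with `d`
#' the Euclidean distance to the wave centre `c_w`, `sigma` the spatial
#' frequency (radians per pixel) and `omega` a phase shift. The fade factor
#' is `e(x, y) = 1 - d(x, y, c_f)^beta / max_grid d^beta`, where the maximum
#' runs over the image grid, so `e` is 1 at the fade centre `c_f` and 0 at
#' the in-grid point farthest from it. A faded wave is the product `h * e`.
#'
#' @param x,y coordinates (1-based, `x` along columns, `y` along rows);
#'   vectorised.
#' @param c_w,c_f numeric length-2 centres `c(x, y)`; may lie outside the
#'   image.
#' @param sigma spatial frequency in radians per pixel.
#' @param omega phase shift in radians.
#' @param beta fade rate in `[0, 1]`; larger values fade more uniformly.
#' @param domain integer length-2 `c(X, Y)`: width and height of the image
#'   grid over which the fade is normalised.
#' @return `wave_amplitude()` and `faded_wave()` return amplitudes in
#'   `[-1, 1]`; `fade_factor()` returns factors in `[0, 1]` for in-domain
#'   points.
#' @examples
#' wave_amplitude(5, 5, c_w = c(5, 5), sigma = 0.3, omega = pi / 2) # == 1
#' fade_factor(1, 1, c_f = c(1, 1), beta = 1, domain = c(11, 11))   # == 1
#' @name waves
NULL

wave_dist <- function(x, y, centre) {
  sqrt((centre[1] - x)^2 + (centre[2] - y)^2)
}

#' @rdname waves
#' @export
wave_amplitude <- function(x, y, c_w, sigma, omega) {
  sin(wave_dist(x, y, c_w) * sigma + omega)
}

#' @rdname waves
#' @export
fade_factor <- function(x, y, c_f, beta, domain) {
  stopifnot(beta >= 0, beta <= 1, length(domain) == 2, all(domain >= 1))
  dmax <- max_grid_dist(c_f, domain)
  if (dmax == 0) {
    return(rep(1, length(x)))  # 1x1 grid: no fade possible
  }
  d <- wave_dist(x, y, c_f)
  1 - pow0(d, beta) / dmax^beta
}

# Largest distance from `centre` to any grid point (1..X) x (1..Y).
# d is convex in (x, y), so the maximum over the rectangle is attained at a
# corner, and all four corners are grid points.
max_grid_dist <- function(centre, domain) {
  corners_x <- c(1, domain[1], 1, domain[1])
  corners_y <- c(1, 1, domain[2], domain[2])
  max(wave_dist(corners_x, corners_y, centre))
}

# x^b with the degenerate convention 0^0 = 1
pow0 <- function(x, b) {
  if (b == 0) rep(1, length(x)) else x^b
}

#' @rdname waves
#' @export
faded_wave <- function(x, y, c_w, c_f, sigma, omega, beta, domain) {
  wave_amplitude(x, y, c_w, sigma, omega) *
    fade_factor(x, y, c_f, beta, domain)
}

#' Wave parameter sets and their sampling intervals
#'
#' `wave_params()` bundles the parameters of a superposition of `n_w` faded
#' waves: per-wave centres, fade centres, frequencies, phases and fade rates,
#' plus one overall strength `gamma` that bounds the amplitude of the summed
#' pattern. `wave_intervals()` describes the closed intervals the parameters
#' are drawn from, and `sample_wave_params()` draws a parameter set uniformly
#' from those intervals (wave and fade centres are sampled over the image
#' domain expanded by `centre_margin` per side, so wave origins may lie
#' off-frame, as observed in real recordings).
#'
#' @param centers,fade_centers numeric matrices with `n_w` rows and columns
#'   `(x, y)`.
#' @param sigma,omega,beta numeric vectors of length `n_w`.
#' @param gamma overall wave strength, `>= 0`; the composed pattern changes
#'   no pixel by more than `gamma`.
#' @return an object of class `wave_params` / `wave_intervals`.
#' @export
wave_params <- function(centers, fade_centers, sigma, omega, beta, gamma) {
  centers <- rbind(centers)
  fade_centers <- rbind(fade_centers)
  n_w <- nrow(centers)
  stopifnot(
    ncol(centers) == 2, ncol(fade_centers) == 2,
    nrow(fade_centers) == n_w,
    length(sigma) == n_w, length(omega) == n_w, length(beta) == n_w,
    all(beta >= 0), all(beta <= 1), gamma >= 0
  )
  structure(
    list(n_w = n_w, centers = centers, fade_centers = fade_centers,
         sigma = sigma, omega = omega, beta = beta, gamma = gamma),
    class = "wave_params"
  )
}

#' @rdname wave_params
#' @param n_w integer range `c(lo, hi)` for the wave count.
#' @param sigma_range,omega_range,beta_range,gamma_range closed sampling
#'   intervals. Defaults give visually plausible wave regimes from slow
#'   large-scale swells to higher-frequency ripples.
#' @param centre_margin fraction of the image extent added on each side of
#'   the sampling domain for wave/fade centres.
#' @export
wave_intervals <- function(n_w = c(1L, 4L),
                           sigma_range = c(0.05, 0.6),
                           omega_range = c(0, 2 * pi),
                           beta_range = c(0.3, 1),
                           gamma_range = c(0.05, 0.3),
                           centre_margin = 0.5) {
  iv <- list(n_w = as.integer(n_w), sigma_range = sigma_range,
             omega_range = omega_range, beta_range = beta_range,
             gamma_range = gamma_range, centre_margin = centre_margin)
  for (nm in c("n_w", "sigma_range", "omega_range", "beta_range",
               "gamma_range")) {
    if (length(iv[[nm]]) != 2 || iv[[nm]][1] > iv[[nm]][2]) {
      stop("empty interval for ", nm)
    }
  }
  structure(iv, class = "wave_intervals")
}

#' @rdname wave_params
#' @param intervals a [wave_intervals()] object.
#' @param domain integer `c(X, Y)` image extent the waves will be applied to.
#' @export
sample_wave_params <- function(intervals, domain) {
  stopifnot(inherits(intervals, "wave_intervals"), length(domain) == 2)
  n_w <- if (intervals$n_w[1] == intervals$n_w[2]) intervals$n_w[1] else
    sample(intervals$n_w[1]:intervals$n_w[2], 1)
  m <- intervals$centre_margin
  lo <- 1 - m * domain
  hi <- domain + m * domain
  runif2 <- function(r, n = n_w) runif(n, r[1], r[2])
  centers <- cbind(runif(n_w, lo[1], hi[1]), runif(n_w, lo[2], hi[2]))
  fade_centers <- cbind(runif(n_w, lo[1], hi[1]), runif(n_w, lo[2], hi[2]))
  wave_params(
    centers = centers, fade_centers = fade_centers,
    sigma = runif2(intervals$sigma_range),
    omega = runif2(intervals$omega_range),
    beta = runif2(intervals$beta_range),
    gamma = runif(1, intervals$gamma_range[1], intervals$gamma_range[2])
  )
}

#' Superimpose faded waves on an image
#'
#' Adds the `gamma / n_w`-weighted sum of the `n_w` faded waves in `params`
#' to `image`. Because each faded wave has amplitude at most 1, the output
#' differs from the input by at most `gamma` at every pixel. The result is
#' deliberately not clipped to `[0, 1]`; clipping happens once, when an
#' augmented frame is finalised (see [apply_overlay()]).
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param params a [wave_params()] object.
#' @return matrix of the same shape as `image`.
#' @export
compose_waves <- function(image, params) {
  stopifnot(is.matrix(image), inherits(params, "wave_params"))
  if (params$gamma == 0) {
    return(image)
  }
  image + wave_field(dim(image)[2:1], params)
}

# The additive wave pattern alone, for an X-by-Y domain given as c(X, Y).
wave_field <- function(domain, params) {
  X <- domain[1]; Y <- domain[2]
  xg <- matrix(seq_len(X), nrow = Y, ncol = X, byrow = TRUE)
  yg <- matrix(seq_len(Y), nrow = Y, ncol = X)
  acc <- matrix(0, Y, X)
  for (i in seq_len(params$n_w)) {
    acc <- acc + faded_wave(xg, yg, params$centers[i, ],
                            params$fade_centers[i, ], params$sigma[i],
                            params$omega[i], params$beta[i], domain)
  }
  acc * params$gamma / params$n_w
}
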