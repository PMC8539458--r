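#' Configure a synthetic sensor-image stream
#'
#' The simulator emulates preprocessed SPR sensor frames with an additive
#' signal model: every frame is `clip01(P + B + C + U)` where `P >= 0` is
#' the particle signal (bright isotropic Gaussian spots persisting over
#' several consecutive frames), `B` a per-frame constant background, `C` a
#' correlated artifact (fading waves or a softened line), and `U`
#' uncorrelated zero-mean Gaussian pixel noise. The unclipped components are
#' returned alongside each frame so that downstream stages can be tested
#' against the exact decomposition.
#'
#' @param width,height frame extent in pixels.
#' @param n_frames number of frames in the stream.
#' @param n_particles number of particle traces in the stream.
#' @param particle_radius range `c(lo, hi)` of spot radii in pixels; the
#'   Gaussian profile has `sd = radius / 3` and is cut to zero beyond
#'   `radius`, so the spot support (and hence the ground-truth mask) is a
#'   disc of that radius.
#' @param particle_intensity range of peak spot intensities above background.
#' @param particle_lifetime range of trace lengths in frames.
#' @param background range of the per-frame constant background level.
#' @param noise_sigma standard deviation of the uncorrelated pixel noise.
#' @param artifacts correlated-artifact recipe: `"none"`, a
#'   [wave_intervals()] object (fresh wave parameters are drawn per frame),
#'   or `line_artifact_spec()` for a static softened line.
#' @param min_separation minimum pairwise distance between particle centres
#'   in pixels (0 disables the constraint).
#' @param seed optional integer; when given, [simulate_stream()] seeds the
#'   R RNG so the stream is bit-reproducible.
#' @return a `sim_config` object.
#' @export
sim_config <- function(width = 64L, height = 64L, n_frames = 8L,
                       n_particles = 4L,
                       particle_radius = c(2.5, 4),
                       particle_intensity = c(0.25, 0.5),
                       particle_lifetime = c(3L, 6L),
                       background = c(0.35, 0.45),
                       noise_sigma = 0.02,
                       artifacts = "none",
                       min_separation = 0,
                       seed = NULL) {
  if (width < 1 || height < 1) stop("frame must have positive area")
  if (n_frames < 1) stop("stream must contain at least one frame")
  ranges <- list(particle_radius = particle_radius,
                 particle_intensity = particle_intensity,
                 particle_lifetime = particle_lifetime,
                 background = background)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop("empty range for ", nm)
  }
  stopifnot(n_particles >= 0, noise_sigma >= 0, min_separation >= 0)
  ok_artifacts <- identical(artifacts, "none") ||
    inherits(artifacts, "wave_intervals") ||
    inherits(artifacts, "line_artifact_spec")
  if (!ok_artifacts) {
    stop("artifacts must be \"none\", wave_intervals() or line_artifact_spec()")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         n_frames = as.integer(n_frames), n_particles = as.integer(n_particles),
         particle_radius = particle_radius,
         particle_intensity = particle_intensity,
         particle_lifetime = as.integer(particle_lifetime),
         background = background, noise_sigma = noise_sigma,
         artifacts = artifacts, min_separation = min_separation, seed = seed),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @param orientation line angle in radians (0 = horizontal).
#' @param line_width Gaussian cross-profile standard deviation in pixels.
#' @param amplitude peak added intensity of the line.
#' @export
line_artifact_spec <- function(orientation = NULL, line_width = 3,
                               amplitude = 0.15) {
  structure(list(orientation = orientation, line_width = line_width,
                 amplitude = amplitude),
            class = "line_artifact_spec")
}

#' Simulate a particle-bearing image stream
#'
#' Generates a stream of frames under the additive signal model of
#' [sim_config()], together with its ground truth (per-frame binary masks
#' marking exactly the pixels with positive particle signal, and a trace
#' table with one row per particle per visible frame) and the per-frame
#' signal decomposition.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_stream`: a list with elements
#'   `frames` (list of `[0,1]` matrices), `masks` (list of 0/1 matrices),
#'   `traces` (data.frame `trace_id, frame, x_min, y_min, x_max, y_max`,
#'   0-based half-open boxes and 0-based frame indices), `decomposition`
#'   (per frame: `particle` matrix, `background` scalar, `correlated` and
#'   `uncorrelated` matrices, all unclipped) and `config`.
#' @export
simulate_stream <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  X <- config$width; Y <- config$height; TT <- config$n_frames

  particles <- draw_particles(config)
  line_field <- if (inherits(config$artifacts, "line_artifact_spec")) {
    render_line_artifact(config$artifacts, X, Y)
  }

  frames <- masks <- decomposition <- vector("list", TT)
  trace_rows <- list()
  for (t in seq_len(TT)) {
    P <- matrix(0, Y, X)
    for (p in particles) {
      if (t - 1L >= p$start && t - 1L < p$start + p$lifetime) {
        P[p$support] <- P[p$support] + p$values
        trace_rows[[length(trace_rows) + 1L]] <-
          data.frame(trace_id = p$id, frame = t - 1L,
                     x_min = p$box[1], y_min = p$box[2],
                     x_max = p$box[3], y_max = p$box[4])
      }
    }
    B <- runif(1, config$background[1], config$background[2])
    C <- if (inherits(config$artifacts, "wave_intervals")) {
      wave_field(c(X, Y), sample_wave_params(config$artifacts, c(X, Y)))
    } else if (!is.null(line_field)) {
      line_field
    } else {
      matrix(0, Y, X)
    }
    U <- if (config$noise_sigma > 0) {
      matrix(rnorm(X * Y, 0, config$noise_sigma), Y, X)
    } else {
      matrix(0, Y, X)
    }
    frames[[t]] <- clip01(P + B + C + U)
    masks[[t]] <- (P > 0) * 1L
    decomposition[[t]] <- list(particle = P, background = B,
                               correlated = C, uncorrelated = U)
  }

  traces <- if (length(trace_rows)) {
    do.call(rbind, trace_rows)
  } else {
    empty_traces()
  }
  traces <- traces[order(traces$trace_id, traces$frame), , drop = FALSE]
  rownames(traces) <- NULL
  structure(list(frames = frames, masks = masks, traces = traces,
                 decomposition = decomposition, config = config),
            class = "sim_stream")
}

#' @rdname simulate_stream
#' @description `simulate_reference_stream()` runs the identical pipeline
#'   with the particle term forced to zero, producing background + artifact
#'   material (for tile extraction or false-positive evaluation).
#' @export
simulate_reference_stream <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ref <- config
  ref$n_particles <- 0L
  simulate_stream(ref)
}

empty_traces <- function() {
  data.frame(trace_id = integer(), frame = integer(),
             x_min = integer(), y_min = integer(),
             x_max = integer(), y_max = integer())
}

# Draw particle descriptors: centre, radius, intensity, lifetime window and
# the rendered spot (support indices + values) shared by all visible frames.
draw_particles <- function(config) {
  X <- config$width; Y <- config$height
  n <- config$n_particles
  if (n == 0) return(list())
  r_hi <- config$particle_radius[2]
  if (X < 2 * r_hi + 3 || Y < 2 * r_hi + 3) {
    stop("frame too small for the configured particle radius")
  }
  centres <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(1000)) {
      cand <- c(runif(1, r_hi + 2, X - r_hi - 1),
                runif(1, r_hi + 2, Y - r_hi - 1))
      if (config$min_separation == 0 || i == 1) {
        placed <- TRUE; break
      }
      d <- sqrt(colSums((t(centres[seq_len(i - 1L), , drop = FALSE]) - cand)^2))
      if (all(d >= config$min_separation)) {
        placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place particles with the requested ",
                      "min_separation")
    centres[i, ] <- cand
  }
  lapply(seq_len(n), function(i) {
    r <- runif(1, config$particle_radius[1], config$particle_radius[2])
    a <- runif(1, config$particle_intensity[1], config$particle_intensity[2])
    L <- sample1(config$particle_lifetime[1]:config$particle_lifetime[2])
    L <- min(L, config$n_frames)
    start <- sample1(0:(config$n_frames - L))
    spot <- render_spot(centres[i, ], r, a, X, Y)
    c(list(id = i, centre = centres[i, ], radius = r, intensity = a,
           lifetime = L, start = start), spot)
  })
}

# Isotropic Gaussian spot (sd = radius/3) with hard support cutoff at
# `radius`, so mask support is exactly the pixel disc d <= radius.
render_spot <- function(centre, radius, intensity, X, Y) {
  xs <- max(1, ceiling(centre[1] - radius)):min(X, floor(centre[1] + radius))
  ys <- max(1, ceiling(centre[2] - radius)):min(Y, floor(centre[2] + radius))
  dx <- outer(rep(1, length(ys)), xs - centre[1])
  dy <- outer(ys - centre[2], rep(1, length(xs)))
  d2 <- dx^2 + dy^2
  inside <- d2 <= radius^2
  if (!any(inside)) stop("particle radius too small to cover a pixel")
  sd <- radius / 3
  vals <- intensity * exp(-d2[inside] / (2 * sd^2))
  idx <- cbind(rep(ys, times = length(xs))[as.vector(inside)],
               rep(xs, each = length(ys))[as.vector(inside)])
  sup_x <- range(idx[, 2]); sup_y <- range(idx[, 1])
  list(support = idx, values = vals,
       box = c(sup_x[1] - 1L, sup_y[1] - 1L, sup_x[2], sup_y[2]))
}

render_line_artifact <- function(spec, X, Y) {
  theta <- if (is.null(spec$orientation)) runif(1, 0, pi) else spec$orientation
  px <- runif(1, 1, X); py <- runif(1, 1, Y)
  xg <- matrix(seq_len(X), nrow = Y, ncol = X, byrow = TRUE)
  yg <- matrix(seq_len(Y), nrow = Y, ncol = X)
  # signed distance to the line through (px, py) with direction theta
  dist <- -(xg - px) * sin(theta) + (yg - py) * cos(theta)
  spec$amplitude * exp(-dist^2 / (2 * spec$line_width^2))
}

# Uniform draw from a vector, robust to length-1 vectors (for which
# base::sample would draw from 1:x instead).
sample1 <- function(v) {
  if (length(v) == 1) v else sample(v, 1)
}

# Accept either a sim_stream or a bare list of frame matrices.
stream_frames <- function(x) {
  if (inherits(x, "sim_stream")) x$frames
  else if (is.list(x) && all(vapply(x, is.matrix, TRUE))) x
  else stop("expected a sim_stream or a list of frame matrices")
}

#' @export
print.sim_stream <- function(x, ...) {
  cat(sprintf("sim_stream: %d frames of %dx%d, %d traces\n",
              length(x$frames), x$config$width, x$config$height,
              length(unique(x$traces$trace_id))))
  invisible(x)
}
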