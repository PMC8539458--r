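#' Particle-size statistics and size-factor intervals
#'
#' Direct size augmentation rescales training images so that the particle
#' sizes seen during training cover the range of sizes plausible across
#' datasets. For each dataset the median area of its annotated particle
#' regions is computed (the median compensates for annotation outliers);
#' the scale-factor interval for a dataset is
#' `[s_min / s_med, s_max / s_med]`, where `s_min`/`s_max` are the smallest
#' and largest per-dataset medians and `s_med` the dataset's own median.
#'
#' @param annotations either a numeric vector of region areas in pixels, or
#'   a trace data.frame (areas are then the per-record bounding-box areas).
#' @return `median_particle_area()`: a scalar area;
#'   `size_factor_interval()`: a `size_factor_interval` object with fields
#'   `lower` and `upper`.
#' @export
median_particle_area <- function(annotations) {
  areas <- if (is.data.frame(annotations)) {
    (annotations$x_max - annotations$x_min) *
      (annotations$y_max - annotations$y_min)
  } else {
    annotations
  }
  if (length(areas) == 0) stop("no annotated regions")
  median(areas)
}

#' @rdname median_particle_area
#' @param per_dataset_medians numeric vector of median areas, one per
#'   dataset (including this dataset's own).
#' @param own_median this dataset's median area.
#' @export
size_factor_interval <- function(per_dataset_medians, own_median) {
  stopifnot(length(per_dataset_medians) >= 1)
  if (any(per_dataset_medians <= 0) || own_median <= 0) {
    stop("median areas must be positive")
  }
  structure(list(lower = min(per_dataset_medians) / own_median,
                 upper = max(per_dataset_medians) / own_median),
            class = "size_factor_interval")
}

#' Randomly rescale a training image with its labels
#'
#' Draws scale factors uniformly from `interval` — independently per axis by
#' default, one shared factor when `isotropic = TRUE` — and rescales the
#' image (bilinear), the mask (nearest neighbour, so it stays binary) and
#' the trace bounding boxes (floored minima / ceiled maxima, so every
#' rescaled mask pixel stays inside its rescaled box).
#'
#' @param image numeric matrix.
#' @param mask binary matrix of the same shape (or `NULL`).
#' @param traces trace data.frame for this frame (or `NULL`).
#' @param interval a [size_factor_interval()] object or numeric
#'   `c(lower, upper)`.
#' @param isotropic use one factor for both axes.
#' @return list with elements `image`, `mask`, `traces` and the realised
#'   per-axis `factors` `c(fx, fy)`.
#' @export
random_resize <- function(image, mask = NULL, traces = NULL, interval,
                          isotropic = FALSE) {
  if (inherits(interval, "size_factor_interval")) {
    interval <- c(interval$lower, interval$upper)
  }
  stopifnot(length(interval) == 2, interval[1] > 0,
            interval[1] <= interval[2])
  fx <- runif(1, interval[1], interval[2])
  fy <- if (isotropic) fx else runif(1, interval[1], interval[2])
  X <- ncol(image); Y <- nrow(image)
  new_X <- round(X * fx); new_Y <- round(Y * fy)
  if (new_X < 8 || new_Y < 8) {
    stop("rescaled image would be smaller than 8 px per side")
  }
  # realised factors after rounding keep image and boxes consistent
  fx <- new_X / X; fy <- new_Y / Y
  out_image <- if (new_X == X && new_Y == Y) image else
    resize_bilinear(image, new_X, new_Y)
  out_mask <- if (is.null(mask)) NULL else
    resize_nearest(mask, new_X, new_Y)
  out_traces <- if (is.null(traces)) NULL else
    within(traces, {
      x_min <- floor(x_min * fx); x_max <- ceiling(x_max * fx)
      y_min <- floor(y_min * fy); y_max <- ceiling(y_max * fy)
    })
  list(image = out_image, mask = out_mask, traces = out_traces,
       factors = c(fx, fy))
}

resize_bilinear <- function(image, new_X, new_Y) {
  out <- EBImage::resize(image, w = new_Y, h = new_X, filter = "bilinear")
  matrix(as.numeric(out), new_Y, new_X)
}

# Nearest-neighbour resize by index mapping: output pixel centre i - 0.5
# maps to input position (i - 0.5) * n_in / n_out, i.e. input pixel
# ceiling(...). Guarantees scaled-box coverage of mask pixels.
resize_nearest <- function(mask, new_X, new_Y) {
  X <- ncol(mask); Y <- nrow(mask)
  src_x <- pmin(pmax(ceiling((seq_len(new_X) - 0.5) * X / new_X), 1L), X)
  src_y <- pmin(pmax(ceiling((seq_len(new_Y) - 0.5) * Y / new_Y), 1L), Y)
  mask[src_y, src_x, drop = FALSE]
}
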