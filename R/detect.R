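#' Difference-of-Gaussians blob detection
#'
#' Localises bright particle spots in a predicted (binary or soft) mask via
#' a Difference-of-Gaussians scale space: the map is blurred with a
#' geometric ladder of Gaussian widths, consecutive blurs are subtracted
#' (and normalised by the relative sigma step), and local maxima over space
#' and scale above `response_threshold` become detections. The detected
#' scale `sigma` gives a radius estimate `sqrt(2) * sigma` and a bounding
#' box of side `2 * sqrt(2) * sigma`. Same-frame detections whose boxes
#' overlap with IoU > 0.5 are merged, keeping the stronger response.
#'
#' @param map numeric matrix (binary mask or soft network output).
#' @param sigma_min,sigma_max smallest and largest blur widths in pixels.
#' @param n_scales number of blur widths (geometric spacing).
#' @param response_threshold minimum DoG response.
#' @param frame frame index (0-based) stamped on the detections.
#' @return data.frame with columns `frame, x, y, radius, response, x_min,
#'   y_min, x_max, y_max` (centres in 0-based continuous pixel
#'   coordinates; boxes 0-based half-open, clipped to the frame).
#' @export
detect_blobs <- function(map, sigma_min = 1, sigma_max = 8, n_scales = 6L,
                         response_threshold = 0.05, frame = 0L) {
  stopifnot(sigma_min > 0, sigma_min < sigma_max, n_scales >= 2)
  Y <- nrow(map); X <- ncol(map)
  empty <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      radius = numeric(), response = numeric(),
                      x_min = integer(), y_min = integer(),
                      x_max = integer(), y_max = integer())
  if (all(map <= 0)) return(empty)
  sigmas <- exp(seq(log(sigma_min), log(sigma_max), length.out = n_scales))
  blurred <- lapply(sigmas, function(s) {
    # kernel must fit inside the image; truncate wide kernels on small frames
    r <- min(2 * ceiling(3 * s) + 1, min(X, Y))
    if (r %% 2 == 0) r <- r - 1L
    matrix(as.numeric(EBImage::gblur(map, sigma = s, radius = r,
                                     boundary = "replicate")),
           Y, X)
  })
  k <- sigmas[2] / sigmas[1]  # constant ratio of the geometric ladder
  dog <- array(0, dim = c(Y, X, n_scales - 1L))
  for (i in seq_len(n_scales - 1L)) {
    dog[, , i] <- (blurred[[i]] - blurred[[i + 1L]]) / (k - 1)
  }
  peaks <- local_maxima_3d(dog, response_threshold)
  if (nrow(peaks) == 0) return(empty)
  det <- data.frame(
    frame = frame,
    x = peaks[, "col"] - 0.5,            # 0-based pixel-centre coordinates
    y = peaks[, "row"] - 0.5,
    radius = sqrt(2) * sigmas[peaks[, "scale"]],
    response = peaks[, "value"]
  )
  det$x_min <- pmax(0L, floor(det$x - det$radius))
  det$y_min <- pmax(0L, floor(det$y - det$radius))
  det$x_max <- pmin(X, ceiling(det$x + det$radius))
  det$y_max <- pmin(Y, ceiling(det$y + det$radius))
  merge_detections(det, iou_cutoff = 0.5)
}

# Local maxima of a (Y, X, S) array: voxels >= all existing neighbours in
# the 3x3x3 neighbourhood and above `threshold`.
local_maxima_3d <- function(a, threshold) {
  d <- dim(a)
  is_max <- a > threshold
  for (ds in -1:1) for (dc in -1:1) for (dr in -1:1) {
    if (ds == 0 && dc == 0 && dr == 0) next
    shifted <- shift_array(a, dr, dc, ds)
    is_max <- is_max & (a >= shifted)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(cbind(row = integer(), col = integer(), scale = integer(),
                 value = numeric()))
  }
  cbind(row = idx[, 1], col = idx[, 2], scale = idx[, 3],
        value = a[idx])
}

# Shift with -Inf fill so border voxels compare only against real values.
shift_array <- function(a, dr, dc, ds) {
  d <- dim(a)
  out <- array(-Inf, dim = d)
  src_r <- seq_len(d[1]) + dr; src_c <- seq_len(d[2]) + dc
  src_s <- seq_len(d[3]) + ds
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  ok_s <- src_s >= 1 & src_s <= d[3]
  out[ok_r, ok_c, ok_s] <- a[src_r[ok_r], src_c[ok_c], src_s[ok_s]]
  out
}

# Greedy non-maximum suppression on same-frame detections.
merge_detections <- function(det, iou_cutoff = 0.5) {
  if (nrow(det) <= 1) return(det)
  ord <- order(-det$response)
  keep <- logical(nrow(det))
  for (i in ord) {
    kept <- which(keep)
    if (length(kept) == 0 ||
        all(box_iou_vec(det[i, ], det[kept, , drop = FALSE]) <= iou_cutoff)) {
      keep[i] <- TRUE
    }
  }
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# IoU of one box against each row of a box data.frame (half-open boxes).
box_iou_vec <- function(a, b) {
  ix <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  iy <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (area_a + area_b - inter)
}

#' Link detections across frames into particle traces
#'
#' Greedy frame-by-frame linking: detections are processed in ascending
#' frame order; a detection on frame `t + 1` joins the trace whose frame-`t`
#' detection box has the highest IoU with it, provided that IoU is at least
#' `link_threshold` and the trace has not already been extended on this
#' frame. Unmatched detections start new traces; ties in IoU are broken by
#' the lower detection row index. Traces therefore consist of detections on
#' strictly consecutive frames, and every detection belongs to exactly one
#' trace.
#'
#' @param detections data.frame as returned by [detect_blobs()] (rows from
#'   several frames).
#' @param link_threshold minimum IoU to continue a trace.
#' @return the detections with a `trace_id` column.
#' @export
link_traces <- function(detections, link_threshold = 0.3) {
  stopifnot(link_threshold > 0, link_threshold <= 1)
  if (nrow(detections) == 0) {
    detections$trace_id <- integer()
    return(detections)
  }
  detections <- detections[order(detections$frame), , drop = FALSE]
  rownames(detections) <- NULL
  detections$trace_id <- NA_integer_
  next_id <- 1L
  prev_rows <- integer()   # rows of the previous frame, by trace
  for (f in sort(unique(detections$frame))) {
    rows <- which(detections$frame == f)
    active <- prev_rows[detections$frame[prev_rows] == f - 1L]
    taken <- rep(FALSE, length(active))
    for (r in rows) {
      if (length(active) > 0) {
        iou <- box_iou_vec(detections[r, ],
                           detections[active, , drop = FALSE])
        iou[taken] <- -1
        best <- which.max(iou)  # ties: lower index wins
        if (length(best) == 1 && iou[best] >= link_threshold) {
          detections$trace_id[r] <- detections$trace_id[active[best]]
          taken[best] <- TRUE
          next
        }
      }
      detections$trace_id[r] <- next_id
      next_id <- next_id + 1L
    }
    prev_rows <- rows
  }
  detections
}

#' Detect and link traces over a whole stream
#'
#' Convenience pipeline: [detect_blobs()] on every frame's map, then
#' [link_traces()]. Returns a trace table in the shared CSV schema (one row
#' per detection, i.e. per trace per frame).
#'
#' @param maps list of per-frame maps (binary or soft masks).
#' @param ... passed to [detect_blobs()].
#' @param link_threshold passed to [link_traces()].
#' @return data.frame `trace_id, frame, x_min, y_min, x_max, y_max` plus
#'   the detection columns.
#' @export
detect_traces <- function(maps, ..., link_threshold = 0.3) {
  per_frame <- lapply(seq_along(maps), function(t) {
    detect_blobs(maps[[t]], ..., frame = t - 1L)
  })
  det <- do.call(rbind, per_frame)
  linked <- link_traces(det, link_threshold = link_threshold)
  cols <- c("trace_id", "frame", "x_min", "y_min", "x_max", "y_max",
            "x", "y", "radius", "response")
  linked[, cols]
}
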