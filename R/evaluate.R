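#' Trace-level matching of predictions against annotations
#'
#' Both inputs are trace tables (one row per trace per frame). Each trace
#' is summarised by its aggregate bounding box (union over its per-frame
#' boxes) and its frame span. A predicted trace counts as a true positive
#' if its aggregate box overlaps an annotated trace's aggregate box with
#' IoU at least `overlap_threshold` and the two frame spans intersect;
#' otherwise it is a false positive. An annotated trace with no such
#' predicted trace is a false negative. The matching is deliberately
#' non-injective: several predictions overlapping one annotation all count
#' as true positives, so the measure reflects localisation accuracy rather
#' than count agreement.
#'
#' @param predicted,annotated trace data.frames
#'   (`trace_id, frame, x_min, y_min, x_max, y_max`).
#' @param overlap_threshold minimum IoU for a match.
#' @param frame_wise match on per-frame boxes (max IoU over shared frames)
#'   instead of aggregate boxes.
#' @return list with `tp`, `fp`, `fn` and a data.frame `pairs` of matched
#'   (predicted, annotated) trace ids.
#' @export
match_traces <- function(predicted, annotated, overlap_threshold = 0.3,
                         frame_wise = FALSE) {
  ps <- trace_summary(predicted)
  as_ <- trace_summary(annotated)
  pairs <- list()
  matched_pred <- rep(FALSE, nrow(ps))
  matched_ann <- rep(FALSE, nrow(as_))
  for (i in seq_len(nrow(ps))) {
    for (j in seq_len(nrow(as_))) {
      if (ps$frame_max[i] < as_$frame_min[j] ||
          as_$frame_max[j] < ps$frame_min[i]) next
      iou <- if (frame_wise) {
        frame_wise_iou(predicted[predicted$trace_id == ps$trace_id[i], ],
                       annotated[annotated$trace_id == as_$trace_id[j], ])
      } else {
        box_iou_vec(ps[i, ], as_[j, ])
      }
      if (iou >= overlap_threshold) {
        matched_pred[i] <- TRUE
        matched_ann[j] <- TRUE
        pairs[[length(pairs) + 1L]] <-
          data.frame(predicted = ps$trace_id[i], annotated = as_$trace_id[j])
      }
    }
  }
  list(tp = sum(matched_pred),
       fp = sum(!matched_pred),
       fn = sum(!matched_ann),
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(predicted = integer(), annotated = integer()))
}

# Aggregate per-trace summaries: union box and frame span.
trace_summary <- function(traces) {
  if (nrow(traces) == 0) {
    return(data.frame(trace_id = integer(), frame_min = integer(),
                      frame_max = integer(), x_min = integer(),
                      y_min = integer(), x_max = integer(),
                      y_max = integer()))
  }
  ids <- sort(unique(traces$trace_id))
  do.call(rbind, lapply(ids, function(id) {
    tr <- traces[traces$trace_id == id, ]
    data.frame(trace_id = id,
               frame_min = min(tr$frame), frame_max = max(tr$frame),
               x_min = min(tr$x_min), y_min = min(tr$y_min),
               x_max = max(tr$x_max), y_max = max(tr$y_max))
  }))
}

frame_wise_iou <- function(tr_a, tr_b) {
  frames <- intersect(tr_a$frame, tr_b$frame)
  if (length(frames) == 0) return(0)
  max(vapply(frames, function(f) {
    box_iou_vec(tr_a[tr_a$frame == f, ][1, ], tr_b[tr_b$frame == f, ][1, ])
  }, numeric(1)))
}

#' Object-level F1 score
#'
#' `F1 = tp / (tp + 0.5 * (fp + fn))`. The degenerate all-zero case (no
#' predictions and no annotations) is defined as 1, so particle-free
#' streams with no false detections score perfectly.
#'
#' @param tp,fp,fn non-negative counts.
#' @return score in `[0, 1]`.
#' @export
f1_score <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) return(1)
  tp / (tp + 0.5 * (fp + fn))
}

#' Count exactness
#'
#' `1 - |n_a - n_p| / max(n_a, n_p)`: how well the number of predicted
#' traces `n_p` agrees with the number of annotated traces `n_a`,
#' irrespective of where the traces are. `e(0, 0)` is defined as 1.
#'
#' @param n_a,n_p annotated and predicted trace counts.
#' @return score in `[0, 1]`.
#' @export
count_exactness <- function(n_a, n_p) {
  stopifnot(n_a >= 0, n_p >= 0)
  if (max(n_a, n_p) == 0) return(1)
  1 - abs(n_a - n_p) / max(n_a, n_p)
}

#' False-positive traces per image
#'
#' For streams annotated as particle-free: the number of predicted traces
#' (not detections) divided by the number of frames.
#'
#' @param predicted predicted trace data.frame.
#' @param n_frames number of frames in the stream.
#' @return rate `>= 0`.
#' @export
fp_per_image <- function(predicted, n_frames) {
  if (n_frames < 1) stop("n_frames must be at least 1")
  length(unique(predicted$trace_id)) / n_frames
}

#' Evaluate one stream
#'
#' Matches predicted against annotated traces and computes the trace-level
#' scores. For a particle-free stream (no annotated traces) the
#' false-positive rate per image is reported as well.
#'
#' @inheritParams match_traces
#' @param n_frames stream length in frames.
#' @return list with `tp`, `fp`, `fn`, `f1`, `count_exactness` and
#'   `fp_per_image` (`NA` unless the stream is particle-free).
#' @export
evaluate_stream <- function(predicted, annotated, n_frames,
                            overlap_threshold = 0.3, frame_wise = FALSE) {
  m <- match_traces(predicted, annotated, overlap_threshold, frame_wise)
  n_a <- length(unique(annotated$trace_id))
  n_p <- length(unique(predicted$trace_id))
  list(tp = m$tp, fp = m$fp, fn = m$fn,
       f1 = f1_score(m$tp, m$fp, m$fn),
       count_exactness = count_exactness(n_a, n_p),
       fp_per_image = if (n_a == 0) fp_per_image(predicted, n_frames)
                      else NA_real_)
}

#' Aggregate per-stream results into a grouped report
#'
#' @param results data.frame with one row per stream: columns `stream`,
#'   `group` (one of `"highly_visible"`, `"strong_noise"`, `"wave_like"`,
#'   `"particle_free"`), `f1`, `count_exactness`, `fp_per_image`.
#' @return an `eval_report`: list with `per_stream`, `per_group` (mean and
#'   minimum F1 and count exactness; mean and maximum FP/image for
#'   particle-free groups) and `overall` aggregates over particle-bearing
#'   streams.
#' @export
aggregate_report <- function(results) {
  allowed <- c("highly_visible", "strong_noise", "wave_like",
               "particle_free")
  stopifnot(nrow(results) >= 1)
  if (!all(results$group %in% allowed)) {
    stop("unknown group label(s): ",
         paste(setdiff(results$group, allowed), collapse = ", "))
  }
  per_group <- do.call(rbind, lapply(split(results, results$group),
                                     function(g) {
    data.frame(group = g$group[1], n_streams = nrow(g),
               avg_f1 = mean(g$f1), min_f1 = min(g$f1),
               avg_count_exactness = mean(g$count_exactness),
               min_count_exactness = min(g$count_exactness),
               avg_fp_per_image = mean(g$fp_per_image),
               max_fp_per_image = suppressWarnings(max(g$fp_per_image)))
  }))
  rownames(per_group) <- NULL
  particle <- results[results$group != "particle_free", , drop = FALSE]
  overall <- if (nrow(particle)) {
    data.frame(avg_f1 = mean(particle$f1), min_f1 = min(particle$f1),
               avg_count_exactness = mean(particle$count_exactness),
               min_count_exactness = min(particle$count_exactness))
  }
  structure(list(per_stream = results, per_group = per_group,
                 overall = overall),
            class = "eval_report")
}

#' Render an evaluation report as a markdown table
#'
#' One row per group: average/minimum F1 and count exactness, and for
#' particle-free groups the average/maximum false positives per image.
#'
#' @param report an `eval_report` from [aggregate_report()].
#' @return a character scalar of markdown.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  g <- report$per_group
  fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", x))
  lines <- c(
    "| Group | Avg F1 | Min F1 | Avg CE | Min CE | Avg FP/img | Max FP/img |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s | %s | %s |",
            g$group, fmt(g$avg_f1), fmt(g$min_f1),
            fmt(g$avg_count_exactness), fmt(g$min_count_exactness),
            fmt(g$avg_fp_per_image), fmt(g$max_fp_per_image)))
  paste(lines, collapse = "\n")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Trace-level evaluation\n")
  print(x$per_group, digits = 3)
  if (!is.null(x$overall)) {
    cat("Overall (particle-bearing streams):\n")
    print(x$overall, digits = 3)
  }
  invisible(x)
}
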