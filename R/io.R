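#' Read and write image streams, masks and trace tables
#'
#' Streams are stored either as one multi-page 32-bit float TIFF or as a
#' numbered 16-bit PNG sequence (`frame_0000.png`, ...). Masks are stored as
#' single-channel PNGs with values 0/255. Trace tables use one CSV schema
#' for annotations and predictions alike:
#' `trace_id,frame,x_min,y_min,x_max,y_max` with 0-based frame indices and
#' 0-based, half-open pixel boxes.
#'
#' @param frames list of `[0,1]` matrices (or a `sim_stream`).
#' @param path output file (`.tif`) or directory (PNG sequence).
#' @param format `"tiff"` or `"png"`.
#' @return `read_stream()` returns a list of matrices; writers return their
#'   path(s) invisibly.
#' @name stream_io
NULL

#' @rdname stream_io
#' @export
write_stream <- function(frames, path, format = c("tiff", "png")) {
  frames <- stream_frames(frames)
  format <- match.arg(format)
  if (format == "tiff") {
    tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
    invisible(path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(seq_along(frames), function(i) {
      p <- file.path(path, sprintf("frame_%04d.png", i - 1L))
      png::writePNG(clip01(frames[[i]]), p)
      p
    }, character(1))
    invisible(paths)
  }
}

#' @rdname stream_io
#' @export
read_stream <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0) stop("no PNG frames in ", path)
    lapply(files, read_image_gray)
  } else {
    frames <- tiff::readTIFF(path, all = TRUE)
    lapply(frames, function(f) {
      if (length(dim(f)) == 3) f[, , 1] else f
    })
  }
}

#' @rdname stream_io
#' @param masks list of binary matrices.
#' @export
write_masks <- function(masks, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(masks), function(i) {
    p <- file.path(path, sprintf("mask_%04d.png", i - 1L))
    png::writePNG((masks[[i]] > 0) * 1, p)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname stream_io
#' @export
read_masks <- function(path) {
  files <- sort(list.files(path, pattern = "^mask_.*\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no mask PNGs in ", path)
  lapply(files, function(f) (read_image_gray(f) > 0.5) * 1L)
}

#' @rdname stream_io
#' @param traces a trace data.frame (see above for the schema).
#' @export
write_traces <- function(traces, path) {
  cols <- c("trace_id", "frame", "x_min", "y_min", "x_max", "y_max")
  stopifnot(all(cols %in% names(traces)))
  write.csv(traces[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_traces <- function(path) {
  tr <- read.csv(path)
  cols <- c("trace_id", "frame", "x_min", "y_min", "x_max", "y_max")
  if (!all(cols %in% names(tr))) {
    stop("trace CSV must have columns ", paste(cols, collapse = ","))
  }
  tr[, cols]
}
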