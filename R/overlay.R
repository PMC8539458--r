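#' Extract a zero-centred artifact signal from a reference frame
#'
#' Reference frames are recorded (or simulated) without particles of
#' interest, so they contain only a constant background plus correlated and
#' uncorrelated artifacts. Assuming the artifact signals are zero-centred,
#' the background is approximated by the mean intensity of the frame and the
#' artifact signal is the frame minus that scalar mean. The result has mean
#' zero to floating-point accuracy and is idempotent under re-extraction.
#'
#' @param reference numeric matrix, a frame free of particle signal.
#' @return numeric matrix of the same shape with mean 0; values may lie
#'   outside `[0, 1]`.
#' @export
extract_artifact <- function(reference) {
  stopifnot(is.matrix(reference))
  reference - mean(reference)
}

#' Tile sources
#'
#' A tile source supplies fixed-size, zero-centred artifact patches
#' ("tiles") that [build_overlay()] mosaics into full-frame overlays. All
#' sources share one protocol: a list with elements `shape` (`c(v, w)`, the
#' tile width `v` and height `w` in pixels) and `next_tiles(count)`, which
#' returns `count` fresh tiles (matrices with `w` rows and `v` columns).
#' Tiles are drawn independently of the frames they will be applied to, and
#' the sequence of tiles is reproducible given the R random seed.
#'
#' `real_cutout_source()` draws uniformly located `v x w` cutout windows
#' from uniformly chosen frames of a reference stream and zero-centres each
#' cutout individually, mirroring the direct use of recorded artifact
#' images. `directory_tile_source()` adapts externally produced artifact
#' images (for instance the output of a generative model) stored as
#' PNG/TIFF files: each file is read, converted to a `[0, 1]` grayscale
#' matrix, cropped to its top-left `v x w` window, zero-centred, and served
#' in random order with replacement.
#'
#' @param reference_stream a list of frames (numeric matrices) or a
#'   `sim_stream` object; must contain no particle signal.
#' @param v,w tile width and height in pixels.
#' @return a `tile_source` object (see Details for the protocol).
#' @seealso [build_overlay()], [compose_tiles()]
#' @name tile_source
NULL

tile_source <- function(shape, next_tiles, kind) {
  structure(list(shape = as.integer(shape), next_tiles = next_tiles,
                 kind = kind),
            class = "tile_source")
}

#' @rdname tile_source
#' @export
real_cutout_source <- function(reference_stream, v = 128L, w = v) {
  frames <- stream_frames(reference_stream)
  stopifnot(length(frames) >= 1)
  Y <- nrow(frames[[1]]); X <- ncol(frames[[1]])
  if (v > X || w > Y) {
    stop("tile shape ", v, "x", w, " exceeds frame shape ", X, "x", Y)
  }
  tile_source(c(v, w), kind = "real", next_tiles = function(count) {
    lapply(seq_len(count), function(i) {
      f <- frames[[sample.int(length(frames), 1)]]
      x0 <- sample.int(X - v + 1L, 1)
      y0 <- sample.int(Y - w + 1L, 1)
      extract_artifact(f[y0:(y0 + w - 1L), x0:(x0 + v - 1L), drop = FALSE])
    })
  })
}

#' @rdname tile_source
#' @param path directory containing PNG or TIFF artifact images, each at
#'   least `v x w` pixels.
#' @export
directory_tile_source <- function(path, v = 128L, w = v) {
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", full.names = TRUE,
                      ignore.case = TRUE)
  tiles <- list()
  for (f in files) {
    img <- tryCatch(read_image_gray(f), error = function(e) NULL)
    if (is.null(img) || nrow(img) < w || ncol(img) < v) {
      warning("skipping unreadable or undersized tile image: ", f)
      next
    }
    tiles[[length(tiles) + 1L]] <-
      extract_artifact(img)[seq_len(w), seq_len(v), drop = FALSE]
  }
  if (length(tiles) == 0) {
    stop("no usable tile images in ", path)
  }
  tile_source(c(v, w), kind = "generated", next_tiles = function(count) {
    tiles[sample.int(length(tiles), count, replace = TRUE)]
  })
}

#' Compose tiles into a single full-frame artifact
#'
#' Tiles are butted edge to edge, row-major over the tile grid: the tile for
#' pixel `(x, y)` (0-based here, matching the composition rule) has index
#' `floor(x / v) + ceiling(X / v) * floor(y / w)`, and the pixel within the
#' tile is `(x mod v, y mod w)`. When `v` does not divide `X` (or `w`
#' divide `Y`) the rightmost (bottom) tiles are cropped. No blending is
#' applied across seams.
#'
#' @param tiles list of tile matrices (`w` rows, `v` columns), all the same
#'   shape, at least `ceiling(X/v) * ceiling(Y/w)` of them.
#' @param X,Y width and height of the composed artifact in pixels.
#' @return numeric `Y x X` matrix.
#' @export
compose_tiles <- function(tiles, X, Y) {
  stopifnot(length(tiles) >= 1, is.matrix(tiles[[1]]))
  w <- nrow(tiles[[1]]); v <- ncol(tiles[[1]])
  nx <- ceiling(X / v); ny <- ceiling(Y / w)
  if (length(tiles) < nx * ny) {
    stop("need at least ", nx * ny, " tiles, got ", length(tiles))
  }
  out <- matrix(0, Y, X)
  for (ty in seq_len(ny) - 1L) {
    for (tx in seq_len(nx) - 1L) {
      tile <- tiles[[tx + nx * ty + 1L]]
      stopifnot(nrow(tile) == w, ncol(tile) == v)
      xs <- (tx * v + 1L):min((tx + 1L) * v, X)
      ys <- (ty * w + 1L):min((ty + 1L) * w, Y)
      out[ys, xs] <- tile[seq_along(ys), seq_along(xs)]
    }
  }
  out
}

# Inverse of compose_tiles for testing/tile making: split a frame into its
# v x w blocks (row-major over the tile grid), cropping overhang blocks.
split_tiles <- function(frame, v, w) {
  Y <- nrow(frame); X <- ncol(frame)
  nx <- ceiling(X / v); ny <- ceiling(Y / w)
  tiles <- vector("list", nx * ny)
  for (ty in seq_len(ny) - 1L) {
    for (tx in seq_len(nx) - 1L) {
      xs <- (tx * v + 1L):min((tx + 1L) * v, X)
      ys <- (ty * w + 1L):min((ty + 1L) * w, Y)
      tiles[[tx + nx * ty + 1L]] <- frame[ys, xs, drop = FALSE]
    }
  }
  tiles
}

#' Build a full-frame artifact overlay
#'
#' Draws a fresh set of tiles from `correlated_source`, composes them into a
#' correlated artifact covering `X x Y`, and adds uncorrelated zero-mean
#' Gaussian pixel noise with standard deviation `uncorrelated_sigma`. A new
#' overlay is intended to be generated for every training image. When tiles
#' originate from real or generated reference imagery they already carry
#' uncorrelated noise, so `uncorrelated_sigma = 0` (the default) avoids
#' counting that noise twice.
#'
#' @param correlated_source a [tile_source] or `NULL` for no correlated
#'   component.
#' @param uncorrelated_sigma standard deviation of the added Gaussian noise.
#' @param X,Y overlay width and height in pixels.
#' @return numeric `Y x X` matrix; values may lie outside `[0, 1]`.
#' @export
build_overlay <- function(correlated_source, X, Y, uncorrelated_sigma = 0) {
  correlated <- if (is.null(correlated_source)) {
    matrix(0, Y, X)
  } else {
    v <- correlated_source$shape[1]; w <- correlated_source$shape[2]
    n <- ceiling(X / v) * ceiling(Y / w)
    compose_tiles(correlated_source$next_tiles(n), X, Y)
  }
  if (uncorrelated_sigma > 0) {
    correlated <- correlated + matrix(rnorm(X * Y, 0, uncorrelated_sigma), Y, X)
  }
  correlated
}

#' Overlay an artifact signal on a training frame
#'
#' Adds the overlay pointwise and clips the result to `[0, 1]`, the range of
#' preprocessed sensor frames, so augmented inputs live in the same domain
#' as real ones. The segmentation ground truth of the frame is untouched by
#' construction: overlays carry no particle signal.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param overlay numeric matrix of the same shape.
#' @return augmented frame, clipped to `[0, 1]`.
#' @export
apply_overlay <- function(image, overlay) {
  if (!identical(dim(image), dim(overlay))) {
    stop("image and overlay shapes differ")
  }
  clip01(image + overlay)
}

clip01 <- function(x) {
  pmin(pmax(x, 0), 1)
}

#' Cut a reference stream into tile files
#'
#' Writes `n` random cutout tiles from a reference stream to `path` as PNG
#' files (tile values are shifted by +0.5 for storage, so re-reading them
#' through [directory_tile_source()], which re-centres, recovers the tile up
#' to clipping). Mainly useful to stage tile directories for
#' [directory_tile_source()] and for visual inspection of artifact material.
#'
#' @inheritParams tile_source
#' @param path output directory, created if missing.
#' @param n number of tiles to write.
#' @return invisibly, the written file paths.
#' @export
make_tiles <- function(reference_stream, path, n, v = 128L, w = v) {
  src <- real_cutout_source(reference_stream, v, w)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tiles <- src$next_tiles(n)
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(path, sprintf("tile_%04d.png", i))
    png::writePNG(clip01(tiles[[i]] + 0.5), paths[i])
  }
  invisible(paths)
}

# Read an image file as a grayscale [0,1] matrix (mean over colour channels).
read_image_gray <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) {
    img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE],
                 c(1, 2), mean)
  }
  img
}
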