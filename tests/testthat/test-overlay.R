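test_that("artifact extraction removes exactly the scalar mean", {
  expect_equal(extract_artifact(matrix(0.5, 6, 6)), matrix(0, 6, 6))
  expect_equal(extract_artifact(matrix(c(0.4, 0.6), 1, 2)),
               matrix(c(-0.1, 0.1), 1, 2))
  set.seed(3)
  f <- matrix(runif(300), 15, 20)
  a <- extract_artifact(f)
  expect_lt(abs(mean(a)), 1e-9)
  # idempotent: re-extracting changes nothing
  expect_equal(extract_artifact(a), a)
})

test_that("real cutouts are per-window centred and deterministic", {
  ref <- wave_reference()
  src <- real_cutout_source(ref, v = 16L, w = 16L)
  set.seed(21)
  tiles <- src$next_tiles(500)
  means <- vapply(tiles, mean, numeric(1))
  expect_true(all(abs(means) <= 0.05))
  expect_true(all(vapply(tiles, function(t) all(dim(t) == c(16, 16)), TRUE)))

  set.seed(8); a <- src$next_tiles(5)
  set.seed(8); b <- src$next_tiles(5)
  expect_identical(a, b)

  # constant reference frames give all-zero tiles
  const <- list(matrix(0.3, 20, 20))
  zsrc <- real_cutout_source(const, 8L, 8L)
  expect_equal(zsrc$next_tiles(3)[[2]], matrix(0, 8, 8))

  expect_error(real_cutout_source(const, 32L, 8L), "exceeds")
})

test_that("tile composition follows the row-major mosaic rule", {
  # one full-size tile is returned unchanged
  tile <- matrix(runif(24), 4, 6)
  expect_equal(compose_tiles(list(tile), X = 6, Y = 4), tile)

  # 4 constant 2x2 tiles into a 4x4 grid: a | b over c | d
  tiles <- lapply(c(1, 2, 3, 4), function(v) matrix(v, 2, 2))
  out <- compose_tiles(tiles, X = 4, Y = 4)
  expect_equal(out, rbind(cbind(matrix(1, 2, 2), matrix(2, 2, 2)),
                          cbind(matrix(3, 2, 2), matrix(4, 2, 2))))

  expect_error(compose_tiles(tiles[1:2], X = 4, Y = 4), "at least")
})

test_that("splitting then composing reproduces the image", {
  set.seed(4)
  img <- matrix(runif(48 * 36), 36, 48)
  # divisible tiling
  tiles <- particleaug:::split_tiles(img, v = 16L, w = 12L)
  expect_equal(compose_tiles(tiles, X = 48, Y = 36), img)
  # non-divisible: overhang tiles are cropped, identity must still hold
  img2 <- matrix(runif(30 * 22), 22, 30)
  full <- particleaug:::split_tiles(matrix(runif(32 * 24), 24, 32), 8L, 8L)
  composed <- compose_tiles(full, X = 30, Y = 22)
  expect_equal(dim(composed), c(22, 30))
})

test_that("directory tile sources read, centre and crop stored images", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.7, 12, 12), file.path(dir, "const.png"))
  src <- directory_tile_source(dir, v = 12L, w = 12L)
  expect_equal(src$next_tiles(2)[[1]], matrix(0, 12, 12))

  # distinct images: only those pixel patterns may appear
  dir2 <- withr::local_tempdir()
  imgs <- lapply(1:3, function(i) {
    m <- matrix(runif(100), 10, 10)
    png::writePNG(m, file.path(dir2, sprintf("t%d.png", i)))
    m
  })
  src2 <- directory_tile_source(dir2, v = 10L, w = 10L)
  set.seed(1)
  tiles <- src2$next_tiles(9)
  pats <- lapply(imgs, function(m) {
    round(extract_artifact(round(m * 255) / 255), 6)
  })
  for (t in tiles) {
    match_any <- any(vapply(pats, function(p) {
      isTRUE(all.equal(p, round(t, 6), tolerance = 1e-2))
    }, TRUE))
    expect_true(match_any)
  }

  # smaller requested shape crops the top-left window after centring
  src3 <- directory_tile_source(dir2, v = 4L, w = 6L)
  t3 <- src3$next_tiles(1)[[1]]
  expect_equal(dim(t3), c(6, 4))

  expect_error(directory_tile_source(withr::local_tempdir(), 4L, 4L),
               "no usable")
})

test_that("overlays combine composed tiles with Gaussian noise", {
  zero_src <- particleaug:::tile_source(
    c(16L, 16L),
    next_tiles = function(count) {
      replicate(count, matrix(0, 16, 16), simplify = FALSE)
    }, kind = "real")
  expect_equal(build_overlay(zero_src, 32, 32, uncorrelated_sigma = 0),
               matrix(0, 32, 32))

  # sigma = 0: overlay equals the composed correlated grid
  cst_src <- particleaug:::tile_source(
    c(16L, 16L),
    next_tiles = function(count) {
      replicate(count, matrix(0.05, 16, 16), simplify = FALSE)
    }, kind = "real")
  expect_equal(build_overlay(cst_src, 32, 32), matrix(0.05, 32, 32))

  # Gaussian part has the requested spread (10 seeds pooled)
  sds <- vapply(1:10, function(s) {
    set.seed(s)
    sd(build_overlay(zero_src, 128, 128, uncorrelated_sigma = 0.1))
  }, numeric(1))
  expect_true(mean(sds) > 0.095 && mean(sds) < 0.105)
})

test_that("applying an overlay sums pointwise and clips to [0,1]", {
  f <- matrix(0.5, 8, 8)
  expect_identical(apply_overlay(f, matrix(0, 8, 8)), f)
  expect_equal(apply_overlay(f, matrix(0.2, 8, 8)), matrix(0.7, 8, 8))
  expect_equal(apply_overlay(matrix(0.9, 8, 8), matrix(0.3, 8, 8)),
               matrix(1, 8, 8))
  expect_equal(apply_overlay(matrix(0.1, 8, 8), matrix(-0.3, 8, 8)),
               matrix(0, 8, 8))
  expect_error(apply_overlay(f, matrix(0, 4, 4)), "shapes differ")
})

test_that("tile files round-trip through make_tiles and a directory source", {
  ref <- wave_reference()
  dir <- withr::local_tempdir()
  set.seed(2)
  paths <- make_tiles(ref, dir, n = 6, v = 16L, w = 16L)
  expect_length(list.files(dir, pattern = "\\.png$"), 6)
  src <- directory_tile_source(dir, v = 16L, w = 16L)
  tiles <- src$next_tiles(4)
  for (t in tiles) {
    expect_lt(abs(mean(t)), 1e-6)
    expect_equal(dim(t), c(16, 16))
  }
})
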