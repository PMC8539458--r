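# Independent brute-force oracles, written from the definitions via
# precision and recall rather than the packaged closed forms.
oracle_f1 <- function(tp, fp, fn) {
  if (tp + fp + fn == 0) return(1)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}
oracle_ce <- function(n_a, n_p) {
  if (n_a == 0 && n_p == 0) return(1)
  1 - abs(n_a - n_p) / max(n_a, n_p)
}

test_that("F1 and count exactness match brute force on all inputs <= 20", {
  for (tp in 0:20) for (fp in 0:20) for (fn in 0:20) {
    expect_equal(f1_score(tp, fp, fn), oracle_f1(tp, fp, fn))
  }
  for (n_a in 0:20) for (n_p in 0:20) {
    expect_equal(count_exactness(n_a, n_p), oracle_ce(n_a, n_p))
  }
})

test_that("F1 is monotone in its arguments", {
  grid <- expand.grid(tp = 0:12, fp = 0:12, fn = 0:12)
  f <- mapply(f1_score, grid$tp, grid$fp, grid$fn)
  for (i in sample(nrow(grid), 300)) {
    g <- grid[i, ]
    if (g$tp + g$fp + g$fn == 0) next
    expect_lte(f1_score(g$tp, g$fp + 1, g$fn), f[i])
    expect_lte(f1_score(g$tp, g$fp, g$fn + 1), f[i])
    expect_gte(f1_score(g$tp + 1, g$fp, g$fn), f[i])
  }
})

test_that("count exactness is symmetric and bounded", {
  for (i in 1:100) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    e <- count_exactness(a, b)
    expect_equal(e, count_exactness(b, a))
    expect_gte(e, 0); expect_lte(e, 1)
  }
  expect_equal(count_exactness(5, 5), 1)
  expect_equal(count_exactness(0, 7), 0)
  expect_equal(count_exactness(4, 5), 0.8)
})

make_trace <- function(id, frames, box) {
  data.frame(trace_id = id, frame = frames,
             x_min = box[1], y_min = box[2], x_max = box[3], y_max = box[4])
}

test_that("trace matching applies the non-injective true-positive rule", {
  ann <- rbind(make_trace(1, 0:2, c(10, 10, 20, 20)),
               make_trace(2, 1:3, c(40, 40, 50, 50)))
  # identical sets
  m <- match_traces(ann, ann)
  expect_equal(m[c("tp", "fp", "fn")], list(tp = 2L, fp = 0L, fn = 0L))

  # two predictions over one annotation: both are true positives
  pred <- rbind(make_trace(1, 0:1, c(10, 10, 19, 20)),
                make_trace(2, 1:2, c(11, 10, 20, 20)))
  ann1 <- make_trace(7, 0:2, c(10, 10, 20, 20))
  m2 <- match_traces(pred, ann1)
  expect_equal(m2$tp, 2)
  expect_equal(m2$fp, 0)
  expect_equal(m2$fn, 0)

  # disjoint sets: everything is fp / fn
  pred3 <- rbind(make_trace(1, 0, c(0, 0, 5, 5)),
                 make_trace(2, 1, c(0, 30, 5, 35)))
  ann3 <- rbind(make_trace(1, 0, c(50, 50, 60, 60)),
                make_trace(2, 1, c(20, 0, 28, 8)),
                make_trace(3, 2, c(40, 20, 48, 28)))
  m3 <- match_traces(pred3, ann3)
  expect_equal(m3[c("tp", "fp", "fn")], list(tp = 0L, fp = 2L, fn = 3L))
})

test_that("matching requires temporal overlap, not only box overlap", {
  ann <- make_trace(1, 0:2, c(10, 10, 20, 20))
  pred <- make_trace(1, 5:6, c(10, 10, 20, 20))  # same box, later frames
  m <- match_traces(pred, ann)
  expect_equal(m$tp, 0)
  expect_equal(m$fp, 1)
  expect_equal(m$fn, 1)
})

test_that("false-positive rate counts traces, not detections", {
  pred <- rbind(make_trace(1, 0:9, c(1, 1, 4, 4)),    # long trace
                make_trace(2, 3, c(10, 10, 14, 14)),
                make_trace(3, 7, c(20, 20, 24, 24)))
  expect_equal(fp_per_image(pred, 100), 0.03)
  expect_equal(fp_per_image(empty <- pred[0, ], 50), 0)
  expect_error(fp_per_image(pred, 0), "at least 1")
})

test_that("stream evaluation assembles the scores coherently", {
  ann <- rbind(make_trace(1, 0:2, c(10, 10, 20, 20)),
               make_trace(2, 1:3, c(40, 40, 50, 50)))
  ev <- evaluate_stream(ann, ann, n_frames = 4)
  expect_equal(ev$f1, 1)
  expect_equal(ev$count_exactness, 1)
  expect_true(is.na(ev$fp_per_image))

  # particle-free stream: no annotations, two spurious predictions
  free <- evaluate_stream(rbind(make_trace(1, 0, c(0, 0, 4, 4)),
                                make_trace(2, 2, c(8, 8, 12, 12))),
                          ann[0, ], n_frames = 10)
  expect_equal(free$f1, 0)
  expect_equal(free$fp_per_image, 0.2)

  # perfect emptiness scores perfectly
  silent <- evaluate_stream(ann[0, ], ann[0, ], n_frames = 5)
  expect_equal(silent$f1, 1)
  expect_equal(silent$count_exactness, 1)
  expect_equal(silent$fp_per_image, 0)
})

test_that("grouped aggregation reports means, minima and fp maxima", {
  res <- data.frame(
    stream = c("a", "b", "c"),
    group = c("wave_like", "wave_like", "particle_free"),
    f1 = c(0.2, 0.8, 1),
    count_exactness = c(0.1, 0.9, 1),
    fp_per_image = c(NA, NA, 0.25))
  rep <- aggregate_report(res)
  wave <- rep$per_group[rep$per_group$group == "wave_like", ]
  expect_equal(wave$avg_f1, 0.5)
  expect_equal(wave$min_f1, 0.2)
  free <- rep$per_group[rep$per_group$group == "particle_free", ]
  expect_equal(free$max_fp_per_image, 0.25)
  # overall aggregates exclude the particle-free stream
  expect_equal(rep$overall$avg_f1, 0.5)

  # single stream: aggregates equal that stream's scores
  one <- aggregate_report(res[1, ])
  expect_equal(one$per_group$avg_f1, 0.2)
  expect_equal(one$per_group$min_f1, 0.2)

  # adding a stream cannot raise the minimum
  more <- rbind(res, data.frame(stream = "d", group = "wave_like",
                                f1 = 0.05, count_exactness = 0.1,
                                fp_per_image = NA))
  rep2 <- aggregate_report(more)
  expect_lte(rep2$per_group$min_f1[rep2$per_group$group == "wave_like"],
             wave$min_f1)

  expect_error(aggregate_report(transform(res, group = "mystery")),
               "unknown group")
})

test_that("reports render to a markdown table", {
  res <- data.frame(stream = c("a", "b"),
                    group = c("wave_like", "particle_free"),
                    f1 = c(0.5, 1), count_exactness = c(0.4, 1),
                    fp_per_image = c(NA, 0.1))
  md <- report_markdown(aggregate_report(res))
  expect_match(md, "\\| wave_like \\| 0.50 \\|")
  expect_match(md, "particle_free")
  expect_equal(length(strsplit(md, "\n")[[1]]), 4)
})
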