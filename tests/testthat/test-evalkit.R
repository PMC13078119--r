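# Evaluation kit: matching, precision/recall arithmetic, interpolated AP
# against curve enumeration, mAP averaging and run statistics.

mkbox <- function(x1, y1, x2, y2, score = NA, class_id = 0L) {
  if (is.na(score)) data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                               class_id = class_id)
  else data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2, score = score,
                  class_id = class_id)
}

test_that("perfect predictions match all truths; sub-threshold IoU is FP + FN", {
  truths <- rbind(mkbox(0, 0, 10, 10), mkbox(20, 20, 40, 40, class_id = 1L))
  dets <- cbind(truths[, 1:4], score = c(0.9, 0.8), class_id = truths$class_id)
  m <- match_detections(dets, truths, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))
  # IoU 0.4 < 0.5 threshold
  d2 <- mkbox(0, 0, 10, 4, score = 0.9)   # IoU with (0,0,10,10) = 0.4
  m2 <- match_detections(d2, mkbox(0, 0, 10, 10), 0.5)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0L, 1L, 1L))
  # cross-class matches are never allowed
  d3 <- cbind(truths[1, 1:4], score = 0.9, class_id = 3L)
  m3 <- match_detections(d3, truths[1, ], 0.5)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0L, 1L, 1L))
})

test_that("greedy matching equals exhaustive greedy-order assignment", {
  set.seed(81)
  for (rep in 1:5) {
    x1 <- runif(4, 0, 30); y1 <- runif(4, 0, 30)
    dets <- data.frame(x1 = x1, y1 = y1, x2 = x1 + runif(4, 10, 30),
                       y2 = y1 + runif(4, 10, 30), score = runif(4),
                       class_id = 0L)
    t1 <- runif(3, 0, 30); t2 <- runif(3, 0, 30)
    truths <- data.frame(x1 = t1, y1 = t2, x2 = t1 + runif(3, 10, 30),
                         y2 = t2 + runif(3, 10, 30), class_id = 0L)
    m <- match_detections(dets, truths, 0.3)
    # oracle: walk detections by descending score, best unmatched IoU >= thr
    ord <- order(-dets$score)
    used <- logical(3); tp <- 0
    for (i in ord) {
      ious <- sapply(seq_len(3), function(j)
        oracle_iou(as.numeric(dets[i, 1:4]), as.numeric(truths[j, 1:4])))
      ious[used] <- -1
      j <- which.max(ious)
      if (ious[j] >= 0.3) { used[j] <- TRUE; tp <- tp + 1 }
    }
    expect_equal(m$tp, tp)
    expect_equal(m$tp + m$fn, nrow(truths))   # count conservation
    expect_equal(m$tp + m$fp, nrow(dets))
  }
})

test_that("precision and recall follow the count formulas with 0/0 -> 0", {
  expect_equal(unname(precision_recall(list(tp = 9, fp = 1, fn = 5))[1]), 0.9)
  expect_equal(unname(precision_recall(list(tp = 8, fp = 9, fn = 2))[2]), 0.8)
  expect_equal(unname(precision_recall(list(tp = 0, fp = 0, fn = 0))), c(0, 0))
  expect_error(precision_recall(list(tp = -1, fp = 0, fn = 0)), "negative")
})

test_that("average precision: perfect and empty detectors, enumerated example", {
  expect_equal(average_precision(c(TRUE, TRUE, TRUE), 3), 1)
  expect_equal(average_precision(logical(0), 4), 0)
  expect_equal(average_precision(c(TRUE, FALSE), 0), 0)
  # flags (tp, fp, tp) with 2 truths: P steps 1, 1/2, 2/3; R steps .5, .5, 1
  flags <- c(TRUE, FALSE, TRUE)
  expect_equal(average_precision(flags, 2), (51 + 50 * 2 / 3) / 101,
               tolerance = 1e-12)
  expect_equal(average_precision(flags, 2), oracle_ap101(flags, 2),
               tolerance = 1e-12)
  # continuous mode integrates the exact envelope
  expect_equal(average_precision(flags, 2, mode = "continuous"),
               0.5 * 1 + 0.5 * 2 / 3, tolerance = 1e-12)
})

test_that("AP is monotone in added top-ranked hits and in IoU threshold", {
  set.seed(82)
  flags <- runif(10) > 0.5
  base_ap <- average_precision(flags, 6)
  expect_gte(average_precision(c(TRUE, flags), 6), base_ap)
  # threshold monotonicity via a matched pair of stricter flag sequences
  loose <- c(TRUE, TRUE, FALSE, TRUE)
  strict <- c(TRUE, FALSE, FALSE, FALSE)    # same dets, fewer pass at IoU .95
  expect_gte(average_precision(loose, 3), average_precision(strict, 3))
})

test_that("mAP averages the class-by-threshold grid", {
  expect_equal(map_50_95(matrix(1, 6, 10)), 1)
  expect_equal(map_50_95(c(0.5, 1.0)), 0.75)
  set.seed(83)
  grid <- matrix(runif(60), 6, 10)
  expect_equal(map_50_95(grid), mean(grid), tolerance = 1e-12)
  expect_warning(map_50_95(c(0.4, NA)), "treated as 0")
})

test_that("run statistics reproduce closed forms and the printed style", {
  rs <- run_statistics(c(1, 2, 3))
  expect_equal(rs$mean, 2)
  expect_equal(rs$sd, 1)
  expect_equal(run_statistics(rep(5, 5))$sd, 0)
  set.seed(84)
  v <- runif(5)
  rs2 <- run_statistics(v)
  expect_equal(rs2$sd, sqrt(sum((v - mean(v))^2) / 4), tolerance = 1e-12)
  expect_warning(run_statistics(0.5), "single run")
  expect_error(run_statistics(numeric(0)), "no values")
  expect_equal(format_mean_sd(run_statistics(c(0.992, 0.994))),
               "99.3 ± 0.1")
})

test_that("end-to-end scoring: ground truth fed back as detections is perfect", {
  set.seed(85)
  truths <- lapply(1:3, function(i) {
    n <- sample(1:3, 1)
    x1 <- runif(n, 0, 400); y1 <- runif(n, 0, 400)
    data.frame(class_id = sample(0:5, n, TRUE), x1 = x1, y1 = y1,
               x2 = x1 + runif(n, 30, 100), y2 = y1 + runif(n, 30, 100))
  })
  dets <- lapply(truths, function(t) cbind(t[, c("x1", "y1", "x2", "y2")],
                                           score = 0.99, class_id = t$class_id))
  rep_ <- evaluate_detections(dets, truths, n_classes = 6L)
  expect_equal(rep_$map_50_95, 1)
  expect_equal(rep_$precision, 1)
  expect_equal(rep_$recall, 1)
})
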