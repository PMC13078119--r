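# Network assembly, determinism, decoding/NMS, complexity accounting and
# checkpoint round trips. Assembly tests use a reduced input size; the
# complexity contracts are closed-form and size-independent.

tiny_arch <- function() {
  a <- sda_arch()
  a$conv_widths <- c(8L, 8L, 16L, 16L, 32L)
  a$conv_depths <- c(1L, 1L)
  a$star <- list(stem = 8L, widths = c(8L, 8L, 16L, 32L), depths = c(1L, 1L, 1L, 1L))
  a$neck <- c(n3 = 16L, n4 = 16L, n5 = 32L)
  a$head_width <- 8L
  a
}

test_that("all builds emit three pyramid-level head outputs with 6-class logits", {
  for (bb in c("starnet", "baseline_conv")) {
    spec <- model_spec(bb, "dysample", "a2c2f_scsa", input_size = 96L,
                       arch = tiny_arch())
    model <- assemble(spec, seed = 1)
    raw <- forward_detect(model, rmap(96, 96, 3))
    expect_named(raw, c("p8", "p16", "p32"))
    expect_equal(dim(vv(raw$p8$cls))[1:3], c(12L, 12L, 6L))
    expect_equal(dim(vv(raw$p16$box))[1:3], c(6L, 6L, 4L))
    expect_equal(dim(vv(raw$p32$cls))[1:3], c(3L, 3L, 6L))
  }
  expect_error(forward_detect(model, rmap(50, 50, 3)), "divisible by 32")
})

test_that("eval-mode forward is deterministic and batch-independent", {
  spec <- model_spec("starnet", "nearest", "a2c2f", input_size = 64L,
                     arch = tiny_arch())
  model <- assemble(spec, seed = 2)
  x <- rmap(64, 64, 3, 2, seed = 9)
  r1 <- forward_detect(model, x)
  r2 <- forward_detect(model, x)
  expect_identical(vv(r1$p8$cls), vv(r2$p8$cls))
  expect_identical(vv(r1$p32$box), vv(r2$p32$box))
  # batch of 2 equals stacked singleton calls
  s1 <- forward_detect(model, x[, , , 1, drop = FALSE])
  s2 <- forward_detect(model, x[, , , 2, drop = FALSE])
  expect_equal(vv(r1$p8$cls)[, , , 1], vv(s1$p8$cls)[, , , 1], tolerance = 1e-6)
  expect_equal(vv(r1$p8$cls)[, , , 2], vv(s2$p8$cls)[, , , 1], tolerance = 1e-6)
})

test_that("decode_and_nms removes duplicates and respects thresholds", {
  # two identical boxes with scores 0.9 / 0.8 -> one survivor at 0.9
  raw <- list(p8 = list(
    box = array(0, dim = c(2, 2, 4, 1)),
    cls = array(-20, dim = c(2, 2, 6, 1))))
  # cell (1,1): strong class 1; cell (1,2) identical box via offsets
  raw$p8$box[1, 1, , 1] <- c(2, 2, 2, 2)
  raw$p8$box[1, 2, , 1] <- c(3.05, 2, 0.62, 2)   # shifted cell, same decoded box
  raw$p8$cls[1, 1, 1, 1] <- log(0.9 / 0.1)
  raw$p8$cls[1, 2, 1, 1] <- log(0.8 / 0.2)
  dets <- decode_and_nms(raw, conf_threshold = 0.25, iou_threshold = 0.5)
  # the two decoded boxes overlap heavily; the 0.9 one must survive
  expect_equal(max(dets$score), 0.9, tolerance = 1e-6)
  top <- dets[which.max(dets$score), ]
  others <- dets[dets$class_id == top$class_id & dets$score < max(dets$score), ]
  if (nrow(others)) {
    expect_true(all(box_iou(as.matrix(top[, 1:4]),
                            as.matrix(others[, 1:4])) <= 0.5))
  }
  expect_equal(nrow(decode_and_nms(raw, conf_threshold = 1)), 0L)
})

test_that("NMS agrees with the O(n^2) greedy oracle on random boxes", {
  set.seed(55)
  for (rep in 1:5) {
    n <- 5
    x1 <- runif(n, 0, 50); y1 <- runif(n, 0, 50)
    df <- data.frame(x1 = x1, y1 = y1, x2 = x1 + runif(n, 5, 40),
                     y2 = y1 + runif(n, 5, 40),
                     score = runif(n), class_id = sample(0:1, n, TRUE))
    got <- stardetect:::.nms_frame(df, 0.4)
    ref <- oracle_nms(df, 0.4)
    expect_equal(got$score, ref$score)
    expect_equal(got$x1, ref$x1)
  }
})

test_that("complexity matches closed-form accounting for a single convolution", {
  m <- mod_conv(3L, 16L, 3L, bn = FALSE, bias = TRUE)
  expect_identical(module_n_params(m), 3 * 3 * 3 * 16 + 16)
  expect_equal(sd_flops(m, 640, 640), 2 * (3 * 3 * 3) * 16 * 640 * 640)
})

test_that("complexity report fields are consistent", {
  spec <- model_spec("starnet", "nearest", "a2c2f", input_size = 64L,
                     arch = tiny_arch())
  cr <- complexity(spec)
  model <- assemble(spec, seed = 0)
  expect_identical(cr$parameters, module_n_params(model))
  expect_equal(cr$serialized_bytes, 2 * cr$parameters + 1024)
  expect_equal(cr$params_m, round(cr$parameters / 1e6, 1))
})

test_that("module swaps move complexity in the documented directions", {
  base <- complexity(baseline_spec())
  star <- complexity(model_spec("starnet", "nearest", "a2c2f"))
  scsa <- complexity(model_spec("baseline_conv", "nearest", "a2c2f_scsa"))
  dys <- complexity(model_spec("baseline_conv", "dysample", "a2c2f"))
  sda <- complexity(yolo_sda_spec())
  # backbone swap strictly decreases parameters
  expect_lt(star$parameters, base$parameters)
  # the SCSA fusion block does not increase FLOPs at equal widths
  expect_lte(scsa$flops, base$flops)
  # the dynamic upsampler adds (a little) to both
  expect_gt(dys$parameters, base$parameters)
  expect_gt(dys$flops, base$flops)
  # full build is the lightest
  expect_lt(sda$parameters, star$parameters + 1e5)
  expect_lt(sda$flops, base$flops)
})

test_that("checkpoint round trip reproduces eval-mode outputs bitwise", {
  spec <- model_spec("starnet", "dysample", "a2c2f_scsa", input_size = 64L,
                     arch = tiny_arch())
  model <- assemble(spec, seed = 3)
  x <- rmap(64, 64, 3, 1, seed = 10)
  before <- vv(forward_detect(model, x)$p8$cls)
  path <- file.path(tempdir(), "ck.rds")
  save_checkpoint(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  restored <- load_checkpoint(path)
  after <- vv(forward_detect(restored, x)$p8$cls)
  expect_identical(before, after)
})
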