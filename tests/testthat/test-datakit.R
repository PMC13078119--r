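# Dataset kit: label IO, the five augmentation operators, expansion
# accounting, stratified splitting and the synthetic scene generator.

test_that("labels round-trip and pixel conversion matches hand arithmetic", {
  tmp <- tempfile(fileext = ".txt")
  lab <- data.frame(class_id = c(0L, 3L, 5L),
                    cx = c(0.5, 0.25, 0.8), cy = c(0.5, 0.75, 0.1),
                    w = c(0.2, 0.1, 0.05), h = c(0.3, 0.2, 0.05))
  write_labels(lab, tmp)
  expect_equal(read_labels(tmp), lab, tolerance = 1e-7)
  # pixel box (100,150)-(300,350) on 640x640
  row <- pixel_to_yolo(2L, 100, 150, 300, 350, 640, 640)
  expect_equal(row$cx, 0.3125)
  expect_equal(row$cy, 0.390625)
  expect_equal(row$w, 0.3125)
  expect_equal(row$h, 0.3125)
})

test_that("label validation reports offending rows", {
  tmp <- tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.1 0.1", "7 0.5 0.5 0.1 0.1"), tmp)
  expect_error(read_labels(tmp, n_classes = 6L), "class id out of range.*line\\(s\\) 2")
  writeLines("0 1.5 0.5 0.1 0.1", tmp)
  expect_error(read_labels(tmp), "outside \\[0,1\\]")
  writeLines("0 0.5 0.5", tmp)
  expect_error(read_labels(tmp), "malformed row")
  expect_equal(nrow(read_labels(tempfile())), 0L)   # absent file = no boxes
})

test_that("photometric operators leave labels unchanged; identity settings are exact", {
  set.seed(61)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  lab <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  sp <- augment(img, lab, augment_op("salt_pepper", density = 0))
  expect_identical(sp$image, img)
  expect_identical(sp$labels, lab)
  for (kind in c("gaussian_noise", "brightness", "exposure")) {
    out <- augment(img, lab, augment_op(kind, seed = 2))
    expect_identical(out$labels, lab)
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
})

test_that("full-turn rotation is the identity on labels", {
  lab <- data.frame(class_id = 1L, cx = 0.3, cy = 0.6, w = 0.1, h = 0.2)
  img <- array(0.5, dim = c(16, 16, 3))
  out <- augment(img, lab, augment_op("rotation", angle = 360))
  expect_equal(out$labels$cx, lab$cx, tolerance = 1e-9)
  expect_equal(out$labels$w, lab$w, tolerance = 1e-9)
})

test_that("90-degree rotation maps boxes by the corner-rotation oracle", {
  lab <- data.frame(class_id = 0L, cx = 0.25, cy = 0.25, w = 0.1, h = 0.2)
  img <- array(0.5, dim = c(16, 16, 3))
  out <- augment(img, lab, augment_op("rotation", angle = 90))
  # rotate the 4 corners explicitly: centre (0.25,0.25) -> (0.75, 0.25), w/h swap
  expect_equal(out$labels$cx, 0.75, tolerance = 1e-9)
  expect_equal(out$labels$cy, 0.25, tolerance = 1e-9)
  expect_equal(out$labels$w, 0.2, tolerance = 1e-9)
  expect_equal(out$labels$h, 0.1, tolerance = 1e-9)
})

test_that("rotated image content lands inside the rotated label box", {
  # a bright square patch; after rotation its pixel mass must sit in the new box
  img <- array(0, dim = c(64, 64, 3))
  img[13:20, 25:36, ] <- 1    # rows 13-20 (y), cols 25-36 (x)
  lab <- pixel_to_yolo(0L, 24, 12, 36, 20, 64, 64)
  out <- augment(img, lab, augment_op("rotation", angle = 90))
  w <- which(out$image[, , 1] > 0.5, arr.ind = TRUE)
  bx <- out$labels
  x1 <- (bx$cx - bx$w / 2) * 64; x2 <- (bx$cx + bx$w / 2) * 64
  y1 <- (bx$cy - bx$h / 2) * 64; y2 <- (bx$cy + bx$h / 2) * 64
  expect_gte(min(w[, 2]), x1 - 1.5)
  expect_lte(max(w[, 2]), x2 + 1.5)
  expect_gte(min(w[, 1]), y1 - 1.5)
  expect_lte(max(w[, 1]), y2 + 1.5)
})

test_that("expansion multiplies per-class counts exactly by the factor", {
  counts <- c(healthy = 16, early_leaf_spot = 9, late_rust = 7)
  items <- rep(names(counts), times = counts)
  man <- dataset_manifest(sprintf("img_%03d.png", seq_along(items)),
                          sprintf("img_%03d.txt", seq_along(items)), items)
  ex <- expand_dataset(man, factor = 5L, seed = 3)
  expect_equal(nrow(ex), 5 * length(items))
  expect_equal(unname(table(ex$class_name)[names(counts)]),
               unname(5 * counts), ignore_attr = TRUE)
  # originals retained, four augmented copies each, ops without replacement
  expect_equal(sum(ex$provenance == "original"), length(items))
  one <- ex[ex$image == ex$image[1] | grepl("img_001_aug", ex$image), ]
  ops <- sub("augmented\\((.*)\\)", "\\1", one$provenance[-1])
  expect_equal(length(unique(ops)), 4L)
  expect_identical(expand_dataset(man, factor = 1L), man)
})

test_that("splitting respects ratios, stratification, determinism, disjointness", {
  man <- dataset_manifest(sprintf("i%03d", 1:10), sprintf("l%03d", 1:10),
                          rep("a", 10))
  sp <- split_dataset(man, c(7, 2, 1), seed = 5)
  expect_equal(unname(table(factor(sp$split, c("train", "val", "test")))),
               c(7L, 2L, 1L), ignore_attr = TRUE)
  # determinism and partition property
  sp2 <- split_dataset(man, c(7, 2, 1), seed = 5)
  expect_identical(sp$split, sp2$split)
  expect_false(any(is.na(sp$split)))
  # stratified two-class case: each class near-proportional in each split
  man2 <- dataset_manifest(sprintf("i%03d", 1:100), sprintf("l%03d", 1:100),
                           rep(c("a", "b"), each = 50))
  sp3 <- split_dataset(man2, c(7, 2, 1), seed = 1)
  tab <- table(sp3$class_name, sp3$split)
  expect_true(all(abs(tab[, "train"] - 35) <= 1))
  expect_true(all(abs(tab[, "test"] - 5) <= 1))
})

test_that("largest-remainder totals for the x5-expanded class table", {
  # per-class originals scaled by 5 and split 7:2:1 give global 5152/1472/736
  counts <- c(1280, 1245, 1215, 1195, 1180, 1245)
  items <- rep(letters[1:6], times = counts)
  man <- dataset_manifest(paste0("i", seq_along(items)),
                          paste0("l", seq_along(items)), items)
  sp <- split_dataset(man, c(7, 2, 1), seed = 2)
  tot <- table(factor(sp$split, c("train", "val", "test")))
  expect_equal(unname(tot), c(5152L, 1472L, 736L), ignore_attr = TRUE)
})

test_that("scene generator honours its contract", {
  z <- generate_scene(seed = 7, n_objects = 0, size = 64)
  expect_equal(nrow(z$labels), 0L)
  s1 <- generate_scene(seed = 8, n_objects = 5, size = 96)
  expect_equal(nrow(s1$labels), 5L)
  expect_true(all(s1$labels$cx - s1$labels$w / 2 >= 0))
  expect_true(all(s1$labels$cx + s1$labels$w / 2 <= 1))
  expect_true(all(s1$labels$cy + s1$labels$h / 2 <= 1))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  # pixel-identical reproducibility
  s2 <- generate_scene(seed = 8, n_objects = 5, size = 96)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$labels, s2$labels)
  # class-conditional appearance: healthy vs late rust differ in lesion pixels
  h <- generate_scene(seed = 9, n_objects = 1, class_mix = c(1, 0, 0, 0, 0, 0),
                      size = 64)
  r <- generate_scene(seed = 9, n_objects = 1, class_mix = c(0, 0, 0, 0, 1, 0),
                      size = 64)
  expect_equal(h$labels$class_id, 0L)
  expect_equal(r$labels$class_id, 4L)
})

test_that("image filtering drops small and duplicate images", {
  d <- tempfile(); dir.create(d)
  set.seed(71)
  big <- array(runif(220 * 220 * 3), dim = c(220, 220, 3))
  small <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  p1 <- file.path(d, "a.png"); p2 <- file.path(d, "b.png")
  p3 <- file.path(d, "dup.png"); p4 <- file.path(d, "small.png")
  write_image(big, p1)
  write_image(array(runif(220 * 220 * 3), dim = c(220, 220, 3)), p2)
  write_image(big, p3)                      # exact duplicate of a.png
  write_image(small, p4)
  res <- filter_images(c(p1, p2, p3, p4), min_size = 200)
  expect_true(res$keep[1]); expect_true(res$keep[2])
  expect_false(res$keep[3]); expect_equal(res$reason[3], "duplicate")
  expect_false(res$keep[4]); expect_equal(res$reason[4], "too small")
})
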