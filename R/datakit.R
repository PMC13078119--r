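# Dataset tooling: YOLO-format TXT labels, the five-operator augmentation
# protocol with x5 expansion, stratified ratio splitting, image filtering,
# and a synthetic leaf-scene generator that stands in for field imagery.
# Images are (H, W, 3) arrays with values in [0, 1].

#' The six disease classes
#' @export
sda_class_names <- function() {
  c("healthy", "early_leaf_spot", "late_leaf_spot",
    "early_rust", "late_rust", "nutrient_deficiency")
}

#' Read YOLO-format labels ("class cx cy w h", normalized)
#'
#' @param path label file; an absent or empty file yields zero boxes
#' @param n_classes class-id upper bound (ids are 0-based)
#' @return data frame with columns class_id, cx, cy, w, h
#' @export
read_labels <- function(path, n_classes = 6L) {
  empty <- data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric())
  if (!file.exists(path) || file.size(path) == 0) return(empty)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) != 5 || anyNA(f)) {
      stop(sprintf("%s line %d: malformed row '%s'", path, i, lines[i]))
    }
    f
  })
  m <- do.call(rbind, rows)
  bad <- which(m[, 1] < 0 | m[, 1] >= n_classes | m[, 1] != round(m[, 1]))
  if (length(bad)) {
    stop(sprintf("%s: class id out of range 0..%d on line(s) %s",
                 path, n_classes - 1L, paste(bad, collapse = ", ")))
  }
  oob <- which(m[, 2] < 0 | m[, 2] > 1 | m[, 3] < 0 | m[, 3] > 1 |
                 m[, 4] <= 0 | m[, 4] > 1 | m[, 5] <= 0 | m[, 5] > 1)
  if (length(oob)) {
    stop(sprintf("%s: coordinates outside [0,1] (or non-positive size) on line(s) %s",
                 path, paste(oob, collapse = ", ")))
  }
  data.frame(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' Write YOLO-format labels
#' @param labels data frame as returned by [read_labels()]
#' @param path output file
#' @export
write_labels <- function(labels, path) {
  lines <- sprintf("%d %.8f %.8f %.8f %.8f", labels$class_id,
                   labels$cx, labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

#' Convert a pixel box to a normalized YOLO row
#' @param x1,y1,x2,y2 pixel corners; @param width,height image size
#' @param class_id 0-based class
#' @export
pixel_to_yolo <- function(class_id, x1, y1, x2, y2, width, height) {
  data.frame(class_id = as.integer(class_id),
             cx = (x1 + x2) / 2 / width, cy = (y1 + y2) / 2 / height,
             w = (x2 - x1) / width, h = (y2 - y1) / height)
}

# ---- augmentation ----------------------------------------------------------

#' Construct an augmentation operator
#'
#' Five kinds: `rotation` (angle, degrees), `gaussian_noise` (sigma on the
#' `[0,1]` scale), `salt_pepper` (density), `brightness` (delta, additive) and
#' `exposure` (gamma).
#' @param kind one of the five operator names
#' @param ... operator parameter overrides
#' @param seed RNG seed for the stochastic operators
#' @export
augment_op <- function(kind = c("rotation", "gaussian_noise", "salt_pepper",
                                "brightness", "exposure"),
                       ..., seed = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
                     rotation = list(angle = NULL),           # NULL: random
                     gaussian_noise = list(sigma = 10 / 255),
                     salt_pepper = list(density = 0.02),
                     brightness = list(delta = NULL),         # +-25 %
                     exposure = list(gamma = NULL))           # [0.7, 1.4]
  params <- utils::modifyList(defaults, list(...))
  structure(list(kind = kind, params = params, seed = seed), class = "augment_op")
}

.rotate_image <- function(img, angle) {
  # inverse-map bilinear rotation about the image centre, reflected borders
  d <- dim(img); H <- d[1]; W <- d[2]
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- rep(seq_len(H), times = W) - cy
  xx <- rep(seq_len(W), each = H) - cx
  sy <- cy - sin(th) * xx + cos(th) * yy
  sx <- cx + cos(th) * xx + sin(th) * yy
  sy <- pmin(pmax(sy, 1), H); sx <- pmin(pmax(sx, 1), W)
  y0 <- pmin(floor(sy), H - 1); x0 <- pmin(floor(sx), W - 1)
  fy <- sy - y0; fx <- sx - x0
  out <- array(0, dim = d)
  for (c in 1:3) {
    pl <- img[, , c]
    v <- (1 - fy) * (1 - fx) * pl[cbind(y0, x0)] +
      (1 - fy) * fx * pl[cbind(y0, x0 + 1)] +
      fy * (1 - fx) * pl[cbind(y0 + 1, x0)] +
      fy * fx * pl[cbind(y0 + 1, x0 + 1)]
    out[, , c] <- v
  }
  out
}

.rotate_labels <- function(labels, angle, min_area_frac = 0.1) {
  if (!nrow(labels)) return(labels)
  # rotate each box's corners about the centre (0.5, 0.5) by the image angle
  # and take the axis-aligned hull, clipped to [0,1]
  th <- angle * pi / 180
  res <- labels[0, ]
  for (i in seq_len(nrow(labels))) {
    cx <- labels$cx[i] - 0.5; cy <- labels$cy[i] - 0.5
    hw <- labels$w[i] / 2; hh <- labels$h[i] / 2
    corners_x <- cx + c(-hw, hw, hw, -hw)
    corners_y <- cy + c(-hh, -hh, hh, hh)
    rx <- cos(th) * corners_x - sin(th) * corners_y + 0.5
    ry <- sin(th) * corners_x + cos(th) * corners_y + 0.5
    x1 <- max(0, min(rx)); x2 <- min(1, max(rx))
    y1 <- max(0, min(ry)); y2 <- min(1, max(ry))
    if (x2 <= x1 || y2 <= y1) next
    if ((x2 - x1) * (y2 - y1) < min_area_frac * labels$w[i] * labels$h[i]) next
    res <- rbind(res, data.frame(class_id = labels$class_id[i],
                                 cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
                                 w = x2 - x1, h = y2 - y1))
  }
  res
}

#' Apply an augmentation operator to an image and its labels
#'
#' Photometric operators (noise, salt-and-pepper, brightness, exposure)
#' leave labels untouched. Rotation maps each box to the axis-aligned hull
#' of its rotated corners, clips to the image, and drops boxes whose clipped
#' area falls below 10 % of the original.
#'
#' @param image (H, W, 3) array in `[0, 1]`
#' @param labels data frame of YOLO rows
#' @param op an [augment_op()]
#' @return list(image, labels)
#' @export
augment <- function(image, labels, op) {
  stopifnot(inherits(op, "augment_op"))
  if (!is.null(op$seed)) set.seed(op$seed)
  p <- op$params
  out <- switch(op$kind,
    rotation = {
      angle <- p$angle %||% stats::runif(1, 0, 360)
      list(image = if (angle %% 360 == 0) image else .rotate_image(image, angle),
           labels = if (angle %% 360 == 0) labels else .rotate_labels(labels, angle))
    },
    gaussian_noise = {
      noise <- array(stats::rnorm(length(image), 0, p$sigma), dim = dim(image))
      list(image = pmin(pmax(image + noise, 0), 1), labels = labels)
    },
    salt_pepper = {
      img <- image
      if (p$density > 0) {
        npx <- prod(dim(image)[1:2])
        n <- round(p$density * npx)
        if (n > 0) {
          idx <- sample.int(npx, n)
          salt <- stats::runif(n) < 0.5
          for (c in 1:3) {
            pl <- img[, , c]; pl[idx] <- as.numeric(salt); img[, , c] <- pl
          }
        }
      }
      list(image = img, labels = labels)
    },
    brightness = {
      delta <- p$delta %||% stats::runif(1, -0.25, 0.25)
      list(image = pmin(pmax(image + delta, 0), 1), labels = labels)
    },
    exposure = {
      gamma <- p$gamma %||% stats::runif(1, 0.7, 1.4)
      list(image = pmin(pmax(image, 0), 1)^gamma, labels = labels)
    })
  out
}

# ---- manifest, expansion, splitting ----------------------------------------

#' Construct a dataset manifest
#'
#' @param image paths of images; @param label parallel label paths
#' @param class_name per-item category tag used for stratification
#' @param split optional split tags; @param provenance `"original"` or
#'   `"augmented(<op>)"`
#' @return data frame of class `dataset_manifest`
#' @export
dataset_manifest <- function(image, label, class_name,
                             split = NA_character_, provenance = "original") {
  n <- length(image)
  m <- data.frame(image = image, label = label, class_name = class_name,
                  split = rep_len(split, n), provenance = rep_len(provenance, n),
                  stringsAsFactors = FALSE)
  class(m) <- c("dataset_manifest", class(m))
  m
}

#' Expand a manifest by the five-operator augmentation rule
#'
#' Each original item is kept and `factor - 1` augmented copies are added,
#' their operators sampled without replacement from the five kinds, so
#' per-class counts scale exactly by `factor`. With `materialize = TRUE`
#' the augmented images and labels are also written next to `out_dir`.
#'
#' @param manifest a [dataset_manifest()]
#' @param factor expansion factor (>= 1)
#' @param seed RNG seed
#' @param materialize write augmented images/labels to disk
#' @param out_dir output directory when materializing
#' @return expanded manifest
#' @export
expand_dataset <- function(manifest, factor = 5L, seed = 1L,
                           materialize = FALSE, out_dir = NULL) {
  stopifnot(factor >= 1L)
  if (factor == 1L) return(manifest)
  set.seed(seed)
  kinds <- c("rotation", "gaussian_noise", "salt_pepper", "brightness", "exposure")
  stopifnot(factor - 1L <= length(kinds))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    it <- manifest[i, , drop = FALSE]
    ops <- sample(kinds, factor - 1L)
    aug <- it[rep(1L, factor - 1L), , drop = FALSE]
    stem <- sub("\\.[A-Za-z]+$", "", basename(it$image))
    ext <- sub(".*(\\.[A-Za-z]+)$", "\\1", it$image)
    aug$provenance <- paste0("augmented(", ops, ")")
    aug$image <- file.path(dirname(it$image), sprintf("%s_aug%d%s", stem,
                                                      seq_len(factor - 1L), ext))
    aug$label <- sub("\\.[A-Za-z]+$", ".txt", aug$image)
    if (materialize) {
      img <- read_image(it$image)
      lab <- read_labels(it$label)
      for (j in seq_len(factor - 1L)) {
        res <- augment(img, lab, augment_op(ops[j], seed = seed + i * 7L + j))
        tgt_img <- if (is.null(out_dir)) aug$image[j] else
          file.path(out_dir, basename(aug$image[j]))
        tgt_lab <- sub("\\.[A-Za-z]+$", ".txt", tgt_img)
        write_image(res$image, tgt_img)
        write_labels(res$labels, tgt_lab)
        aug$image[j] <- tgt_img; aug$label[j] <- tgt_lab
      }
    }
    rows[[i]] <- rbind(it, aug)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- class(manifest)
  out
}

#' Split a manifest into train/val/test by ratio, stratified by class
#'
#' Global split sizes follow largest-remainder rounding of the ratios; items
#' are assigned per class so every class is represented near-proportionally
#' in every split. Deterministic for a fixed seed.
#'
#' @param manifest a [dataset_manifest()]
#' @param ratios positive weights, default `c(7, 2, 1)`
#' @param seed RNG seed
#' @return manifest with the `split` column filled (train/val/test)
#' @export
split_dataset <- function(manifest, ratios = c(7, 2, 1), seed = 1L) {
  stopifnot(all(ratios > 0), length(ratios) == 3L)
  set.seed(seed)
  n <- nrow(manifest)
  frac <- ratios / sum(ratios)
  # global largest-remainder totals
  exact <- n * frac
  sizes <- floor(exact)
  left <- n - sum(sizes)
  if (left > 0) {
    ord <- order(exact - sizes, decreasing = TRUE)
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1L
  }
  split_names <- c("train", "val", "test")
  remaining <- sizes
  out <- manifest
  out$split <- NA_character_
  for (cl in unique(manifest$class_name)) {
    idx <- which(manifest$class_name == cl)
    idx <- idx[sample.int(length(idx))]
    nc <- length(idx)
    ex <- nc * frac
    alloc <- floor(ex)
    lo <- nc - sum(alloc)
    if (lo > 0) {
      # give leftovers to the splits with the largest global deficit,
      # breaking ties by fractional remainder
      ord <- order(remaining - alloc, ex - floor(ex), decreasing = TRUE)
      alloc[ord[seq_len(lo)]] <- alloc[ord[seq_len(lo)]] + 1L
    }
    # clamp to the remaining global budget
    alloc <- pmin(alloc, remaining)
    while (sum(alloc) < nc) {
      k <- which.max(remaining - alloc)
      alloc[k] <- alloc[k] + 1L
    }
    at <- 0L
    for (s in 1:3) {
      if (alloc[s] > 0) out$split[idx[at + seq_len(alloc[s])]] <- split_names[s]
      at <- at + alloc[s]
    }
    remaining <- remaining - alloc
  }
  class(out) <- class(manifest)
  out
}

# ---- image IO and filtering ------------------------------------------------

#' Read a PNG image as an (H, W, 3) array in `[0, 1]`
#' @param path image path
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  a
}

#' Write an (H, W, 3) array in `[0, 1]` as PNG
#' @param img image array; @param path output path
#' @export
write_image <- function(img, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

.avg_hash <- function(img, n = 8L) {
  g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  d <- dim(g)
  ri <- pmin(d[1], pmax(1, round(seq(1, d[1], length.out = n))))
  ci <- pmin(d[2], pmax(1, round(seq(1, d[2], length.out = n))))
  s <- g[ri, ci]
  as.integer(s >= mean(s))
}

#' Filter an image set: drop non-RGB files, small images and near-duplicates
#'
#' @param paths image files (PNG)
#' @param min_size minimum height/width in pixels
#' @param dup_threshold maximum Hamming distance (out of 64 hash bits) at
#'   which two images count as duplicates
#' @return data frame with columns path, keep, reason
#' @export
filter_images <- function(paths, min_size = 200L, dup_threshold = 4L) {
  keep <- rep(TRUE, length(paths))
  reason <- rep("", length(paths))
  hashes <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    a <- tryCatch(png::readPNG(paths[i]), error = function(e) NULL)
    if (is.null(a)) { keep[i] <- FALSE; reason[i] <- "unreadable"; next }
    if (length(dim(a)) == 2L || dim(a)[3] < 3L) {
      keep[i] <- FALSE; reason[i] <- "non-RGB"; next
    }
    if (dim(a)[1] < min_size || dim(a)[2] < min_size) {
      keep[i] <- FALSE; reason[i] <- "too small"; next
    }
    h <- .avg_hash(a[, , 1:3, drop = FALSE])
    dup <- FALSE
    for (j in seq_len(i - 1L)) {
      if (keep[j] && !is.null(hashes[[j]]) &&
          sum(h != hashes[[j]]) <= dup_threshold) { dup <- TRUE; break }
    }
    if (dup) { keep[i] <- FALSE; reason[i] <- "duplicate" } else hashes[[i]] <- h
  }
  data.frame(path = paths, keep = keep, reason = reason, stringsAsFactors = FALSE)
}

# ---- synthetic leaf scenes -------------------------------------------------

.scene_background <- function(size) {
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  base <- 0.12 * sin(yy / (size / 9) + stats::runif(1, 0, 6)) *
    cos(xx / (size / 7) + stats::runif(1, 0, 6)) +
    0.08 * sin((xx + yy) / (size / 13))
  soil <- array(0, dim = c(size, size, 3))
  soil[, , 1] <- 0.35 + base + stats::rnorm(size^2, 0, 0.03)
  soil[, , 2] <- 0.28 + base + stats::rnorm(size^2, 0, 0.03)
  soil[, , 3] <- 0.18 + 0.5 * base + stats::rnorm(size^2, 0, 0.03)
  pmin(pmax(soil, 0), 1)
}

.leaf_palette <- function(class_id) {
  # base leaf colour + lesion description per class
  switch(class_id + 1L,
         list(col = c(0.20, 0.55, 0.20), spots = 0L, scol = NULL, sr = 0),       # healthy
         list(col = c(0.24, 0.52, 0.20), spots = 4L, scol = c(0.45, 0.30, 0.10), sr = 0.05),  # early leaf spot
         list(col = c(0.28, 0.45, 0.16), spots = 10L, scol = c(0.25, 0.14, 0.06), sr = 0.09), # late leaf spot
         list(col = c(0.26, 0.50, 0.18), spots = 6L, scol = c(0.85, 0.50, 0.10), sr = 0.035), # early rust
         list(col = c(0.33, 0.42, 0.14), spots = 16L, scol = c(0.75, 0.35, 0.05), sr = 0.06), # late rust
         list(col = c(0.55, 0.60, 0.20), spots = 0L, scol = NULL, sr = 0))       # nutrient deficiency
}

#' Generate a synthetic leaf scene with ground-truth boxes
#'
#' Renders a soil/foliage background and `n_objects` elliptical leaves with
#' class-conditional appearance (lesion spot density, colour and size differ
#' per class; nutrient deficiency shows chlorotic yellowing), and returns
#' exact bounding boxes. Identical seeds give pixel-identical scenes.
#'
#' @param seed RNG seed
#' @param n_objects number of leaves
#' @param class_mix sampling weights over the 6 classes (default uniform)
#' @param size square image size in pixels
#' @return list(image = (size, size, 3) array, labels = YOLO data frame)
#' @export
generate_scene <- function(seed = 1L, n_objects = 3L, class_mix = rep(1, 6),
                           size = 640L) {
  stopifnot(n_objects >= 0L)
  set.seed(seed)
  img <- .scene_background(size)
  labels <- data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                       w = numeric(), h = numeric())
  if (n_objects == 0L) return(list(image = img, labels = labels))
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  for (k in seq_len(n_objects)) {
    cid <- sample.int(6L, 1L, prob = class_mix) - 1L
    pal <- .leaf_palette(cid)
    a <- stats::runif(1, 0.10, 0.22) * size     # semi-axes
    b <- a * stats::runif(1, 0.45, 0.75)
    th <- stats::runif(1, 0, pi)
    cy <- stats::runif(1, a, size - a)
    cx <- stats::runif(1, a, size - a)
    u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
    v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
    m <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(m)) next
    shade <- 1 - 0.25 * ((u / a)^2 + (v / b)^2)[m]
    for (c in 1:3) {
      pl <- img[, , c]
      col <- pal$col[c]
      if (cid == 5L) {    # chlorosis gradient towards the tip
        col <- col + 0.25 * (c == 1) * (u[m] / a + 1) / 2
        pl[m] <- pmin(1, col * shade + stats::rnorm(sum(m), 0, 0.02))
      } else {
        pl[m] <- pmin(1, col * shade + stats::rnorm(sum(m), 0, 0.02))
      }
      img[, , c] <- pl
    }
    # central vein
    vein <- m & abs(v) < max(1, 0.02 * size)
    for (c in 1:3) {
      pl <- img[, , c]; pl[vein] <- pl[vein] * 0.8 + 0.2 * 0.7; img[, , c] <- pl
    }
    if (pal$spots > 0L) {
      for (s in seq_len(pal$spots)) {
        su <- stats::runif(1, -0.8, 0.8) * a
        sv <- stats::runif(1, -0.8, 0.8) * b
        sr <- max(1.5, pal$sr * size * stats::runif(1, 0.6, 1.3))
        sm <- m & ((u - su)^2 + (v - sv)^2 <= sr^2)
        if (!any(sm)) next
        for (c in 1:3) {
          pl <- img[, , c]
          pl[sm] <- pal$scol[c] + stats::rnorm(sum(sm), 0, 0.02)
          img[, , c] <- pl
        }
      }
    }
    wi <- which(m, arr.ind = TRUE)
    y1 <- min(wi[, 1]) - 1; y2 <- max(wi[, 1])
    x1 <- min(wi[, 2]) - 1; x2 <- max(wi[, 2])
    labels <- rbind(labels, pixel_to_yolo(cid, x1, y1, x2, y2, size, size))
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, labels = labels)
}

#' Materialize a synthetic dataset on disk (images/, labels/, data.yaml)
#'
#' @param dir output directory
#' @param n number of scenes
#' @param seed base seed; scene i uses `seed + i`
#' @param size image size; @param n_objects leaves per scene (scalar or range)
#' @return a [dataset_manifest()] for the generated items
#' @export
make_synthetic_dataset <- function(dir, n = 100L, seed = 1L, size = 640L,
                                   n_objects = c(1L, 5L)) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  cls <- sda_class_names()
  img_paths <- character(n); lab_paths <- character(n); tags <- character(n)
  for (i in seq_len(n)) {
    set.seed(seed + i)
    no <- if (length(n_objects) == 2L) sample(n_objects[1]:n_objects[2], 1L)
          else n_objects
    sc <- generate_scene(seed = seed + i, n_objects = no, size = size)
    img_paths[i] <- file.path(dir, "images", sprintf("scene_%05d.png", i))
    lab_paths[i] <- file.path(dir, "labels", sprintf("scene_%05d.txt", i))
    write_image(sc$image, img_paths[i])
    write_labels(sc$labels, lab_paths[i])
    tags[i] <- if (nrow(sc$labels)) cls[sc$labels$class_id[1] + 1L] else "healthy"
  }
  yaml::write_yaml(list(path = dir, names = as.list(cls)),
                   file.path(dir, "data.yaml"))
  dataset_manifest(img_paths, lab_paths, tags)
}
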