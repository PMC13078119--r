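# Training: anchor-free assignment (each ground-truth box is assigned to the
# cell containing its centre at a level chosen by box size), binary
# cross-entropy classification loss over all cells and complete-IoU box
# regression on positives, optimised by SGD with momentum and cosine decay.

ad_row <- function(a, i) {
  av <- vv(a)
  .emit(av[i, ], function(g) {
    gd <- matrix(0, nrow(av), ncol(av))
    gd[i, ] <- g
    .acc(a, gd)
  })
}

.assign_level <- function(w, h) {
  s <- sqrt(w * h)           # normalized box size
  if (s < 0.15) "p8" else if (s < 0.35) "p16" else "p32"
}

#' Complete-IoU between predicted and target boxes (differentiable)
#'
#' @param px1,py1,px2,py2 tensor vectors of predicted corners (pixels)
#' @param t matrix P x 4 of target corners
#' @return tensor vector of CIoU values
#' @keywords internal
#' @noRd
ad_ciou <- function(px1, py1, px2, py2, t) {
  eps <- 1e-7
  iw <- ad_clamp_min(ad_sub(ad_min2(px2, t[, 3]), ad_max2(px1, t[, 1])), 0)
  ih <- ad_clamp_min(ad_sub(ad_min2(py2, t[, 4]), ad_max2(py1, t[, 2])), 0)
  inter <- ad_mul(iw, ih)
  pw <- ad_clamp_min(ad_sub(px2, px1), eps)
  ph <- ad_clamp_min(ad_sub(py2, py1), eps)
  area_t <- (t[, 3] - t[, 1]) * (t[, 4] - t[, 2])
  un <- ad_sub(ad_add(ad_mul(pw, ph), area_t), inter)
  iou <- ad_div(inter, ad_add(un, eps))
  # centre distance over enclosing-box diagonal
  pcx <- ad_mul(ad_add(px1, px2), 0.5); pcy <- ad_mul(ad_add(py1, py2), 0.5)
  tcx <- (t[, 1] + t[, 3]) / 2; tcy <- (t[, 2] + t[, 4]) / 2
  rho2 <- ad_add(ad_square(ad_sub(pcx, tcx)), ad_square(ad_sub(pcy, tcy)))
  ex1 <- ad_min2(px1, t[, 1]); ey1 <- ad_min2(py1, t[, 2])
  ex2 <- ad_max2(px2, t[, 3]); ey2 <- ad_max2(py2, t[, 4])
  c2 <- ad_add(ad_add(ad_square(ad_sub(ex2, ex1)), ad_square(ad_sub(ey2, ey1))), eps)
  tw <- t[, 3] - t[, 1]; th <- t[, 4] - t[, 2]
  v <- ad_mul(ad_square(ad_sub(ad_atan(ad_div(pw, ph)), atan(tw / pmax(th, eps)))),
              4 / pi^2)
  vc <- vv(v); iouc <- vv(iou)
  alpha <- vc / (1 - iouc + vc + eps)   # detached, standard practice
  ad_sub(ad_sub(iou, ad_div(rho2, c2)), ad_mul(v, alpha))
}

#' Detection loss for one batch
#'
#' @param raw output of [forward_detect()] in training mode
#' @param targets list per image of data frames (class_id, cx, cy, w, h)
#' @param input_size pixels
#' @param num_classes N
#' @param lambda_box box loss weight
#' @return list(loss = scalar node, cls = value, box = value, n_pos)
#' @export
detection_loss <- function(raw, targets, input_size, num_classes = 6L,
                           lambda_box = 2) {
  strides <- c(p8 = 8L, p16 = 16L, p32 = 32L)
  pos <- list(p8 = NULL, p16 = NULL, p32 = NULL)   # cells + target boxes
  cls_target <- lapply(raw, function(lv) array(0, dim = dim(vv(lv$cls))))
  for (n in seq_along(targets)) {
    tg <- targets[[n]]
    if (is.null(tg) || !nrow(tg)) next
    for (i in seq_len(nrow(tg))) {
      lv <- .assign_level(tg$w[i], tg$h[i])
      s <- strides[[lv]]
      Hl <- dim(vv(raw[[lv]]$cls))[1]; Wl <- dim(vv(raw[[lv]]$cls))[2]
      ch <- min(Hl, max(1L, ceiling(tg$cy[i] * Hl)))
      cw <- min(Wl, max(1L, ceiling(tg$cx[i] * Wl)))
      cls_target[[lv]][ch, cw, tg$class_id[i] + 1L, n] <- 1
      box <- c((tg$cx[i] - tg$w[i] / 2), (tg$cy[i] - tg$h[i] / 2),
               (tg$cx[i] + tg$w[i] / 2), (tg$cy[i] + tg$h[i] / 2)) * input_size
      pos[[lv]] <- rbind(pos[[lv]], c(ch, cw, n, box))
    }
  }
  loss_cls <- NULL
  for (lv in names(raw)) {
    l <- ad_bce_logits(raw[[lv]]$cls, cls_target[[lv]])
    loss_cls <- if (is.null(loss_cls)) l else ad_add(loss_cls, l)
  }
  n_pos <- sum(vapply(pos, function(p) if (is.null(p)) 0L else nrow(p), integer(1)))
  loss_box <- NULL
  if (n_pos > 0) {
    terms <- NULL
    for (lv in names(raw)) {
      p <- pos[[lv]]
      if (is.null(p)) next
      s <- strides[[lv]]
      cells <- matrix(p[, 1:3], ncol = 3)
      t <- matrix(p[, 4:7], ncol = 4)
      feats <- ad_gather_cells(raw[[lv]]$box, cells)     # 4 x P
      dist <- ad_mul(ad_softplus(feats), s)
      cyv <- (cells[, 1] - 0.5) * s
      cxv <- (cells[, 2] - 0.5) * s
      x1 <- ad_sub(ad_neg(ad_row(dist, 1)), -cxv)
      y1 <- ad_sub(ad_neg(ad_row(dist, 2)), -cyv)
      x2 <- ad_add(ad_row(dist, 3), cxv)
      y2 <- ad_add(ad_row(dist, 4), cyv)
      ci <- ad_ciou(x1, y1, x2, y2, t)
      one_minus <- ad_sub(1, ci)
      terms <- if (is.null(terms)) ad_sum(one_minus) else
        ad_add(terms, ad_sum(one_minus))
    }
    loss_box <- ad_div(terms, n_pos)
  }
  total <- if (is.null(loss_box)) loss_cls else
    ad_add(loss_cls, ad_mul(loss_box, lambda_box))
  list(loss = total, cls = vv(loss_cls),
       box = if (is.null(loss_box)) 0 else vv(loss_box), n_pos = n_pos)
}

# ---- optimiser -------------------------------------------------------------

sgd_new <- function(params, lr = 0.01, momentum = 0.9) {
  list(params = params, lr = lr, momentum = momentum,
       vel = lapply(params, function(p) {
         v <- vv(p); if (is.null(dim(v))) numeric(length(v)) else array(0, dim(v))
       }))
}

sgd_step <- function(opt, lr = NULL) {
  lr <- lr %||% opt$lr
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    opt$vel[[i]] <- opt$momentum * opt$vel[[i]] - lr * p$grad
    p$value <- p$value + opt$vel[[i]]
    p$grad <- NULL
  }
  opt
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- configuration and entry points ----------------------------------------

#' Training configuration
#'
#' Defaults mirror the reference protocol: batch size 4, 150 epochs,
#' 640 x 640 inputs. SGD with momentum and cosine learning-rate decay.
#'
#' @param batch_size images per step (>= 1)
#' @param epochs training epochs (>= 1)
#' @param input_size square input, divisible by 32
#' @param seed master seed recorded in every artifact
#' @param lr,momentum SGD settings
#' @param lr_schedule `"cosine"` or `"constant"`
#' @param lambda_box box loss weight
#' @param augment apply the five-operator augmentation during loading
#' @param spec a [model_spec()]
#' @export
train_config <- function(batch_size = 4L, epochs = 150L, input_size = 640L,
                         seed = 1L, lr = 0.01, momentum = 0.9,
                         lr_schedule = c("cosine", "constant"),
                         lambda_box = 2, augment = TRUE,
                         spec = yolo_sda_spec(input_size = input_size)) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(batch_size >= 1L, epochs >= 1L, input_size %% 32L == 0L)
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 input_size = as.integer(input_size), seed = as.integer(seed),
                 lr = lr, momentum = momentum, lr_schedule = lr_schedule,
                 lambda_box = lambda_box, augment = augment, spec = spec),
            class = "train_config")
}

.load_item <- function(img_path, lab_path, S) {
  img <- read_image(img_path)
  if (dim(img)[1] != S || dim(img)[2] != S) img <- resize_image(img, S)
  list(image = img, labels = read_labels(lab_path))
}

#' Bilinear resize of an (H,W,3) image to S x S
#' @param img image array; @param S output side
#' @export
resize_image <- function(img, S) {
  d <- dim(img)
  sy <- pmin(pmax((seq_len(S) - 0.5) * d[1] / S + 0.5, 1), d[1])
  sx <- pmin(pmax((seq_len(S) - 0.5) * d[2] / S + 0.5, 1), d[2])
  y0 <- pmin(floor(sy), d[1] - 1); x0 <- pmin(floor(sx), d[2] - 1)
  fy <- sy - y0; fx <- sx - x0
  out <- array(0, dim = c(S, S, 3))
  for (c in 1:3) {
    pl <- img[, , c]
    a <- pl[y0, x0] * outer(1 - fy, 1 - fx) + pl[y0, x0 + 1] * outer(1 - fy, fx) +
      pl[y0 + 1, x0] * outer(fy, 1 - fx) + pl[y0 + 1, x0 + 1] * outer(fy, fx)
    out[, , c] <- a
  }
  out
}

#' Train a detector
#'
#' @param config a [train_config()]
#' @param manifest a [dataset_manifest()]; alternatively pass in-memory
#'   `scenes` (a list of `list(image, labels)`)
#' @param scenes optional in-memory data
#' @param iterations optional cap on total optimisation steps (overrides
#'   epochs for quick experiments)
#' @param out_dir if given, writes checkpoint.rds, history.csv and the
#'   resolved config snapshot there
#' @param model optionally continue training an assembled model
#' @param verbose print per-epoch loss
#' @return list(model, history (data frame), checkpoint path or NULL)
#' @export
sda_train <- function(config, manifest = NULL, scenes = NULL, iterations = NULL,
                      out_dir = NULL, model = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (is.null(manifest) && is.null(scenes)) stop("no training data given")
  if (!is.null(manifest) && nrow(manifest) == 0) stop("empty manifest")
  if (is.null(scenes)) {
    scenes <- lapply(seq_len(nrow(manifest)), function(i) {
      .load_item(manifest$image[i], manifest$label[i], config$input_size)
    })
  }
  if (!length(scenes)) stop("empty training set")
  set.seed(config$seed)
  if (is.null(model)) model <- assemble(config$spec, seed = config$seed)
  params <- module_params(model)
  opt <- sgd_new(params, config$lr, config$momentum)
  nimg <- length(scenes)
  steps_per_epoch <- max(1L, ceiling(nimg / config$batch_size))
  total_steps <- if (!is.null(iterations)) iterations
                 else config$epochs * steps_per_epoch
  hist <- data.frame(epoch = integer(), loss = numeric(), cls = numeric(),
                     box = numeric(), lr = numeric())
  step <- 0L
  ep <- 0L
  aug_kinds <- c("rotation", "gaussian_noise", "salt_pepper", "brightness", "exposure")
  while (step < total_steps) {
    ep <- ep + 1L
    ord <- sample.int(nimg)
    ep_losses <- c()
    ep_cls <- c(); ep_box <- c()
    for (b in seq_len(steps_per_epoch)) {
      if (step >= total_steps) break
      idx <- ord[((b - 1L) * config$batch_size) %% nimg + seq_len(config$batch_size)]
      idx <- idx[!is.na(idx) & idx <= nimg]
      if (!length(idx)) idx <- ord[seq_len(min(config$batch_size, nimg))]
      imgs <- vector("list", length(idx)); tgts <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        sc <- scenes[[idx[j]]]
        if (config$augment && stats::runif(1) < 0.5) {
          op <- augment_op(sample(aug_kinds, 1))
          sc <- augment(sc$image, sc$labels, op)
        }
        imgs[[j]] <- sc$image
        tgts[[j]] <- sc$labels
      }
      S <- config$input_size
      batch <- array(0, dim = c(S, S, 3L, length(idx)))
      for (j in seq_along(idx)) batch[, , , j] <- imgs[[j]]
      lr_t <- if (config$lr_schedule == "cosine") {
        config$lr * 0.5 * (1 + cos(pi * step / max(1, total_steps)))
      } else config$lr
      ad_tape_start()
      xin <- .emit(batch, NULL)
      raw <- forward_detect(model, xin, training = TRUE)
      ls <- detection_loss(raw, tgts, S, config$spec$num_classes,
                           config$lambda_box)
      ad_backward(ls$loss)
      opt <- sgd_step(opt, lr_t)
      step <- step + 1L
      ep_losses <- c(ep_losses, vv(ls$loss))
      ep_cls <- c(ep_cls, ls$cls); ep_box <- c(ep_box, ls$box)
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(ep_losses),
                                   cls = mean(ep_cls), box = mean(ep_box),
                                   lr = lr_t))
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f (cls %.4f, box %.4f)",
                      ep, mean(ep_losses), mean(ep_cls), mean(ep_box)))
    }
  }
  ckpt <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- file.path(out_dir, "checkpoint.rds")
    save_checkpoint(model, ckpt)
    utils::write.csv(hist, file.path(out_dir, "history.csv"), row.names = FALSE)
    cfg <- config; cfg$spec <- NULL
    jsonlite::write_json(c(cfg, list(backbone = config$spec$backbone,
                                     upsampler = config$spec$upsampler,
                                     fusion_block = config$spec$fusion_block)),
                         file.path(out_dir, "config.json"), auto_unbox = TRUE)
  }
  list(model = model, history = hist, checkpoint = ckpt)
}

.labels_to_xyxy <- function(labels, S) {
  data.frame(class_id = labels$class_id,
             x1 = (labels$cx - labels$w / 2) * S,
             y1 = (labels$cy - labels$h / 2) * S,
             x2 = (labels$cx + labels$w / 2) * S,
             y2 = (labels$cy + labels$h / 2) * S)
}

#' Evaluate a trained detector, with the repeated-run protocol
#'
#' Runs inference on every item, scores COCO-style metrics, and (for
#' `runs > 1`) repeats evaluation on seeded bootstrap resamples of the image
#' set to quantify run-to-run variability, summarised as mean +- sd.
#'
#' @param model assembled network or a checkpoint path
#' @param manifest dataset manifest (or in-memory `scenes`)
#' @param scenes optional list of `list(image, labels)`
#' @param runs number of repeated evaluations
#' @param seeds per-run seeds (default `1:runs`)
#' @param conf_threshold,iou_threshold decoding thresholds
#' @param input_size evaluation input size
#' @return list(report (pooled [evaluate_detections()] result), runs
#'   (per-run reports), stats (named [run_statistics()]), formatted)
#' @export
sda_evaluate <- function(model, manifest = NULL, scenes = NULL, runs = 1L,
                         seeds = NULL, conf_threshold = 0.25,
                         iou_threshold = 0.45, input_size = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  S <- input_size %||% model$spec$input_size
  if (is.null(scenes)) {
    stopifnot(!is.null(manifest))
    missing <- !file.exists(manifest$label)
    if (any(missing)) {
      for (p in manifest$label[missing]) warning("missing label file: ", p)
      if (mean(missing) > 0.1) stop("more than 10% of label files are missing")
    }
    scenes <- lapply(seq_len(nrow(manifest)), function(i) {
      .load_item(manifest$image[i], manifest$label[i], S)
    })
  }
  dets <- vector("list", length(scenes))
  truths <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    raw <- forward_detect(model, scenes[[i]]$image, training = FALSE)
    dets[[i]] <- decode_and_nms(raw, conf_threshold, iou_threshold)
    truths[[i]] <- .labels_to_xyxy(scenes[[i]]$labels, S)
  }
  nc <- model$spec$num_classes
  pooled <- evaluate_detections(dets, truths, nc)
  seeds <- seeds %||% seq_len(runs)
  run_reports <- list()
  metr <- list(map_50_95 = numeric(), map_50 = numeric(),
               precision = numeric(), recall = numeric())
  for (r in seq_len(runs)) {
    if (runs == 1L) {
      rep_r <- pooled
    } else {
      set.seed(seeds[r])
      take <- sample.int(length(scenes), length(scenes), replace = TRUE)
      rep_r <- evaluate_detections(dets[take], truths[take], nc)
    }
    run_reports[[r]] <- rep_r
    metr$map_50_95 <- c(metr$map_50_95, rep_r$map_50_95)
    metr$map_50 <- c(metr$map_50, rep_r$map_50)
    metr$precision <- c(metr$precision, rep_r$precision)
    metr$recall <- c(metr$recall, rep_r$recall)
  }
  stats <- lapply(metr, function(v) suppressWarnings(run_statistics(v)))
  list(report = pooled, runs = run_reports, stats = stats,
       formatted = vapply(stats, format_mean_sd, character(1)))
}
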