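# Detection evaluation: greedy matching, precision/recall, 101-point
# interpolated average precision, mAP over IoU thresholds 0.50-0.95, and
# repeated-run mean +- sd summaries.

#' Greedy matching of detections to ground truth at one IoU threshold
#'
#' Detections are processed in descending score order; each matches the
#' highest-IoU unmatched ground-truth box of the same class with IoU at or
#' above the threshold. Unmatched detections are false positives; unmatched
#' truths are false negatives.
#'
#' @param dets data frame with x1, y1, x2, y2, score, class_id
#' @param truths data frame with x1, y1, x2, y2, class_id
#' @param iou_threshold matching threshold
#' @return list with counts `tp`, `fp`, `fn`, logical vector `det_tp`
#'   (per detection, in score order), the score-ordered detections and
#'   matched pair indices with IoU values
#' @export
match_detections <- function(dets, truths, iou_threshold = 0.5) {
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  nd <- nrow(dets); nt <- nrow(truths)
  det_tp <- logical(nd)
  matched <- logical(nt)
  pairs <- data.frame(det = integer(), truth = integer(), iou = numeric())
  if (nd && nt) {
    iou <- box_iou(as.matrix(dets[, c("x1", "y1", "x2", "y2")]),
                   as.matrix(truths[, c("x1", "y1", "x2", "y2")]))
    for (i in seq_len(nd)) {
      cand <- which(!matched & truths$class_id == dets$class_id[i] &
                      iou[i, ] >= iou_threshold)
      if (length(cand)) {
        j <- cand[which.max(iou[i, cand])]
        matched[j] <- TRUE
        det_tp[i] <- TRUE
        pairs <- rbind(pairs, data.frame(det = i, truth = j, iou = iou[i, j]))
      }
    }
  }
  list(tp = sum(det_tp), fp = nd - sum(det_tp), fn = nt - sum(matched),
       det_tp = det_tp, dets = dets, pairs = pairs)
}

#' Precision and recall from match counts
#'
#' P = TP / (TP + FP), R = TP / (TP + FN); the empty 0/0 case is 0 by
#' convention.
#'
#' @param m a [match_detections()] result, or a list with tp/fp/fn
#' @return named numeric c(precision, recall)
#' @export
precision_recall <- function(m) {
  if (any(c(m$tp, m$fp, m$fn) < 0)) stop("negative counts")
  p <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0
  r <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0
  c(precision = p, recall = r)
}

#' Average precision from a score-ordered TP/FP flag sequence
#'
#' Integrates the precision envelope over recall. The default is 101-point
#' interpolation on the monotonized envelope (COCO convention);
#' `mode = "continuous"` integrates the exact step curve instead.
#'
#' @param flags logical vector, TRUE for a true positive, ordered by
#'   decreasing score
#' @param n_truths number of ground-truth boxes
#' @param mode `"interp101"` or `"continuous"`
#' @return AP in `[0, 1]`
#' @export
average_precision <- function(flags, n_truths, mode = c("interp101", "continuous")) {
  mode <- match.arg(mode)
  stopifnot(n_truths >= 0)
  if (n_truths == 0 || !length(flags)) return(0)
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  rec <- tp / n_truths
  prec <- tp / (tp + fp)
  if (mode == "interp101") {
    rgrid <- seq(0, 1, by = 0.01)
    # precision envelope: best precision at recall >= r
    ap <- 0
    env <- rev(cummax(rev(prec)))
    for (r in rgrid) {
      i <- which(rec >= r)
      ap <- ap + (if (length(i)) env[i[1]] else 0)
    }
    ap / length(rgrid)
  } else {
    env <- rev(cummax(rev(prec)))
    dr <- diff(c(0, rec))
    sum(env * dr)
  }
}

#' Mean average precision over a class-by-threshold AP grid
#'
#' @param per_threshold_aps numeric matrix (classes x thresholds) or vector
#' @return the mean; missing values are treated as AP 0 with a warning
#' @export
map_50_95 <- function(per_threshold_aps) {
  x <- as.numeric(per_threshold_aps)
  if (anyNA(x)) {
    warning("missing AP entries treated as 0")
    x[is.na(x)] <- 0
  }
  mean(x)
}

#' Repeated-run summary statistics
#'
#' Sample mean and sample standard deviation (n - 1 denominator). A single
#' run reports sd 0 with a warning.
#'
#' @param values per-run metric values
#' @return object of class `run_statistics` with mean, sd, n, values
#' @export
run_statistics <- function(values) {
  if (!length(values)) stop("no values")
  n <- length(values)
  s <- if (n >= 2) stats::sd(values) else { warning("single run; sd reported as 0"); 0 }
  structure(list(mean = mean(values), sd = s, n = n, values = values),
            class = "run_statistics")
}

#' @export
print.run_statistics <- function(x, ...) {
  cat(format_mean_sd(x), "\n")
  invisible(x)
}

#' Format a run summary as "xx.x +- y.y" in percent
#' @param x a [run_statistics()] object (values on the 0-1 scale)
#' @export
format_mean_sd <- function(x) {
  sprintf("%.1f ± %.1f", 100 * x$mean, 100 * x$sd)
}

#' Evaluate detections against ground truth over a set of images
#'
#' Computes per-class AP at IoU thresholds 0.50 to 0.95 (step 0.05),
#' mAP@0.5-0.95, and precision/recall at the F1-maximising confidence.
#'
#' @param dets_list per-image detection data frames
#' @param truths_list per-image truth data frames (class_id + xyxy)
#' @param n_classes class count N
#' @param iou_thresholds matching thresholds
#' @return object of class `eval_report`: fields `ap` (classes x
#'   thresholds), `map_50_95`, `map_50`, `precision`, `recall`
#' @export
evaluate_detections <- function(dets_list, truths_list, n_classes = 6L,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(length(dets_list) == length(truths_list))
  ap <- matrix(0, n_classes, length(iou_thresholds),
               dimnames = list(NULL, sprintf("%.2f", iou_thresholds)))
  for (ti in seq_along(iou_thresholds)) {
    th <- iou_thresholds[ti]
    for (cl in seq_len(n_classes) - 1L) {
      flags <- numeric(); scores <- numeric(); ntr <- 0L
      for (i in seq_along(dets_list)) {
        d <- dets_list[[i]]; g <- truths_list[[i]]
        d <- d[d$class_id == cl, , drop = FALSE]
        g <- g[g$class_id == cl, , drop = FALSE]
        ntr <- ntr + nrow(g)
        if (nrow(d)) {
          m <- match_detections(d, g, th)
          flags <- c(flags, m$det_tp)
          scores <- c(scores, m$dets$score)
        }
      }
      if (ntr == 0L) { ap[cl + 1L, ti] <- NA; next }
      ord <- order(-scores)
      ap[cl + 1L, ti] <- average_precision(as.logical(flags[ord]), ntr)
    }
  }
  present <- rowSums(!is.na(ap)) > 0
  # P/R at the F1-maximising confidence over the 0.5-IoU sweep
  all_flags <- logical(); all_scores <- numeric(); total_truths <- 0L
  for (i in seq_along(dets_list)) {
    d <- dets_list[[i]]; g <- truths_list[[i]]
    total_truths <- total_truths + nrow(g)
    if (nrow(d)) {
      m <- match_detections(d, g, 0.5)
      all_flags <- c(all_flags, m$det_tp)
      all_scores <- c(all_scores, m$dets$score)
    }
  }
  pr <- c(precision = 0, recall = 0)
  if (length(all_flags) && total_truths > 0) {
    ord <- order(-all_scores)
    fl <- all_flags[ord]
    tp <- cumsum(fl); fp <- cumsum(!fl)
    prec <- tp / (tp + fp); rec <- tp / total_truths
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    k <- which.max(f1)
    pr <- c(precision = prec[k], recall = rec[k])
  }
  apc <- ap
  structure(list(ap = apc,
                 map_50_95 = map_50_95(ap[present, , drop = FALSE]),
                 map_50 = map_50_95(ap[present, 1, drop = FALSE]),
                 precision = unname(pr["precision"]),
                 recall = unname(pr["recall"]),
                 n_classes = n_classes),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("mAP@0.5      : %.3f\nmAP@0.5-0.95 : %.3f\nP / R (best F1): %.3f / %.3f\n",
              x$map_50, x$map_50_95, x$precision, x$recall))
  invisible(x)
}
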