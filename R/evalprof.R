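# Detection evaluation (greedy matching, precision/recall/F1, 101-point
# interpolated AP, mAP over IoU thresholds, FPS) and the analytic
# architecture profiler (parameters, FLOPs at a reference input size,
# half-precision serialized size).

#' Intersection over union of two boxes
#' @param a,b numeric length-4 `c(x1, y1, x2, y2)` boxes.
#' @return numeric scalar in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  uni <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (uni <= 0) return(0)
  inter / uni
}

#' Match detections to ground truth for PR analysis
#'
#' Detections are processed in decreasing score order; each matches the
#' highest-IoU not-yet-matched ground-truth box of its class (within its
#' image) at IoU >= `iou_threshold` and becomes a true positive, otherwise a
#' false positive. Unmatched ground truth counts as false negatives.
#'
#' @param preds data.frame with x1, y1, x2, y2, score, class_id and
#'   optionally image_id.
#' @param gts data.frame with x1, y1, x2, y2, class_id and optionally
#'   image_id.
#' @param iou_threshold IoU threshold (default 0.5).
#' @return list with `ranked` (data.frame score, is_tp, class_id ordered by
#'   decreasing score), `gt_count` (named per-class vector), and the scalar
#'   counts `TP`, `FP`, `FN`.
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  preds <- as.data.frame(preds); gts <- as.data.frame(gts)
  if (is.null(preds$image_id)) preds$image_id <- 1L
  if (is.null(gts$image_id)) gts$image_id <- 1L
  ord <- order(-preds$score)
  preds <- preds[ord, , drop = FALSE]
  matched <- rep(FALSE, nrow(gts))
  is_tp <- logical(nrow(preds))
  for (i in seq_len(nrow(preds))) {
    cand <- which(!matched & gts$class_id == preds$class_id[i] &
                    gts$image_id == preds$image_id[i])
    if (length(cand) == 0L) next
    ious <- vapply(cand, function(j)
      box_iou(as.numeric(preds[i, c("x1", "y1", "x2", "y2")]),
              as.numeric(gts[j, c("x1", "y1", "x2", "y2")])), 0)
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      matched[cand[best]] <- TRUE
      is_tp[i] <- TRUE
    }
  }
  classes <- sort(unique(c(preds$class_id, gts$class_id)))
  gt_count <- vapply(classes, function(cl) sum(gts$class_id == cl), 0L)
  names(gt_count) <- classes
  list(ranked = data.frame(score = preds$score, is_tp = is_tp,
                           class_id = preds$class_id),
       gt_count = gt_count,
       TP = sum(is_tp), FP = sum(!is_tp), FN = sum(!matched))
}

check_counts <- function(...) {
  if (any(c(...) < 0)) stop("counts must be non-negative")
  invisible(TRUE)
}

#' Precision, recall and F1 from detection counts
#'
#' Zero denominators return 0 by convention.
#'
#' @param TP,FP,FN non-negative counts.
#' @param P,R precision and recall fractions.
#' @return numeric scalar in `[0, 1]`.
#' @export
precision <- function(TP, FP) {
  check_counts(TP, FP)
  if (TP + FP == 0) 0 else TP / (TP + FP)
}

#' @rdname precision
#' @export
recall <- function(TP, FN) {
  check_counts(TP, FN)
  if (TP + FN == 0) 0 else TP / (TP + FN)
}

#' @rdname precision
#' @export
f1 <- function(P, R) {
  if (P + R == 0) 0 else 2 * P * R / (P + R)
}

#' Average precision of a ranked detection list
#'
#' `"101point"` (default) samples the precision envelope at recalls 0, 0.01,
#' ..., 1.00; `"envelope"` integrates the exact precision envelope over
#' recall.
#'
#' @param is_tp logical vector, detections ordered by decreasing score.
#' @param n_gt number of ground-truth boxes for the class (must be >= 1).
#' @param convention AP convention.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(is_tp, n_gt,
                              convention = c("101point", "envelope")) {
  convention <- match.arg(convention)
  if (n_gt < 1) stop("average precision undefined without ground truth")
  if (length(is_tp) == 0L) return(0)
  tp <- cumsum(is_tp)
  fp <- cumsum(!is_tp)
  rec <- tp / n_gt
  prec <- tp / (tp + fp)
  # precision envelope: best precision at recall >= r
  env <- rev(cummax(rev(prec)))
  if (convention == "101point") {
    rs <- seq(0, 1, by = 0.01)
    ps <- vapply(rs, function(r) {
      i <- which(rec >= r)
      if (length(i) == 0L) 0 else env[i[1L]]
    }, 0)
    mean(ps)
  } else {
    r_prev <- c(0, rec[-length(rec)])
    sum((rec - r_prev) * env)
  }
}

#' Mean average precision over classes
#' @param aps numeric vector of per-class APs (classes without ground truth
#'   excluded before calling).
#' @return mean AP.
#' @export
mean_ap <- function(aps) if (length(aps) == 0L) 0 else mean(aps)

# mAP at one IoU threshold from prediction/gt tables.
map_at_iou <- function(preds, gts, iou) {
  m <- match_detections(preds, gts, iou)
  classes <- as.integer(names(m$gt_count)[m$gt_count > 0])
  aps <- vapply(classes, function(cl) {
    r <- m$ranked[m$ranked$class_id == cl, , drop = FALSE]
    average_precision(r$is_tp, m$gt_count[[as.character(cl)]])
  }, 0)
  mean_ap(aps)
}

#' Evaluate detections against ground truth
#'
#' @param preds,gts data.frames as in [match_detections()].
#' @param iou IoU threshold for the precision/recall/F1 and mAP50 numbers.
#' @return list with `precision`, `recall`, `f1`, `mAP50`, `mAP50_95`.
#' @export
evaluate_detections <- function(preds, gts, iou = 0.5) {
  m <- match_detections(preds, gts, iou)
  P <- precision(m$TP, m$FP)
  R <- recall(m$TP, m$FN)
  thr <- seq(0.5, 0.95, by = 0.05)
  maps <- vapply(thr, function(t) map_at_iou(preds, gts, t), 0)
  list(precision = P, recall = R, f1 = f1(P, R),
       mAP50 = maps[1L], mAP50_95 = mean(maps))
}

#' Frames per second from inference timings
#'
#' The reciprocal of the arithmetic mean inference time. Hardware-dependent;
#' reported for information only.
#'
#' @param timings numeric vector of per-image inference times in seconds.
#' @return frames per second.
#' @export
fps <- function(timings) {
  if (length(timings) == 0L) stop("need at least one timing")
  if (any(timings <= 0)) stop("timings must be positive")
  1 / mean(timings)
}

# --- profiler ---------------------------------------------------------------

#' Profile a detector's size and compute cost
#'
#' Counts trainable parameters exactly and computes analytic FLOPs at the
#' given input size with a 2-ops-per-multiply-accumulate convention
#' (convolutions: `2 k^2 C_in C_out H W / groups`; linear layers:
#' `2 n_in n_out n_tokens`; attention: both projection and `QK^T`/`AV`
#' matmul terms; WTConv layers: depthwise band cost plus the closed-form
#' decomposition/reconstruction counts). The serialized size assumes
#' half-precision storage (2 bytes per weight).
#'
#' @param model a detector from [build_model()].
#' @param input_size square input size in pixels (default: the model's
#'   configured size).
#' @return a `model_profile` list: `params`, `params_m`, `flops`, `gflops`,
#'   `size_mb`, plus a per-component breakdown.
#' @export
profile_model <- function(model, input_size = NULL) {
  stopifnot(inherits(model, "wmc_detector"))
  size <- as.integer(input_size %||% model$cfg$input_size)
  count <- function(module)
    sum(vapply(collect_params(module), function(p) length(p$v), 0))
  p_back <- count(model$backbone)
  p_enc <- count(model$encoder)
  p_dec <- count(model$decoder)
  params <- p_back + p_enc + p_dec
  bb <- backbone_flops(model$backbone, size, size)
  h3 <- bb$sizes[[2L]][1]; w3 <- bb$sizes[[2L]][2]
  f_enc <- encoder_flops(model$encoder, h3, w3)
  f_dec <- decoder_flops(model$decoder, bb$sizes[2:4])
  flops <- bb$f + f_enc + f_dec
  structure(list(params = params,
                 params_m = round(params / 1e6, 2),
                 flops = flops,
                 gflops = round(flops / 1e9, 1),
                 size_mb = round(params * 2 / 1e6, 1),
                 breakdown = data.frame(
                   component = c("backbone", "encoder", "decoder"),
                   params = c(p_back, p_enc, p_dec),
                   flops = c(bb$f, f_enc, f_dec)),
                 input_size = size),
            class = "model_profile")
}

#' @export
print.model_profile <- function(x, ...) {
  cat("model profile @", x$input_size, "x", x$input_size, "\n")
  cat(sprintf("  params: %.2f M   flops: %.1f G   size: %.1f MB\n",
              x$params / 1e6, x$flops / 1e9, x$size_mb))
  b <- x$breakdown
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-9s %8.2f M  %6.1f G\n", b$component[i],
                b$params[i] / 1e6, b$flops[i] / 1e9))
  invisible(x)
}

# Hook-based FLOP measurement: runs a real forward pass with the engine's
# op-level meter enabled. Independent cross-check for profile_model().
measure_flops <- function(model, input_size = NULL) {
  size <- as.integer(input_size %||% model$cfg$input_size)
  img <- array(0.5, c(size, size, 3L))
  flops_meter_start()
  invisible(model_forward(model, img))
  flops_meter_stop()
}
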