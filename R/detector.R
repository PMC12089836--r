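# Detector assembly and training: model variants (baseline RT-DETR-style vs
# wavelet/M2SA/CSRFPN-improved), GIoU, Hungarian matching, the DETR loss with
# denoising queries, a desk-scale AdamW training loop and thresholded
# prediction (end-to-end, no NMS anywhere).

#' Detector configuration
#'
#' The `variant` maps one-to-one onto the ablation grid: which of the three
#' improvements (WTConv backbone, M2SA-AIFI encoder layer, CSRFPN neck) are
#' switched on over the shared decoder.
#'
#' @param variant one of `"baseline"`, `"wtconv_only"`, `"m2sa_only"`,
#'   `"wtconv+m2sa"`, `"csrfpn_only"`, `"full"`.
#' @param hidden hidden width of encoder/decoder (default 256).
#' @param decoder_layers number of decoder layers (default 3).
#' @param queries number of object queries (default 300; capped at the token
#'   count for small inputs).
#' @param denoising number of denoising queries during training (default 100).
#' @param input_size expected square input size in pixels (default 640).
#' @param num_classes number of object classes (default 2: tea leaf blight,
#'   green mirid bug).
#' @param wt_policy WTConv replacement policy (see [build_wt_backbone()]).
#' @param wtcfg a [wtconv_config()].
#' @param m2sa a [m2sa_config()] used when the variant includes M2SA.
#' @param neck a [neck_config()] used when the variant includes CSRFPN.
#' @param ffn feed-forward width of encoder/decoder layers.
#' @return a `model_config` list.
#' @export
model_config <- function(variant = c("baseline", "wtconv_only", "m2sa_only",
                                     "wtconv+m2sa", "csrfpn_only", "full"),
                         hidden = 256L, decoder_layers = 3L, queries = 300L,
                         denoising = 100L, input_size = 640L,
                         num_classes = 2L, wt_policy = "balanced",
                         wtcfg = wtconv_config(), m2sa = m2sa_config(),
                         neck = neck_config(), ffn = 1024L) {
  variant <- match.arg(variant)
  flags <- switch(variant,
    baseline      = c(wt = FALSE, m2sa = FALSE, csrfpn = FALSE),
    wtconv_only   = c(wt = TRUE, m2sa = FALSE, csrfpn = FALSE),
    m2sa_only     = c(wt = FALSE, m2sa = TRUE, csrfpn = FALSE),
    `wtconv+m2sa` = c(wt = TRUE, m2sa = TRUE, csrfpn = FALSE),
    csrfpn_only   = c(wt = FALSE, m2sa = FALSE, csrfpn = TRUE),
    full          = c(wt = TRUE, m2sa = TRUE, csrfpn = TRUE))
  structure(list(variant = variant, flags = flags,
                 hidden = as.integer(hidden),
                 decoder_layers = as.integer(decoder_layers),
                 queries = as.integer(queries),
                 denoising = as.integer(denoising),
                 input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes),
                 wt_policy = wt_policy, wtcfg = wtcfg, m2sa = m2sa,
                 neck = neck, ffn = as.integer(ffn)),
            class = "model_config")
}

#' Build a detector
#'
#' Assembles backbone, hybrid encoder and decoder for the configured variant.
#' Weight initialization is driven by `seed`, so the same (config, seed) pair
#' reproduces the same model.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return a `wmc_detector` object.
#' @export
build_model <- function(cfg = model_config(), seed = 0L) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(seed)
  model <- list(cfg = cfg,
                backbone = build_wt_backbone(wt = cfg$flags[["wt"]],
                                             policy = cfg$wt_policy,
                                             wtcfg = cfg$wtcfg,
                                             input_size = cfg$input_size),
                encoder = make_encoder(hidden = cfg$hidden,
                                       use_m2sa = cfg$flags[["m2sa"]],
                                       use_csrfpn = cfg$flags[["csrfpn"]],
                                       ffn = cfg$ffn, m2sa_cfg = cfg$m2sa,
                                       neck_cfg = cfg$neck),
                decoder = make_decoder(d = cfg$hidden, nc = cfg$num_classes,
                                       layers = cfg$decoder_layers,
                                       queries = cfg$queries,
                                       ffn = cfg$ffn,
                                       denoising = cfg$denoising))
  class(model) <- "wmc_detector"
  model
}

#' @export
print.wmc_detector <- function(x, ...) {
  np <- sum(vapply(collect_params(x), function(p) length(p$v), 0))
  cat("<wmc_detector variant=", x$cfg$variant,
      " params=", format(round(np / 1e6, 2), nsmall = 2), "M",
      " input=", x$cfg$input_size, "x", x$cfg$input_size, ">\n", sep = "")
  invisible(x)
}

# Full forward pass on one (H, W, 3) image array scaled to [0, 1].
model_forward <- function(model, img, dn = NULL) {
  x <- tt(img)
  feats <- backbone_fwd(model$backbone, x)
  neck <- encoder_fwd(model$encoder, feats)
  decoder_fwd(model$decoder, neck, dn)
}

# --- GIoU -------------------------------------------------------------------

#' Generalized intersection over union of two boxes
#'
#' IoU penalized by the empty fraction of the smallest enclosing (hull) box:
#' `IoU - |hull \\ union| / |hull|`, in (-1, 1] with 1 for identical boxes.
#'
#' @param a,b numeric length-4 boxes `c(x1, y1, x2, y2)` with `x1 < x2`,
#'   `y1 < y2`.
#' @return numeric scalar.
#' @examples
#' giou(c(0, 0, 10, 10), c(0, 0, 10, 10))   # 1
#' giou(c(0, 0, 10, 10), c(10, 0, 20, 10))  # 0 (touching)
#' @export
giou <- function(a, b) {
  if (a[1] >= a[3] || a[2] >= a[4] || b[1] >= b[3] || b[2] >= b[4])
    stop("degenerate box: need x1 < x2 and y1 < y2")
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  uni <- area_a + area_b - inter
  hull <- (max(a[3], b[3]) - min(a[1], b[1])) *
          (max(a[4], b[4]) - min(a[2], b[2]))
  inter / uni - (hull - uni) / hull
}

# Vectorized pairwise GIoU between two box matrices (xyxy rows).
giou_matrix <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(nrow(B))) {
    b <- B[j, ]
    iw <- pmax(0, pmin(A[, 3], b[3]) - pmax(A[, 1], b[1]))
    ih <- pmax(0, pmin(A[, 4], b[4]) - pmax(A[, 2], b[2]))
    inter <- iw * ih
    uni <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2]) +
      (b[3] - b[1]) * (b[4] - b[2]) - inter
    hull <- (pmax(A[, 3], b[3]) - pmin(A[, 1], b[1])) *
            (pmax(A[, 4], b[4]) - pmin(A[, 2], b[2]))
    out[, j] <- inter / uni - (hull - uni) / hull
  }
  out
}

cxcywh_to_xyxy <- function(b) {
  cbind(b[, 1] - b[, 3] / 2, b[, 2] - b[, 4] / 2,
        b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
}

xyxy_to_cxcywh <- function(b) {
  cbind((b[, 1] + b[, 3]) / 2, (b[, 2] + b[, 4]) / 2,
        b[, 3] - b[, 1], b[, 4] - b[, 2])
}

# --- Hungarian assignment ---------------------------------------------------

# Optimal assignment for a rectangular cost matrix (shortest augmenting
# paths, O(n^3)). Returns 0 for unassigned rows.
hungarian_solve <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(integer(nr))
  n <- max(nr, nc)
  big <- max(abs(cost)) * (n + 1) + 1
  C <- matrix(0, n, n)
  C[seq_len(nr), seq_len(nc)] <- cost
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (used[j]) next
        cur <- C[i0, j - 1L] - u[i0 + 0L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_row <- integer(nr)
  for (j in 2L:(n + 1L)) {
    i <- p[j]
    if (i >= 1L && i <= nr && (j - 1L) <= nc) assign_row[i] <- j - 1L
  }
  assign_row
}

#' Hungarian matching between predictions and ground truth
#'
#' One-to-one assignment of predicted boxes to ground-truth boxes minimizing
#' a combined classification + L1 + GIoU cost; unmatched predictions are
#' background.
#'
#' @param pred list with `boxes` (n x 4 xyxy, pixels), `scores` (n x classes
#'   matrix of per-class probabilities).
#' @param gt data.frame or matrix with columns x1, y1, x2, y2, class_id.
#' @param weights named numeric: `class`, `l1`, `giou` cost weights.
#' @param image_size image extent used to normalize the L1 term.
#' @return data.frame with columns `pred` and `gt` (1-based indices), one row
#'   per matched pair; zero rows if `gt` is empty.
#' @export
hungarian_match <- function(pred, gt,
                            weights = c(class = 2, l1 = 5, giou = 2),
                            image_size = 640) {
  gt <- as.data.frame(gt)
  if (nrow(gt) == 0L)
    return(data.frame(pred = integer(0), gt = integer(0)))
  gtb <- as.matrix(gt[, c("x1", "y1", "x2", "y2")])
  cost_cls <- -pred$scores[, gt$class_id + 1L, drop = FALSE]
  A <- xyxy_to_cxcywh(pred$boxes) / image_size
  B <- xyxy_to_cxcywh(gtb) / image_size
  cost_l1 <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(nrow(B)))
    cost_l1[, j] <- rowSums(abs(sweep(A, 2L, B[j, ])))
  cost_giou <- -giou_matrix(pred$boxes, gtb)
  cost <- weights[["class"]] * cost_cls + weights[["l1"]] * cost_l1 +
    weights[["giou"]] * cost_giou
  gt_of_pred <- hungarian_solve(t(cost))  # assign each gt a prediction
  data.frame(pred = gt_of_pred, gt = seq_len(nrow(gt)))
}

# --- loss -------------------------------------------------------------------

# GIoU of matched (M, 4) cxcywh tensors as a differentiable scalar sum(1-giou).
giou_loss_t <- function(pred, gtc) {
  g <- function(i) t_cols(pred, i, i)
  x1 <- t_sub(g(1), t_scale(g(3), 0.5)); x2 <- t_add(g(1), t_scale(g(3), 0.5))
  y1 <- t_sub(g(2), t_scale(g(4), 0.5)); y2 <- t_add(g(2), t_scale(g(4), 0.5))
  bx1 <- matrix(gtc[, 1] - gtc[, 3] / 2, ncol = 1L)
  bx2 <- matrix(gtc[, 1] + gtc[, 3] / 2, ncol = 1L)
  by1 <- matrix(gtc[, 2] - gtc[, 4] / 2, ncol = 1L)
  by2 <- matrix(gtc[, 2] + gtc[, 4] / 2, ncol = 1L)
  iw <- t_clamp_min(t_sub(t_minimum(x2, tt(bx2)), t_maximum(x1, tt(bx1))), 0)
  ih <- t_clamp_min(t_sub(t_minimum(y2, tt(by2)), t_maximum(y1, tt(by1))), 0)
  inter <- t_mul(iw, ih)
  area_a <- t_mul(t_sub(x2, x1), t_sub(y2, y1))
  area_b <- (bx2 - bx1) * (by2 - by1)
  uni <- t_sub(t_add(area_a, area_b), inter)
  hw <- t_sub(t_maximum(x2, tt(bx2)), t_minimum(x1, tt(bx1)))
  hh <- t_sub(t_maximum(y2, tt(by2)), t_minimum(y1, tt(by1)))
  hull <- t_mul(hw, hh)
  gv <- t_sub(t_div(inter, uni), t_div(t_sub(hull, uni), hull))
  t_sum(t_sub(tt(matrix(1, nrow(gtc), 1L)), gv))
}

# Classification + box loss for one prediction set against (possibly empty)
# ground truth with a given assignment (gt index per query row; 0 = bg).
# Positive classification targets are IoU-weighted (varifocal-style), so the
# score ranking tracks localization quality.
detr_set_loss <- function(logits, boxes, gt_boxes, gt_classes, assign,
                          nc, w_cls = 1, w_l1 = 5, w_giou = 2,
                          box_on = NULL) {
  nq <- nrow(val(logits))
  target <- matrix(0, nq, nc)
  matched <- which(assign > 0L)
  if (is.null(box_on)) box_on <- matched
  if (length(matched)) {
    pb <- cxcywh_to_xyxy(val(boxes)[matched, , drop = FALSE])
    gb <- cxcywh_to_xyxy(gt_boxes[assign[matched], , drop = FALSE])
    for (k in seq_along(matched)) {
      q <- matched[k]
      iou <- box_iou(pb[k, ], gb[k, ])
      target[q, gt_classes[assign[q]] + 1L] <- max(iou, 0.05)
    }
  }
  ngt <- max(1L, nrow(gt_boxes))
  loss <- t_scale(t_bce_logits(logits, target), w_cls / ngt)
  box_q <- intersect(matched, box_on)
  if (length(box_q) > 0L) {
    pb <- t_rows_gather(boxes, box_q)
    gb <- gt_boxes[assign[box_q], , drop = FALSE]
    l1 <- t_sum(t_abs(t_sub(pb, tt(gb))))
    gl <- giou_loss_t(pb, gb)
    loss <- t_add(loss, t_add(t_scale(l1, w_l1 / ngt),
                              t_scale(gl, w_giou / ngt)))
  }
  loss
}

# Hungarian assignment for one layer's raw outputs (values only, no grad).
match_layer <- function(logits_v, boxes_v, gt_boxes, gt_classes) {
  ngt <- nrow(gt_boxes)
  nq <- nrow(logits_v)
  if (ngt == 0L) return(integer(nq))
  prob <- 1 / (1 + exp(-logits_v))
  cost_cls <- -prob[, gt_classes + 1L, drop = FALSE]
  cost_l1 <- matrix(0, nq, ngt)
  for (j in seq_len(ngt))
    cost_l1[, j] <- rowSums(abs(sweep(boxes_v, 2L, gt_boxes[j, ])))
  cost_giou <- -giou_matrix(cxcywh_to_xyxy(boxes_v), cxcywh_to_xyxy(gt_boxes))
  cost <- 2 * cost_cls + 5 * cost_l1 + 2 * cost_giou
  gt_of_pred <- hungarian_solve(t(cost))
  assign <- integer(nq)
  for (j in seq_len(ngt)) if (gt_of_pred[j] > 0L) assign[gt_of_pred[j]] <- j
  assign
}

# Total training loss for one image: per-decoder-layer Hungarian losses,
# encoder auxiliary loss on the selected queries, and the denoising loss with
# its known assignment.
image_loss <- function(model, img, gt_boxes, gt_classes, dn = NULL) {
  fw <- model_forward(model, img, dn)
  nc <- model$cfg$num_classes
  ndn <- fw$ndn
  total <- NULL
  for (li in seq_along(fw$layers)) {
    lay <- fw$layers[[li]]
    nq_all <- nrow(val(lay$logits))
    match_rows <- (ndn + 1L):nq_all
    logits_m <- t_rows_gather(lay$logits, match_rows)
    boxes_m <- t_rows_gather(lay$boxes, match_rows)
    assign <- match_layer(val(logits_m), val(boxes_m), gt_boxes, gt_classes)
    part <- detr_set_loss(logits_m, boxes_m, gt_boxes, gt_classes, assign, nc)
    total <- if (is.null(total)) part else t_add(total, part)
    if (ndn > 0L) {
      logits_d <- t_rows_gather(lay$logits, seq_len(ndn))
      boxes_d <- t_rows_gather(lay$boxes, seq_len(ndn))
      dn_assign <- ifelse(dn$positive, dn$gt_index, 0L)
      dpart <- detr_set_loss(logits_d, boxes_d, gt_boxes, gt_classes,
                             dn_assign, nc)
      total <- t_add(total, dpart)
    }
  }
  sel <- fw$enc$sel
  enc_logits <- t_rows_gather(fw$enc$logits, sel)
  enc_boxes <- t_rows_gather(fw$enc$boxes, sel)
  assign <- match_layer(val(enc_logits), val(enc_boxes), gt_boxes, gt_classes)
  total <- t_add(total, detr_set_loss(enc_logits, enc_boxes, gt_boxes,
                                      gt_classes, assign, nc))
  total
}

# --- training ---------------------------------------------------------------

record_targets <- function(rec, size) {
  if (nrow(rec$boxes) == 0L)
    return(list(boxes = matrix(0, 0L, 4L), classes = integer(0)))
  b <- as.matrix(rec$boxes[, c("x1", "y1", "x2", "y2")])
  list(boxes = xyxy_to_cxcywh(b) / size,
       classes = as.integer(rec$boxes$class_id))
}

#' Train a detector
#'
#' Desk-scale AdamW training loop: batches are accumulated per image, the
#' loss is the standard DETR combination (classification + L1 + GIoU box
#' terms, with auxiliary per-layer and denoising-query losses), and per-step
#' metrics are logged as JSON lines. A non-finite loss aborts, returning the
#' last finite-state model.
#'
#' @param model a [build_model()] detector.
#' @param manifest a dataset manifest from [split_dataset()], or a plain list
#'   of sample records; records whose `split` is `"train"` are used (all
#'   records when no split tags are present).
#' @param hyper named list overriding `lr` (1e-4), `batch_size` (4),
#'   `iterations` (one pass), `weight_decay` (1e-4), `grad_clip` (0.1),
#'   `warmup` (10 linear warmup steps), `schedule` ("cosine" or "constant"),
#'   `lr_floor` (cosine floor as a fraction of `lr`), `seed` (0).
#' @param log_file optional path for the JSON-lines training log.
#' @return the trained model (invisibly modified in place), with attributes
#'   `log` (data.frame of per-iteration losses).
#' @export
train <- function(model, manifest, hyper = list(), log_file = NULL) {
  h <- utils::modifyList(list(lr = 1e-4, batch_size = 4L, iterations = NULL,
                              weight_decay = 1e-4, grad_clip = 0.1,
                              warmup = 10L, schedule = "cosine",
                              lr_floor = 0.05, seed = 0L), hyper)
  recs <- if (!is.null(manifest$records)) manifest$records else manifest
  splits <- vapply(recs, function(r) r$split %||% "train", "")
  splits[is.na(splits)] <- "train"
  recs <- recs[splits == "train"]
  if (length(recs) == 0L) stop("no training records in manifest")
  set.seed(h$seed)
  size <- model$cfg$input_size
  params <- collect_params(model)
  state <- adamw_state(params)
  iters <- h$iterations %||% ceiling(length(recs) / h$batch_size)
  log <- data.frame(iteration = integer(0), loss = numeric(0))
  con <- if (!is.null(log_file)) file(log_file, open = "wt") else NULL
  on.exit(if (!is.null(con)) close(con))
  order_idx <- sample(rep_len(seq_along(recs),
                              max(length(recs), iters * h$batch_size)))
  pos <- 1L
  for (it in seq_len(iters)) {
    zero_grads(params)
    batch_loss <- 0
    for (bi in seq_len(h$batch_size)) {
      if (pos > length(order_idx)) { order_idx <- sample(order_idx); pos <- 1L }
      rec <- recs[[order_idx[pos]]]; pos <- pos + 1L
      img <- rec$image / 255
      tg <- record_targets(rec, size)
      dn <- make_dn_queries(model$decoder, tg$boxes, tg$classes)
      loss <- image_loss(model, img, tg$boxes, tg$classes, dn)
      batch_loss <- batch_loss + val(loss)
      backward(loss, grad = 1 / h$batch_size)
    }
    if (!is.finite(batch_loss)) {
      warning("non-finite loss at iteration ", it, "; aborting with ",
              "last finite state")
      break
    }
    # global-norm gradient clipping
    gn <- sqrt(sum(vapply(params, function(p)
      if (is.null(p$grad)) 0 else sum(p$grad^2), 0)))
    if (h$grad_clip > 0 && gn > h$grad_clip)
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * h$grad_clip / gn
    lr_t <- h$lr
    if (h$warmup > 0L && it <= h$warmup) lr_t <- h$lr * it / h$warmup
    else if (identical(h$schedule, "cosine"))
      lr_t <- h$lr * (h$lr_floor + (1 - h$lr_floor) * 0.5 *
                        (1 + cos(pi * (it - h$warmup) /
                                   max(1L, iters - h$warmup))))
    state <- adamw_step(params, state, it, lr = lr_t,
                        weight_decay = h$weight_decay)
    mean_loss <- batch_loss / h$batch_size
    log <- rbind(log, data.frame(iteration = it, loss = mean_loss))
    if (!is.null(con))
      writeLines(jsonlite::toJSON(list(iteration = it, loss = mean_loss),
                                  auto_unbox = TRUE), con)
  }
  attr(model, "log") <- log
  invisible(model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- prediction -------------------------------------------------------------

# Letterbox an (H, W, 3) image to size x size; returns image + mapping info.
letterbox <- function(img, size) {
  d <- dim(img)
  s <- min(size / d[1], size / d[2])
  nh <- round(d[1] * s); nw <- round(d[2] * s)
  Lh <- interp_matrix(nh, d[1]); Lw <- interp_matrix(nw, d[2])
  resized <- apply_hw(img, Lh, Lw)
  out <- array(0.5, c(size, size, d[3]))
  oy <- (size - nh) %/% 2L; ox <- (size - nw) %/% 2L
  out[(oy + 1L):(oy + nh), (ox + 1L):(ox + nw), ] <- resized
  list(image = out, scale = s, ox = ox, oy = oy, h = d[1], w = d[2])
}

#' Run inference
#'
#' Forward pass and score thresholding; boxes are clipped to the image and no
#' non-maximum suppression is applied (the decoder is end-to-end). Images not
#' matching the configured input size are letterboxed.
#'
#' @param model a (possibly trained) detector.
#' @param images one (H, W, 3) array in `[0, 1]` (or 0-255), or a list of
#'   them.
#' @param score_threshold minimum class probability to keep a box.
#' @return a list of data.frames with columns x1, y1, x2, y2, score,
#'   class_id, image_id.
#' @export
predict_boxes <- function(model, images, score_threshold = 0.5) {
  if (!is.list(images)) images <- list(images)
  size <- model$cfg$input_size
  out <- vector("list", length(images))
  for (k in seq_along(images)) {
    img <- images[[k]]
    if (max(img) > 1.5) img <- img / 255
    lb <- NULL
    if (!all(dim(img)[1:2] == size)) {
      lb <- letterbox(img, size)
      img <- lb$image
      message("input ", k, " letterboxed to ", size, "x", size)
    }
    fw <- model_forward(model, img)
    last <- fw$layers[[length(fw$layers)]]
    prob <- 1 / (1 + exp(-val(last$logits)))
    cls <- max.col(prob, ties.method = "first")
    score <- prob[cbind(seq_len(nrow(prob)), cls)]
    boxes <- cxcywh_to_xyxy(val(last$boxes)) * size
    keep <- which(score >= score_threshold)
    if (!is.null(lb) && length(keep)) {
      boxes[, c(1, 3)] <- (boxes[, c(1, 3)] - lb$ox) / lb$scale
      boxes[, c(2, 4)] <- (boxes[, c(2, 4)] - lb$oy) / lb$scale
      wlim <- lb$w; hlim <- lb$h
    } else { wlim <- size; hlim <- size }
    boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), wlim)
    boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), hlim)
    out[[k]] <- data.frame(x1 = boxes[keep, 1], y1 = boxes[keep, 2],
                           x2 = boxes[keep, 3], y2 = boxes[keep, 4],
                           score = score[keep], class_id = cls[keep] - 1L,
                           image_id = rep(k, length(keep)))
  }
  out
}

# --- checkpointing ----------------------------------------------------------

# Named flat list of parameter arrays, keys like
# "backbone.stages.2.1.conv1.w". Used by save_weights()/load_weights().
named_params <- function(module, prefix = character(0)) {
  out <- list()
  rec <- function(x, path) {
    if (inherits(x, "wt")) {
      if (x$param) out[[paste(path, collapse = ".")]] <<- x$v
    } else if (is.list(x) && !inherits(x, "model_config")) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        rec(x[[i]], c(path, nm))
      }
    }
  }
  rec(module, prefix)
  out
}

#' Save / load detector weights
#'
#' Weights are serialized as a named list of arrays with dotted keys
#' (`backbone.stages.2.1.conv1.w`, `encoder.aifi...`, `decoder.layers...`).
#'
#' @param model a detector.
#' @param path file path.
#' @export
save_weights <- function(model, path) {
  saveRDS(named_params(model), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, path) {
  w <- readRDS(path)
  rec <- function(x, path_) {
    if (inherits(x, "wt")) {
      key <- paste(path_, collapse = ".")
      if (x$param) {
        if (is.null(w[[key]])) stop("checkpoint missing key ", key)
        stopifnot(length(w[[key]]) == length(x$v))
        x$v <- array(w[[key]], dim = dims_of(x$v))
      }
    } else if (is.list(x) && !inherits(x, "model_config")) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        rec(x[[i]], c(path_, nm))
      }
    }
  }
  rec(model, character(0))
  invisible(model)
}
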