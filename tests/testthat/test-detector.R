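# Detector assembly: GIoU, Hungarian matching, forward contracts,
# determinism, gradient flow and checkpointing.

test_that("GIoU evaluates hand-computed box pairs", {
  expect_equal(giou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1.0)
  # touching boxes: IoU 0, hull 200 = union 200
  expect_equal(giou(c(0, 0, 10, 10), c(10, 0, 20, 10)), 0.0)
  # far apart in a 100x100 hull: 0 - (10000 - 200) / 10000
  expect_equal(giou(c(0, 0, 10, 10), c(90, 90, 100, 100)), -0.98)
  # symmetry
  a <- c(3, 4, 20, 18); b <- c(10, 2, 30, 25)
  expect_equal(giou(a, b), giou(b, a))
  expect_gt(giou(a, b), -1); expect_lte(giou(a, b), 1)
  expect_error(giou(c(5, 0, 5, 10), b), "degenerate")
})

brute_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  k <- min(nr, nc)
  best <- Inf; best_assign <- NULL
  rowsets <- utils::combn(nr, k, simplify = FALSE)
  for (rows in rowsets) {
    for (perm in combinat_perms(nc, k)) {
      tot <- sum(cost[cbind(rows, perm)])
      if (tot < best) { best <- tot; best_assign <- cbind(rows, perm) }
    }
  }
  list(cost = best, assign = best_assign)
}

combinat_perms <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(chosen) {
    if (length(chosen) == k) { out[[length(out) + 1]] <<- chosen; return() }
    for (i in setdiff(seq_len(n), chosen)) rec(c(chosen, i))
  }
  rec(integer(0))
  out
}

test_that("Hungarian solver matches brute force on the worked and random cases", {
  ns <- asNamespace("wmcdetr")
  # 3 predictions, 2 ground truths, hand-built cost
  cost <- matrix(c(1, 9, 5, 9, 1, 5), 3, 2)
  gt_of_pred <- ns$hungarian_solve(t(cost))  # rows = gt
  expect_equal(gt_of_pred, c(1L, 2L))        # gt1 -> pred1, gt2 -> pred2
  expect_equal(cost[1, 1] + cost[2, 2], 2)
  set.seed(10)
  for (i in 1:25) {
    nr <- sample(1:5, 1); nc <- sample(1:5, 1)
    cost <- matrix(round(runif(nr * nc), 3), nr, nc)
    sol <- ns$hungarian_solve(cost)
    total <- sum(cost[cbind(which(sol > 0), sol[sol > 0])])
    expect_equal(total, brute_assignment(cost)$cost, tolerance = 1e-9)
  }
})

test_that("hungarian_match pairs identical boxes and handles empty ground truth", {
  pred <- list(boxes = rbind(c(0, 0, 10, 10), c(50, 50, 80, 90)),
               scores = rbind(c(0.9, 0.1), c(0.2, 0.8)))
  gt <- data.frame(x1 = c(0, 50), y1 = c(0, 50), x2 = c(10, 80),
                   y2 = c(10, 90), class_id = c(0L, 1L))
  m <- hungarian_match(pred, gt, image_size = 100)
  expect_equal(m$pred[order(m$gt)], c(1L, 2L))
  m0 <- hungarian_match(pred, gt[0, ], image_size = 100)
  expect_equal(nrow(m0), 0)
})

small_cfg <- function(variant)
  model_config(variant = variant, input_size = 64L, queries = 40L,
               denoising = 16L)

test_that("forward pass yields scored proposals, clipped and deterministic", {
  set.seed(1)
  m <- build_model(small_cfg("baseline"), seed = 2)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  det_all <- predict_boxes(m, img, score_threshold = 0)[[1]]
  expect_equal(nrow(det_all), 40)           # one proposal per query
  expect_true(all(det_all$score >= 0 & det_all$score <= 1))
  expect_true(all(det_all$x1 >= 0 & det_all$x2 <= 64 &
                    det_all$y1 >= 0 & det_all$y2 <= 64))
  det_none <- predict_boxes(m, img, score_threshold = 1)[[1]]
  expect_equal(nrow(det_none), 0)
  # bit-identical forwards under fixed weights
  again <- predict_boxes(m, img, score_threshold = 0)[[1]]
  expect_identical(det_all, again)
  # non-square inputs are letterboxed (and reported)
  expect_message(out <- predict_boxes(m, array(runif(50 * 64 * 3),
                                               c(50, 64, 3)),
                                      score_threshold = 0),
                 "letterbox")
  expect_true(all(out[[1]]$y2 <= 50 + 1e-9))
})

test_that("every architectural component receives gradient", {
  set.seed(3)
  ns <- asNamespace("wmcdetr")
  m <- build_model(small_cfg("full"), seed = 3)
  rec <- generate_base_images(1, size = 64, seed = 4)[[1]]
  tg <- ns$record_targets(rec, 64)
  dn <- ns$make_dn_queries(m$decoder, tg$boxes, tg$classes)
  loss <- ns$image_loss(m, rec$image / 255, tg$boxes, tg$classes, dn)
  ns$backward(loss)
  has_grad <- function(module) {
    ps <- ns$collect_params(module)
    any(vapply(ps, function(p) !is.null(p$grad) && any(p$grad != 0), TRUE))
  }
  expect_true(has_grad(m$backbone$stem))
  for (s in 1:4) expect_true(has_grad(m$backbone$stages[[s]]))
  expect_true(has_grad(m$encoder$aifi))
  expect_true(has_grad(m$encoder$neck$pce))
  expect_true(has_grad(m$encoder$neck$mff3))
  expect_true(has_grad(m$encoder$neck$rcm5))
  for (l in m$decoder$layers) {
    expect_true(has_grad(l$self_attn))
    expect_true(has_grad(l$cross))
  }
  expect_true(has_grad(m$decoder$enc_bbox))
  expect_true(has_grad(m$decoder$bbox_heads))
})

test_that("a few optimizer steps run, log, and move the weights", {
  set.seed(4)
  ns <- asNamespace("wmcdetr")
  recs <- generate_base_images(2, size = 64, seed = 5)
  m <- build_model(small_cfg("full"), seed = 5)
  before <- ns$named_params(m)
  log_file <- withr::local_tempfile(fileext = ".jsonl")
  m <- train(m, recs, hyper = list(iterations = 2L, batch_size = 1L,
                                   lr = 1e-3, seed = 1), log_file = log_file)
  lg <- attr(m, "log")
  expect_equal(nrow(lg), 2)
  expect_true(all(is.finite(lg$loss)))
  after <- ns$named_params(m)
  moved <- vapply(names(before), function(k)
    max(abs(before[[k]] - after[[k]])), 0)
  expect_gt(mean(moved > 0), 0.95)   # nearly all tensors updated
  # JSON-lines log parses
  lines <- readLines(log_file)
  expect_length(lines, 2)
  rec1 <- jsonlite::fromJSON(lines[1])
  expect_equal(rec1$iteration, 1)
})

test_that("checkpoints round-trip through save/load with dotted keys", {
  set.seed(5)
  m <- build_model(small_cfg("full"), seed = 6)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  ref <- predict_boxes(m, img, score_threshold = 0)[[1]]
  path <- withr::local_tempfile(fileext = ".rds")
  save_weights(m, path)
  keys <- names(readRDS(path))
  expect_true(any(grepl("^backbone\\.stages\\.", keys)))
  expect_true(any(grepl("^decoder\\.layers\\.", keys)))
  m2 <- build_model(small_cfg("full"), seed = 999)   # different init
  m2 <- load_weights(m2, path)
  expect_identical(predict_boxes(m2, img, score_threshold = 0)[[1]], ref)
})

test_that("deterministic training trajectory under a fixed seed", {
  recs <- generate_base_images(1, size = 64, seed = 6)
  run <- function() {
    m <- build_model(small_cfg("baseline"), seed = 7)
    m <- train(m, recs, hyper = list(iterations = 2L, batch_size = 1L,
                                     seed = 3))
    attr(m, "log")$loss
  }
  expect_identical(run(), run())
})
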