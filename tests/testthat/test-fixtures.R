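# Synthetic fixture generator, augmentation expansion, split and annotation
# round trips.

boxes_in_bounds <- function(rec) {
  d <- dim(rec$image)
  b <- rec$boxes
  all(b$x1 >= 0 & b$x1 < b$x2 & b$x2 <= d[2] &
        b$y1 >= 0 & b$y1 < b$y2 & b$y2 <= d[1])
}

test_that("generated base images honour the object contract", {
  recs <- generate_base_images(20, size = 128, seed = 7)
  expect_length(recs, 20)
  for (rec in recs) {
    expect_equal(dim(rec$image), c(128L, 128L, 3L))
    expect_true(is.integer(rec$image))
    expect_true(all(rec$image >= 0L & rec$image <= 255L))
    expect_gte(nrow(rec$boxes), 1)
    expect_lte(nrow(rec$boxes), 12)
    expect_true(boxes_in_bounds(rec))
    # blight lesions are large, bugs small
    b <- rec$boxes
    area <- (b$x2 - b$x1) * (b$y2 - b$y1) / 128^2
    expect_true(all(area[b$class_id == 0] > 0.01))
    expect_true(all(area[b$class_id == 1] < 0.04))
  }
  # a reasonable share of multi-object images contains an overlapping pair
  multi <- Filter(function(r) nrow(r$boxes) >= 2, recs)
  has_overlap <- vapply(multi, function(r) {
    b <- as.matrix(r$boxes[, 1:4])
    n <- nrow(b)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (box_iou(b[i, ], b[j, ]) > 0) return(TRUE)
    FALSE
  }, TRUE)
  expect_gte(mean(has_overlap), 0.2)
})

test_that("class mix and seeds behave as documented", {
  one <- generate_base_images(1, size = 64, seed = 5, class_mix = 1.0)
  expect_true(all(one[[1]]$boxes$class_id == 0L))
  zero <- generate_base_images(1, size = 64, seed = 5, class_mix = 0.0)
  expect_true(all(zero[[1]]$boxes$class_id == 1L))
  a <- generate_base_images(5, size = 64, seed = 7)
  b <- generate_base_images(5, size = 64, seed = 7)
  expect_identical(a, b)                     # byte-identical under one seed
  c <- generate_base_images(5, size = 64, seed = 8)
  expect_false(identical(a, c))
  expect_error(generate_base_images(0), "n must")
  expect_error(generate_base_images(1, size = 32), "size must")
})

test_that("augmentation expands by the factor with exact box transforms", {
  recs <- generate_base_images(3, size = 64, seed = 7)
  aug <- augment_expand(recs, factor = 8, seed = 7)
  expect_length(aug, 24)
  expect_equal(vapply(aug[1:8], function(r) r$provenance, ""),
               c("original", "fliplr", "flipud", "rot90", "rot180", "rot270",
                 "gauss", "fliplr+gauss"))
  expect_error(augment_expand(recs, factor = 9), "exhausted")
  # mirror formula on a known box
  rec <- recs[[1]]
  rec$boxes <- data.frame(x1 = 10, y1 = 20, x2 = 50, y2 = 60, class_id = 0L)
  rec$image <- array(0L, c(640, 640, 3))
  out <- augment_expand(list(rec), factor = 8, seed = 1)
  fl <- out[[2]]$boxes
  expect_equal(as.numeric(fl[1, 1:4]), c(590, 20, 630, 60))
  r90 <- out[[4]]$boxes
  expect_equal(as.numeric(r90[1, 1:4]), c(20, 590, 60, 630))
  # noise-only variants keep boxes exactly
  expect_identical(out[[7]]$boxes, rec$boxes)
  expect_identical(out[[8]]$boxes, fl)
})

test_that("flip and rotation groups act as involutions / 4-cycles on pixels and boxes", {
  ns <- asNamespace("wmcdetr")
  rec <- generate_base_images(1, size = 64, seed = 3)[[1]]
  flip2 <- ns$apply_geom(ns$new_record(ns$apply_geom(rec, "fliplr")$image,
                                       ns$apply_geom(rec, "fliplr")$boxes, 1),
                         "fliplr")
  expect_identical(flip2$image, rec$image)
  expect_equal(flip2$boxes, rec$boxes)
  cur <- rec
  for (i in 1:4) {
    g <- ns$apply_geom(cur, "rot90")
    cur <- ns$new_record(g$image, g$boxes, 1)
  }
  expect_identical(cur$image, rec$image)
  expect_equal(cur$boxes, rec$boxes)
})

test_that("transforming boxes matches transforming a rendered mask", {
  ns <- asNamespace("wmcdetr")
  render <- function(boxes, h, w) {
    m <- matrix(0L, h, w)
    for (i in seq_len(nrow(boxes))) {
      b <- boxes[i, ]
      m[(floor(b$y1) + 1):ceiling(b$y2), (floor(b$x1) + 1):ceiling(b$x2)] <- 1L
    }
    m
  }
  rec <- generate_base_images(1, size = 64, seed = 9)[[1]]
  for (op in c("fliplr", "flipud", "rot90", "rot180", "rot270")) {
    g <- ns$apply_geom(rec, op)
    mask_then <- render(g$boxes, dim(g$image)[1], dim(g$image)[2])
    m0 <- rec
    m0$image <- array(rep(render(rec$boxes, 64, 64), 3), c(64, 64, 3))
    m0$image <- array(as.integer(m0$image), dim(m0$image))
    then_mask <- ns$apply_geom(m0, op)$image[, , 1]
    expect_identical(mask_then, matrix(as.integer(then_mask), nrow(then_mask)))
  }
})

test_that("the grouped split reproduces the study counts without leakage", {
  recs <- generate_base_images(20, size = 64, seed = 7)
  aug <- augment_expand(recs, factor = 8, seed = 7)
  man <- split_dataset(aug, seed = 7)
  expect_equal(unname(man$counts), c(112, 32, 16))  # 20 sources * 8, 7:2:1
  bysrc <- split(vapply(man$records, function(r) r$split, ""),
                 vapply(man$records, function(r) r$source_id, 0))
  for (s in bysrc) expect_length(unique(s), 1)      # leakage guard
  man2 <- split_dataset(aug, seed = 7)
  expect_identical(lapply(man$records, `[[`, "split"),
                   lapply(man2$records, `[[`, "split"))
  expect_error(split_dataset(aug, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("YOLO lines are normalized with 6 decimals and round trips are exact", {
  rec <- list(image = array(127L, c(640, 640, 3)),
              boxes = data.frame(x1 = 0, y1 = 0, x2 = 320, y2 = 320,
                                 class_id = 0L),
              source_id = 1L, provenance = "original", split = "train")
  tmp <- withr::local_tempdir()
  write_annotations(list(records = list(rec)), "yolo-txt", tmp)
  lab <- list.files(file.path(tmp, "train", "labels"), full.names = TRUE)
  expect_equal(readLines(lab), "0 0.250000 0.250000 0.500000 0.500000")

  recs <- generate_base_images(4, size = 64, seed = 7)
  aug <- augment_expand(recs, factor = 2, seed = 7)
  man <- split_dataset(aug, seed = 7)
  for (fmt in c("yolo-txt", "coco-json")) {
    dir <- withr::local_tempdir()
    write_annotations(man, fmt, dir)
    back <- read_annotations(dir, fmt)
    expect_equal(length(back$records), length(man$records))
    expect_identical(back$class_names, man$class_names)
    expect_equal(unname(back$counts), unname(man$counts))
    for (i in seq_along(man$records)) {
      a <- man$records[[i]]; b <- back$records[[i]]
      expect_identical(b$image, a$image)
      expect_identical(b$split, a$split)
      expect_identical(b$provenance, a$provenance)
      expect_equal(as.matrix(b$boxes), as.matrix(a$boxes), tolerance = 1e-4)
    }
  }
  expect_error(write_annotations(man, "voc-xml", withr::local_tempdir()))
  bad <- withr::local_tempdir()
  dir.create(file.path(bad, "train", "images"), recursive = TRUE)
  dir.create(file.path(bad, "train", "labels"), recursive = TRUE)
  png::writePNG(array(0.5, c(8, 8, 3)),
                file.path(bad, "train", "images", "img_00001_src0001_x.png"))
  writeLines("0 nonsense", file.path(bad, "train", "labels",
                                     "img_00001_src0001_x.txt"))
  expect_error(read_annotations(bad, "yolo-txt"), "line 1")
})
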