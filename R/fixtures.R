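# Synthetic annotated imagery emulating the study's two classes - "tea leaf
# blight" (irregular brown lesions on green leaf texture) and "green mirid
# bug" (small elongated dark blobs) - plus the augmentation expansion
# (flips, right-angle rotations, Gaussian noise), the grouped train/val/test
# split, and YOLO-txt / COCO-JSON annotation I/O.

CLASS_NAMES <- c("tea leaf blight", "green mirid bug")

new_record <- function(image, boxes, source_id, provenance = "original",
                       split = NA_character_) {
  list(image = image, boxes = boxes, source_id = source_id,
       provenance = provenance, split = split)
}

empty_boxes <- function() {
  data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
             y2 = numeric(0), class_id = integer(0))
}

# Irregular radial blob mask in a local window; returns the window's pixel
# mask and its bounding box in image coordinates (0-based, half-open).
render_blob <- function(size, cx, cy, rx, ry, angle, wobble = 0.25,
                        nharm = 4L) {
  r0 <- max(rx, ry)
  x0 <- max(0L, floor(cx - 1.6 * r0)); x1 <- min(size, ceiling(cx + 1.6 * r0))
  y0 <- max(0L, floor(cy - 1.6 * r0)); y1 <- min(size, ceiling(cy + 1.6 * r0))
  if (x1 <= x0 || y1 <= y0) return(NULL)
  xs <- (x0:(x1 - 1L)) + 0.5
  ys <- (y0:(y1 - 1L)) + 0.5
  X <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys - cy, length(ys), length(xs))
  Xr <- X * cos(angle) + Y * sin(angle)
  Yr <- -X * sin(angle) + Y * cos(angle)
  th <- atan2(Yr / ry, Xr / rx)
  rad <- sqrt((Xr / rx)^2 + (Yr / ry)^2)
  mod <- rep(1, length(th))
  amp <- stats::runif(nharm, 0, wobble / nharm)
  ph <- stats::runif(nharm, 0, 2 * pi)
  for (k in seq_len(nharm)) mod <- mod + amp[k] * cos(k * th + ph[k])
  mask <- rad <= matrix(mod, nrow(rad), ncol(rad))
  if (!any(mask)) return(NULL)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  list(mask = mask, x0 = x0, y0 = y0,
       box = c(x0 + cols[1] - 1, y0 + rows[1] - 1, x0 + cols[2], y0 + rows[2]))
}

paint_blob <- function(img, blob, rgb, jitter = 10) {
  m <- blob$mask
  nr <- nrow(m); ncl <- ncol(m)
  ridx <- (blob$y0 + 1L):(blob$y0 + nr)
  cidx <- (blob$x0 + 1L):(blob$x0 + ncl)
  for (ch in 1:3) {
    patch <- img[ridx, cidx, ch]
    val <- rgb[ch] + matrix(stats::rnorm(nr * ncl, 0, jitter), nr, ncl)
    patch[m] <- pmin(pmax(val[m], 0), 255)
    img[ridx, cidx, ch] <- patch
  }
  img
}

leaf_background <- function(size) {
  base <- c(72, 118, 58)
  img <- array(0, c(size, size, 3L))
  # low-frequency illumination + vein-like texture + pixel noise
  gx <- matrix(seq(0, 2 * pi, length.out = size), size, size, byrow = TRUE)
  gy <- matrix(seq(0, 2 * pi, length.out = size), size, size)
  shade <- 12 * sin(gx * stats::runif(1, 0.5, 1.5) + stats::runif(1, 0, 6)) +
    9 * cos(gy * stats::runif(1, 0.5, 1.5) + stats::runif(1, 0, 6))
  for (ch in 1:3) {
    img[, , ch] <- base[ch] + shade +
      matrix(stats::rnorm(size * size, 0, 6), size, size)
  }
  pmin(pmax(img, 0), 255)
}

sample_object <- function(size, class_id) {
  if (class_id == 0L) {
    # blight lesion: >= 2% of image area, roughly round
    area <- stats::runif(1, 0.02, 0.06) * size^2
    aspect <- stats::runif(1, 0.7, 1.4)
    rx <- sqrt(area * aspect / pi); ry <- area / (pi * rx)
    list(rx = rx, ry = ry, wobble = 0.35,
         rgb = c(stats::runif(1, 95, 125), stats::runif(1, 60, 80),
                 stats::runif(1, 25, 45)))
  } else {
    # mirid bug: <= 1% of image area, elongated and dark
    area <- stats::runif(1, 0.002, 0.008) * size^2
    aspect <- stats::runif(1, 2.5, 4.5)
    rx <- sqrt(area * aspect / pi); ry <- area / (pi * rx)
    list(rx = rx, ry = ry, wobble = 0.18,
         rgb = c(stats::runif(1, 25, 50), stats::runif(1, 35, 60),
                 stats::runif(1, 20, 40)))
  }
}

#' Generate synthetic annotated base images
#'
#' Each image carries 1-12 objects of the two classes on a textured green
#' background; blight lesions are irregular brown blobs of at least 2% image
#' area, bugs are small elongated dark blobs. A fixed fraction of
#' multi-object images contains at least one overlapping pair, emulating
#' occlusion. Output is byte-identical for a given seed.
#'
#' @param n number of images (>= 1).
#' @param size square image size in pixels (>= 64).
#' @param seed integer seed.
#' @param class_mix probability that an object is class 0 (tea leaf blight).
#' @return list of sample records: `image` (H, W, 3 integer array, 0-255),
#'   `boxes` (data.frame x1, y1, x2, y2, class_id; 0-based half-open pixel
#'   coordinates), `source_id`, `provenance`, `split`.
#' @export
generate_base_images <- function(n, size = 640L, seed = 7L, class_mix = 0.5) {
  if (n < 1L) stop("n must be >= 1")
  if (size < 64L) stop("size must be >= 64")
  set.seed(seed)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    img <- leaf_background(size)
    nobj <- sample.int(12L, 1L)
    force_overlap <- nobj >= 2L && stats::runif(1) < 0.35
    boxes <- empty_boxes()
    prev <- NULL
    for (o in seq_len(nobj)) {
      class_id <- if (stats::runif(1) < class_mix) 0L else 1L
      spec <- sample_object(size, class_id)
      if (force_overlap && o == 2L && !is.null(prev)) {
        cx <- (prev[1] + prev[3]) / 2 + stats::runif(1, -0.4, 0.4) *
          (prev[3] - prev[1])
        cy <- (prev[2] + prev[4]) / 2 + stats::runif(1, -0.4, 0.4) *
          (prev[4] - prev[2])
      } else {
        margin <- max(spec$rx, spec$ry)
        cx <- stats::runif(1, margin, size - margin)
        cy <- stats::runif(1, margin, size - margin)
      }
      blob <- render_blob(size, cx, cy, spec$rx, spec$ry,
                          stats::runif(1, 0, pi), spec$wobble)
      if (is.null(blob)) next
      img <- paint_blob(img, blob, spec$rgb)
      b <- pmin(pmax(blob$box, 0), size)
      if (b[3] - b[1] < 2 || b[4] - b[2] < 2) next
      boxes <- rbind(boxes, data.frame(x1 = b[1], y1 = b[2], x2 = b[3],
                                       y2 = b[4], class_id = class_id))
      if (o == 1L) prev <- b
    }
    records[[i]] <- new_record(array(as.integer(round(img)), dim(img)),
                               boxes, source_id = i)
  }
  records
}

# --- augmentation -----------------------------------------------------------

rot90ccw_img <- function(img) {
  d <- dim(img)
  out <- array(0L, c(d[2], d[1], d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- t(img[, d[2]:1, ch])
  out
}

transform_boxes <- function(boxes, op, w, h) {
  b <- boxes
  switch(op,
    fliplr = { b$x1 <- w - boxes$x2; b$x2 <- w - boxes$x1 },
    flipud = { b$y1 <- h - boxes$y2; b$y2 <- h - boxes$y1 },
    rot90  = { b$x1 <- boxes$y1; b$x2 <- boxes$y2
               b$y1 <- w - boxes$x2; b$y2 <- w - boxes$x1 },
    stop("unknown box transform ", op))
  b
}

apply_geom <- function(rec, op) {
  d <- dim(rec$image)
  h <- d[1]; w <- d[2]
  img <- rec$image
  boxes <- rec$boxes
  reps <- switch(op, fliplr = , flipud = , rot90 = 1L,
                 rot180 = 2L, rot270 = 3L)
  base <- switch(op, rot180 = "rot90", rot270 = "rot90", op)
  for (r in seq_len(reps)) {
    if (base == "fliplr") {
      img <- img[, w:1, , drop = FALSE]
    } else if (base == "flipud") {
      img <- img[h:1, , , drop = FALSE]
    } else {
      img <- rot90ccw_img(img)
    }
    boxes <- transform_boxes(boxes, base, w, h)
    d <- dim(img); h <- d[1]; w <- d[2]
  }
  list(image = img, boxes = boxes)
}

add_gauss <- function(img, sigma) {
  d <- dim(img)
  noisy <- img + array(stats::rnorm(prod(d), 0, sigma), d)
  array(as.integer(round(pmin(pmax(noisy, 0), 255))), d)
}

AUG_MENU <- c("original", "fliplr", "flipud", "rot90", "rot180", "rot270",
              "gauss", "fliplr+gauss")

#' Expand a record list by deterministic augmentation
#'
#' Each source record yields `factor` records: the original plus, in order,
#' horizontal flip, vertical flip, right-angle rotations (90/180/270
#' counter-clockwise), Gaussian noise, and flipped+noise. Geometric variants
#' transform the boxes exactly; noise-only variants keep them unchanged.
#'
#' @param records list of sample records.
#' @param factor expansion factor, 1-8 (default 8).
#' @param noise_sigma Gaussian noise standard deviation on the 0-255 scale.
#' @param seed integer seed (noise realizations).
#' @return list of `length(records) * factor` records with `provenance` set.
#' @export
augment_expand <- function(records, factor = 8L, noise_sigma = 10, seed = 7L) {
  if (factor < 1L) stop("factor must be >= 1")
  if (factor > length(AUG_MENU))
    stop("factor > ", length(AUG_MENU), ": the augmentation menu (",
         paste(AUG_MENU, collapse = ", "), ") is exhausted")
  set.seed(seed)
  out <- vector("list", length(records) * factor)
  k <- 0L
  for (rec in records) {
    for (v in AUG_MENU[seq_len(factor)]) {
      k <- k + 1L
      if (v == "original") {
        new <- rec
      } else if (v %in% c("fliplr", "flipud", "rot90", "rot180", "rot270")) {
        g <- apply_geom(rec, v)
        new <- new_record(g$image, g$boxes, rec$source_id, v, rec$split)
      } else if (v == "gauss") {
        new <- new_record(add_gauss(rec$image, noise_sigma), rec$boxes,
                          rec$source_id, v, rec$split)
      } else { # fliplr+gauss
        g <- apply_geom(rec, "fliplr")
        new <- new_record(add_gauss(g$image, noise_sigma), g$boxes,
                          rec$source_id, v, rec$split)
      }
      new$provenance <- v
      out[[k]] <- new
    }
  }
  out
}

#' Split records into train/val/test without source leakage
#'
#' Records are grouped by source image so that all augmented variants of one
#' source land in the same split; sources are shuffled and assigned by the
#' given ratios (rounded to whole sources).
#'
#' @param records list of sample records.
#' @param ratios length-3 numeric summing to 1 (train, val, test).
#' @param seed integer seed for the source shuffle.
#' @return a dataset manifest: list with `records`, `class_names`, `counts`.
#' @export
split_dataset <- function(records, ratios = c(train = 0.7, val = 0.2,
                                              test = 0.1), seed = 7L) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  set.seed(seed)
  src <- vapply(records, function(r) r$source_id, 0)
  sources <- sample(unique(src))
  ns <- length(sources)
  n_train <- round(ns * ratios[[1]])
  n_val <- round(ns * ratios[[2]])
  n_test <- ns - n_train - n_val
  assign <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  names(assign) <- as.character(sources)
  for (i in seq_along(records))
    records[[i]]$split <- assign[[as.character(src[i])]]
  splits <- vapply(records, function(r) r$split, "")
  manifest <- list(records = records, class_names = CLASS_NAMES,
                   counts = c(train = sum(splits == "train"),
                              val = sum(splits == "val"),
                              test = sum(splits == "test")))
  class(manifest) <- "dataset_manifest"
  manifest
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("<dataset_manifest ", length(x$records), " records; ",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), ">\n",
      sep = "")
  invisible(x)
}

# --- annotation I/O ---------------------------------------------------------

record_filename <- function(rec, i)
  sprintf("img_%05d_src%04d_%s", i, rec$source_id,
          gsub("[^a-z0-9]", "-", rec$provenance))

#' Write / read dataset annotations
#'
#' `"yolo-txt"` writes one normalized `class cx cy w h` text file per image
#' (6 decimals) beside PNG images, under one directory per split;
#' `"coco-json"` writes a single COCO-style JSON (absolute `[x, y, w, h]`
#' pixel boxes, 1-based category ids) plus the images. `read_annotations()`
#' inverts either layout; a round trip reproduces the manifest up to float
#' rounding of the coordinates.
#'
#' @param manifest a dataset manifest (or plain record list).
#' @param format `"yolo-txt"` or `"coco-json"`.
#' @param path output directory.
#' @return `write_annotations()`: the path, invisibly; `read_annotations()`:
#'   a dataset manifest.
#' @export
write_annotations <- function(manifest, format = c("yolo-txt", "coco-json"),
                              path) {
  format <- match.arg(format)
  recs <- if (!is.null(manifest$records)) manifest$records else manifest
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (format == "yolo-txt") {
    writeLines(CLASS_NAMES, file.path(path, "classes.txt"))
    for (i in seq_along(recs)) {
      rec <- recs[[i]]
      split <- if (is.na(rec$split)) "all" else rec$split
      idir <- file.path(path, split, "images")
      ldir <- file.path(path, split, "labels")
      dir.create(idir, recursive = TRUE, showWarnings = FALSE)
      dir.create(ldir, recursive = TRUE, showWarnings = FALSE)
      fn <- record_filename(rec, i)
      png::writePNG(rec$image / 255, file.path(idir, paste0(fn, ".png")))
      d <- dim(rec$image)
      b <- rec$boxes
      lines <- sprintf("%d %.6f %.6f %.6f %.6f", b$class_id,
                       (b$x1 + b$x2) / 2 / d[2], (b$y1 + b$y2) / 2 / d[1],
                       (b$x2 - b$x1) / d[2], (b$y2 - b$y1) / d[1])
      writeLines(lines, file.path(ldir, paste0(fn, ".txt")))
    }
  } else {
    idir <- file.path(path, "images")
    dir.create(idir, recursive = TRUE, showWarnings = FALSE)
    images <- list(); annotations <- list(); aid <- 0L
    for (i in seq_along(recs)) {
      rec <- recs[[i]]
      fn <- paste0(record_filename(rec, i), ".png")
      png::writePNG(rec$image / 255, file.path(idir, fn))
      d <- dim(rec$image)
      images[[i]] <- list(id = i, file_name = fn, width = d[2], height = d[1],
                          split = if (is.na(rec$split)) "all" else rec$split,
                          source_id = rec$source_id,
                          provenance = rec$provenance)
      b <- rec$boxes
      for (j in seq_len(nrow(b))) {
        aid <- aid + 1L
        annotations[[aid]] <- list(
          id = aid, image_id = i, category_id = b$class_id[j] + 1L,
          bbox = c(b$x1[j], b$y1[j], b$x2[j] - b$x1[j], b$y2[j] - b$y1[j]),
          area = (b$x2[j] - b$x1[j]) * (b$y2[j] - b$y1[j]), iscrowd = 0L)
      }
    }
    categories <- lapply(seq_along(CLASS_NAMES), function(k)
      list(id = k, name = CLASS_NAMES[k]))
    jsonlite::write_json(list(images = images, annotations = annotations,
                              categories = categories),
                         file.path(path, "annotations.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

parse_filename <- function(fn) {
  m <- regmatches(fn, regexec("^img_(\\d+)_src(\\d+)_(.+)$", fn))[[1]]
  if (length(m) != 4L) return(NULL)
  list(source_id = as.integer(m[3]),
       provenance = gsub("-", "+", m[4], fixed = TRUE))
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, format = c("yolo-txt", "coco-json")) {
  format <- match.arg(format)
  recs <- list()
  keys <- character(0)
  if (format == "yolo-txt") {
    class_file <- file.path(path, "classes.txt")
    class_names <- if (file.exists(class_file)) readLines(class_file)
                   else CLASS_NAMES
    splits <- setdiff(list.dirs(path, recursive = FALSE, full.names = FALSE),
                      character(0))
    for (split in splits) {
      idir <- file.path(path, split, "images")
      if (!dir.exists(idir)) next
      for (f in sort(list.files(idir, pattern = "\\.png$"))) {
        img <- png::readPNG(file.path(idir, f))
        img <- array(as.integer(round(img * 255)), dim(img))
        d <- dim(img)
        lf <- file.path(path, split, "labels",
                        sub("\\.png$", ".txt", f))
        boxes <- empty_boxes()
        if (file.exists(lf)) {
          for (li in seq_along(lines <- readLines(lf))) {
            if (!nzchar(lines[li])) next
            parts <- suppressWarnings(as.numeric(strsplit(lines[li],
                                                          "\\s+")[[1]]))
            if (length(parts) != 5L || any(is.na(parts)))
              stop("malformed YOLO annotation at ", lf, " line ", li)
            boxes <- rbind(boxes, data.frame(
              x1 = (parts[2] - parts[4] / 2) * d[2],
              y1 = (parts[3] - parts[5] / 2) * d[1],
              x2 = (parts[2] + parts[4] / 2) * d[2],
              y2 = (parts[3] + parts[5] / 2) * d[1],
              class_id = as.integer(parts[1])))
          }
        }
        info <- parse_filename(sub("\\.png$", "", f))
        recs[[length(recs) + 1L]] <- new_record(
          img, boxes,
          source_id = info$source_id %||% length(recs) + 1L,
          provenance = info$provenance %||% "original",
          split = if (split == "all") NA_character_ else split)
        keys <- c(keys, f)
      }
    }
    recs <- recs[order(keys)]   # restore the original write order
  } else {
    jf <- file.path(path, "annotations.json")
    if (!file.exists(jf)) stop("missing annotations.json under ", path)
    j <- jsonlite::read_json(jf)
    class_names <- vapply(j$categories, function(c) c$name, "")
    ann_by_img <- split(j$annotations,
                        vapply(j$annotations, function(a) a$image_id, 0))
    for (im in j$images) {
      img <- png::readPNG(file.path(path, "images", im$file_name))
      img <- array(as.integer(round(img * 255)), dim(img))
      boxes <- empty_boxes()
      for (a in ann_by_img[[as.character(im$id)]]) {
        bb <- unlist(a$bbox)
        if (length(bb) != 4L)
          stop("malformed COCO bbox for annotation id ", a$id)
        boxes <- rbind(boxes, data.frame(
          x1 = bb[1], y1 = bb[2], x2 = bb[1] + bb[3], y2 = bb[2] + bb[4],
          class_id = as.integer(a$category_id) - 1L))
      }
      recs[[length(recs) + 1L]] <- new_record(
        img, boxes, source_id = im$source_id %||% im$id,
        provenance = im$provenance %||% "original",
        split = if (identical(im$split, "all") || is.null(im$split))
          NA_character_ else im$split)
    }
  }
  splits <- vapply(recs, function(r)
    if (is.na(r$split)) "all" else r$split, "")
  manifest <- list(records = recs, class_names = class_names,
                   counts = c(train = sum(splits == "train"),
                              val = sum(splits == "val"),
                              test = sum(splits == "test")))
  class(manifest) <- "dataset_manifest"
  manifest
}
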