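BENIGN_SUBCLASSES <- c("adenosis", "fibroadenoma", "phyllodes_tumor",
                       "tubular_adenoma")
MALIGNANT_SUBCLASSES <- c("ductal_carcinoma", "lobular_carcinoma",
                          "mucinous_carcinoma", "papillary_carcinoma")

#' Read an image file as an H x W x 3 array in [0, 1]
#'
#' Grayscale images are replicated to three channels; an alpha channel is
#' dropped.
#'
#' @param path PNG/JPEG/TIFF file path.
#' @return numeric `H x W x 3` array.
#' @export
read_image <- function(path) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop_val("cannot decode image '", path,
                                               "': ", conditionMessage(e)))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(2L, 1L, 3L))            # EBImage stores (x, y, c)
}

write_image <- function(img, path) {
  png::writePNG(aperm(pmin(pmax(img, 0), 1), c(1L, 2L, 3L)), target = path)
  invisible(path)
}

resize_bilinear <- function(img, size) {
  d <- dim(img)
  if (d[1] == size && d[2] == size) return(img)
  e <- EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
  out <- EBImage::resize(e, w = size, h = size, filter = "bilinear")
  aperm(EBImage::imageData(out), c(2L, 1L, 3L))
}

#' Preprocess an image for model input
#'
#' Decodes (if given a path), promotes grayscale to RGB, resizes with
#' bilinear interpolation to `size x size`, and clamps values to `[0, 1]`
#' (the pixel convention of the trainable tiny backbone). Deterministic.
#'
#' @param input file path or `H x W x 3` array.
#' @param size square output side in pixels (default 224).
#' @return numeric `size x size x 3` array in `[0, 1]`.
#' @export
preprocess <- function(input, size = 224L) {
  img <- if (is.character(input)) read_image(input) else input
  if (length(dim(img)) == 2L)
    img <- array(rep(img, 3L), c(dim(img), 3L))
  pmin(pmax(resize_bilinear(img, size), 0), 1)
}

#' Scan a BreaKHis-style directory tree into a dataset manifest
#'
#' Expects `root/<class>/<subclass>/<magnification>X/image.(png|jpg)`;
#' magnification directories look like `40X`, `100X` etc. A slide id is
#' parsed from the BreaKHis filename convention
#' (`SOB_B_A-14-22549AB-40-001.png`) when present, otherwise the file stem
#' is used. Files whose magnification cannot be parsed are collected in
#' `attr(manifest, "problems")`, never silently dropped.
#'
#' @param root directory to scan.
#' @param magnification_filter optional magnification (e.g. `400`) to retain.
#' @param task `"fine_grained"` (label = subclass) or `"binary"`
#'   (label = class).
#' @return a `data.frame` manifest with columns `path`, `class`, `subclass`,
#'   `magnification`, `slide_id`, ordered lexicographically by path, with
#'   attributes `task` and `problems`.
#' @export
scan_layout <- function(root, magnification_filter = NULL,
                        task = c("fine_grained", "binary")) {
  task <- match.arg(task)
  if (!dir.exists(root)) stop_val("directory does not exist: ", root)
  files <- sort(list.files(root, pattern = "\\.(png|jpe?g|tiff?)$",
                           recursive = TRUE, ignore.case = TRUE))
  if (length(files) == 0L) stop_val("no images found under ", root)
  recs <- list(); problems <- character()
  for (f in files) {
    parts <- strsplit(f, "/", fixed = TRUE)[[1]]
    fname <- parts[length(parts)]
    dirs <- parts[-length(parts)]
    mag_i <- grep("^[0-9]+X$", dirs, ignore.case = TRUE)
    mag <- if (length(mag_i) >= 1L) {
      as.integer(sub("X$", "", dirs[mag_i[1]], ignore.case = TRUE))
    } else {
      m <- regmatches(fname, regexec("-([0-9]+)-[0-9]+\\.", fname))[[1]]
      if (length(m) == 2L) as.integer(m[2]) else NA_integer_
    }
    if (is.na(mag) || length(dirs) < 2L) {
      problems <- c(problems, f)
      next
    }
    sm <- regmatches(fname, regexec("^[A-Z]+_[BM]_[A-Za-z]+-([0-9A-Za-z-]+?)-[0-9]+-", fname))[[1]]
    slide <- if (length(sm) == 2L) sm[2] else tools::file_path_sans_ext(fname)
    recs[[length(recs) + 1L]] <- data.frame(
      path = file.path(root, f), class = dirs[1], subclass = dirs[2],
      magnification = mag, slide_id = slide, stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L)
    stop_val("no parseable images found under ", root)
  manifest <- do.call(rbind, recs)
  if (!is.null(magnification_filter))
    manifest <- manifest[manifest$magnification %in% magnification_filter, ,
                         drop = FALSE]
  if (nrow(manifest) == 0L) stop_val("no images left after magnification filter")
  rownames(manifest) <- NULL
  attr(manifest, "task") <- task
  attr(manifest, "problems") <- problems
  manifest
}

#' Label column of a manifest for its task
#'
#' @param manifest a manifest `data.frame`.
#' @param task optional override of the manifest's task attribute.
#' @return character vector of labels (`subclass` for fine-grained tasks,
#'   `class` for binary).
#' @export
manifest_labels <- function(manifest, task = NULL) {
  task <- task %||% attr(manifest, "task") %||% "fine_grained"
  if (task == "binary") manifest$class else manifest$subclass
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified k-fold assignment
#'
#' Partitions manifest rows into `k` folds, stratified by label: within each
#' class, members are shuffled (seeded) and dealt round-robin, so per-fold
#' class counts differ from perfect stratification by at most 1. The
#' starting fold is rotated per class to balance total fold sizes.
#'
#' @param manifest a manifest `data.frame`.
#' @param k number of folds (default 5).
#' @param seed integer seed; the same seed always yields the same
#'   assignment.
#' @param stratify_by `"label"` (default) or `"none"` for a plain random
#'   split.
#' @return integer vector of fold indices in `1..k`, one per row.
#' @export
make_folds <- function(manifest, k = 5L, seed = 1L,
                       stratify_by = c("label", "none")) {
  stratify_by <- match.arg(stratify_by)
  k <- as.integer(k)
  if (k < 2L) stop_val("k must be >= 2")
  n <- nrow(manifest)
  labels <- if (stratify_by == "label") manifest_labels(manifest)
            else rep("all", n)
  counts <- table(labels)
  if (any(counts < k))
    stop_val("class '", names(counts)[which.min(counts)], "' has ",
             min(counts), " members, fewer than k = ", k)
  fold <- integer(n)
  with_seed(seed, {
    cls <- sort(unique(labels))
    for (ci in seq_along(cls)) {
      idx <- which(labels == cls[ci])
      idx <- sample(idx)
      start <- sample.int(k, 1L)
      fold[idx] <- ((seq_along(idx) - 1L + start - 1L) %% k) + 1L
    }
  })
  fold
}

#' Oversample records to class balance
#'
#' Duplicates minority-class rows by sampling with replacement until every
#' class count equals the majority count. Intended for training folds only;
#' never discards a record.
#'
#' @param records manifest rows (a `data.frame`).
#' @param seed integer seed.
#' @param by label column values to balance on; defaults to the manifest
#'   task's labels.
#' @return the augmented `data.frame` (original rows first, duplicates
#'   appended).
#' @export
oversample <- function(records, seed = 1L, by = NULL) {
  labels <- by %||% manifest_labels(records)
  if (length(labels) != nrow(records))
    stop_val("label vector length does not match records")
  counts <- table(labels)
  if (any(counts == 0L)) stop_val("empty class in records")
  target <- max(counts)
  extras <- integer(0)
  with_seed(seed, {
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need > 0L) {
        idx <- which(labels == cl)
        extras <- c(extras, sample(idx, need, replace = TRUE))
      }
    }
  })
  out <- rbind(records, records[extras, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "task") <- attr(records, "task")
  out
}

#' Augmentation parameter set
#'
#' Defaults follow the common practice for histology-style augmentation:
#' both flips at probability 0.5, shifts up to 10% of the side, rotations
#' up to 40 degrees.
#'
#' @param h_flip,v_flip enable random horizontal / vertical flips (p = 0.5).
#' @param shift_fraction maximum shift as a fraction of image side, in
#'   `[0, 1)`.
#' @param rotation_degrees maximum absolute rotation angle (>= 0).
#' @param seed default seed used when [augment()] is called without `rng`.
#' @return an `augment_params` list.
#' @export
augment_params <- function(h_flip = TRUE, v_flip = TRUE, shift_fraction = 0.1,
                           rotation_degrees = 40, seed = 1L) {
  if (shift_fraction < 0 || shift_fraction >= 1)
    stop_val("shift_fraction must be in [0, 1)")
  if (rotation_degrees < 0) stop_val("rotation_degrees must be >= 0")
  structure(list(h_flip = isTRUE(h_flip), v_flip = isTRUE(v_flip),
                 shift_fraction = shift_fraction,
                 rotation_degrees = rotation_degrees, seed = as.integer(seed)),
            class = "augment_params")
}

shift_image <- function(img, dy, dx) {
  d <- dim(img)
  out <- array(0, d)
  src_y <- seq_len(d[1]) - dy; src_x <- seq_len(d[2]) - dx
  ok_y <- src_y >= 1 & src_y <= d[1]; ok_x <- src_x >= 1 & src_x <= d[2]
  out[which(ok_y), which(ok_x), ] <- img[src_y[ok_y], src_x[ok_x], ]
  out
}

rotate_image <- function(img, angle) {
  if (angle == 0) return(img)
  e <- EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
  out <- EBImage::rotate(e, angle, filter = "bilinear",
                         output.dim = dim(img)[c(2L, 1L)], bg.col = 0)
  pmin(pmax(aperm(EBImage::imageData(out), c(2L, 1L, 3L)), 0), 1)
}

#' Randomly augment an image
#'
#' Applies a random composition of horizontal/vertical flips, integer
#' height/width shifts (translation) and rotation within the configured
#' ranges. Fully determined by `rng`: the same seed always yields the same
#' output, and with all ranges zero (and flips disabled) the image is
#' returned unchanged.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param params an [augment_params()] object.
#' @param rng integer seed for this draw (defaults to `params$seed`).
#' @return augmented image of identical dimensions.
#' @export
augment <- function(image, params = augment_params(), rng = params$seed) {
  d <- dim(image)
  with_seed(rng, {
    if (params$h_flip && stats::runif(1) < 0.5)
      image <- image[, rev(seq_len(d[2])), , drop = FALSE]
    if (params$v_flip && stats::runif(1) < 0.5)
      image <- image[rev(seq_len(d[1])), , , drop = FALSE]
    if (params$shift_fraction > 0) {
      max_dy <- floor(params$shift_fraction * d[1])
      max_dx <- floor(params$shift_fraction * d[2])
      dy <- sample.int(2L * max_dy + 1L, 1L) - max_dy - 1L
      dx <- sample.int(2L * max_dx + 1L, 1L) - max_dx - 1L
      if (dy != 0L || dx != 0L) image <- shift_image(image, dy, dx)
    }
    if (params$rotation_degrees > 0) {
      ang <- stats::runif(1, -params$rotation_degrees, params$rotation_degrees)
      image <- rotate_image(image, ang)
    }
  })
  image
}

#' Write / read a manifest CSV
#'
#' Columns: `path`, `class`, `subclass`, `magnification`, `slide_id` and,
#' when present, `fold`.
#'
#' @param manifest manifest `data.frame`.
#' @param path CSV file path.
#' @return `read_manifest()` returns the `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param task task attribute to attach on read.
#' @export
read_manifest <- function(path, task = "fine_grained") {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(m, "task") <- task
  m
}
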