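make_fixture_tree <- function() {
  root <- tempfile("tree")
  put <- function(rel, seed, size = 10L) {
    dir.create(file.path(root, dirname(rel)), recursive = TRUE,
               showWarnings = FALSE)
    img <- fastbcnn:::with_seed(seed,
      array(stats::runif(size * size * 3), c(size, size, 3L)))
    png::writePNG(img, file.path(root, rel))
  }
  put("benign/adenosis/40X/SOB_B_A-14-22549AB-40-001.png", 1)
  put("benign/adenosis/40X/SOB_B_A-14-22549AB-40-002.png", 2)
  put("malignant/ductal_carcinoma/400X/SOB_M_DC-14-2523-400-001.png", 3)
  put("malignant/ductal_carcinoma/400X/SOB_M_DC-14-2523-400-002.png", 4)
  put("malignant/ductal_carcinoma/400X/SOB_M_DC-14-2980-400-003.png", 5)
  put("stray.png", 6)   # unparseable: no subclass/magnification structure
  root
}

test_that("layout scanning parses class, subclass, magnification and slide", {
  root <- make_fixture_tree()
  m <- scan_layout(root)
  expect_equal(nrow(m), 5L)
  ben <- m[m$class == "benign", ]
  expect_equal(nrow(ben), 2L)
  expect_true(all(ben$subclass == "adenosis"))
  expect_true(all(ben$magnification == 40L))
  expect_true(all(m$slide_id[m$class == "malignant"] %in%
                    c("14-2523", "14-2980")))
  expect_identical(attr(m, "problems"), "stray.png")
  expect_identical(m$path, sort(m$path))
  m400 <- scan_layout(root, magnification_filter = 400)
  expect_true(all(m400$magnification == 400L))
  expect_equal(nrow(m400), 3L)
  expect_error(scan_layout(tempfile()), "exist")
  empty <- tempfile(); dir.create(empty)
  expect_error(scan_layout(empty), "no images")
})

test_that("stratified folds partition exactly with balanced classes", {
  man <- data.frame(path = sprintf("p%02d", 1:10),
                    class = rep(c("benign", "malignant"), each = 5),
                    subclass = rep(c("a", "d"), each = 5),
                    magnification = 40L, slide_id = "s")
  attr(man, "task") <- "fine_grained"
  f <- make_folds(man, k = 5, seed = 3)
  expect_setequal(f, 1:5)
  for (k in 1:5)
    expect_equal(as.integer(table(man$subclass[f == k])), c(1L, 1L))
  expect_identical(f, make_folds(man, k = 5, seed = 3))
  expect_false(identical(f, make_folds(man, k = 5, seed = 4)))
  expect_error(make_folds(man, k = 6, seed = 1), "fewer than k")
})

test_that("fold stratification is within one of perfect over random manifests", {
  set.seed(99)
  for (trial in 1:20) {
    ncl <- sample(2:5, 1)
    counts <- sample(5:23, ncl, replace = TRUE)
    man <- data.frame(path = sprintf("p%03d", seq_len(sum(counts))),
                      class = "x",
                      subclass = rep(letters[seq_len(ncl)], counts),
                      magnification = 40L, slide_id = "s")
    attr(man, "task") <- "fine_grained"
    k <- sample(2:5, 1)
    f <- make_folds(man, k = k, seed = trial)
    expect_equal(sort(unique(f)), 1:k)
    for (cl in letters[seq_len(ncl)]) {
      per <- tabulate(f[man$subclass == cl], nbins = k)
      expect_lte(diff(range(per)), 1L)
    }
    # disjoint and exhaustive by construction of a single assignment vector
    expect_equal(length(f), nrow(man))
  }
})

test_that("oversampling balances to the majority count without discarding", {
  man <- data.frame(path = sprintf("p%02d", 1:10),
                    class = c(rep("benign", 3), rep("malignant", 7)),
                    subclass = c(rep("a", 3), rep("d", 7)),
                    magnification = 40L, slide_id = "s")
  attr(man, "task") <- "binary"
  o <- oversample(man, seed = 1)
  expect_equal(as.integer(table(o$class)), c(7L, 7L))
  expect_true(all(man$path %in% o$path))
  # already balanced: unchanged multiset
  bal <- man[4:9, ]; bal$class <- rep(c("benign", "malignant"), 3)
  attr(bal, "task") <- "binary"
  expect_equal(sort(oversample(bal, seed = 2)$path), sort(bal$path))
})

test_that("the 40x subclass census oversamples to a uniform 864", {
  counts <- c(adenosis = 114, fibroadenoma = 253, phyllodes_tumor = 149,
              tubular_adenoma = 109, ductal_carcinoma = 864,
              lobular_carcinoma = 156, mucinous_carcinoma = 205,
              papillary_carcinoma = 145)
  man <- data.frame(path = sprintf("p%04d", seq_len(sum(counts))),
                    class = rep(c("benign", "malignant"), c(625, 1370)),
                    subclass = rep(names(counts), counts),
                    magnification = 40L, slide_id = "s")
  attr(man, "task") <- "fine_grained"
  o <- oversample(man, seed = 5)
  expect_true(all(table(o$subclass) == 864L))
  expect_equal(nrow(o), 864L * 8L)
})

test_that("augmentation is seeded, shape-preserving and identity at zero ranges", {
  img <- rand_image(20, 31)
  id <- augment_params(h_flip = FALSE, v_flip = FALSE, shift_fraction = 0,
                       rotation_degrees = 0)
  expect_identical(augment(img, id, rng = 1), img)
  p <- augment_params()
  a1 <- augment(img, p, rng = 42)
  expect_identical(a1, augment(img, p, rng = 42))
  expect_false(identical(a1, augment(img, p, rng = 43)))
  expect_identical(dim(a1), dim(img))
  expect_true(all(a1 >= 0 & a1 <= 1))
  # a flip-only augmentation is an involution at fixed seed
  pf <- augment_params(h_flip = TRUE, v_flip = FALSE, shift_fraction = 0,
                       rotation_degrees = 0)
  expect_identical(augment(augment(img, pf, rng = 7), pf, rng = 7), img)
})

test_that("preprocessing resizes, clamps and promotes grayscale", {
  wide <- fastbcnn:::with_seed(8, array(stats::runif(70 * 46 * 3), c(46, 70, 3)))
  f <- tempfile(fileext = ".png")
  png::writePNG(wide, f)
  out <- preprocess(f, size = 24)
  expect_identical(dim(out), c(24L, 24L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  # already at target size: values pass through
  sq <- rand_image(24, 9)
  expect_equal(preprocess(sq, size = 24), sq)
  gray <- matrix(stats::runif(24 * 24), 24, 24)
  g <- tempfile(fileext = ".png")
  png::writePNG(gray, g)
  pg <- preprocess(g, size = 24)
  expect_identical(dim(pg), c(24L, 24L, 3L))
  expect_equal(pg[, , 1], pg[, , 2])
  expect_error(suppressWarnings(preprocess(tempfile(fileext = ".png"))),
               "decode")
})
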