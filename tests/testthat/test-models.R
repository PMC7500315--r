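test_that("the tiny backbone honors its shape contract", {
  bk <- tiny_backbone(seed = 2, D = 16L, input = 64L, widths = c(8L, 16L, 16L))
  fm <- extract_features(bk, rand_image(64, 1))[[1]]
  expect_identical(dim(fm), c(16L, 8L, 8L))
  expect_true(all(is.finite(fm)))
  expect_error(extract_features(bk, rand_image(32, 1)), "shape")
})

test_that("standard backbones error explicitly when no runtime exists", {
  expect_error(build_backbone(backbone_spec("resnet50", 2048L)),
               "runtime")
  expect_error(backbone_spec("resnet50", 2048L, input_size = 100L), "197")
  expect_error(backbone_spec("tiny", init = "imagenet-pretrained"), "random")
})

test_that("SE insertion halves outputs at zero gate weights and is shape-stable", {
  bk <- tiny_backbone(seed = 4)
  img <- rand_image(16, 9)
  base <- extract_features(bk, img)[[1]]
  bk_se <- insert_se_blocks(bk, length(bk$stages), init = "zero")
  gated <- extract_features(bk_se, img)[[1]]
  expect_equal(as.numeric(gated), 0.5 * as.numeric(base))
  expect_identical(dim(gated), dim(base))
  # empty position list is a no-op on the network function
  expect_equal(extract_features(insert_se_blocks(bk, integer(0)), img)[[1]],
               base)
  expect_error(insert_se_blocks(bk, 99), "invalid")
})

test_that("SE insertion adds exactly 2*C^2/r parameters per gated stage", {
  bk <- tiny_backbone(seed = 5, D = 8L, widths = c(4L, 8L, 8L))
  p0 <- count_parameters(bk)
  r <- 2L
  bk_se <- insert_se_blocks(bk, "all", reduction_ratio = r)
  widths <- c(4L, 8L, 8L)
  expect_equal(count_parameters(bk_se) - p0, sum(2 * widths^2 / r))
})

test_that("fast model is the exact reduction of the shared two-stream model", {
  for (s in 1:3) {
    bk <- tiny_backbone(seed = s, se = (s == 2))
    fast <- assemble_fast_bcnn(bk, 3, seed = s)
    two <- assemble_bcnn(bk, bk, 3, seed = s)
    for (i in 1:3) {
      img <- rand_image(16, 100 * s + i)
      pf <- predict(fast, img); pt <- predict(two, img)
      expect_lt(max(abs(pf - pt)), 1e-6)
    }
  }
})

test_that("predictions are softmax distributions and deterministic", {
  bk <- tiny_backbone(seed = 6)
  m <- assemble_fast_bcnn(bk, 8, seed = 6)
  imgs <- lapply(1:4, function(i) rand_image(16, i))
  p <- predict(m, imgs)
  expect_identical(dim(p), c(4L, 8L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_identical(p, predict(m, imgs))
  # an all-zero image yields zero features, hence uniform class probabilities
  expect_equal(as.numeric(predict(m, array(0, c(16, 16, 3)))),
               rep(1 / 8, 8))
  expect_error(predict(m, rand_image(8, 1)), "expects")
})

test_that("parameter counts satisfy the closed forms", {
  K <- 4L
  bk1 <- tiny_backbone(seed = 1, D = 16L, input = 64L, widths = c(8L, 16L, 16L))
  bk2 <- tiny_backbone(seed = 2, D = 16L, input = 64L, widths = c(8L, 16L, 16L))
  pb <- count_parameters(bk1)
  fast <- assemble_fast_bcnn(bk1, K)
  expect_equal(count_parameters(fast), pb + 16^2 * K + K)
  expect_identical(length(fast$classifier$W), 1024L)
  expect_identical(length(fast$classifier$b), 4L)
  two <- assemble_bcnn(bk1, bk2, K)
  expect_equal(count_parameters(two),
               count_parameters(bk1) + count_parameters(bk2) +
                 16 * 16 * K + K)
  expect_lt(count_parameters(fast), count_parameters(two))
  # shared streams collapse to the fast parameter set
  shared <- assemble_bcnn(bk1, bk1, K)
  expect_equal(count_parameters(shared), count_parameters(fast))
  # SE variants keep the direction
  bse <- tiny_backbone(seed = 3, D = 8L, widths = c(4L, 8L, 8L), se = TRUE)
  bse2 <- tiny_backbone(seed = 4, D = 8L, widths = c(4L, 8L, 8L), se = TRUE)
  expect_lt(count_parameters(assemble_fast_bcnn(bse, K)),
            count_parameters(assemble_bcnn(bse, bse2, K)))
})

test_that("the GAP baseline is parameter-matched within 10%", {
  bk <- tiny_backbone(seed = 1, D = 16L, input = 64L, widths = c(8L, 16L, 16L))
  fast <- assemble_fast_bcnn(bk, 4)
  gap <- assemble_gap_baseline(fast, seed = 2)
  ratio <- count_parameters(gap) / count_parameters(fast)
  expect_lt(abs(ratio - 1), 0.10)
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("fastbcnn")
  spec <- backbone_spec("tiny", output_channels = 8L, input_size = 16L,
                        widths = c(4L, 8L, 8L), se_blocks = TRUE, seed = 3)
  model <- assemble_fast_bcnn(build_backbone(spec), 3, seed = 5)
  img <- rand_image(16, 1)
  x <- aperm(img, c(3, 1, 2))
  loss_of <- function(m) -log(ns$model_forward(m, x)$hf$p[2])
  fw <- ns$model_forward(model, x)
  dlog <- fw$hf$p; dlog[2] <- dlog[2] - 1
  g <- ns$model_backward(model, fw, dlog)$grads
  p <- ns$model_params(model)
  floor_ok <- abs(fw$hf$v) > fastbcnn:::SQRT_GRAD_FLOOR
  set.seed(8)
  for (nm in names(p)) {
    for (k in sample(seq_along(p[[nm]]), min(4, length(p[[nm]])))) {
      eps <- 1e-5
      p2 <- p; p2[[nm]][k] <- p2[[nm]][k] + eps
      lp <- loss_of(ns$set_model_params(model, p2))
      p2[[nm]][k] <- p2[[nm]][k] - 2 * eps
      lm <- loss_of(ns$set_model_params(model, p2))
      fd <- (lp - lm) / (2 * eps)
      an <- g[[nm]][k]
      denom <- max(1e-4, abs(fd) + abs(an))
      # coordinates flowing through the floored signed-sqrt derivative are
      # intentionally clamped; check the unclamped ones tightly
      if (nm %in% c("cls.W", "cls.b") || all(floor_ok)) {
        expect_lt(abs(fd - an) / denom, 1e-3)
      }
    }
  }
})

test_that("every parameter group receives gradient on a generic batch", {
  ns <- asNamespace("fastbcnn")
  spec <- backbone_spec("tiny", output_channels = 8L, input_size = 16L,
                        widths = c(4L, 8L, 8L), se_blocks = TRUE, seed = 3)
  model <- assemble_fast_bcnn(build_backbone(spec), 3, seed = 5)
  gsum <- NULL
  for (i in 1:4) {
    x <- aperm(rand_image(16, 50 + i), c(3, 1, 2))
    fw <- ns$model_forward(model, x)
    dlog <- fw$hf$p; dlog[1] <- dlog[1] - 1
    g <- ns$model_backward(model, fw, dlog)$grads
    if (is.null(gsum)) gsum <- g
    else for (nm in names(g)) gsum[[nm]] <- gsum[[nm]] + g[[nm]]
  }
  for (nm in names(gsum))
    expect_gt(max(abs(gsum[[nm]])), 0)
})

test_that("saved models reload with bitwise-identical predictions", {
  bk <- tiny_backbone(seed = 12)
  m <- assemble_fast_bcnn(bk, 4, seed = 12)
  img <- rand_image(16, 3)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m, img), predict(m2, img))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(sidecar$type, "fast_bcnn")
  expect_equal(sidecar$n_parameters, count_parameters(m))
})
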