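STANDARD_BACKBONES <- c("resnet50", "inceptionv3", "inceptionresnetv2")

#' Describe a backbone feature extractor
#'
#' @param name `"tiny"` (a small trainable 3-stage convolutional network) or
#'   one of `"resnet50"`, `"inceptionv3"`, `"inceptionresnetv2"`. The large
#'   backbones require a deep-learning runtime with their published
#'   architectures and weights; [build_backbone()] raises an explicit error
#'   when that runtime is unavailable rather than silently substituting a
#'   random network.
#' @param output_channels number of channels D of the final feature map.
#' @param init `"random"` (seeded He-uniform) or `"imagenet-pretrained"`;
#'   the tiny backbone supports only `"random"`.
#' @param input_size square input side in pixels (default 64 for tiny; the
#'   standard backbones require at least 197).
#' @param se_blocks insert a squeeze-and-excitation block after every stage.
#' @param widths per-stage channel widths for the tiny backbone; last entry
#'   must equal `output_channels`. Default `c(8, 16, output_channels)`.
#' @param se_reduction reduction ratio of inserted SE gates (must divide
#'   every gated stage width; default 4, suited to tiny widths).
#' @param seed integer seed for weight initialization.
#' @return a `backbone_spec` list.
#' @export
backbone_spec <- function(name = "tiny", output_channels = 16L,
                          init = c("random", "imagenet-pretrained"),
                          input_size = if (name == "tiny") 64L else 224L,
                          se_blocks = FALSE, widths = NULL,
                          se_reduction = 4L, seed = 1L) {
  init <- match.arg(init)
  name <- match.arg(name, c("tiny", STANDARD_BACKBONES))
  if (name == "tiny" && init != "random")
    stop_val("the tiny backbone supports only random initialization")
  if (name != "tiny" && input_size < 197L)
    stop_val(name, " requires input_size >= 197 (its minimum input resolution)")
  if (is.null(widths)) widths <- c(8L, 16L, as.integer(output_channels))
  if (utils::tail(widths, 1L) != output_channels)
    stop_val("last width (", utils::tail(widths, 1L),
             ") must equal output_channels (", output_channels, ")")
  structure(list(name = name, output_channels = as.integer(output_channels),
                 init = init, input_size = as.integer(input_size),
                 se_blocks = isTRUE(se_blocks), widths = as.integer(widths),
                 se_reduction = as.integer(se_reduction),
                 seed = as.integer(seed)),
            class = "backbone_spec")
}

#' Build a backbone feature extractor
#'
#' The tiny backbone is a stack of 3x3 stride-2 convolutions with ReLU
#' (optionally followed by squeeze-and-excitation recalibration), mapping a
#' `3 x S x S` image to a `D x S/2^n x S/2^n` feature map, with no fully
#' connected head. Weights are He-uniform, biases zero, fully seeded.
#'
#' @param spec a [backbone_spec()].
#' @return an object of class `fb_backbone`; apply it with
#'   [extract_features()].
#' @export
build_backbone <- function(spec) {
  if (!inherits(spec, "backbone_spec")) stop_val("spec must be a backbone_spec")
  if (spec$name %in% STANDARD_BACKBONES) {
    stop_val("backbone '", spec$name, "' requires a deep-learning runtime ",
             "with the published architecture",
             if (spec$init == "imagenet-pretrained") " and ImageNet weights",
             ", which is not available in this installation; use the 'tiny' ",
             "backbone or install such a runtime")
  }
  widths <- spec$widths
  in_ch <- 3L
  stages <- vector("list", length(widths))
  plans <- vector("list", length(widths))
  H <- spec$input_size
  prev <- in_ch
  for (i in seq_along(widths)) {
    cw <- widths[i]
    stages[[i]] <- list(
      W = with_seed(spec$seed + 97L * i,
                    he_uniform(cw, prev * 9L, fan_in = prev * 9L)),
      b = numeric(cw),
      se = NULL)
    plans[[i]] <- conv_plan(prev, H, H)
    H <- plans[[i]]$H_out
    prev <- cw
  }
  bk <- structure(list(name = spec$name, spec = spec, stages = stages,
                       plans = plans, in_channels = in_ch,
                       input_size = spec$input_size,
                       out_channels = utils::tail(widths, 1L),
                       out_spatial = H),
                  class = "fb_backbone")
  if (spec$se_blocks)
    bk <- insert_se_blocks(bk, seq_along(widths),
                           reduction_ratio = spec$se_reduction,
                           seed = spec$seed + 7L)
  bk
}

#' Insert squeeze-and-excitation blocks after backbone stages
#'
#' Appends an SE recalibration (squeeze, two-layer sigmoid gate, channel
#' rescale) after each named stage. Output shapes are unchanged; only the
#' gate parameters are added.
#'
#' @param backbone an `fb_backbone`.
#' @param positions integer stage indices (or `"all"`).
#' @param reduction_ratio SE reduction ratio; must divide each gated stage's
#'   channel width.
#' @param init `"he"` or `"zero"` gate weights.
#' @param seed integer seed.
#' @return the backbone with SE parameters attached.
#' @export
insert_se_blocks <- function(backbone, positions, reduction_ratio = 4L,
                             init = c("he", "zero"), seed = 1L) {
  init <- match.arg(init)
  if (identical(positions, "all")) positions <- seq_along(backbone$stages)
  positions <- as.integer(positions)
  if (length(positions) == 0L) return(backbone)
  if (any(positions < 1L | positions > length(backbone$stages)))
    stop_val("invalid SE position(s): backbone has ",
             length(backbone$stages), " stages")
  for (i in positions) {
    cw <- nrow(backbone$stages[[i]]$W)
    backbone$stages[[i]]$se <-
      se_params(cw, reduction_ratio, init = init, seed = seed + 13L * i)
  }
  backbone
}

#' Apply a backbone to images
#'
#' @param backbone an `fb_backbone`.
#' @param images a single `H x W x 3` image array in `[0, 1]`, or a list of
#'   them, matching the backbone's input size.
#' @return a list of [feature_map()] arrays (one per image).
#' @export
extract_features <- function(backbone, images) {
  images <- as_image_list(images)
  lapply(images, function(img) {
    x <- aperm(img, c(3L, 1L, 2L))
    feature_map(backbone_forward(backbone, x)$fmap)
  })
}

as_image_list <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L) return(list(images))
  if (is.list(images)) return(images)
  stop_val("images must be an H x W x 3 array or a list of such arrays")
}

new_model <- function(type, n_classes, feat_dim, pooling, seed, extra) {
  cls <- list(
    W = with_seed(seed + 991L, he_uniform(n_classes, feat_dim,
                                          fan_in = feat_dim)),
    b = numeric(n_classes))
  structure(c(list(type = type, n_classes = as.integer(n_classes),
                   classifier = cls, pooling = pooling,
                   class_names = paste0("class", seq_len(n_classes))),
              extra),
            class = c(type, "fb_model"))
}

#' Assemble a two-stream bilinear model
#'
#' Forward pass: both streams extract feature maps from the same image,
#' which are combined by [bilinear_pool()], passed through the signed square
#' root and L2 normalization, and classified by a single affine layer with
#' softmax. If `f_a` and `f_b` are the identical object the streams share
#' weights (and parameters are counted once).
#'
#' @param f_a,f_b backbones built by [build_backbone()], with equal input
#'   sizes and output spatial dimensions.
#' @param n_classes number of classes.
#' @param pooling `"sum"` (default) or `"mean"` spatial aggregation.
#' @param seed seed for the classifier initialization.
#' @return an object of class `bcnn`.
#' @export
assemble_bcnn <- function(f_a, f_b, n_classes, pooling = c("sum", "mean"),
                          seed = 1L) {
  pooling <- match.arg(pooling)
  if (f_a$input_size != f_b$input_size || f_a$out_spatial != f_b$out_spatial)
    stop_dim("stream backbones must agree on input size and output spatial dims")
  shared <- identical(f_a, f_b)
  new_model("bcnn", n_classes, f_a$out_channels * f_b$out_channels, pooling,
            seed,
            list(f_a = f_a, f_b = if (shared) NULL else f_b, shared = shared,
                 input_size = f_a$input_size))
}

#' Assemble a fast (single-stream) bilinear model
#'
#' The single backbone's feature map is pooled against itself
#' ([bilinear_pool_fast()]); the rest of the pipeline (signed sqrt, L2
#' normalization, affine + softmax) is identical to the two-stream model, of
#' which this is the exact reduction when both streams share weights.
#'
#' @param f a backbone built by [build_backbone()].
#' @inheritParams assemble_bcnn
#' @return an object of class `fast_bcnn`.
#' @export
assemble_fast_bcnn <- function(f, n_classes, pooling = c("sum", "mean"),
                               seed = 1L) {
  pooling <- match.arg(pooling)
  new_model("fast_bcnn", n_classes, f$out_channels^2, pooling, seed,
            list(f = f, input_size = f$input_size))
}

#' Assemble a global-average-pooling baseline classifier
#'
#' First-order control model: the backbone feature map is globally averaged
#' per channel and classified by affine + softmax. Used as the
#' parameter-matched baseline against which the bilinear models' capability
#' is measured.
#'
#' @inheritParams assemble_fast_bcnn
#' @return an object of class `gap_cnn`.
#' @export
assemble_gap_cnn <- function(f, n_classes, seed = 1L) {
  new_model("gap_cnn", n_classes, f$out_channels, "mean", seed,
            list(f = f, input_size = f$input_size))
}

#' Build a GAP baseline whose parameter count matches a bilinear model
#'
#' Widens the final stage of a tiny backbone so that the total trainable
#' parameter count of the GAP model is as close as possible to the reference
#' bilinear model's count (the bilinear head is much larger than a GAP head,
#' so the extra budget goes into backbone width).
#'
#' @param reference a `fast_bcnn` or `bcnn` model with a tiny backbone.
#' @param seed seed for the new weights.
#' @return a `gap_cnn` model with total parameters within a few percent of
#'   `count_parameters(reference)`.
#' @export
assemble_gap_baseline <- function(reference, seed = 1L) {
  target <- count_parameters(reference)
  bk <- if (reference$type == "fast_bcnn") reference$f else reference$f_a
  widths <- bk$spec$widths
  K <- reference$n_classes
  n <- length(widths)
  prev <- if (n >= 2L) widths[n - 1L] else 3L
  fixed <- 0L
  in_ch <- 3L
  for (i in seq_len(n - 1L)) {
    fixed <- fixed + widths[i] * (in_ch * 9L) + widths[i]
    in_ch <- widths[i]
  }
  count_for <- function(w3) fixed + w3 * (prev * 9L + 1L) + w3 * K + K
  cand <- seq(widths[n], widths[n] + 256L)
  w3 <- cand[which.min(abs(vapply(cand, count_for, numeric(1)) - target))]
  spec <- backbone_spec("tiny", output_channels = w3,
                        input_size = bk$input_size,
                        se_blocks = bk$spec$se_blocks,
                        widths = c(widths[-n], w3),
                        se_reduction = bk$spec$se_reduction, seed = seed)
  assemble_gap_cnn(build_backbone(spec), K, seed = seed)
}

# ---- forward / backward over whole models --------------------------------

model_forward <- function(model, x) {
  if (model$type == "fast_bcnn") {
    bf <- backbone_forward(model$f, x)
    X <- matrix(bf$fmap, nrow = dim(bf$fmap)[1])
    hf <- bilinear_head_forward(X, X, model$classifier$W, model$classifier$b,
                                model$pooling)
    list(hf = hf, bf = bf, X = X, fmap_dim = dim(bf$fmap))
  } else if (model$type == "bcnn") {
    bfa <- backbone_forward(model$f_a, x)
    Xa <- matrix(bfa$fmap, nrow = dim(bfa$fmap)[1])
    if (model$shared) {
      bfb <- bfa; Xb <- Xa
    } else {
      bfb <- backbone_forward(model$f_b, x)
      Xb <- matrix(bfb$fmap, nrow = dim(bfb$fmap)[1])
    }
    hf <- bilinear_head_forward(Xa, Xb, model$classifier$W, model$classifier$b,
                                model$pooling)
    list(hf = hf, bf_a = bfa, bf_b = bfb, X_a = Xa, X_b = Xb,
         fmap_dim_a = dim(bfa$fmap), fmap_dim_b = dim(bfb$fmap))
  } else {
    bf <- backbone_forward(model$f, x)
    X <- matrix(bf$fmap, nrow = dim(bf$fmap)[1])
    hf <- gap_head_forward(X, model$classifier$W, model$classifier$b)
    list(hf = hf, bf = bf, X = X, fmap_dim = dim(bf$fmap))
  }
}

flatten_stage_grads <- function(prefix, stage_grads) {
  out <- list()
  for (i in seq_along(stage_grads)) {
    for (nm in names(stage_grads[[i]]))
      out[[paste0(prefix, "s", i, ".", nm)]] <- stage_grads[[i]][[nm]]
  }
  out
}

# Returns named gradients plus the gradient at the final feature map(s),
# which Grad-CAM consumes directly.
model_backward <- function(model, fw, dlogits) {
  if (model$type == "fast_bcnn") {
    hb <- bilinear_head_backward(dlogits, fw$hf, fw$X, fw$X,
                                 model$classifier$W)
    dfmap <- array(hb$dX_a, fw$fmap_dim)
    bb <- backbone_backward(model$f, fw$bf, dfmap)
    grads <- c(list(cls.W = hb$dWc, cls.b = hb$dbc),
               flatten_stage_grads("f.", bb$stage_grads))
    list(grads = grads, dfmap = dfmap, bb = list(f = bb))
  } else if (model$type == "bcnn") {
    hb <- bilinear_head_backward(dlogits, fw$hf, fw$X_a, fw$X_b,
                                 model$classifier$W)
    if (model$shared) {
      dfmap <- array(hb$dX_a, fw$fmap_dim_a)
      bb <- backbone_backward(model$f_a, fw$bf_a, dfmap)
      grads <- c(list(cls.W = hb$dWc, cls.b = hb$dbc),
                 flatten_stage_grads("fa.", bb$stage_grads))
      list(grads = grads, dfmap_a = dfmap, dfmap_b = dfmap,
           bb = list(f_a = bb))
    } else {
      dfa <- array(hb$dX_a, fw$fmap_dim_a)
      dfb <- array(hb$dX_b, fw$fmap_dim_b)
      bba <- backbone_backward(model$f_a, fw$bf_a, dfa)
      bbb <- backbone_backward(model$f_b, fw$bf_b, dfb)
      grads <- c(list(cls.W = hb$dWc, cls.b = hb$dbc),
                 flatten_stage_grads("fa.", bba$stage_grads),
                 flatten_stage_grads("fb.", bbb$stage_grads))
      list(grads = grads, dfmap_a = dfa, dfmap_b = dfb,
           bb = list(f_a = bba, f_b = bbb))
    }
  } else {
    hb <- gap_head_backward(dlogits, fw$hf, fw$X, model$classifier$W)
    dfmap <- array(hb$dX, fw$fmap_dim)
    bb <- backbone_backward(model$f, fw$bf, dfmap)
    grads <- c(list(cls.W = hb$dWc, cls.b = hb$dbc),
               flatten_stage_grads("f.", bb$stage_grads))
    list(grads = grads, dfmap = dfmap, bb = list(f = bb))
  }
}

backbone_param_list <- function(prefix, bk) {
  out <- list()
  for (i in seq_along(bk$stages)) {
    st <- bk$stages[[i]]
    out[[paste0(prefix, "s", i, ".W")]] <- st$W
    out[[paste0(prefix, "s", i, ".b")]] <- st$b
    if (!is.null(st$se)) {
      out[[paste0(prefix, "s", i, ".se.W1")]] <- st$se$W1
      out[[paste0(prefix, "s", i, ".se.W2")]] <- st$se$W2
    }
  }
  out
}

model_params <- function(model) {
  out <- list(cls.W = model$classifier$W, cls.b = model$classifier$b)
  if (model$type == "bcnn") {
    out <- c(out, backbone_param_list("fa.", model$f_a))
    if (!model$shared) out <- c(out, backbone_param_list("fb.", model$f_b))
  } else {
    out <- c(out, backbone_param_list("f.", model$f))
  }
  out
}

set_model_params <- function(model, params) {
  put_bk <- function(bk, prefix) {
    for (i in seq_along(bk$stages)) {
      bk$stages[[i]]$W[] <- params[[paste0(prefix, "s", i, ".W")]]
      bk$stages[[i]]$b[] <- params[[paste0(prefix, "s", i, ".b")]]
      if (!is.null(bk$stages[[i]]$se)) {
        bk$stages[[i]]$se$W1[] <- params[[paste0(prefix, "s", i, ".se.W1")]]
        bk$stages[[i]]$se$W2[] <- params[[paste0(prefix, "s", i, ".se.W2")]]
      }
    }
    bk
  }
  model$classifier$W[] <- params$cls.W
  model$classifier$b[] <- params$cls.b
  if (model$type == "bcnn") {
    model$f_a <- put_bk(model$f_a, "fa.")
    if (!model$shared) model$f_b <- put_bk(model$f_b, "fb.")
  } else {
    model$f <- put_bk(model$f, "f.")
  }
  model
}

#' Count trainable parameters
#'
#' Total number of trainable scalars in a model or backbone. For the
#' bilinear models this satisfies the closed forms
#' `P(f_A) + P(f_B) + D_A * D_B * K + K` (two-stream, unshared) and
#' `P(f) + D^2 * K + K` (fast / shared): the single-stream model always has
#' strictly fewer parameters than the unshared two-stream model.
#'
#' @param model a model or `fb_backbone`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "fb_backbone"))
    return(sum(lengths(backbone_param_list("", model))))
  sum(lengths(model_params(model)))
}

#' Predict class probabilities
#'
#' @param object a model from [assemble_fast_bcnn()], [assemble_bcnn()] or
#'   [assemble_gap_cnn()].
#' @param images an `H x W x 3` array in `[0, 1]` or a list of them, with
#'   `H = W =` the model's input size.
#' @param ... unused.
#' @return an `n x n_classes` matrix of softmax probabilities (rows sum
#'   to 1), with class names as column names.
#' @export
predict.fb_model <- function(object, images, ...) {
  images <- as_image_list(images)
  out <- matrix(NA_real_, length(images), object$n_classes,
                dimnames = list(NULL, object$class_names))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (length(dim(img)) != 3L || dim(img)[3] != 3L ||
        dim(img)[1] != object$input_size || dim(img)[2] != object$input_size)
      stop_dim("image ", i, " has shape ", paste(dim(img), collapse = "x"),
               "; model expects ", object$input_size, "x",
               object$input_size, "x3")
    out[i, ] <- model_forward(object, aperm(img, c(3L, 1L, 2L)))$hf$p
  }
  out
}

#' Save / load a model
#'
#' `save_model()` writes the model object plus a `<path>.json` sidecar with
#' the backbone spec, class names and pixel normalization convention;
#' `load_model()` restores it. Reloaded models reproduce predictions
#' bitwise.
#'
#' @param model a model.
#' @param path file path for the checkpoint (the JSON sidecar gets `.json`
#'   appended).
#' @return `load_model()` returns the model; `save_model()` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(
    type = model$type, n_classes = model$n_classes,
    class_names = model$class_names, pooling = model$pooling,
    input_size = model$input_size, pixel_range = "[0,1]",
    n_parameters = count_parameters(model))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
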