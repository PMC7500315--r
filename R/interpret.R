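resolve_layer <- function(backbone, layer) {
  n <- length(backbone$stages)
  if (identical(layer, "final")) return(n)
  if (identical(layer, "first_conv")) return(1L)
  if (is.numeric(layer) && layer >= 1 && layer <= n) return(as.integer(layer))
  m <- regmatches(layer, regexec("^s([0-9]+)$", as.character(layer)))[[1]]
  if (length(m) == 2L) {
    i <- as.integer(m[2])
    if (i >= 1L && i <= n) return(i)
  }
  stop_val("unknown layer '", layer, "'; backbone has stages s1..s", n)
}

cam_from <- function(act_mat, grad_mat, spatial) {
  alpha <- rowMeans(grad_mat)                 # per-channel importance
  grid <- matrix(pmax(as.vector(crossprod(act_mat, alpha)), 0),
                 spatial[1], spatial[2])
  mx <- max(grid)
  if (mx > 0) grid <- grid / mx
  grid
}

upsample_grid <- function(grid, size) {
  e <- EBImage::Image(t(grid))
  out <- EBImage::resize(e, w = size, h = size, filter = "bilinear")
  t(EBImage::imageData(out))
}

#' Grad-CAM localization heatmap
#'
#' Backpropagates the target class logit to a convolutional layer's feature
#' map; channel weights are the spatial means of those gradients, and the
#' heatmap is the ReLU of the weighted channel sum, max-normalized to 1
#' when nonzero (an all-zero map stays all-zero — no NaN). For two-stream
#' models the heatmaps of the two streams are averaged.
#'
#' @param model a trained model.
#' @param image `H x W x 3` array matching the model input size.
#' @param target_class class name or index whose logit is explained.
#' @param layer `"final"` (default: the feature map feeding the pooling
#'   head), `"first_conv"`, or `"s<i>"` for stage i.
#' @return a `heatmap` object: `grid` (layer resolution), `upsampled`
#'   (bilinear, input resolution), `target_class`, `layer`.
#' @export
grad_cam <- function(model, image, target_class, layer = "final") {
  if (is.character(target_class)) {
    k <- match(target_class, model$class_names)
    if (is.na(k)) stop_val("unknown class '", target_class, "'")
  } else k <- as.integer(target_class)
  x <- aperm(image, c(3L, 1L, 2L))
  fw <- model_forward(model, x)
  dlogits <- numeric(model$n_classes)
  dlogits[k] <- 1
  mb <- model_backward(model, fw, dlogits)
  grids <- list()
  if (model$type == "bcnn") {
    streams <- if (model$shared) list(c("f_a", "f_a")) else
      list(c("f_a", "f_a"), c("f_b", "f_b"))
    bks <- list(f_a = model$f_a, f_b = if (model$shared) NULL else model$f_b)
    fws <- list(f_a = fw$bf_a, f_b = fw$bf_b)
    for (s in streams) {
      bk <- bks[[s[1]]] %||% model$f_a
      li <- resolve_layer(bk, layer)
      plan <- bk$plans[[li]]
      act <- matrix(fws[[s[1]]]$caches[[li]]$out, nrow = nrow(bk$stages[[li]]$W))
      gr <- matrix(mb$bb[[s[1]]]$d_stage_out[[li]],
                   nrow = nrow(bk$stages[[li]]$W))
      grids[[length(grids) + 1L]] <-
        cam_from(act, gr, c(plan$H_out, plan$W_out))
    }
  } else {
    bk <- model$f
    li <- resolve_layer(bk, layer)
    plan <- bk$plans[[li]]
    act <- matrix(fw$bf$caches[[li]]$out, nrow = nrow(bk$stages[[li]]$W))
    gr <- matrix(mb$bb$f$d_stage_out[[li]], nrow = nrow(bk$stages[[li]]$W))
    grids[[1L]] <- cam_from(act, gr, c(plan$H_out, plan$W_out))
  }
  grid <- Reduce(`+`, grids) / length(grids)
  mx <- max(grid)
  if (mx > 0) grid <- grid / mx
  structure(list(grid = grid,
                 upsampled = upsample_grid(grid, model$input_size),
                 target_class = model$class_names[k], layer = layer),
            class = "heatmap")
}

#' Per-channel activation maps at a convolutional layer
#'
#' Returns the raw per-channel activations at the requested layer, min-max
#' scaled to `[0, 1]` per channel for display (a constant channel maps to
#' zeros). For a two-stream model both streams' maps are returned so their
#' responses can be compared.
#'
#' @param model a model.
#' @param image `H x W x 3` input array.
#' @param layer `"first_conv"` (default), `"final"`, or `"s<i>"`.
#' @return list of `C x H' x W'` arrays, one per stream (named `stream_a`,
#'   `stream_b` for two-stream models, `stream` otherwise).
#' @export
activation_maps <- function(model, image, layer = "first_conv") {
  x <- aperm(image, c(3L, 1L, 2L))
  fw <- model_forward(model, x)
  scale01 <- function(mat, plan) {
    a <- array(mat, c(nrow(mat), plan$H_out, plan$W_out))
    for (c in seq_len(dim(a)[1])) {
      ch <- a[c, , ]
      rng <- range(ch)
      a[c, , ] <- if (diff(rng) > 0) (ch - rng[1]) / diff(rng) else ch * 0
    }
    a
  }
  if (model$type == "bcnn") {
    li <- resolve_layer(model$f_a, layer)
    pa <- model$f_a$plans[[li]]
    out <- list(stream_a = scale01(fw$bf_a$caches[[li]]$out, pa))
    if (model$shared) out$stream_b <- out$stream_a
    else {
      lib <- resolve_layer(model$f_b, layer)
      out$stream_b <- scale01(fw$bf_b$caches[[lib]]$out,
                              model$f_b$plans[[lib]])
    }
    out
  } else {
    li <- resolve_layer(model$f, layer)
    list(stream = scale01(fw$bf$caches[[li]]$out, model$f$plans[[li]]))
  }
}

#' Write a heatmap overlay PNG
#'
#' Blends the upsampled heatmap (red channel) over the image for human
#' inspection; the numeric grid is the object tests operate on.
#'
#' @param hm a `heatmap` from [grad_cam()].
#' @param image the `H x W x 3` input image.
#' @param path output PNG path.
#' @param alpha blend weight of the heatmap (default 0.5).
#' @return `path`, invisibly.
#' @export
write_heatmap_overlay <- function(hm, image, path, alpha = 0.5) {
  h <- hm$upsampled
  overlay <- image
  overlay[, , 1] <- (1 - alpha) * image[, , 1] + alpha * h
  overlay[, , 2] <- (1 - alpha) * image[, , 2]
  overlay[, , 3] <- (1 - alpha) * image[, , 3] + alpha * (1 - h)
  write_image(overlay, path)
}
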