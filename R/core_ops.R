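#' Construct a feature map
#'
#' A feature map is a 3-D numeric array with dimensions channels x height x
#' width, the intermediate representation produced by a convolutional
#' backbone and consumed by the pooling and attention operations.
#'
#' @param values numeric array of dim `c(C, H, W)`, or a matrix/vector that
#'   can be shaped with explicit `channels`, `height`, `width`.
#' @param channels,height,width optional dimensions when `values` is not
#'   already a 3-D array.
#' @return a numeric array of class `feature_map` with dim `c(C, H, W)`.
#' @examples
#' fm <- feature_map(array(rnorm(2 * 3 * 3), c(2, 3, 3)))
#' dim(fm)
#' @export
feature_map <- function(values, channels = NULL, height = NULL, width = NULL) {
  if (!is.null(channels)) {
    values <- array(as.numeric(values), c(channels, height, width))
  }
  if (length(dim(values)) != 3L)
    stop_dim("a feature map must be a 3-D array (channels x height x width)")
  if (any(dim(values) < 1L)) stop_dim("feature map dimensions must all be >= 1")
  check_finite(values, "feature map")
  structure(values, class = c("feature_map", class(array(0))))
}

as_cl_matrix <- function(fmap) {
  # channels x locations view; columns are per-location channel vectors
  d <- dim(fmap)
  matrix(fmap, nrow = d[1L], ncol = d[2L] * d[3L])
}

#' Bilinear pooling of two feature maps
#'
#' At every spatial location the outer product of the two channel vectors is
#' taken and the products are aggregated over all locations (sum-pooling by
#' default), yielding an orderless descriptor: no spatial information
#' survives the aggregation, so the descriptor is invariant to where in the
#' image the local patterns occurred.
#'
#' The `C_a x C_b` outer-product matrix is flattened row-major (the channel
#' index of `fmap_a` varies slowest), a convention that must stay fixed for
#' classifier weights to be reproducible.
#'
#' @param fmap_a,fmap_b feature maps with identical spatial dimensions
#'   (channel counts may differ).
#' @param pooling `"sum"` (default) or `"mean"` over spatial locations.
#' @return numeric vector of length `C_a * C_b` with attribute
#'   `stream_dims = c(C_a, C_b)`.
#' @seealso [bilinear_pool_fast()] for the single-stream variant.
#' @export
bilinear_pool <- function(fmap_a, fmap_b, pooling = c("sum", "mean")) {
  pooling <- match.arg(pooling)
  da <- dim(fmap_a); db <- dim(fmap_b)
  if (length(da) != 3L || length(db) != 3L)
    stop_dim("inputs must be 3-D arrays (channels x height x width)")
  if (!identical(da[2:3], db[2:3]))
    stop_dim("spatial dimensions differ: ", da[2], "x", da[3],
             " vs ", db[2], "x", db[3])
  check_finite(fmap_a, "fmap_a"); check_finite(fmap_b, "fmap_b")
  A <- as_cl_matrix(fmap_a)            # C_a x L
  B <- as_cl_matrix(fmap_b)            # C_b x L
  phi <- A %*% t(B)                    # sum over locations of outer products
  if (pooling == "mean") phi <- phi / (da[2L] * da[3L])
  structure(as.vector(t(phi)), stream_dims = c(da[1L], db[1L]))
}

#' Fast (single-stream) bilinear pooling
#'
#' Pools one feature map against itself: equivalent to [bilinear_pool()]
#' with both streams identical, so the reshaped `D x D` matrix is symmetric
#' positive semidefinite. This is the descriptor used by the fast bilinear
#' model, which needs only one backbone pass per image.
#'
#' @inheritParams bilinear_pool
#' @param fmap a feature map.
#' @return numeric vector of length `D^2` with `stream_dims = c(D, D)`.
#' @export
bilinear_pool_fast <- function(fmap, pooling = c("sum", "mean")) {
  pooling <- match.arg(pooling)
  bilinear_pool(fmap, fmap, pooling = pooling)
}

#' Signed square root
#'
#' Elementwise `sign(x) * sqrt(|x|)`: tempers the heavy-tailed magnitudes of
#' bilinear descriptors while preserving sign pattern and zeros.
#'
#' @param v finite numeric vector.
#' @return numeric vector of the same length.
#' @export
signed_sqrt <- function(v) {
  check_finite(v)
  sign(v) * sqrt(abs(v))
}

#' L2 normalization with an epsilon floor
#'
#' Divides by `max(||v||_2, eps)`; the floor makes the zero vector map to
#' itself instead of NaN.
#'
#' @param v finite numeric vector.
#' @param eps small positive floor on the norm (default `1e-12`).
#' @return numeric vector with unit L2 norm whenever `||v|| >= eps`.
#' @export
l2_normalize <- function(v, eps = 1e-12) {
  check_finite(v)
  v / max(sqrt(sum(v * v)), eps)
}

#' Squeeze: global average pooling of a feature map
#'
#' Integrates each `H x W` channel plane into a single descriptor value,
#' the first stage of the squeeze-and-excitation attention block.
#'
#' @param fmap a feature map (C x H x W array).
#' @return numeric vector of length C.
#' @export
se_squeeze <- function(fmap) {
  d <- dim(fmap)
  if (length(d) != 3L) stop_dim("se_squeeze expects a 3-D array")
  if (d[2L] < 1L || d[3L] < 1L) stop_dim("empty spatial extent")
  rowMeans(as_cl_matrix(fmap))
}

#' Create squeeze-and-excitation gate parameters
#'
#' Two bias-free fully connected layers: `C -> C/r` (ReLU) then `C/r -> C`
#' (sigmoid). `r` is the reduction ratio and must divide `C`. By default
#' weights are He-uniform initialized; pass `init = "zero"` for a gate that
#' outputs a constant 0.5.
#'
#' @param channels number of channels C.
#' @param reduction_ratio positive integer r dividing C (default 16, the
#'   original squeeze-and-excitation convention).
#' @param init `"he"` or `"zero"`.
#' @param seed integer seed for the He draw.
#' @return list with `W1` (C/r x C), `W2` (C x C/r), `reduction_ratio`.
#' @export
se_params <- function(channels, reduction_ratio = 16L, init = c("he", "zero"),
                      seed = 1L) {
  init <- match.arg(init)
  r <- as.integer(reduction_ratio)
  if (r < 1L || channels %% r != 0L)
    stop_val("reduction ratio ", r, " must divide channel count ", channels)
  hidden <- channels %/% r
  if (init == "zero") {
    W1 <- matrix(0, hidden, channels)
    W2 <- matrix(0, channels, hidden)
  } else {
    # W1 nonnegative: squeezed descriptors are nonnegative after ReLU
    # stages, so this guarantees live gate units at initialization (a
    # symmetric draw can leave every hidden unit dead when C/r is small).
    W1 <- with_seed(seed, abs(he_uniform(hidden, channels)))
    W2 <- with_seed(seed + 1L, he_uniform(channels, hidden))
  }
  list(W1 = W1, W2 = W2, reduction_ratio = r)
}

#' Excitation: channel gate from a squeezed descriptor
#'
#' Computes `sigmoid(W2 %*% relu(W1 %*% s))`. Every output lies strictly in
#' (0, 1); with zero weights the gate is constant 0.5.
#'
#' @param s numeric channel descriptor, length C.
#' @param params gate parameters from [se_params()].
#' @return numeric vector of per-channel weights in (0, 1).
#' @export
se_excite <- function(s, params) {
  if (ncol(params$W1) != length(s))
    stop_dim("descriptor length ", length(s), " does not match W1 columns ",
             ncol(params$W1))
  if (!identical(dim(params$W2), rev(dim(params$W1))))
    stop_dim("W2 must have the transposed shape of W1")
  h <- pmax(params$W1 %*% s, 0)
  as.vector(1 / (1 + exp(-(params$W2 %*% h))))
}

#' Recalibrate a feature map by per-channel weights
#'
#' Multiplies channel c of the map by `e[c]`; shape is preserved. With unit
#' weights this is the identity.
#'
#' @param fmap a feature map (C x H x W).
#' @param e numeric vector of length C.
#' @return feature map of the same shape.
#' @export
se_apply <- function(fmap, e) {
  d <- dim(fmap)
  if (length(d) != 3L) stop_dim("se_apply expects a 3-D array")
  if (length(e) != d[1L])
    stop_dim("weight length ", length(e), " does not match channels ", d[1L])
  array(as.vector(fmap) * as.vector(e), d)
}
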