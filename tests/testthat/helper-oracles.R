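# Independent oracles, written before the implementations they check.

# Triple loop over channel pairs and locations: the defining computation of
# bilinear pooling, deliberately naive.
oracle_bilinear <- function(fa, fb, pooling = "sum") {
  Ca <- dim(fa)[1]; Cb <- dim(fb)[1]
  H <- dim(fa)[2]; W <- dim(fa)[3]
  out <- numeric(Ca * Cb)
  for (a in seq_len(Ca)) for (b in seq_len(Cb)) {
    s <- 0
    for (i in seq_len(H)) for (j in seq_len(W)) s <- s + fa[a, i, j] * fb[b, i, j]
    out[(a - 1) * Cb + b] <- if (pooling == "mean") s / (H * W) else s
  }
  out
}

# Pairwise-concordance AUC: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc_concordance <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  if (length(sp) == 0L || length(sn) == 0L) return(NA_real_)
  tot <- 0
  for (p in sp) for (q in sn) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# Scalar evaluation of the excitation gate sigma(W2 relu(W1 s)).
oracle_se_excite <- function(s, W1, W2) {
  hidden <- numeric(nrow(W1))
  for (i in seq_len(nrow(W1))) {
    acc <- 0
    for (j in seq_len(ncol(W1))) acc <- acc + W1[i, j] * s[j]
    hidden[i] <- max(acc, 0)
  }
  out <- numeric(nrow(W2))
  for (i in seq_len(nrow(W2))) {
    acc <- 0
    for (j in seq_len(ncol(W2))) acc <- acc + W2[i, j] * hidden[j]
    out[i] <- 1 / (1 + exp(-acc))
  }
  out
}

# Mean silhouette width over points, computed by definition.
silhouette_score <- function(coords, labels) {
  D <- as.matrix(dist(coords))
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]; same[i] <- FALSE
    a <- mean(D[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

rand_fmap <- function(C, H, W, sd = 1) {
  array(stats::rnorm(C * H * W, sd = sd), c(C, H, W))
}

tiny_backbone <- function(seed = 1L, D = 8L, input = 16L, widths = c(4L, 8L, D),
                          se = FALSE) {
  build_backbone(backbone_spec("tiny", output_channels = D, input_size = input,
                               widths = widths, se_blocks = se, seed = seed))
}

rand_image <- function(size, seed) {
  fastbcnn:::with_seed(seed, array(stats::runif(size * size * 3), c(size, size, 3L)))
}
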