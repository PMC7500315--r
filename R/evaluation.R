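#' Evaluate a classifier on labeled records
#'
#' Computes overall and per-class accuracy, the confusion matrix, and
#' one-vs-rest ROC/AUC from the model's softmax scores. Deterministic given
#' the model and records; the confusion matrix and accuracy are consistent
#' by construction (`accuracy = trace / total`).
#'
#' @param model a model with a [predict()] method returning class
#'   probabilities.
#' @param records manifest rows with labels drawn from the model's class
#'   set.
#' @param class_names label set (default: the model's `class_names`).
#' @return an `evaluation_report`: `accuracy`, `per_class_accuracy`,
#'   `confusion` (true class in rows), `roc` (per-class FPR/TPR points),
#'   `auc` (per-class), `macro_auc`, and the score matrix `scores`.
#' @export
evaluate <- function(model, records, class_names = NULL) {
  if (nrow(records) == 0L) stop_val("no records to evaluate")
  class_names <- class_names %||% model$class_names
  labels <- manifest_labels(records)
  if (!all(labels %in% class_names))
    stop_val("label(s) outside the model's class set: ",
             paste(setdiff(labels, class_names), collapse = ", "))
  imgs <- if (inherits(model, "fb_model"))
    load_preprocessed(records$path, model$input_size)
  else lapply(records$path, preprocess, size = 64L)
  scores <- predict(model, imgs)
  colnames(scores) <- class_names
  pred <- class_names[max.col(scores, ties.method = "first")]
  K <- length(class_names)
  confusion <- matrix(0L, K, K, dimnames = list(true = class_names,
                                                predicted = class_names))
  for (i in seq_along(labels))
    confusion[labels[i], pred[i]] <- confusion[labels[i], pred[i]] + 1L
  acc <- sum(diag(confusion)) / sum(confusion)
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1L)
  roc <- roc_curves(scores, labels, class_names = class_names)
  structure(list(accuracy = acc, per_class_accuracy = per_class,
                 confusion = confusion, roc = roc$curves, auc = roc$auc,
                 macro_auc = roc$macro_auc, scores = scores,
                 labels = labels),
            class = "evaluation_report")
}

#' One-vs-rest ROC curves and AUC
#'
#' For every class, sweeps a threshold over that class's score column
#' against the binary "is this class" labels, producing monotone FPR/TPR
#' sequences; AUC is the area under the curve by the trapezoidal rule.
#' Classes with no positive or no negative examples have an undefined AUC,
#' reported as `NA` and excluded from the macro average.
#'
#' @param scores `n x K` matrix of class scores (e.g. softmax rows).
#' @param labels character vector of true labels, length n.
#' @param class_names class order; default the score column names.
#' @return list with `curves` (per-class data.frames of `fpr`, `tpr`),
#'   `auc` (named vector) and `macro_auc`.
#' @export
roc_curves <- function(scores, labels, class_names = colnames(scores)) {
  if (is.null(class_names))
    class_names <- paste0("class", seq_len(ncol(scores)))
  curves <- list(); auc <- stats::setNames(rep(NA_real_, length(class_names)),
                                           class_names)
  for (k in seq_along(class_names)) {
    pos <- labels == class_names[k]
    s <- scores[, k]
    P <- sum(pos); N <- sum(!pos)
    ord <- order(s, decreasing = TRUE)
    tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
    keep <- c(diff(s[ord]) != 0, TRUE)   # one point per distinct threshold
    if (P == 0L || N == 0L) {
      curves[[class_names[k]]] <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
      next
    }
    fpr <- c(0, fp[keep] / N); tpr <- c(0, tp[keep] / P)
    curves[[class_names[k]]] <- data.frame(fpr = fpr, tpr = tpr)
    auc[k] <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  list(curves = curves, auc = auc,
       macro_auc = if (all(is.na(auc))) NA_real_ else mean(auc, na.rm = TRUE))
}

#' Pre-softmax features for embedding
#'
#' Returns the activations of the last fully connected layer (the class
#' logits) per image, in record order — the representation visualized by
#' the t-SNE plots.
#'
#' @param model a trained model.
#' @param records manifest rows (or a list of preprocessed images).
#' @return `n x n_classes` numeric matrix.
#' @export
extract_embedding_features <- function(model, records) {
  imgs <- if (is.data.frame(records))
    load_preprocessed(records$path, model$input_size)
  else as_image_list(records)
  t(vapply(imgs, function(img)
    model_forward(model, aperm(img, c(3L, 1L, 2L)))$hf$logits,
    numeric(model$n_classes)))
}

#' 2-D t-SNE embedding
#'
#' A compact exact t-SNE (perplexity-calibrated Gaussian affinities, early
#' exaggeration, momentum gradient descent on the Kullback-Leibler
#' divergence), O(n^2) per iteration — a visualization utility for the
#' modest sample counts this package handles. Fully seeded.
#'
#' @param features `n x d` numeric matrix.
#' @param seed integer seed for the initial layout.
#' @param perplexity target perplexity (default 30, capped at `(n - 1) / 3`).
#' @param max_iter gradient-descent iterations (default 400).
#' @return list with `coords` (`n x 2`), `seed`, `perplexity`.
#' @export
tsne_embed <- function(features, seed = 1L, perplexity = 30, max_iter = 400L) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 8L) stop_val("too few samples for t-SNE (need at least 8)")
  perplexity <- min(perplexity, (n - 1) / 3)
  D <- as.matrix(stats::dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (it in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - target) < 1e-6) break
      if (H > target) { lo <- beta; beta <- if (hi < 1e19) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- w / sw
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    V <- matrix(0, n, 2)
    for (iter in seq_len(max_iter)) {
      Pe <- if (iter <= 100L) P * 12 else P
      sq <- rowSums(Y^2)
      num <- 1 / (1 + outer(sq, sq, `+`) - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      mom <- if (iter <= 250L) 0.5 else 0.8
      V <- mom * V - 200 * grad
      Y <- Y + V
      Y <- sweep(Y, 2, colMeans(Y))
    }
    list(coords = Y, seed = seed, perplexity = perplexity)
  })
}

#' Measure single-image inference throughput
#'
#' Wall-clock frames per second of single-image forward passes (batch size
#' 1) after a warm-up, reported as the median over trials. Hardware- and
#' load-dependent: informational only, never a correctness measure.
#'
#' @param model a model.
#' @param n_frames frames per trial (default 20).
#' @param warmup warm-up frames (default 10).
#' @param trials number of trials (default 5).
#' @return frames per second (median across trials).
#' @export
measure_fps <- function(model, n_frames = 20L, warmup = 10L, trials = 5L) {
  if (n_frames < 1L) stop_val("n_frames must be >= 1")
  img <- array(0.5, c(model$input_size, model$input_size, 3L))
  x <- aperm(img, c(3L, 1L, 2L))
  for (i in seq_len(warmup)) model_forward(model, x)
  fps <- vapply(seq_len(trials), function(t) {
    el <- system.time(for (i in seq_len(n_frames)) model_forward(model, x))[["elapsed"]]
    n_frames / max(el, 1e-9)
  }, numeric(1))
  stats::median(fps)
}
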