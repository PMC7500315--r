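#' Training configuration
#'
#' The optimization protocol: mini-batch stochastic gradient descent with a
#' plateau-based learning-rate schedule — whenever the training loss has
#' failed to improve for `lr_patience_epochs` consecutive epochs the
#' learning rate is multiplied by `lr_factor`. Defaults mirror the
#' full-scale protocol (initial rate 0.1, batch 16, factor 0.1, patience
#' 10); desk-scale experiments in this package's tests use a profile with
#' `initial_lr = 0.01` and few epochs.
#'
#' @param initial_lr initial learning rate (default 0.1).
#' @param batch_size mini-batch size (default 16).
#' @param lr_factor multiplicative decay on plateau, in (0, 1) (default 0.1).
#' @param lr_patience_epochs epochs without improvement before decay
#'   (default 10).
#' @param max_epochs maximum number of epochs (default 100).
#' @param min_lr training stops once the rate would fall below this
#'   (default 1e-5).
#' @param momentum SGD momentum (default 0).
#' @param seed master seed for shuffling, initialization draws and
#'   augmentation.
#' @param pretrained request ImageNet-pretrained backbone weights (see
#'   [load_pretrained()]).
#' @param augment optional [augment_params()] applied on the fly to
#'   training images (`NULL` = no augmentation).
#' @return a `train_config` list.
#' @export
train_config <- function(initial_lr = 0.1, batch_size = 16L, lr_factor = 0.1,
                         lr_patience_epochs = 10L, max_epochs = 100L,
                         min_lr = 1e-5, momentum = 0, seed = 1L,
                         pretrained = FALSE, augment = NULL) {
  if (lr_factor <= 0 || lr_factor >= 1) stop_val("lr_factor must be in (0, 1)")
  if (lr_patience_epochs < 1L) stop_val("lr_patience_epochs must be >= 1")
  if (batch_size < 1L) stop_val("batch_size must be >= 1")
  structure(list(optimizer = "sgd", initial_lr = initial_lr,
                 batch_size = as.integer(batch_size), lr_factor = lr_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 max_epochs = as.integer(max_epochs), min_lr = min_lr,
                 momentum = momentum, seed = as.integer(seed),
                 pretrained = isTRUE(pretrained), augment = augment),
            class = "train_config")
}

#' Read a training config from YAML
#' @param path YAML file with fields matching [train_config()].
#' @return a `train_config`.
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$augment)) y$augment <- do.call(augment_params, y$augment)
  do.call(train_config, y)
}

# Plateau scheduler step: returns the updated schedule state.
plateau_step <- function(state, loss, config) {
  if (loss < state$best - 1e-10) {
    state$best <- loss
    state$since <- 0L
  } else {
    state$since <- state$since + 1L
    if (state$since >= config$lr_patience_epochs) {
      state$lr <- state$lr * config$lr_factor
      state$since <- 0L
    }
  }
  state
}

load_preprocessed <- function(paths, size) {
  cache <- new.env(parent = emptyenv())
  for (p in unique(paths)) assign(p, preprocess(p, size), envir = cache)
  lapply(paths, function(p) get(p, envir = cache))
}

#' Train a model by mini-batch SGD
#'
#' Minimizes categorical cross-entropy on the model's softmax outputs with
#' the protocol described in [train_config()]. Fully seeded: the same
#' config, model and records give an identical history. Aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param model a model from [assemble_fast_bcnn()], [assemble_bcnn()] or
#'   [assemble_gap_cnn()].
#' @param train_records manifest rows used for training (typically
#'   oversampled).
#' @param val_records optional manifest rows used only to report per-epoch
#'   held-out accuracy (must be disjoint from training rows).
#' @param config a [train_config()].
#' @param class_names fixed class label set; defaults to the sorted unique
#'   training labels.
#' @return list with `model` (trained) and `history` (data.frame of epoch,
#'   train_loss, val_accuracy, lr).
#' @export
train_model <- function(model, train_records, val_records = NULL,
                        config = train_config(), class_names = NULL) {
  if (!inherits(model, "fb_model")) {
    # non-trainable reference models (e.g. constant baselines) pass through
    return(list(model = model,
                history = data.frame(epoch = integer(), train_loss = numeric(),
                                     val_accuracy = numeric(), lr = numeric())))
  }
  if (nrow(train_records) == 0L) stop_val("empty training set")
  labels <- manifest_labels(train_records)
  class_names <- class_names %||% sort(unique(labels))
  if (length(class_names) != model$n_classes)
    stop_val("model has ", model$n_classes, " classes but data has ",
             length(class_names))
  model$class_names <- class_names
  y <- match(labels, class_names)
  if (anyNA(y)) stop_val("training label outside the model's class set")
  if (!is.null(val_records) &&
      length(intersect(rownames(train_records), rownames(val_records))))
    stop_val("train and validation records overlap")

  imgs <- load_preprocessed(train_records$path, model$input_size)
  val_imgs <- if (!is.null(val_records))
    load_preprocessed(val_records$path, model$input_size)
  val_y <- if (!is.null(val_records))
    match(manifest_labels(val_records), class_names)

  n <- length(imgs)
  params <- model_params(model)
  vel <- lapply(params, function(p) p * 0)
  sched <- list(lr = config$initial_lr, best = Inf, since = 0L)
  hist <- list()

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      if (sched$lr < config$min_lr) break
      ord <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        gacc <- NULL
        for (i in idx) {
          img <- imgs[[i]]
          if (!is.null(config$augment))
            img <- augment(img, config$augment,
                           rng = sample.int(.Machine$integer.max, 1L))
          fw <- model_forward(model, aperm(img, c(3L, 1L, 2L)))
          p <- fw$hf$p
          loss_i <- -log(max(p[y[i]], 1e-12))
          if (!is.finite(loss_i))
            stop_val("non-finite loss at epoch ", epoch, "; aborting")
          epoch_loss <- epoch_loss + loss_i
          dlogits <- p
          dlogits[y[i]] <- dlogits[y[i]] - 1
          g <- model_backward(model, fw, dlogits)$grads
          if (is.null(gacc)) gacc <- lapply(g, function(x) x / length(idx))
          else for (nm in names(g)) gacc[[nm]] <- gacc[[nm]] + g[[nm]] / length(idx)
        }
        for (nm in names(params)) {
          vel[[nm]] <- config$momentum * vel[[nm]] - sched$lr * gacc[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
        model <- set_model_params(model, params)
      }
      epoch_loss <- epoch_loss / n
      val_acc <- NA_real_
      if (!is.null(val_records)) {
        probs <- predict(model, val_imgs)
        val_acc <- mean(max.col(probs) == val_y)
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = epoch_loss,
                                  val_accuracy = val_acc, lr = sched$lr)
      sched <- plateau_step(sched, epoch_loss, config)
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

#' k-fold cross-validation
#'
#' Trains `k` independent models from fresh initializations, one per fold:
#' each is trained on the other `k - 1` folds (oversampled to class balance
#' inside the training split only) and evaluated on the held-out fold.
#'
#' @param manifest dataset manifest.
#' @param model_factory `function(seed)` returning a freshly initialized
#'   model.
#' @param config a [train_config()].
#' @param k number of folds (default 5).
#' @param folds optional precomputed fold assignment from [make_folds()].
#' @return a `cv_result` list: `fold_accuracy` (length k), `mean_accuracy`,
#'   `se` (standard error over folds), `folds`.
#' @export
cross_validate <- function(manifest, model_factory, config = train_config(),
                           k = 5L, folds = NULL) {
  folds <- folds %||% make_folds(manifest, k = k, seed = config$seed)
  class_names <- sort(unique(manifest_labels(manifest)))
  accs <- numeric(k)
  for (f in seq_len(k)) {
    test <- manifest[folds == f, , drop = FALSE]
    train <- manifest[folds != f, , drop = FALSE]
    attr(train, "task") <- attr(test, "task") <- attr(manifest, "task")
    train <- oversample(train, seed = config$seed + f)
    cfg <- config
    cfg$seed <- config$seed + 1000L * f
    model <- model_factory(cfg$seed)
    fit <- train_model(model, train, config = cfg, class_names = class_names)
    rep <- evaluate(fit$model, test, class_names = class_names)
    accs[f] <- rep$accuracy
  }
  structure(list(fold_accuracy = accs, mean_accuracy = mean(accs),
                 se = stats::sd(accs) / sqrt(k), folds = folds, k = k),
            class = "cv_result")
}

#' Expand explicit hyperparameter lists into a config sweep
#'
#' Grid search over training hyperparameters is expressed as explicit value
#' lists; this helper expands them into one [train_config()] per
#' combination, to be run through [cross_validate()] and compared on mean
#' fold accuracy. No search heuristic is involved.
#'
#' @param ... named vectors of candidate values for [train_config()] fields
#'   (e.g. `initial_lr = c(0.1, 0.01), batch_size = c(8, 16)`).
#' @param base a [train_config()] supplying all unswept fields.
#' @return a list of `train_config` objects, one per grid point, each
#'   carrying a `grid_point` attribute with its combination.
#' @export
config_grid <- function(..., base = train_config()) {
  grid <- expand.grid(..., KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][i]
    attr(cfg, "grid_point") <- as.list(grid[i, , drop = FALSE])
    cfg
  })
}

#' Load ImageNet-pretrained backbone weights
#'
#' Transfer initialization for the standard backbones. No deep-learning
#' runtime with published ImageNet weights is available in this
#' installation, so this function always raises an explicit error rather
#' than silently falling back to random initialization; the tiny backbone
#' does not support pretraining at all.
#'
#' @param spec a [backbone_spec()].
#' @return (never returns here; errors as described)
#' @export
load_pretrained <- function(spec) {
  if (spec$name == "tiny")
    stop_val("the tiny backbone has no pretrained weights; use init = 'random'")
  stop_val("ImageNet weights for '", spec$name, "' require a deep-learning ",
           "runtime with a local weight cache; none is installed. Train ",
           "from random initialization or provide such a runtime offline.")
}
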