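# Small shared synthetic datasets, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

mini_dataset <- function(n_classes = 2L, images_per_class = 10L,
                         image_size = 16L, key = NULL) {
  key <- key %||% paste("mini", n_classes, images_per_class, image_size,
                        sep = "_")
  if (!exists(key, envir = .fixture_env)) {
    cfg <- synthetic_config(n_classes = n_classes,
                            images_per_class = images_per_class,
                            image_size = image_size, scales = 100L,
                            n_motifs = 8L, motif_radius = 3L, seed = 42L)
    man <- generate_synthetic_dataset(cfg, tempfile("mini"))
    attr(man, "task") <- "fine_grained"
    assign(key, man, envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dummy_model <- function(probs, class_names) {
  structure(list(probs = probs, class_names = class_names,
                 n_classes = length(probs)),
            class = "dummy_model")
}

predict.dummy_model <- function(object, images, ...) {
  matrix(object$probs, length(images), length(object$probs), byrow = TRUE)
}

registerS3method("predict", "dummy_model", predict.dummy_model,
                 envir = asNamespace("stats"))
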