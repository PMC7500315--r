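#' Default per-class motif definitions
#'
#' Produces up to eight pairwise-distinct texture motif parameter sets.
#' Classes differ in the local texture painted inside each motif (stripe
#' orientation, spot lattices, wavelength), never in where motifs sit: the
#' class signal is location-free by construction, which is exactly the
#' inductive bias orderless bilinear pooling is meant to exploit.
#'
#' @param n_classes number of classes (2 to 8).
#' @return list of motif definitions (`type`, `theta` in degrees,
#'   `wavelength` in pixels, `color`, `color_jitter`).
#' @export
default_motifs <- function(n_classes) {
  defs <- list(
    list(type = "stripe", theta = 0,   wavelength = 6),
    list(type = "stripe", theta = 90,  wavelength = 6),
    list(type = "stripe", theta = 45,  wavelength = 6),
    list(type = "spots",  theta = 0,   wavelength = 7),
    list(type = "stripe", theta = 135, wavelength = 6),
    list(type = "stripe", theta = 0,   wavelength = 10),
    list(type = "spots",  theta = 0,   wavelength = 12),
    list(type = "stripe", theta = 90,  wavelength = 10))
  if (n_classes < 2L || n_classes > 8L) stop_val("n_classes must be in 2..8")
  lapply(defs[seq_len(n_classes)], function(d) {
    d$color <- c(0.80, 0.55, 0.88)   # bright stain on a dark field
    d$color_jitter <- 0.05
    d
  })
}

#' Synthetic dataset configuration
#'
#' Describes a seeded generator of histology-styled RGB texture images:
#' brightly "stained" textured disks on a dark field, emulating localized
#' tissue structures whose texture — not their position — carries class
#' identity. Each image holds `n_motifs` motif disks at positions uniform
#' over the whole image; the texture inside the disks (stripe orientation,
#' spot lattice, wavelength) identifies the class, while motif color,
#' density and placement statistics are identical across classes. `scales`
#' are pseudo-magnifications: motif radius and texture wavelength are
#' multiplied by `scale / 100`, emulating the same structure imaged at
#' different magnification factors.
#'
#' @param n_classes number of classes (2 to 8; default 4).
#' @param images_per_class images generated per class (spread evenly over
#'   scales).
#' @param image_size square image side in pixels (default 64).
#' @param motifs per-class motif definitions; default [default_motifs()].
#' @param scales integer pseudo-magnifications (default `c(100, 200, 400)`).
#' @param n_motifs motifs per image (default 12).
#' @param motif_radius base motif radius in pixels at scale 100 (default 5).
#' @param noise_sd additive Gaussian pixel noise (default 0.03).
#' @param seed integer master seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_classes = 4L, images_per_class = 40L,
                             image_size = 64L, motifs = NULL,
                             scales = c(100L, 150L, 200L), n_motifs = 60L,
                             motif_radius = 8, noise_sd = 0.02, seed = 1L) {
  motifs <- motifs %||% default_motifs(n_classes)
  if (length(motifs) != n_classes)
    stop_val("need one motif definition per class")
  keys <- vapply(motifs, function(m)
    paste(m$type, m$theta, m$wavelength, sep = "|"), character(1))
  if (anyDuplicated(keys))
    stop_val("motif parameter sets must be pairwise distinct across classes")
  structure(list(n_classes = as.integer(n_classes),
                 images_per_class = as.integer(images_per_class),
                 image_size = as.integer(image_size), motifs = motifs,
                 scales = as.integer(scales), n_motifs = as.integer(n_motifs),
                 motif_radius = motif_radius, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate one synthetic texture image
#'
#' @param motif a per-class motif definition (see [default_motifs()]).
#' @param image_size square side in pixels.
#' @param scale pseudo-magnification (motif radius scales as `scale / 100`).
#' @param n_motifs number of motifs.
#' @param motif_radius base radius at scale 100.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed; the same seed gives a bitwise-identical image.
#' @return list with `image` (`size x size x 3` in `[0, 1]`) and `motifs`
#'   (data.frame of center coordinates `cy`, `cx` and radius `r`).
#' @export
generate_synthetic_image <- function(motif, image_size = 64L, scale = 100L,
                                     n_motifs = 60L, motif_radius = 8,
                                     noise_sd = 0.02, seed = 1L) {
  S <- image_size
  r <- motif_radius * scale / 100
  with_seed(seed, {
    yy <- matrix(seq_len(S), S, S)
    xx <- matrix(seq_len(S), S, S, byrow = TRUE)
    # dark field with slow illumination drift; keeping the background low
    # leaves the rectified conv features dominated by motif texture rather
    # than by a constant illumination response
    phase <- stats::runif(2, 0, 2 * pi)
    drift <- 0.02 * sin(2 * pi * yy / S + phase[1]) *
                    cos(2 * pi * xx / S + phase[2])
    base <- c(0.12, 0.09, 0.13)
    img <- array(0, c(S, S, 3L))
    for (ch in 1:3) img[, , ch] <- base[ch] + drift
    centers <- data.frame(cy = stats::runif(n_motifs, 1, S),
                          cx = stats::runif(n_motifs, 1, S), r = r)
    th <- motif$theta * pi / 180
    lam <- motif$wavelength * scale / 100
    col0 <- motif$color + stats::runif(3, -motif$color_jitter,
                                       motif$color_jitter)
    for (m in seq_len(n_motifs)) {
      dy <- yy - centers$cy[m]; dx <- xx - centers$cx[m]
      dist <- sqrt(dy^2 + dx^2)
      alpha <- pmin(pmax((r - dist) / 1.5, 0), 1)   # soft-edged disk
      if (all(alpha == 0)) next
      pat <- if (motif$type == "stripe") {
        0.5 + 0.5 * sin(2 * pi * (dx * cos(th) + dy * sin(th)) / lam)
      } else {
        0.5 + 0.5 * sin(2 * pi * dx / lam) * sin(2 * pi * dy / lam)
      }
      inten <- 0.10 + 0.90 * pat
      for (ch in 1:3) {
        tgt <- col0[ch] * inten
        img[, , ch] <- img[, , ch] * (1 - alpha) + tgt * alpha
      }
    }
    img <- img + array(stats::rnorm(S * S * 3L, 0, noise_sd), c(S, S, 3L))
    list(image = pmin(pmax(img, 0), 1), motifs = centers)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes PNG images in the directory schema understood by [scan_layout()]
#' (`out_dir/<class>/<class>/<scale>X/img_###.png`) plus a `manifest.csv`.
#' Images per class are dealt round-robin over the configured scales. Fully
#' deterministic: the same config yields byte-identical files.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return the dataset manifest (invisibly also written as
#'   `out_dir/manifest.csv`).
#' @export
generate_synthetic_dataset <- function(cfg, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_val("cannot create output directory ", out_dir)
  class_names <- sprintf("texclass%d", seq_len(cfg$n_classes))
  recs <- list()
  for (ci in seq_len(cfg$n_classes)) {
    for (ii in seq_len(cfg$images_per_class)) {
      scale <- cfg$scales[((ii - 1L) %% length(cfg$scales)) + 1L]
      dir <- file.path(out_dir, class_names[ci], class_names[ci],
                       paste0(scale, "X"))
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      seed_i <- cfg$seed + 7919L * ci + 17L * ii
      g <- generate_synthetic_image(cfg$motifs[[ci]], cfg$image_size, scale,
                                    cfg$n_motifs, cfg$motif_radius,
                                    cfg$noise_sd, seed = seed_i)
      path <- file.path(dir, sprintf("img_%03d.png", ii))
      write_image(g$image, path)
      recs[[length(recs) + 1L]] <- data.frame(
        path = path, class = class_names[ci], subclass = class_names[ci],
        magnification = scale,
        slide_id = sprintf("%s_s%02d", class_names[ci], ii %% 10L),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, recs)
  manifest <- manifest[order(manifest$path), , drop = FALSE]
  rownames(manifest) <- NULL
  attr(manifest, "task") <- "fine_grained"
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a synthetic config from YAML
#'
#' @param path YAML file with fields matching [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(synthetic_config, y)
}
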