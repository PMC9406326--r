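#' Dataset generation profile
#'
#' Describes a synthetic two-class image dataset: class counts (mirroring
#' the class imbalance of the clinical datasets, e.g. 1621/374, 160/40,
#' 320/141), image side length, a separability knob in `[0, 1]` scaling
#' every between-class difference (0 means the two class-generating
#' distributions are identical), and the generation seed.
#'
#' @param name Dataset identifier.
#' @param n_normal,n_abnormal Class counts (label 0 / label 1), `>= 0`.
#' @param image_size Side length in pixels, `>= 8` (default 224).
#' @param separability Between-class effect size in `[0, 1]`.
#' @param seed Integer seed; regeneration is bit-identical.
#' @return An object of class `"dataset_profile"`.
#' @export
dataset_profile <- function(name, n_normal, n_abnormal, image_size = 224,
                            separability = 0.8, seed = 1) {
  if (!is.numeric(image_size) || image_size < 8) {
    stop("invalid profile: image_size must be >= 8")
  }
  if (n_normal < 0 || n_abnormal < 0) {
    stop("invalid profile: class counts must be >= 0")
  }
  if (separability < 0 || separability > 1) {
    stop("invalid profile: separability must lie in [0, 1]")
  }
  structure(list(name = as.character(name),
                 n_normal = as.integer(n_normal),
                 n_abnormal = as.integer(n_abnormal),
                 image_size = as.integer(image_size),
                 separability = as.numeric(separability),
                 seed = as.integer(seed)),
            class = "dataset_profile")
}

.new_manifest <- function(images, labels, profile, kind) {
  structure(list(images = images, labels = as.integer(labels),
                 profile = profile, kind = kind),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("<dataset_manifest> ", x$profile$name, " (", x$kind, "): ",
      sum(x$labels == 0), " normal / ", sum(x$labels == 1), " abnormal, ",
      x$profile$image_size, "px, separability ", x$profile$separability,
      "\n", sep = "")
  invisible(x)
}

.clip8 <- function(x) round(pmin(pmax(x, 0), 255))

# Smooth 0..1 ramp over [0, 1] used for soft region edges.
.smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

.lesion_image <- function(S, abnormal, sep) {
  xg <- matrix(seq_len(S), S, S)           # row (y) coordinate
  yg <- t(xg)                              # column (x) coordinate
  # textured skin background: base tone + low-frequency field + pixel noise
  base <- c(196, 158, 140)
  ang <- stats::runif(1, 0, pi)
  fr <- stats::runif(1, 0.5, 1.5) / S
  ph <- stats::runif(1, 0, 2 * pi)
  field <- 8 * cos(2 * pi * fr * (cos(ang) * xg + sin(ang) * yg) + ph)
  # lesion geometry: abnormal cases drift off-centre and grow an irregular
  # boundary; both effects scale with separability
  off_r <- if (abnormal) sep * 0.10 * S * stats::runif(1, 0.5, 1) else 0
  off_a <- stats::runif(1, 0, 2 * pi)
  cx <- S / 2 + off_r * cos(off_a) + stats::rnorm(1, 0, 0.02 * S)
  cy <- S / 2 + off_r * sin(off_a) + stats::rnorm(1, 0, 0.02 * S)
  r0 <- 0.22 * S * stats::runif(1, 0.85, 1.15)
  irr <- 0.04 + (if (abnormal) 0.45 * sep else 0)
  theta <- atan2(yg - cy, xg - cx)
  rb <- r0
  for (h in 2:6) {
    rb <- rb + r0 * stats::rnorm(1, 0, irr / h) * cos(h * theta +
                                                      stats::runif(1, 0, 2 * pi))
  }
  dist <- sqrt((xg - cx)^2 + (yg - cy)^2)
  mask <- .smoothstep((rb - dist) / 1.5)
  # interior tone: uniform for normal lesions; abnormal lesions gain a
  # multi-tone pigment field and darken overall (variegated, hyperpigmented)
  tone_mod <- if (abnormal && sep > 0) {
    ta <- stats::runif(1, 0, pi)
    tf <- stats::runif(1, 1.5, 3) / S
    tp <- stats::runif(1, 0, 2 * pi)
    1 - 0.25 * sep +
      0.35 * sep * sin(2 * pi * tf * (cos(ta) * xg + sin(ta) * yg) + tp)
  } else 1
  img <- array(0, c(S, S, 3))
  for (ch in 1:3) {
    bg <- base[ch] + field + stats::rnorm(S * S, 0, 6)
    lesion <- base[ch] * 0.45 * tone_mod
    img[, , ch] <- .clip8(bg * (1 - mask) + lesion * mask)
  }
  img
}

#' Generate a synthetic dermoscopy-like lesion dataset
#'
#' Two-class images of a central pigmented region on textured skin: class 0
#' lesions are near-elliptical with a smooth boundary and uniform tone;
#' class 1 lesions add boundary irregularity (radial harmonics), centroid
#' offset (asymmetry) and a multi-tone interior, each scaled by the
#' profile's `separability`. Three channels, 8-bit values in `[0, 255]`.
#'
#' @param profile A [dataset_profile()].
#' @return A `dataset_manifest`: `images` (list of `S x S x 3` arrays),
#'   `labels` (0/1 in profile order: normals first), `profile`.
#' @export
generate_lesion_dataset <- function(profile) {
  stopifnot(inherits(profile, "dataset_profile"))
  labels <- c(rep(0L, profile$n_normal), rep(1L, profile$n_abnormal))
  images <- with_seed(profile$seed, {
    lapply(labels, function(lab) {
      .lesion_image(profile$image_size, lab == 1L, profile$separability)
    })
  })
  .new_manifest(images, labels, profile, "lesion")
}

.scalogram_image <- function(S, abnormal, sep) {
  tg <- matrix(seq_len(S), S, S, byrow = TRUE)  # time (column) coordinate
  fg <- matrix(seq_len(S), S, S)                # frequency (row) coordinate
  period <- S / 3.2
  t0 <- stats::runif(1, 0, period)
  amp <- 170 * stats::runif(1, 0.85, 1.15)
  img <- matrix(18, S, S)
  centers <- seq(t0, S + period, by = period)
  gaus <- function(tc, fc, st, sf, a) {
    a * exp(-((tg - tc)^2 / (2 * st^2) + (fg - fc)^2 / (2 * sf^2)))
  }
  for (tc in centers) {
    # S1 and S2: low-frequency energy bursts in every cardiac cycle
    img <- img + gaus(tc, 0.10 * S, 0.025 * S, 0.04 * S, amp)
    img <- img + gaus(tc + 0.32 * period, 0.13 * S, 0.025 * S, 0.04 * S,
                      amp * stats::runif(1, 0.8, 1))
    if (abnormal && sep > 0) {
      # murmur: mid-frequency band between the S1/S2 pair
      img <- img + gaus(tc + 0.16 * period, 0.32 * S, 0.08 * period,
                        0.09 * S, 110 * sep * stats::runif(1, 0.8, 1.2))
    }
  }
  img <- img + stats::rnorm(S * S, 0, 8)
  array(.clip8(img), c(S, S, 1))
}

#' Generate a synthetic heart-sound scalogram dataset
#'
#' Time-frequency images mimicking heart-sound scalograms: periodic pairs
#' of low-frequency Gaussian energy bursts (S1/S2) in both classes; class 1
#' adds a mid-frequency murmur band between the pair with amplitude
#' proportional to `separability`. All content sits in the lower part of
#' the frequency axis (rows are frequency, increasing downward from row 1 =
#' lowest), mirroring the low-pass-limited recordings the study used.
#' Single channel, 8-bit.
#'
#' @param profile A [dataset_profile()].
#' @return A `dataset_manifest` with `S x S x 1` images.
#' @export
generate_scalogram_dataset <- function(profile) {
  stopifnot(inherits(profile, "dataset_profile"))
  labels <- c(rep(0L, profile$n_normal), rep(1L, profile$n_abnormal))
  images <- with_seed(profile$seed, {
    lapply(labels, function(lab) {
      .scalogram_image(profile$image_size, lab == 1L, profile$separability)
    })
  })
  .new_manifest(images, labels, profile, "scalogram")
}

#' Scalar class discriminants of the synthetic generators
#'
#' `lesion_discriminant` is the pixel standard deviation inside the central
#' disc (radius `0.12 * S`), which grows with interior multi-tonality and
#' boundary irregularity. `scalogram_band_energy` is the mean intensity of
#' the murmur frequency band (rows `0.22*S` to `0.42*S`). Both are the
#' fixed statistics used to verify that the class-mean gap grows with the
#' profile's `separability`.
#'
#' @param img An image array from a generator.
#' @return A scalar score.
#' @export
lesion_discriminant <- function(img) {
  S <- dim(img)[1]
  xg <- matrix(seq_len(S), S, S)
  inside <- sqrt((xg - S / 2)^2 + (t(xg) - S / 2)^2) <= 0.12 * S
  stats::sd(apply(img, 1:2, mean)[inside])
}

#' @rdname lesion_discriminant
#' @export
scalogram_band_energy <- function(img) {
  S <- dim(img)[1]
  rows <- max(1, round(0.22 * S)):min(S, round(0.42 * S))
  mean(img[rows, , 1])
}

#' Write a dataset manifest to disk
#'
#' Images as PNG files, a `manifest.csv` with columns `path,label`, and the
#' profile echoed as a `profile.yaml` sidecar.
#'
#' @param manifest A `dataset_manifest`.
#' @param dir Output directory (created if missing).
#' @return The manifest CSV path, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(manifest$images)
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(dir, sprintf("img_%05d.png", i))
    png::writePNG(manifest$images[[i]] / 255, paths[i])
  }
  df <- data.frame(path = paths, label = manifest$labels)
  csv <- file.path(dir, "manifest.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  yaml::write_yaml(unclass(manifest$profile), file.path(dir, "profile.yaml"))
  invisible(csv)
}

#' Published per-fold metric tables
#'
#' The 10-fold results printed in the study for each dataset/structure
#' combination, as transcribed fixtures (fold rows only; the printed
#' summary rows are recomputed, never stored, because some of them are
#' internally inconsistent with the fold values).
#'
#' @param dataset_id `"ISIC2017"`, `"PH2"` or `"PASCAL"`.
#' @param structure_id `"complex"` or `"real"`.
#' @return A [fold_metric_table()] with 10 rows and the five metrics.
#' @export
load_paper_fold_table <- function(dataset_id = c("ISIC2017", "PH2", "PASCAL"),
                                  structure_id = c("complex", "real")) {
  dataset_id <- match.arg(dataset_id)
  structure_id <- match.arg(structure_id)
  f <- system.file("extdata",
                   sprintf("fold_metrics_%s_%s.csv", dataset_id, structure_id),
                   package = "cvfair")
  if (f == "") stop("fixture not found for ", dataset_id, "/", structure_id)
  fold_metric_table(utils::read.csv(f), dataset_id, structure_id)
}

#' Column summaries of a fold-metric table
#'
#' @param tbl A [fold_metric_table()].
#' @return A data frame with rows `mean`, `max`, `min` over the five metric
#'   columns (always recomputed from the fold values).
#' @export
fold_table_summary <- function(tbl) {
  m <- tbl[setdiff(names(tbl), "fold")]
  data.frame(rbind(mean = colMeans(m), max = apply(m, 2, max),
                   min = apply(m, 2, min)))
}

#' The published per-layer parameter ledger
#'
#' The per-layer trainable-parameter counts reported for the two studied
#' networks (complex counts in complex units, real counts in scalars), as a
#' transcribed fixture. Summing the columns gives totals of 1,155,610
#' complex units versus 2,429,790 real scalars, a ratio of about 0.476 -
#' i.e. the complex network carries about half as many complex units as the
#' real network has scalars, which is parameter parity once each complex
#' unit is counted as two scalars.
#'
#' @return A data frame with columns `layer`, `complex_units`,
#'   `real_scalars`.
#' @export
load_parameter_ledger <- function() {
  f <- system.file("extdata", "parameter_ledger.csv", package = "cvfair")
  utils::read.csv(f)
}
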