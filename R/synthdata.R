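#' Specification of a synthetic multispectral palm-like dataset
#'
#' Bundles every knob of the generator so that a spec plus its seed fully
#' determines the dataset. Identities are defined by a set of smooth dark
#' curvilinear strokes (principal lines and wrinkles) shared by all four
#' spectral bands; Red and NIR additionally carry lower-contrast vein
#' strokes. Within a class, instances differ by a small common translation
#' and additive noise; test instances can be corrupted by a smooth
#' multiplicative uneven-illumination field.
#'
#' @param n_classes number of identities.
#' @param train_per_class,test_per_class instances per identity and split.
#' @param size image side length in pixels (square ROIs; default 64,
#'   128 matches full-size ROIs).
#' @param n_lines principal strokes per identity (default 4).
#' @param n_veins vein strokes added to Red/NIR (default 3).
#' @param line_amplitude stroke darkness on the unit intensity scale
#'   (default 0.45).
#' @param vein_amplitude vein stroke darkness (default 0.3).
#' @param line_width Gaussian stroke half-width in pixels (default 1.5).
#' @param jitter_px maximum |translation| per instance, pixels (default 2).
#' @param noise_sd additive Gaussian sensor noise sd, drawn per band
#'   (default 0.1).
#' @param illum_type illumination corruption of test images: `"none"`,
#'   `"linear"` or `"gaussian_bump"`.
#' @param illum_strength field amplitude in `[0, 0.9]`: values span
#'   `[1 - strength, 1 + strength]`.
#' @param seed integer master seed.
#' @return object of class `synth_spec` (a validated list).
#' @export
synth_spec <- function(n_classes = 10L, train_per_class = 6L,
                       test_per_class = 6L, size = 64L, n_lines = 4L,
                       n_veins = 3L, line_amplitude = 0.45,
                       vein_amplitude = 0.3, line_width = 1.5,
                       jitter_px = 2L, noise_sd = 0.1,
                       illum_type = c("none", "linear", "gaussian_bump"),
                       illum_strength = 0, seed = 1L) {
  illum_type <- match.arg(illum_type)
  spec <- list(n_classes = as.integer(n_classes),
               train_per_class = as.integer(train_per_class),
               test_per_class = as.integer(test_per_class),
               size = as.integer(size), n_lines = as.integer(n_lines),
               n_veins = as.integer(n_veins),
               line_amplitude = line_amplitude,
               vein_amplitude = vein_amplitude, line_width = line_width,
               jitter_px = as.integer(jitter_px), noise_sd = noise_sd,
               illum_type = illum_type, illum_strength = illum_strength,
               seed = as.integer(seed))
  stopifnot(spec$n_classes >= 1L, spec$train_per_class >= 1L,
            spec$test_per_class >= 0L, spec$size >= 16L,
            spec$n_lines >= 1L, spec$noise_sd >= 0,
            spec$illum_strength >= 0, spec$illum_strength <= 0.9)
  structure(spec, class = "synth_spec")
}

# Draw one smooth stroke (random quadratic curve with Gaussian cross-profile)
# onto an accumulator image. Called inside an established RNG stream.
draw_stroke <- function(acc, width) {
  n <- nrow(acc)
  p0 <- runif(2, 0.1, 0.9) * n
  p2 <- runif(2, 0.1, 0.9) * n
  mid <- (p0 + p2) / 2 + rnorm(2, 0, n / 6)
  tseq <- seq(0, 1, length.out = 4L * n)
  bx <- (1 - tseq)^2 * p0[1] + 2 * tseq * (1 - tseq) * mid[1] + tseq^2 * p2[1]
  by <- (1 - tseq)^2 * p0[2] + 2 * tseq * (1 - tseq) * mid[2] + tseq^2 * p2[2]
  rows <- matrix(rep(seq_len(n), n), n, n)
  cols <- t(rows)
  stroke <- matrix(0, n, n)
  # distance to the sampled curve, accumulated as a soft max of profiles
  for (s in seq(1L, length(tseq), by = 4L)) {
    d2 <- (rows - bx[s])^2 + (cols - by[s])^2
    stroke <- pmax(stroke, exp(-d2 / (2 * width^2)))
  }
  pmax(acc, stroke)
}

#' Generate the per-band identity template of one class
#'
#' Deterministic in `(class_id, spec$seed)`. All bands share the same
#' principal-line image; Blue and Green differ only by a band gain, while
#' Red and NIR add a vein-stroke component at lower contrast (mimicking the
#' extra subdermal structure those wavelengths capture).
#'
#' @param class_id integer identity.
#' @param spec a [synth_spec()].
#' @return named list of 4 matrices (Blue, Green, Red, NIR), values in
#'   `[0, 1]`.
#' @export
generate_identity_template <- function(class_id, spec) {
  withr_seed(derive_seed(spec$seed, 1000L + class_id), {
    n <- spec$size
    lines <- matrix(0, n, n)
    for (i in seq_len(spec$n_lines)) lines <- draw_stroke(lines, spec$line_width)
    veins <- matrix(0, n, n)
    for (i in seq_len(spec$n_veins)) veins <- draw_stroke(veins, spec$line_width * 1.6)
    gains <- c(Blue = 1.0, Green = 0.9, Red = 0.85, NIR = 0.8)
    out <- lapply(MSPALM_BANDS, function(b) {
      img <- 0.85 - gains[[b]] * spec$line_amplitude * lines
      if (b %in% c("Red", "NIR")) img <- img - spec$vein_amplitude * veins
      pmin(pmax(img, 0), 1)
    })
    names(out) <- MSPALM_BANDS
    out
  })
}

#' Draw one instance of an identity template
#'
#' Applies a small integer translation — identical across the four bands,
#' since the acquisition captures bands nearly simultaneously and they stay
#' co-registered — plus additive Gaussian sensor noise drawn independently
#' per band. Deterministic in `(class_id, instance_id, spec$seed)`.
#'
#' @param template output of [generate_identity_template()].
#' @param spec a [synth_spec()].
#' @param class_id,instance_id integers identifying the draw.
#' @return named list of 4 matrices, values in `[0, 1]`.
#' @export
sample_instance <- function(template, spec, class_id, instance_id) {
  withr_seed(derive_seed(spec$seed, 100000L + 1000L * class_id + instance_id), {
    n <- spec$size
    sh <- if (spec$jitter_px > 0)
      sample(seq(-spec$jitter_px, spec$jitter_px), 2L, replace = TRUE)
    else c(0L, 0L)
    lapply(template, function(img) {
      noise <- if (spec$noise_sd > 0) matrix(rnorm(n * n, 0, spec$noise_sd), n, n)
               else matrix(0, n, n)
      pmin(pmax(shift_image(img, sh[1L], sh[2L]) + noise, 0), 1)
    })
  })
}

# Integer translation with replicated-edge padding.
shift_image <- function(img, dr, dc) {
  n <- nrow(img); m <- ncol(img)
  ridx <- pmin(pmax(seq_len(n) - dr, 1L), n)
  cidx <- pmin(pmax(seq_len(m) - dc, 1L), m)
  img[ridx, cidx, drop = FALSE]
}

#' Smooth multiplicative uneven-illumination field
#'
#' `"linear"` ramps along a random direction; `"gaussian_bump"` is a bright
#' or dark smooth bump at a random centre. Fields are centred so their mean
#' is exactly 1 and scaled so all values lie in
#' `[1 - strength, 1 + strength]`; `strength = 0` gives the all-ones field.
#'
#' @param size image side length.
#' @param type `"none"`, `"linear"` or `"gaussian_bump"`.
#' @param strength amplitude in `[0, 0.9]`.
#' @param seed integer seed.
#' @return matrix `size x size` of positive values with mean 1.
#' @export
make_illumination_field <- function(size, type = c("none", "linear", "gaussian_bump"),
                                    strength = 0.4, seed = 1L) {
  type <- match.arg(type)
  if (strength < 0 || strength > 0.9)
    stop("`strength` must be in [0, 0.9]", call. = FALSE)
  n <- as.integer(size)
  if (type == "none" || strength == 0) return(matrix(1, n, n))
  withr_seed(seed, {
    rows <- matrix(rep(seq_len(n), n), n, n) / n
    cols <- t(rows)
    raw <- if (type == "linear") {
      theta <- runif(1, 0, 2 * pi)
      cos(theta) * rows + sin(theta) * cols
    } else {
      ctr <- runif(2, 0.25, 0.75)
      sgn <- sample(c(-1, 1), 1L)
      sgn * exp(-((rows - ctr[1])^2 + (cols - ctr[2])^2) / (2 * 0.25^2))
    }
    raw <- raw - mean(raw)
    1 + strength * raw / max(abs(raw))
  })
}

#' Apply a multiplicative illumination field to an image
#'
#' Elementwise product, clipped to `[0, 1]`.
#'
#' @param image matrix with values in `[0, 1]`.
#' @param field matrix from [make_illumination_field()].
#' @return corrupted image.
#' @export
apply_illumination <- function(image, field) {
  if (!all(dim(image) == dim(field)))
    stop("image and field shapes differ", call. = FALSE)
  pmin(pmax(image * field, 0), 1)
}

#' Generate a full train/test multispectral dataset
#'
#' Training instances are clean; test instances are fresh jitter/noise draws
#' of the same identities, corrupted by a per-sample illumination field when
#' `spec$illum_type != "none"`. Fully deterministic in the spec.
#'
#' @param spec a [synth_spec()].
#' @return list with `train` and `test`, each a list of samples; a sample
#'   is `list(label =, sample_id =, bands = named list of 4 matrices)`.
#'   Also `manifest`, a data frame (sample_id, label, band, split), and
#'   `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  make_split <- function(split, per_class, offset) {
    out <- vector("list", spec$n_classes * per_class)
    i <- 0L
    for (cl in seq_len(spec$n_classes)) {
      tmpl <- generate_identity_template(cl, spec)
      for (r in seq_len(per_class)) {
        i <- i + 1L
        inst <- sample_instance(tmpl, spec, cl, offset + r)
        if (split == "test" && spec$illum_type != "none") {
          fld <- make_illumination_field(
            spec$size, spec$illum_type, spec$illum_strength,
            seed = derive_seed(spec$seed, 500000L + 1000L * cl + r))
          inst <- lapply(inst, apply_illumination, field = fld)
        }
        out[[i]] <- list(label = cl,
                         sample_id = sprintf("%s_c%02d_i%02d", split, cl, r),
                         bands = inst)
      }
    }
    out
  }
  train <- make_split("train", spec$train_per_class, 0L)
  test <- make_split("test", spec$test_per_class, spec$train_per_class)
  manifest <- do.call(rbind, lapply(c(train, test), function(s) {
    data.frame(sample_id = s$sample_id, label = s$label, band = MSPALM_BANDS,
               split = if (grepl("^train", s$sample_id)) "train" else "test")
  }))
  list(train = train, test = test, manifest = manifest, spec = spec)
}

#' Write a generated dataset to disk as PNGs plus a manifest CSV
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest data frame (with a `path` column), invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in c(dataset$train, dataset$test)) {
    split <- if (grepl("^train", s$sample_id)) "train" else "test"
    for (b in names(s$bands)) {
      path <- file.path(dir, sprintf("%s_%s.png", s$sample_id, b))
      png::writePNG(s$bands[[b]], path)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, label = s$label, band = b, split = split,
        path = path)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# Derive a 31-bit child seed from (master, stream) without touching the RNG.
derive_seed <- function(master, stream) {
  x <- (as.double(master) * 2654435761 + as.double(stream) * 40503) %% 2147483647
  as.integer(x) + 1L
}
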