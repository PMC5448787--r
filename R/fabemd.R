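#' Locate strict local extrema of an image
#'
#' A pixel is a local maximum (minimum) when its value is strictly greater
#' (smaller) than every other pixel inside the `window` x `window`
#' neighbourhood centred on it; neighbours falling outside the image are
#' ignored, so border pixels compete only against their in-image neighbours.
#' Ties never produce extrema.
#'
#' @param image numeric matrix of finite intensities.
#' @param window odd integer neighbourhood size (default 3, the usual choice
#'   for extrema detection in FABEMD).
#' @return list with logical matrices `maxima` and `minima`, same shape as
#'   `image`.
#' @export
#' @examples
#' img <- matrix(0, 3, 3); img[2, 2] <- 5
#' ex <- find_extrema(img)
#' which(ex$maxima)  # the centre pixel
find_extrema <- function(image, window = 3L) {
  image <- as_image(image)
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  .cpp_find_extrema(image, window)
}

#' Nearest-neighbour distances between extrema points
#'
#' For each point, the Euclidean distance to the closest other point. Used to
#' derive the adaptive order-statistics filter window from the adjacent
#' maxima / minima distance vectors.
#'
#' @param points two-column matrix (row, col) or a list of length-2 vectors.
#' @return numeric vector, one entry per point.
#' @export
adjacent_distances <- function(points) {
  pts <- as_points(points)
  if (nrow(pts) < 2L)
    stop_degenerate("need at least 2 points to compute adjacent distances")
  .cpp_adjacent_distances(pts)
}

#' Select the order-statistics filter window size
#'
#' The gross window size is derived from the adjacent-extrema distance
#' vectors: mode `"d1"` takes the minimum of the two minima, mode `"d2"` the
#' maximum. The gross size is rounded to the nearest odd integer (halfway
#' cases round up) and clamped to the working range 3..69.
#'
#' @param maxima,minima extrema coordinates, as for [adjacent_distances()].
#' @param mode `"d1"` (default) or `"d2"`.
#' @return odd integer window size in `[3, 69]`.
#' @export
select_window_size <- function(maxima, minima, mode = c("d1", "d2")) {
  mode <- match.arg(mode)
  dmax <- adjacent_distances(maxima)
  dmin <- adjacent_distances(minima)
  gross <- if (mode == "d1") min(min(dmax), min(dmin)) else max(min(dmax), min(dmin))
  round_odd(gross)
}

# Nearest odd integer; exact ties between two odd candidates go up.
round_odd <- function(x) {
  lo <- 2L * as.integer(floor((x - 1) / 2)) + 1L  # largest odd <= x
  hi <- lo + 2L
  w <- if (x - lo < hi - x) lo else hi
  min(max(w, 3L), 69L)
}

#' Estimate upper and lower envelopes with order-statistics filters
#'
#' The upper (lower) envelope is the moving MAX (MIN) over the
#' `w_en` x `w_en` square centred at each pixel, followed by an
#' arithmetic-mean smoothing filter of the same window size. Windows are
#' clipped at the image boundary and the smoothing mean divides by the
#' clipped pixel count, so a constant image is reproduced exactly.
#'
#' @param source numeric matrix.
#' @param w_en odd integer window size in `[3, 69]`.
#' @return list with matrices `upper`, `lower` (smoothed) and
#'   `upper_raw`, `lower_raw` (before smoothing).
#' @export
estimate_envelopes <- function(source, w_en) {
  source <- as_image(source)
  w_en <- as.integer(w_en)
  if (w_en %% 2L == 0L || w_en < 3L || w_en > 69L)
    stop("`w_en` must be an odd integer in [3, 69]", call. = FALSE)
  up <- .cpp_max_filter(source, w_en)
  lo <- .cpp_min_filter(source, w_en)
  list(upper = .cpp_mean_filter(up, w_en),
       lower = .cpp_mean_filter(lo, w_en),
       upper_raw = up, lower_raw = lo)
}

#' FABEMD: decompose an image into BIMFs plus a residue
#'
#' Fast and adaptive bidimensional empirical mode decomposition. At each
#' level the strict local extrema of the current source signal are detected,
#' an adaptive window size is derived from the adjacent-extrema distances,
#' MAX/MIN order-statistics filters followed by mean smoothing give the
#' upper and lower envelopes, and the level's bidimensional intrinsic mode
#' function (BIMF) is the source minus the envelope mean `(U_E + L_E)/2`.
#' The envelope mean becomes the next level's source; after `K` levels it is
#' the residue — the smooth illumination trend — so the BIMFs plus the
#' residue reconstruct the input exactly (up to floating-point error).
#'
#' If a level's source has fewer than two maxima or two minima (a constant
#' or near-constant remainder), decomposition stops early: the remaining
#' BIMFs are zero and the residue is the current remainder, preserving the
#' additive reconstruction.
#'
#' @param image numeric matrix, at least 3 x 3.
#' @param K number of BIMFs to extract (default 4).
#' @param mode window-size rule, `"d1"` (default) or `"d2"`; `"d1"` selects
#'   the smaller of the two adjacent-extrema minima and tracks the finest
#'   present scale.
#' @param detect_window odd integer extrema-detection neighbourhood
#'   (default 3).
#' @return object of class `bimf_decomposition`: list with `bimfs` (list of
#'   `K` matrices, finest scale first), `residue`, `window_sizes` (integer
#'   vector, 0 marks levels skipped by early stop), and `source_shape`.
#' @export
#' @examples
#' img <- outer(sin(seq_len(32) * pi / 4), sin(seq_len(32) * pi / 4)) +
#'   outer(seq_len(32) / 32, seq_len(32) / 32)
#' dec <- fabemd(img, K = 2)
#' max(abs(img - Reduce(`+`, dec$bimfs) - dec$residue))
fabemd <- function(image, K = 4L, mode = c("d1", "d2"), detect_window = 3L) {
  mode <- match.arg(mode)
  image <- as_image(image)
  K <- as.integer(K)
  if (K < 1L) stop("`K` must be >= 1", call. = FALSE)
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3 x 3", call. = FALSE)

  J <- image
  bimfs <- vector("list", K)
  wins <- integer(K)
  for (i in seq_len(K)) {
    ex <- find_extrema(J, detect_window)
    pmax_ <- which(ex$maxima, arr.ind = TRUE)
    pmin_ <- which(ex$minima, arr.ind = TRUE)
    if (nrow(pmax_) < 2L || nrow(pmin_) < 2L) {
      for (r in i:K) bimfs[[r]] <- matrix(0, nrow(J), ncol(J))
      break
    }
    w <- select_window_size(pmax_, pmin_, mode)
    # levels extract successively coarser scales: never shrink the window
    if (i > 1L && wins[i - 1L] > w) w <- wins[i - 1L]
    wins[i] <- w
    env <- estimate_envelopes(J, wins[i])
    mean_env <- (env$upper + env$lower) / 2
    bimfs[[i]] <- J - mean_env
    J <- mean_env
  }
  structure(list(bimfs = bimfs, residue = J, window_sizes = wins,
                 source_shape = dim(image)),
            class = "bimf_decomposition")
}

#' @export
print.bimf_decomposition <- function(x, ...) {
  cat(sprintf("FABEMD decomposition: %d BIMFs of a %d x %d image\n",
              length(x$bimfs), x$source_shape[1], x$source_shape[2]))
  cat("window sizes:", paste(x$window_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Smooth the FABEMD residue into an illumination estimate
#'
#' The residue tracks the image's illumination trend; an arithmetic-mean
#' filter turns it into a smooth multiplicative illumination estimate. The
#' default 10 x 10 window is even: the extra row/column of the window sits
#' toward larger indices, and boundary windows are clipped with the mean
#' divided by the clipped pixel count.
#'
#' @param residue numeric matrix.
#' @param window integer window size >= 1 (default 10).
#' @return smoothed matrix, same shape.
#' @export
smooth_residue <- function(residue, window = 10L) {
  residue <- as_image(residue)
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1", call. = FALSE)
  .cpp_mean_filter(residue, window)
}

#' Illumination-compensate BIMFs by the smoothed residue
#'
#' Divides each BIMF elementwise by the smoothed residue, which cancels a
#' multiplicative shading field common to both. Pixels where the smoothed
#' residue is smaller than `eps` in magnitude are divided by `eps` instead,
#' guarding against blow-up near zero.
#'
#' @param bimfs list of numeric matrices (one per level) or a
#'   `bimf_decomposition`.
#' @param smooth_residue numeric matrix, same shape as each BIMF. When
#'   `bimfs` is a `bimf_decomposition` and this is missing, it is computed
#'   from the decomposition's residue with [smooth_residue()] and
#'   `smoothing_window`.
#' @param eps small positive guard (default `1e-5`, on the unit intensity
#'   scale).
#' @param smoothing_window passed to [smooth_residue()] when it is computed
#'   here (default 10).
#' @return list with `adjusted` (list of compensated BIMFs),
#'   `smooth_residue`, `eps`.
#' @export
compensate <- function(bimfs, smooth_residue = NULL, eps = 1e-5,
                       smoothing_window = 10L) {
  if (inherits(bimfs, "bimf_decomposition")) {
    if (is.null(smooth_residue))
      smooth_residue <- mspalm::smooth_residue(bimfs$residue, smoothing_window)
    bimfs <- bimfs$bimfs
  }
  if (is.null(smooth_residue))
    stop("`smooth_residue` is required when `bimfs` is a plain list", call. = FALSE)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("`eps` must be a positive scalar", call. = FALSE)
  denom <- ifelse(abs(smooth_residue) >= eps, smooth_residue, eps)
  adjusted <- lapply(bimfs, function(S) {
    if (!all(dim(S) == dim(smooth_residue)))
      stop("BIMF and residue shapes differ", call. = FALSE)
    S / denom
  })
  list(adjusted = adjusted, smooth_residue = smooth_residue, eps = eps)
}

#' Decompose and compensate one image in a single call
#'
#' Convenience wrapper: [fabemd()] followed by [smooth_residue()] and
#' [compensate()]. With `compensation = FALSE` the raw BIMFs are returned in
#' the `adjusted` slot so downstream code is agnostic to the switch.
#'
#' @inheritParams fabemd
#' @inheritParams compensate
#' @param compensation logical; divide BIMFs by the smoothed residue?
#' @return list with `adjusted`, `decomposition`, `smooth_residue`, `eps`.
#' @export
decompose_compensated <- function(image, K = 4L, mode = "d1",
                                  compensation = TRUE, smoothing_window = 10L,
                                  eps = 1e-5, detect_window = 3L) {
  dec <- fabemd(image, K = K, mode = mode, detect_window = detect_window)
  rs <- smooth_residue(dec$residue, smoothing_window)
  if (compensation) {
    comp <- compensate(dec$bimfs, rs, eps = eps)
    adjusted <- comp$adjusted
  } else {
    adjusted <- dec$bimfs
  }
  list(adjusted = adjusted, decomposition = dec, smooth_residue = rs, eps = eps)
}

# --- internal helpers -------------------------------------------------------

as_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected a numeric matrix", call. = FALSE)
  if (!all(is.finite(x))) stop("image contains non-finite values", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

as_points <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, function(p) as.numeric(p[1:2])))
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2L) stop("points must have two columns (row, col)", call. = FALSE)
  pts
}

stop_degenerate <- function(msg) {
  stop(structure(class = c("mspalm_degenerate_extrema", "error", "condition"),
                 list(message = msg, call = NULL)))
}
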