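#' Band names used throughout the package, in fixed fusion order.
#' @export
MSPALM_BANDS <- c("Blue", "Green", "Red", "NIR")

#' Stack compensated BIMFs of all bands into a per-sample feature matrix
#'
#' Builds the `n_pixels x (n_bands * K)` matrix whose columns are the
#' vectorized compensated BIMFs, band-major and level-minor: all `K` levels
#' of the first band, then all levels of the second band, and so on. Pixels
#' are vectorized row-major. The fused image of a sample is `V %*% phi` for
#' a fusion coefficient vector `phi`.
#'
#' @param band_bimfs named list, one entry per band in the desired band
#'   order, each a list of `K` compensated BIMF matrices of identical shape
#'   (the `adjusted` slot of [compensate()] / [decompose_compensated()]).
#' @param K expected number of levels per band (checked).
#' @param n_bands expected number of bands (checked); defaults to the full
#'   four-band layout, pass `length(band_bimfs)` for band subsets.
#' @return object of class `bimf_features`: the matrix `V` with attributes
#'   `shape` (image dimensions), `bands`, `K`.
#' @export
build_feature_matrix <- function(band_bimfs, K = length(band_bimfs[[1L]]),
                                 n_bands = 4L) {
  if (!is.list(band_bimfs) || length(band_bimfs) < 1L)
    stop("`band_bimfs` must be a non-empty list of per-band BIMF lists", call. = FALSE)
  if (length(band_bimfs) != n_bands)
    stop(sprintf("expected %d bands, got %d", n_bands, length(band_bimfs)),
         call. = FALSE)
  K <- as.integer(K)
  shp <- dim(band_bimfs[[1L]][[1L]])
  cols <- vector("list", length(band_bimfs) * K)
  idx <- 0L
  for (b in seq_along(band_bimfs)) {
    lv <- band_bimfs[[b]]
    if (length(lv) != K)
      stop("every band must provide exactly K BIMF levels", call. = FALSE)
    for (i in seq_len(K)) {
      if (!all(dim(lv[[i]]) == shp))
        stop("all BIMFs must share one shape", call. = FALSE)
      idx <- idx + 1L
      cols[[idx]] <- as.vector(t(lv[[i]]))  # row-major pixel order
    }
  }
  V <- do.call(cbind, cols)
  structure(V, shape = shp, bands = names(band_bimfs), K = K,
            class = c("bimf_features", class(V)))
}

#' Contribution factors for the weighted Fisher criterion
#'
#' For each training sample, measures how close it sits to a class border
#' among its `k` nearest neighbours (Frobenius distance between feature
#' matrices). With `Psi_j` the k-nearest-neighbour set of sample `j` and
#' `Psi_b_j` its between-class subset,
#' `mu_j = sum_{i in Psi_b_j} exp(-d_ij^2/delta^2) / sum_{i in Psi_j} exp(-d_ij^2/delta^2)`.
#' Interior samples (all neighbours same-class) get `mu = 0`; samples whose
#' neighbours are all from other classes get `mu = 1`.
#'
#' Raw Frobenius distances between pixel-scale feature matrices are large, so
#' distances are divided by `distance_scale` before the Gaussian; the default
#' scale is the mean k-nearest-neighbour distance over the training set,
#' which keeps the conventional `delta` range (4-8) meaningful regardless of
#' image size.
#'
#' @param samples list of feature matrices (or plain matrices/vectors of a
#'   common size).
#' @param labels class labels, one per sample.
#' @param k neighbour count (default 6).
#' @param delta Gaussian spread (default 5).
#' @param distance_scale positive scalar; `NULL` (default) uses the mean
#'   k-NN distance.
#' @return list with `mu` (vector in `[0,1]`), `k`, `delta`,
#'   `distance_scale`.
#' @export
contribution_factors <- function(samples, labels, k = 6L, delta = 5,
                                 distance_scale = NULL) {
  n <- length(samples)
  k <- as.integer(k)
  if (k < 1L || k >= n)
    stop("`k` must satisfy 1 <= k < number of samples", call. = FALSE)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  labels <- as.vector(labels)
  if (length(labels) != n) stop("one label per sample required", call. = FALSE)

  X <- do.call(rbind, lapply(samples, function(v) as.vector(v)))
  D <- as.matrix(stats::dist(X))
  nn <- t(apply(D, 1L, function(d) order(d)[-1L][seq_len(k)]))

  if (is.null(distance_scale)) {
    distance_scale <- mean(D[cbind(rep(seq_len(n), each = k), as.vector(t(nn)))])
    if (distance_scale <= 0) distance_scale <- 1
  }
  mu <- numeric(n)
  for (j in seq_len(n)) {
    d <- D[j, nn[j, ]] / distance_scale
    w <- exp(-d^2 / delta^2)
    other <- labels[nn[j, ]] != labels[j]
    mu[j] <- if (any(other)) sum(w[other]) / sum(w) else 0
  }
  list(mu = mu, k = k, delta = delta, distance_scale = distance_scale)
}

#' Contribution-weighted between- and within-class scatter matrices
#'
#' `D  = sum_j mu_j (V_j - Vbar)' (V_j - Vbar)` and
#' `Dw = sum_l sum_{j in l} mu_j (V_j - Vbar_l)' (V_j - Vbar_l)`, where
#' `Vbar` and the class means `Vbar_l` are unweighted; the contribution
#' factors weight only the outer products. With all `mu = 1` these are the
#' classic Fisher scatter matrices.
#'
#' @param samples list of feature matrices, common shape `n_pixels x 4K`.
#' @param labels class labels.
#' @param mu contribution factor per sample (default all 1 = classic Fisher).
#' @return list with symmetric PSD matrices `D` and `Dw` (`4K x 4K`).
#' @export
scatter_matrices <- function(samples, labels, mu = rep(1, length(samples))) {
  n <- length(samples)
  labels <- as.vector(labels)
  if (length(labels) != n || length(mu) != n)
    stop("`labels` and `mu` must have one entry per sample", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("need at least 2 classes", call. = FALSE)
  p <- ncol(samples[[1L]])
  Vbar <- Reduce(`+`, samples) / n
  D <- matrix(0, p, p)
  for (j in seq_len(n)) {
    C <- samples[[j]] - Vbar
    D <- D + mu[j] * crossprod(C)
  }
  Dw <- matrix(0, p, p)
  for (l in unique(labels)) {
    idx <- which(labels == l)
    Vl <- Reduce(`+`, samples[idx]) / length(idx)
    for (j in idx) {
      C <- samples[[j]] - Vl
      Dw <- Dw + mu[j] * crossprod(C)
    }
  }
  list(D = (D + t(D)) / 2, Dw = (Dw + t(Dw)) / 2)
}

#' Solve for the fusion coefficient vector
#'
#' Maximizes the (weighted) Fisher ratio `phi' D phi / phi' Dw phi` by the
#' generalized eigenproblem `D phi = lambda (Dw + ridge I) phi`, taking the
#' eigenvector of the largest eigenvalue. A small ridge (default
#' `1e-6 * mean diagonal of Dw`) keeps the within-class scatter invertible
#' when many interior samples carry zero weight. `phi` is normalized to unit
#' Euclidean norm with its largest-magnitude entry made positive.
#'
#' @param D,Dw symmetric PSD scatter matrices from [scatter_matrices()].
#' @param ridge non-negative scalar; `NULL` (default) uses
#'   `1e-6 * trace(Dw)/nrow(Dw)`.
#' @return object of class `fusion_model`: list with `phi`, `eigenvalue`,
#'   `ridge`, `rule = "fisher"` (callers may relabel), `hyperparams`.
#' @export
solve_fusion_coefficients <- function(D, Dw, ridge = NULL) {
  p <- nrow(D)
  if (!all(dim(D) == c(p, p)) || !all(dim(Dw) == c(p, p)))
    stop("`D` and `Dw` must be square matrices of one size", call. = FALSE)
  if (max(abs(D)) == 0)
    stop("between-class scatter is zero: no discriminative information", call. = FALSE)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(Dw)) / p
  Dr <- Dw + diag(ridge, p)
  # Symmetric reduction via Cholesky: L^-1 D L^-T has the same eigenvalues.
  L <- t(chol(Dr))
  A <- forwardsolve(L, t(forwardsolve(L, D)))
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  phi <- backsolve(t(L), e$vectors[, 1L])
  phi <- phi / sqrt(sum(phi^2))
  if (phi[which.max(abs(phi))] < 0) phi <- -phi
  structure(list(phi = phi, eigenvalue = e$values[1L], ridge = ridge,
                 rule = "fisher", hyperparams = NULL),
            class = "fusion_model")
}

#' Fit a fusion model from training feature matrices
#'
#' Front door for the three fusion rules: `"wfisher"` (contribution-weighted
#' Fisher criterion, the default), `"fisher"` (classic Fisher, all weights
#' one) and `"sum"` (fixed all-ones coefficients, no fitting).
#'
#' @param samples list of `bimf_features` matrices (training set).
#' @param labels class labels, one per sample.
#' @param rule `"wfisher"`, `"fisher"` or `"sum"`.
#' @param k,delta contribution-factor hyperparameters (used by `"wfisher"`).
#' @param ridge passed to [solve_fusion_coefficients()].
#' @param distance_scale passed to [contribution_factors()].
#' @return a `fusion_model` with `phi` of length `ncol(samples[[1]])`.
#' @export
fit_fusion <- function(samples, labels, rule = c("wfisher", "fisher", "sum"),
                       k = 6L, delta = 5, ridge = NULL, distance_scale = NULL) {
  rule <- match.arg(rule)
  p <- ncol(samples[[1L]])
  if (rule == "sum") {
    return(structure(list(phi = rep(1, p) / sqrt(p), eigenvalue = NA_real_,
                          ridge = 0, rule = "sum", hyperparams = NULL),
                     class = "fusion_model"))
  }
  if (rule == "wfisher") {
    cf <- contribution_factors(samples, labels, k = k, delta = delta,
                               distance_scale = distance_scale)
    mu <- cf$mu
    hyper <- list(k = cf$k, delta = cf$delta, distance_scale = cf$distance_scale)
  } else {
    mu <- rep(1, length(samples))
    hyper <- NULL
  }
  sc <- scatter_matrices(samples, labels, mu)
  model <- solve_fusion_coefficients(sc$D, sc$Dw, ridge = ridge)
  model$rule <- rule
  model$hyperparams <- hyper
  model
}

#' Fuse one sample's bands into a single image
#'
#' Computes `F = reshape(V %*% phi)` and, by default, min-max rescales the
#' result to `[0, 1]` so the classifier sees a stable intensity range
#' (eigenvector scale is arbitrary).
#'
#' @param sample a `bimf_features` matrix.
#' @param model a `fusion_model` (or a bare coefficient vector).
#' @param rescale logical; rescale the fused image to `[0, 1]`?
#' @return numeric matrix of the sample's image shape.
#' @export
fuse <- function(sample, model, rescale = TRUE) {
  phi <- if (inherits(model, "fusion_model")) model$phi else as.numeric(model)
  if (ncol(sample) != length(phi))
    stop("feature column count does not match length(phi)", call. = FALSE)
  shp <- attr(sample, "shape")
  if (is.null(shp)) stop("`sample` lacks a `shape` attribute", call. = FALSE)
  f <- as.numeric(sample %*% phi)
  Fm <- matrix(f, nrow = shp[1L], ncol = shp[2L], byrow = TRUE)
  if (rescale) {
    rng <- range(Fm)
    if (rng[2L] > rng[1L]) Fm <- (Fm - rng[1L]) / (rng[2L] - rng[1L])
    else Fm[] <- 0
  }
  Fm
}

#' Sum-rule baseline fused image
#'
#' Fuses with all-ones coefficients (every band and level weighted equally).
#'
#' @inheritParams fuse
#' @export
sum_rule_baseline <- function(sample, rescale = TRUE) {
  fuse(sample, rep(1, ncol(sample)), rescale = rescale)
}

#' Classic Fisher-criterion fusion model (all contribution factors = 1)
#'
#' @inheritParams fit_fusion
#' @export
classic_fisher_baseline <- function(samples, labels, ridge = NULL) {
  fit_fusion(samples, labels, rule = "fisher", ridge = ridge)
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("fusion model (%s rule): %d coefficients", x$rule, length(x$phi)))
  if (is.finite(x$eigenvalue))
    cat(sprintf(", leading eigenvalue %.4g", x$eigenvalue))
  cat("\n")
  invisible(x)
}

#' Serialize / restore a fusion model as JSON
#'
#' @param model a `fusion_model`.
#' @param path file path to write to / read from.
#' @return `read_fusion_model` returns a `fusion_model`;
#'   `write_fusion_model` returns `path` invisibly.
#' @export
write_fusion_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fusion_model
#' @export
read_fusion_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$phi <- as.numeric(obj$phi)
  structure(obj, class = "fusion_model")
}
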