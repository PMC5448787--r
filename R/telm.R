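#' Train a tensor-based extreme learning machine (TELM)
#'
#' Single-hidden-layer feedforward classifier for 2D images whose input
#' weights are not random: they are the first `n1` / `n2` columns of the
#' HOSVD factor matrices of the training image tensor, so each image is
#' projected onto an `n1 x n2` multilinear feature subspace that preserves
#' its 2D structure. The hidden activations are the sigmoid of the projected
#' features and the output weights solve the one-hot regression
#' `H beta = T` through the Moore-Penrose pseudoinverse.
#'
#' @param images list of `N` numeric matrices (`I1 x I2`), the training set.
#' @param labels integer class labels in `1..m`, one per image.
#' @param n1,n2 truncation ranks for the row / column factor matrices
#'   (defaults 18 and 15; hidden width is `n1 * n2`).
#' @return object of class `telm_model` with fields `U2_trunc`, `U3_trunc`,
#'   `beta`, `n_classes`, `n1`, `n2`.
#' @export
#' @examples
#' imgs <- c(replicate(5, matrix(rnorm(64, 0), 8, 8), simplify = FALSE),
#'           replicate(5, matrix(rnorm(64, 3), 8, 8), simplify = FALSE))
#' fit <- train_telm(imgs, rep(1:2, each = 5), n1 = 4, n2 = 4)
#' mean(predict(fit, imgs)$labels == rep(1:2, each = 5))
train_telm <- function(images, labels, n1 = 18L, n2 = 15L) {
  labels <- as.integer(labels)
  if (length(images) != length(labels))
    stop("`images` and `labels` lengths differ", call. = FALSE)
  gamma <- as_training_tensor(images)
  d <- dim(gamma)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 > d[2] || n2 > d[3])
    stop("truncation ranks exceed image dimensions", call. = FALSE)
  U <- hosvd_factors(gamma)
  U2t <- U$U2[, seq_len(n1), drop = FALSE]
  U3t <- U$U3[, seq_len(n2), drop = FALSE]
  Z <- mode_product(mode_product(gamma, t(U2t), 2), t(U3t), 3)
  H <- sigmoid(unfold(Z, 1))
  Tm <- one_hot(labels)
  beta <- pinv(H) %*% Tm
  structure(list(U2_trunc = U2t, U3_trunc = U3t, beta = beta,
                 n_classes = ncol(Tm), n1 = n1, n2 = n2),
            class = "telm_model")
}

#' Predict classes with a TELM model
#'
#' Each image is projected as `t(U2_trunc) %*% x %*% U3_trunc`, vectorized in
#' the same order as the training tensor's mode-1 unfolding (column of the
#' projected matrix varying fastest), passed through the sigmoid and
#' multiplied by the output weights. The predicted label is the argmax of
#' the scores; ties resolve to the smallest class index.
#'
#' @param object a `telm_model`.
#' @param images a single matrix or a list of matrices, shape `I1 x I2`.
#' @param ... unused.
#' @return list with `scores` (`N x m` matrix) and `labels` (integer vector).
#' @export
predict.telm_model <- function(object, images, ...) {
  if (is.matrix(images)) images <- list(images)
  Zrows <- t(vapply(images, function(x) {
    if (!all(dim(x) == c(nrow(object$U2_trunc), nrow(object$U3_trunc))))
      stop("image shape does not match the model", call. = FALSE)
    z <- crossprod(object$U2_trunc, x) %*% object$U3_trunc
    as.vector(t(z))  # row-major: matches the mode-1 unfolding column order
  }, numeric(object$n1 * object$n2)))
  scores <- sigmoid(Zrows) %*% object$beta
  list(scores = scores, labels = apply(scores, 1L, which.max))
}

#' @export
print.telm_model <- function(x, ...) {
  cat(sprintf("TELM model: %d x %d truncated HOSVD projection, %d hidden nodes, %d classes\n",
              x$n1, x$n2, x$n1 * x$n2, x$n_classes))
  invisible(x)
}

#' Train a classic random-weight extreme learning machine (ELM)
#'
#' Baseline single-hidden-layer network on vectorized inputs: input weights
#' (and biases, through the `[x 1]` augmentation) are drawn once from
#' Uniform(-1, 1) under `seed` and never tuned; output weights solve
#' `H beta = T` by pseudoinverse.
#'
#' @param x numeric matrix `N x n` of vectorized samples (or a list of
#'   matrices, vectorized row-major).
#' @param labels integer class labels in `1..m`.
#' @param n_hidden hidden-layer width.
#' @param seed integer seed for the random input weights.
#' @return object of class `elm_model` with `alpha` (`(n+1) x n_hidden`),
#'   `beta`, `n_classes`, `seed`.
#' @export
train_elm <- function(x, labels, n_hidden, seed = 1L) {
  x <- as_sample_matrix(x)
  labels <- as.integer(labels)
  if (nrow(x) != length(labels))
    stop("`x` rows and `labels` lengths differ", call. = FALSE)
  n_hidden <- as.integer(n_hidden)
  alpha <- withr_seed(seed, {
    matrix(runif((ncol(x) + 1L) * n_hidden, -1, 1), ncol(x) + 1L, n_hidden)
  })
  H <- sigmoid(cbind(x, 1) %*% alpha)
  Tm <- one_hot(labels)
  beta <- pinv(H) %*% Tm
  structure(list(alpha = alpha, beta = beta, n_classes = ncol(Tm), seed = seed),
            class = "elm_model")
}

#' Predict classes with a classic ELM model
#'
#' @param object an `elm_model`.
#' @param x matrix of vectorized samples (or list of image matrices).
#' @param ... unused.
#' @return list with `scores` and `labels` (argmax, ties to the smallest
#'   index).
#' @export
predict.elm_model <- function(object, x, ...) {
  x <- as_sample_matrix(x)
  if (ncol(x) + 1L != nrow(object$alpha))
    stop("input width does not match the model", call. = FALSE)
  scores <- sigmoid(cbind(x, 1) %*% object$alpha) %*% object$beta
  list(scores = scores, labels = apply(scores, 1L, which.max))
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("ELM model: %d inputs, %d hidden nodes, %d classes (seed %d)\n",
              nrow(x$alpha) - 1L, ncol(x$alpha), x$n_classes, x$seed))
  invisible(x)
}

# --- internal helpers -------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

one_hot <- function(labels) {
  m <- max(labels)
  if (min(labels) < 1L) stop("labels must be in 1..m", call. = FALSE)
  Tm <- matrix(0, length(labels), m)
  Tm[cbind(seq_along(labels), labels)] <- 1
  Tm
}

# Moore-Penrose pseudoinverse via SVD with a relative singular-value cutoff.
pinv <- function(A, rcond = 1e-10) {
  s <- svd(A)
  keep <- s$d > rcond * s$d[1L]
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Vectorize images row-major (consistent with mode-1 unfolding of a stack).
as_sample_matrix <- function(x) {
  if (is.list(x)) x <- do.call(rbind, lapply(x, function(m) as.vector(t(m))))
  as.matrix(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
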