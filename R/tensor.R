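#' Mode-q matrix unfolding of a tensor
#'
#' Flattens an order-p array into an `I_q x prod(I_{-q})` matrix. Column
#' index convention: the remaining modes keep their original order and the
#' last of them varies fastest, i.e. column
#' `j = 1 + sum_{l != q} (i_l - 1) * prod_{o > l, o != q} I_o`.
#'
#' @param a numeric array (a matrix counts as order 2).
#' @param q mode along which to unfold, `1 <= q <= length(dim(a))`.
#' @return numeric matrix.
#' @export
unfold <- function(a, q) {
  d <- dim(a)
  if (is.null(d)) stop("`a` must be an array", call. = FALSE)
  p <- length(d)
  q <- as.integer(q)
  if (q < 1L || q > p) stop("mode `q` out of range", call. = FALSE)
  others <- setdiff(seq_len(p), q)
  m <- aperm(a, c(q, rev(others)))
  dim(m) <- c(d[q], prod(d[others]))
  m
}

#' Refold a mode-q unfolding back into a tensor
#'
#' Inverse of [unfold()]: `refold(unfold(a, q), q, dim(a))` returns `a`.
#'
#' @param m matrix produced by [unfold()] (possibly with a changed mode-q
#'   dimension).
#' @param q the mode that was unfolded.
#' @param dims target tensor dimensions (with `dims[q] == nrow(m)`).
#' @return numeric array of dimension `dims`.
#' @export
refold <- function(m, q, dims) {
  p <- length(dims)
  q <- as.integer(q)
  if (nrow(m) != dims[q]) stop("row count does not match dims[q]", call. = FALSE)
  others <- setdiff(seq_len(p), q)
  perm <- c(q, rev(others))
  dim(m) <- dims[perm]
  aperm(m, order(perm))
}

#' Mode-q product of a tensor with a matrix
#'
#' Contracts mode `q` of `a` with the columns of `b`:
#' `C(i_1, ..., j_q, ..., i_p) = sum_{i_q} A(i_1, ..., i_q, ..., i_p) B(j_q, i_q)`,
#' computed as unfold, multiply, refold.
#'
#' @param a numeric array.
#' @param b matrix with `ncol(b) == dim(a)[q]`.
#' @param q mode index.
#' @return array with mode-q extent `nrow(b)`.
#' @export
mode_product <- function(a, b, q) {
  d <- dim(a)
  if (is.null(d)) stop("`a` must be an array", call. = FALSE)
  b <- as.matrix(b)
  if (ncol(b) != d[q])
    stop("`ncol(b)` must equal the mode-q extent of `a`", call. = FALSE)
  newd <- d
  newd[q] <- nrow(b)
  refold(b %*% unfold(a, q), q, newd)
}

#' HOSVD factor matrices of a training image tensor
#'
#' For an `N x I1 x I2` stack of images, returns the orthogonal factor
#' matrices `U2` (`I1 x I1`) and `U3` (`I2 x I2`): the left singular vectors
#' of the mode-2 and mode-3 unfoldings. The sample mode is never projected,
#' so no mode-1 factor is computed. With the full factors the tensor is
#' recovered exactly: `gamma = core x2 U2 x3 U3` where
#' `core = gamma x2 t(U2) x3 t(U3)`.
#'
#' @param gamma numeric array `N x I1 x I2` (see [as_training_tensor()]).
#' @return list with `U2` and `U3`.
#' @export
hosvd_factors <- function(gamma) {
  d <- dim(gamma)
  if (length(d) != 3L) stop("`gamma` must be an order-3 array", call. = FALSE)
  U2 <- svd(unfold(gamma, 2), nu = d[2], nv = 0)$u
  U3 <- svd(unfold(gamma, 3), nu = d[3], nv = 0)$u
  list(U2 = U2, U3 = U3)
}

#' Stack images into an order-3 training tensor
#'
#' @param images list of `N` numeric matrices, all `I1 x I2`.
#' @return array of dimension `N x I1 x I2` with
#'   `gamma[i, , ] == images[[i]]`.
#' @export
as_training_tensor <- function(images) {
  stopifnot(length(images) >= 1L)
  d <- dim(images[[1L]])
  if (any(!vapply(images, function(x) identical(dim(x), d), logical(1))))
    stop("all images must share one shape", call. = FALSE)
  gamma <- array(0, c(length(images), d[1], d[2]))
  for (i in seq_along(images)) gamma[i, , ] <- images[[i]]
  gamma
}
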