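# Brute-force oracles and shared fixtures. Oracles are written as direct
# per-pixel / per-index translations of the definitions, independent of the
# package's filter and tensor code paths.

# window offsets shared by all clipped-window oracles: size w spans
# [-floor((w-1)/2), +floor(w/2)] around the anchor (even windows lean to
# larger indices)
oracle_win <- function(c, w, n) {
  lo <- max(1L, c - (w - 1L) %/% 2L)
  hi <- min(n, c + w %/% 2L)
  lo:hi
}

oracle_extrema <- function(img, window = 3L) {
  H <- nrow(img); W <- ncol(img)
  mx <- mn <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ri <- oracle_win(i, window, H); cj <- oracle_win(j, window, W)
    nb <- img[ri, cj, drop = FALSE]
    nb[match(i, ri), match(j, cj)] <- NA
    mx[i, j] <- all(img[i, j] > nb, na.rm = TRUE)
    mn[i, j] <- all(img[i, j] < nb, na.rm = TRUE)
  }
  list(maxima = mx, minima = mn)
}

oracle_filter <- function(img, w, stat) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- stat(img[oracle_win(i, w, H), oracle_win(j, w, W)])
  out
}

# mode-q unfolding straight from the index formula
# j = 1 + sum_{l != q} (i_l - 1) prod_{o > l, o != q} I_o
oracle_unfold <- function(a, q) {
  d <- dim(a); p <- length(d)
  out <- matrix(0, d[q], prod(d[-q]))
  idx <- as.matrix(expand.grid(lapply(d, seq_len)))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    j <- 1
    for (l in seq_len(p)) {
      if (l == q) next
      mult <- 1
      for (o in seq_len(p)) if (o > l && o != q) mult <- mult * d[o]
      j <- j + (i[l] - 1) * mult
    }
    out[i[q], j] <- a[matrix(i, 1)]
  }
  out
}

# elementwise mode product: C(i1,..,jq,..,ip) = sum_iq A(..iq..) B(jq, iq)
oracle_mode_product <- function(a, B, q) {
  d <- dim(a); nd <- d; nd[q] <- nrow(B)
  out <- array(0, nd)
  idx <- as.matrix(expand.grid(lapply(nd, seq_len)))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    s <- 0
    for (iq in seq_len(d[q])) {
      ai <- i; ai[q] <- iq
      s <- s + a[matrix(ai, 1)] * B[i[q], iq]
    }
    out[matrix(i, 1)] <- s
  }
  out
}

# multiscale image: fine sinusoid grid (period 8 px) over a coarse ramp
multiscale_fixture <- function(n = 64) {
  fine <- outer(sin(2 * pi * seq_len(n) / 8), sin(2 * pi * seq_len(n) / 8)) * 0.2
  ramp <- outer(seq_len(n) / n, seq_len(n) / n)
  list(image = fine + ramp, fine = fine, ramp = ramp)
}

# The standard synthetic fixture: 10 classes x (6 train + 6 test), 64 x 64,
# clean training, Gaussian-bump illumination (strength 0.4) on test images.
std_spec <- function(seed = 7L, illum = "gaussian_bump") {
  synth_spec(n_classes = 10L, train_per_class = 6L, test_per_class = 6L,
             size = 64L, illum_type = illum,
             illum_strength = if (illum == "none") 0 else 0.4, seed = seed)
}

# cache expensive shared objects across test files (one process per suite)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

std_dataset <- function() cached("std_dataset", generate_dataset(std_spec()))
std_dataset_clean <- function()
  cached("std_dataset_clean", generate_dataset(std_spec(illum = "none")))

# features under the default config, shared by pipeline and acceptance tests
std_features <- function(which = c("train", "test", "test_clean")) {
  which <- match.arg(which)
  cfg <- pipeline_config(seed = 7L)
  switch(which,
    train = cached("feat_train", extract_features(std_dataset()$train, cfg)),
    test = cached("feat_test", extract_features(std_dataset()$test, cfg)),
    test_clean = cached("feat_test_clean",
                        extract_features(std_dataset_clean()$test, cfg)))
}

# random symmetric PSD matrix
random_psd <- function(p) {
  A <- matrix(rnorm(p * (p + 2)), p + 2, p)
  crossprod(A) / (p + 2)
}
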