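# tiny per-band BIMF stacks for layout tests
tiny_bands <- function(K = 1, shape = c(2, 2), seed = 1) {
  set.seed(seed)
  setNames(lapply(1:4, function(b)
    replicate(K, matrix(rnorm(prod(shape)), shape[1], shape[2]),
              simplify = FALSE)), MSPALM_BANDS)
}

test_that("feature matrix layout is band-major, level-minor, row-major pixels", {
  bb <- tiny_bands(K = 1)
  V <- build_feature_matrix(bb, K = 1)
  expect_equal(dim(V), c(4L, 4L))
  expect_equal(V[, 1], as.vector(t(bb$Blue[[1]])))

  bb4 <- tiny_bands(K = 4)
  V4 <- build_feature_matrix(bb4, K = 4)
  expect_equal(ncol(V4), 16L)
  expect_equal(V4[, 5], as.vector(t(bb4$Green[[1]])))  # band-major order

  # unit-vector selection recovers the Blue band's first BIMF
  e1 <- c(1, rep(0, 15))
  expect_equal(fuse(V4, e1, rescale = FALSE), bb4$Blue[[1]])

  expect_error(build_feature_matrix(bb4[1:3], K = 4), "K BIMF|non-empty|4")
})

test_that("contribution factors hit the stated endpoints and midpoint", {
  # two tight clusters: every sample's k neighbours are same-class -> mu = 0
  set.seed(2)
  near0 <- lapply(1:8, function(i) matrix(rnorm(4, ifelse(i <= 4, 0, 100)), 1))
  lab <- rep(1:2, each = 4)
  cf <- contribution_factors(near0, lab, k = 3, delta = 5)
  expect_equal(cf$mu, rep(0, 8))

  # alternating singletons: all k neighbours from other classes -> mu = 1
  solo <- lapply(1:6, function(i) matrix(i * 10, 1))
  cf1 <- contribution_factors(solo, 1:6, k = 2, delta = 5)
  expect_equal(cf1$mu, rep(1, 6))

  # one same-class and one other-class neighbour at equal distance -> 0.5
  eq <- list(matrix(0, 1), matrix(1, 1), matrix(-1, 1), matrix(10, 1))
  cfm <- contribution_factors(eq, c(1, 1, 2, 2), k = 2, delta = 5)
  expect_equal(cfm$mu[1], 0.5)
  expect_true(all(cf$mu >= 0 & cf$mu <= 1))
  expect_error(contribution_factors(solo, 1:6, k = 6), "k")
})

test_that("scatter matrices match scalar arithmetic and reduce to classic Fisher", {
  # 3 samples, 2 classes, 1x1 images, K = 1 -> V is 1x4
  v <- list(matrix(c(1, 0, 0, 0), 1), matrix(c(0, 1, 0, 0), 1),
            matrix(c(0, 0, 1, 0), 1))
  lab <- c(1, 1, 2)
  mu <- c(1, 0.5, 0.25)
  sc <- scatter_matrices(v, lab, mu)
  vb <- Reduce(`+`, v) / 3
  D_want <- matrix(0, 4, 4)
  for (j in 1:3) D_want <- D_want + mu[j] * outer(v[[j]][1, ] - vb[1, ],
                                                  v[[j]][1, ] - vb[1, ])
  expect_equal(sc$D, D_want)
  # hand-computed entry: D[1,1] = 1*(2/3)^2 + 0.5*(1/3)^2 + 0.25*(1/3)^2
  expect_equal(sc$D[1, 1], 19 / 36)
  # class means are unweighted; class 2 is a singleton -> zero contribution
  m1 <- (v[[1]] + v[[2]]) / 2
  Dw_want <- mu[1] * outer(v[[1]][1, ] - m1[1, ], v[[1]][1, ] - m1[1, ]) +
             mu[2] * outer(v[[2]][1, ] - m1[1, ], v[[2]][1, ] - m1[1, ])
  expect_equal(sc$Dw, Dw_want)

  expect_equal(scatter_matrices(v, lab, c(0, 0, 0))$D, matrix(0, 4, 4))
  expect_error(scatter_matrices(v, c(1, 1, 1)), "2 classes")
})

test_that("the generalized eigen solve has the stated closed forms and residuals", {
  m <- solve_fusion_coefficients(diag(c(4, 1)), diag(2), ridge = 0)
  expect_equal(m$phi, c(1, 0))
  expect_equal(m$eigenvalue, 4)

  # Dw = I: reduces to the standard eigenproblem on D
  set.seed(4)
  D <- random_psd(6)
  m2 <- solve_fusion_coefficients(D, diag(6), ridge = 0)
  ev <- eigen(D, symmetric = TRUE)
  expect_equal(abs(sum(m2$phi * ev$vectors[, 1])), 1, tolerance = 1e-8)

  for (r in 1:20) {
    D <- random_psd(5); Dw <- random_psd(5)
    m3 <- solve_fusion_coefficients(D, Dw)
    resid <- D %*% m3$phi -
      m3$eigenvalue * ((Dw + diag(m3$ridge, 5)) %*% m3$phi)
    expect_lt(max(abs(resid)), 1e-8)
    expect_equal(sum(m3$phi^2), 1, tolerance = 1e-12)
  }
  expect_error(solve_fusion_coefficients(matrix(0, 3, 3), diag(3)),
               "no discriminative")
})

test_that("uniform contribution factors reproduce the classic Fisher direction", {
  set.seed(6)
  for (r in 1:20) {
    samples <- lapply(1:12, function(i)
      matrix(rnorm(8, mean = (i %% 3)), 2, 4))
    lab <- rep(1:3, 4)
    # any constant mu must give the classic Fisher direction (scale cancels)
    sc_u <- scatter_matrices(samples, lab, rep(0.37, 12))
    sc_c <- scatter_matrices(samples, lab)
    m_u <- solve_fusion_coefficients(sc_u$D, sc_u$Dw)
    m_c <- solve_fusion_coefficients(sc_c$D, sc_c$Dw)
    expect_gt(abs(sum(m_u$phi * m_c$phi)), 0.9999)
  }
})

test_that("fusion is linear pre-rescale and the sum rule matches all-ones", {
  bb <- tiny_bands(K = 2, shape = c(3, 3))
  V <- build_feature_matrix(bb, K = 2)
  phi <- rnorm(8)
  expect_equal(fuse(V, 3 * phi, rescale = FALSE), 3 * fuse(V, phi, rescale = FALSE))
  expect_equal(sum_rule_baseline(V, rescale = FALSE), fuse(V, rep(1, 8), rescale = FALSE))

  # one band duplicated four times, K = 1: sum rule = 4 x that BIMF
  b1 <- setNames(rep(list(bb$Blue[1]), 4), MSPALM_BANDS)
  V1 <- build_feature_matrix(b1, K = 1)
  expect_equal(sum_rule_baseline(V1, rescale = FALSE), 4 * bb$Blue[[1]])

  f <- fuse(V, phi)
  expect_true(all(f >= 0 & f <= 1))
  expect_error(fuse(V, rnorm(5)), "match")
})

test_that("fused images are stable under illumination after compensation", {
  spec <- std_spec()
  tr <- std_dataset_clean()$train[1:20]
  cfg <- pipeline_config(seed = 7)
  feats <- extract_features(tr, cfg)
  model <- fit_fusion(feats$features, feats$labels)
  cors <- vapply(seq(1, 20, by = 4), function(i) {
    fld <- make_illumination_field(spec$size, "gaussian_bump", 0.4, seed = i)
    noisy <- tr[[i]]
    noisy$bands <- lapply(noisy$bands, apply_illumination, field = fld)
    fn <- extract_features(list(noisy), cfg)
    cor(as.vector(fuse(feats$features[[i]], model)),
        as.vector(fuse(fn$features[[1]], model)))
  }, numeric(1))
  expect_gt(mean(cors), 0.8)
})

test_that("fusion models round-trip through JSON", {
  set.seed(8)
  m <- solve_fusion_coefficients(random_psd(4), random_psd(4))
  path <- withr::local_tempfile(fileext = ".json")
  write_fusion_model(m, path)
  m2 <- read_fusion_model(path)
  expect_equal(m2$phi, m$phi)
  expect_equal(m2$ridge, m$ridge)
})
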