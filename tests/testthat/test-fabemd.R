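test_that("strict extrema detection handles ties, borders and constants", {
  img <- matrix(0, 3, 3); img[2, 2] <- 5
  ex <- find_extrema(img)
  expect_equal(which(ex$maxima), 5L)          # centre only
  expect_false(any(ex$minima))                # zero ties block strict minima

  expect_false(any(unlist(find_extrema(matrix(1, 5, 5)))))

  expect_error(find_extrema(img, window = 4), "odd")
})

test_that("extrema maps match the exhaustive neighbourhood scan", {
  set.seed(101)
  for (r in 1:30) {
    img <- matrix(sample.int(20, 16 * 16, replace = TRUE), 16, 16)
    storage.mode(img) <- "double"
    w <- sample(c(3L, 5L), 1)
    got <- find_extrema(img, w)
    want <- oracle_extrema(img, w)
    expect_identical(got$maxima, want$maxima)
    expect_identical(got$minima, want$minima)
  }
})

test_that("adjacent distances are nearest-other-point distances", {
  expect_equal(adjacent_distances(rbind(c(0, 0), c(3, 4))), c(5, 5))
  expect_equal(adjacent_distances(rbind(c(0, 0), c(0, 2), c(0, 5))), c(2, 2, 3))
  expect_error(adjacent_distances(rbind(c(1, 1))), "at least 2")
})

test_that("window selection follows the d1/d2 rules with odd rounding and clamping", {
  # min adjacent distances: maxima 4.2, minima 3.0
  mx <- rbind(c(0, 0), c(0, 4.2))
  mn <- rbind(c(10, 0), c(10, 3))
  expect_equal(select_window_size(mx, mn, "d1"), 3L)
  expect_equal(select_window_size(mx, mn, "d2"), 5L)  # 4.2 is nearer 5 than 3

  both3 <- rbind(c(0, 0), c(0, 3))
  expect_equal(select_window_size(both3, both3 + 10, "d1"), 3L)
  expect_equal(select_window_size(both3, both3 + 10, "d2"), 3L)

  far <- rbind(c(0, 0), c(0, 71))
  expect_equal(select_window_size(far, far + 100, "d2"), 69L)  # clamp
  # halfway gross sizes round to the larger odd integer
  expect_equal(select_window_size(rbind(c(0, 0), c(0, 4)),
                                  rbind(c(9, 0), c(9, 4)), "d1"), 5L)
})

test_that("envelopes are clipped-window order statistics followed by the mean", {
  cimg <- matrix(0.7, 8, 8)
  env <- estimate_envelopes(cimg, 3)
  expect_equal(env$upper, cimg)
  expect_equal(env$lower, cimg)

  set.seed(7)
  for (r in 1:10) {
    img <- matrix(rnorm(25), 5, 5)
    env <- estimate_envelopes(img, 3)
    expect_true(all(env$upper_raw >= img & img >= env$lower_raw))
    expect_equal(env$upper_raw, oracle_filter(img, 3, max))
    expect_equal(env$lower_raw, oracle_filter(img, 3, min))
    expect_equal(env$upper, oracle_filter(oracle_filter(img, 3, max), 3, mean))
    expect_equal(env$lower, oracle_filter(oracle_filter(img, 3, min), 3, mean))
  }
  expect_error(estimate_envelopes(cimg, 4), "odd")
})

test_that("decomposition reconstructs the source and separates scales", {
  set.seed(11)
  img <- matrix(runif(48 * 48), 48, 48)
  dec <- fabemd(img, K = 4)
  expect_length(dec$bimfs, 4)
  expect_lt(max(abs(img - Reduce(`+`, dec$bimfs) - dec$residue)),
            1e-9 * max(abs(img)))

  cimg <- matrix(0.5, 16, 16)
  dc <- fabemd(cimg, K = 4)
  expect_true(all(vapply(dc$bimfs, function(S) all(S == 0), logical(1))))
  expect_equal(dc$residue, cimg)

  ms <- multiscale_fixture()
  dm <- fabemd(ms$image, K = 2)
  expect_gt(cor(as.vector(dm$bimfs[[1]]), as.vector(ms$fine)), 0.9)
  # window sizes grow with level on the multiscale fixture
  dm4 <- fabemd(ms$image, K = 4)
  expect_true(all(diff(dm4$window_sizes) >= 0))
})

test_that("residue smoothing is a clipped-window mean with the even-anchor rule", {
  expect_equal(smooth_residue(matrix(2.5, 6, 6)), matrix(2.5, 6, 6))
  set.seed(3)
  img <- matrix(rnorm(9), 3, 3)
  expect_equal(smooth_residue(img, 1), img)  # identity
  big <- matrix(rnorm(144), 12, 12)
  expect_equal(smooth_residue(big, 10), oracle_filter(big, 10, mean))
})

test_that("compensation divides by the smoothed residue with an eps guard", {
  set.seed(5)
  bimfs <- replicate(3, matrix(rnorm(16), 4, 4), simplify = FALSE)
  ones <- matrix(1, 4, 4)
  expect_equal(compensate(bimfs, ones)$adjusted, bimfs)
  expect_equal(compensate(bimfs, 2 * ones)$adjusted,
               lapply(bimfs, function(S) S / 2))
  rs <- ones; rs[1, 1] <- 0; rs[2, 2] <- 1e-7  # near-zero also guarded
  adj <- compensate(bimfs, rs)$adjusted[[1]]
  expect_equal(adj[1, 1], bimfs[[1]][1, 1] / 1e-5)
  expect_equal(adj[2, 2], bimfs[[1]][2, 2] / 1e-5)
  expect_error(compensate(bimfs, ones, eps = -1), "positive")
})

test_that("compensated BIMF stacks are stable under multiplicative illumination", {
  spec <- std_spec()
  tmpl <- generate_identity_template(1, spec)
  cors <- unlist(lapply(c(3L, 9L), function(s) {
    fld <- make_illumination_field(spec$size, "gaussian_bump", 0.4, seed = s)
    a <- decompose_compensated(tmpl$Blue, K = 4)$adjusted
    b <- decompose_compensated(apply_illumination(tmpl$Blue, fld), K = 4)$adjusted
    mapply(function(x, y) cor(as.vector(x), as.vector(y)), a, b)
  }))
  expect_gt(mean(cors), 0.8)
})
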