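test_that("expanding windows grow in 1/n steps, centered and nested", {
  w <- expanding_windows(500, 500, n = 50)
  expect_identical(nrow(w), 50L)
  # first window is 10 x 10 at the image center
  expect_identical(c(w$height[1], w$width[1]), c(10L, 10L))
  expect_identical(c(w$top[1], w$left[1]), c(245L, 245L))
  # last window is the full image
  expect_identical(c(w$top[50], w$left[50], w$bottom[50], w$right[50]),
                   c(0L, 0L, 500L, 500L))
})

test_that("window sizes and nesting match direct enumeration on odd dims", {
  w <- expanding_windows(103, 97, n = 50)
  ow <- oracle_windows(103, 97, 50)
  for (k in 1:50) {
    expect_identical(c(w$top[k], w$left[k], w$bottom[k], w$right[k]),
                     as.integer(ow[[k]]))
  }
  # nesting: window k inside window k+1; window 50 is the full image
  expect_true(all(diff(w$top) <= 0) && all(diff(w$left) <= 0))
  expect_true(all(diff(w$bottom) >= 0) && all(diff(w$right) >= 0))
  expect_identical(c(w$bottom[50], w$right[50]), c(103L, 97L))
  expect_error(expanding_windows(100, 100, n = 1), "n must be")
})

test_that("window normalization scales the brightest pixel to 255", {
  img <- matrix(c(10L, 20L, 30L, 40L), 2, 2)
  # scale 255/40 = 6.375, rounded half-up
  expect_identical(normalize_window(img, roi(0, 0, 2, 2)),
                   matrix(c(64L, 128L, 191L, 255L), 2, 2))

  # window already containing 255 is unchanged
  img2 <- matrix(c(0L, 100L, 200L, 255L), 2, 2)
  expect_identical(normalize_window(img2, roi(0, 0, 2, 2)), img2)

  # constant nonzero window maps to all 255; all-zero stays zero
  expect_true(all(normalize_window(matrix(17L, 3, 3), roi(0, 0, 3, 3)) == 255L))
  expect_true(all(normalize_window(matrix(0L, 3, 3), roi(0, 0, 3, 3)) == 0L))
})

test_that("histogram equalization matches a standalone CDF oracle", {
  img <- matrix(c(0L, 0L, 128L, 255L), 2, 2)
  expect_equal(equalize_histogram(img), oracle_equalize(img))

  # constant image is unchanged
  expect_identical(equalize_histogram(matrix(42L, 3, 3)), matrix(42L, 3, 3))

  set.seed(31)
  for (i in 1:5) {
    rimg <- fixture_image(8, 8, seed = 100 + i, levels = 0:40)
    expect_equal(equalize_histogram(rimg), oracle_equalize(rimg))
  }
})

test_that("the equalization level mapping is monotone in gray value", {
  rimg <- fixture_image(12, 12, seed = 77)
  out <- equalize_histogram(rimg)
  o <- order(as.vector(rimg))
  expect_true(all(diff(out[o]) >= 0))
})

test_that("entropy equals direct histogram summation", {
  expect_identical(shannon_entropy(matrix(7L, 5, 5)), 0)
  expect_equal(shannon_entropy(matrix(c(0L, 255L), 4, 4)), 1)
  # proportions (0.25, 0.75)
  img <- matrix(c(10L, 20L, 20L, 20L), 2, 2)
  expect_equal(round(shannon_entropy(img), 4), 0.8113)
  for (i in 1:5) {
    rimg <- fixture_image(10, 10, seed = 200 + i)
    h <- shannon_entropy(rimg)
    expect_equal(h, oracle_entropy(rimg))
    expect_true(h >= 0 && h <= 8)
  }
})

test_that("entropy gradients are first differences and telescope", {
  expect_equal(entropy_gradient(c(1, 2, 4)), c(1, 2))
  expect_equal(entropy_gradient(rep(3.5, 6)), rep(0, 5))
  set.seed(13)
  h <- runif(50, 0, 8)
  g <- entropy_gradient(h)
  expect_equal(sum(g), h[50] - h[1])
  expect_error(entropy_gradient(2), "length")
})

test_that("feature vectors have length 2(n-1) and vanish on constant images", {
  img <- fixture_image(20, 20, seed = 20)
  expect_length(extract_features(img, n = 50), 98L)
  expect_length(extract_features(img, n = 10), 18L)
  expect_true(all(extract_features(matrix(90L, 16, 16), n = 10) == 0))
})

test_that("features equal an independent straight-line re-implementation", {
  for (seed in c(20, 21, 22)) {
    img <- fixture_image(20, 20, seed = seed)
    expect_equal(unname(extract_features(img, n = 50)),
                 oracle_extract_features(img, n = 50))
  }
  # non-square image, fewer windows
  img <- fixture_image(17, 23, seed = 33)
  expect_equal(unname(extract_features(img, n = 12)),
               oracle_extract_features(img, n = 12))
})

test_that("features are invariant under left-right mirroring", {
  # with even width and n | width, every window width is even, so the
  # centered windows are themselves mirror-symmetric regions
  img <- fixture_image(40, 100, seed = 44)
  mirrored <- img[, ncol(img):1]
  expect_equal(extract_features(img, n = 50),
               extract_features(mirrored, n = 50))
})

test_that("features are invariant to collision-free gray rescaling", {
  # two-level image: {100, 200} scaled by 0.5 -> {50, 100}; window-max
  # normalization maps both to the same levels {128, 255}
  set.seed(55)
  img <- matrix(sample(c(100L, 200L), 400, replace = TRUE), 20, 20)
  expect_equal(extract_features(img, n = 10),
               extract_features(img %/% 2L, n = 10))
})

test_that("window entropies stay in [0, 8] and gradients in [-8, 8]", {
  for (seed in 1:5) {
    img <- fixture_image(24, 24, seed = 300 + seed, levels = 0:255)
    fv <- extract_features(img, n = 10)
    expect_true(all(fv >= -8 & fv <= 8))
  }
})

test_that("feature tables carry id and label through extraction", {
  man <- tibble::tibble(id = c("a", "b"), label = c(1, -1),
                        gray = list(fixture_image(16, 16, 1),
                                    fixture_image(16, 16, 2)))
  ft <- extract_feature_table(man, n = 10)
  expect_identical(names(ft)[1:2], c("id", "label"))
  expect_identical(ncol(ft), 2L + 18L)
  expect_equal(unlist(ft[1, -(1:2)], use.names = FALSE),
               unname(extract_features(man$gray[[1]], n = 10)))
})
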