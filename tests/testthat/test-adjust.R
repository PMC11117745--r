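test_that("gamma adjustment fixes endpoints and matches the power law", {
  px <- matrix(c(0, 128, 255, 64), 2, 2)
  expect_equal(apply_gamma(px, 1.0), px)
  for (g in c(0.3, 0.5, 2, 5)) {
    out <- apply_gamma(px, g)
    expect_equal(out[1, 1], 0)
    expect_equal(out[1, 2], 255)
  }
  expect_equal(apply_gamma(matrix(128), 0.5)[1, 1],
               255 * sqrt(128 / 255), tolerance = 1e-12)
  expect_equal(apply_gamma(matrix(128), 0.5)[1, 1], 180.66,
               tolerance = 1e-4)
  expect_error(apply_gamma(px, 0), "positive")
  expect_error(apply_gamma(px, -1), "positive")
})

test_that("brightness is an additive offset with clipping", {
  expect_equal(apply_brightness(matrix(100), 0), matrix(100))
  expect_equal(apply_brightness(matrix(100), 0.10)[1, 1], 125.5)
  expect_equal(apply_brightness(matrix(250), 0.10)[1, 1], 255)
  expect_error(apply_brightness(matrix(1), 1.5), "<= 1")
})

test_that("contrast pivots at mid-scale", {
  px <- matrix(c(127.5, 27.5, 200), 1, 3)
  expect_equal(apply_contrast(px, 0), px)
  for (a in c(-0.5, 0.2, 1)) {
    expect_equal(apply_contrast(matrix(127.5), a)[1, 1], 127.5)
  }
  expect_equal(apply_contrast(matrix(27.5), 0.10)[1, 1], 17.5)
  expect_error(apply_contrast(px, -1), "> -1")
})

test_that("chains render from raw in one float pass", {
  raw <- matrix(100, 2, 2)
  noop <- adjust_chain(c("gamma", "brightness", "contrast"), c(1, 0, 0))
  expect_equal(render_chain(raw, noop), raw)
  cancel <- adjust_chain(c("brightness", "brightness"), c(0.10, -0.10))
  expect_equal(render_chain(raw, cancel), raw)  # no double quantization
  bad <- structure(list(ops = "sharpen", amounts = 1),
                   class = "adjust_chain")
  expect_error(render_chain(raw, bad), "invalid op")
})

test_that("chain composition is associative at float precision", {
  set.seed(31)
  raw <- rand_u8(16, 16)
  c1 <- adjust_chain(c("gamma", "brightness"), c(1.1, 0.05))
  c2 <- adjust_chain(c("contrast", "gamma"), c(-0.1, 0.95))
  joint <- adjust_chain(c(c1$ops, c2$ops), c(c1$amounts, c2$amounts))
  via_float <- render_chain(render_chain(raw, c1, quantize = FALSE), c2)
  expect_equal(render_chain(raw, joint), via_float)
})

test_that("intensity transforms preserve pixel rank order", {
  px <- matrix(sort(sample(0:255, 64)), 8, 8)
  set.seed(9)
  for (i in 1:10) {
    g <- runif(1, 0.2, 4); b <- runif(1, -0.9, 0.9)
    cc <- runif(1, -0.9, 2)
    for (out in list(apply_gamma(px, g), apply_brightness(px, b),
                     apply_contrast(px, cc), hist_equalize(px))) {
      expect_true(all(diff(as.vector(out)) >= 0))
      expect_identical(dim(out), dim(px))
    }
  }
})

test_that("difference of Gaussians kills flat signal and responds to an impulse", {
  flat <- matrix(90, 32, 32)
  out <- difference_of_gaussians(flat, 1, 4)
  expect_true(all(out == out[1, 1]))
  imp <- matrix(0, 33, 33); imp[17, 17] <- 255
  r <- difference_of_gaussians(imp, 1, 4)
  expect_true(r[17, 17] == max(r))          # center-positive
  expect_lt(r[17, 27], r[17, 17])           # ring attenuated
  expect_true(min(r) >= 0 && max(r) <= 255)
  expect_error(difference_of_gaussians(imp, 4, 1), "sigma_high > sigma_low")
})

test_that("histogram equalization is near-identity on a uniform histogram", {
  px <- matrix(0:255, 16, 16)
  out <- hist_equalize(px)
  expect_true(max(abs(out - px)) <= 1)
})

test_that("adaptive equalization maps a constant image to a constant", {
  out <- adaptive_hist_equalize(matrix(120, 64, 64), window = 16)
  expect_true(all(out == out[1, 1]))
  expect_true(all(out >= 0 & out <= 255))
  expect_error(adaptive_hist_equalize(matrix(1, 64, 64), window = 4),
               ">= 8")
  expect_error(adaptive_hist_equalize(matrix(1, 64, 64), clip_limit = 0),
               "clip_limit")
})

test_that("histogram matching hits its fixed points and swaps two-value images", {
  set.seed(13)
  px <- rand_u8(16, 16)
  expect_equal(hist_match(px, px), px + 0)
  expect_true(all(hist_match(px, matrix(77, 4, 4)) == 77))
  src <- matrix(c(rep(10, 32), rep(200, 32)), 8, 8)
  tgt <- matrix(c(rep(40, 32), rep(90, 32)), 8, 8)
  out <- hist_match(src, tgt)
  expect_true(all(out[src == 10] == 40))
  expect_true(all(out[src == 200] == 90))
})

test_that("the preprocessor dispatcher covers every benchmark method", {
  px <- rand_u8(32, 32)
  ref <- rand_u8(32, 32)
  expect_identical(preprocess(px, "raw"), px)
  for (m in c("dog", "he", "ahe", "hm")) {
    out <- preprocess(px, m, target_img = ref)
    expect_identical(dim(out), dim(px))
    expect_true(all(out >= 0 & out <= 255))
  }
  expect_error(preprocess(px, "hm"), "target_img")
})
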