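test_that("otsu threshold maximizes the brute-force variance sweep", {
  set.seed(23)
  for (i in 1:15) {
    px <- matrix(sample(0:255, 400, TRUE, prob = runif(256)^2), 20, 20)
    mk <- otsu_binary(px)
    best <- oracle_otsu(px)
    expect_true(attr(mk, "threshold") %in% best)
    # every maximizing cut induces the same split as the chosen one
    attr(mk, "threshold") <- NULL
    expect_identical(mk, px > best[1])
  }
  half <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  thr <- attr(otsu_binary(half), "threshold")
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_error(otsu_binary(matrix(7, 4, 4)), "degenerate histogram")
})

test_that("inverting an image complements the otsu mask", {
  set.seed(29)
  for (i in 1:10) {
    px <- matrix(sample(0:255, 400, TRUE), 20, 20)
    m1 <- otsu_binary(px); m2 <- otsu_binary(255 - px)
    attr(m1, "threshold") <- NULL; attr(m2, "threshold") <- NULL
    expect_identical(m1, !m2)
  }
})

test_that("metric extraction computes region means and population stds", {
  px <- matrix(100, 4, 4)
  mask <- matrix(c(TRUE, FALSE), 4, 4)
  m <- extract_metric(px, mask, use_std = TRUE)
  expect_equal(m$fg_mean, 100); expect_equal(m$bg_mean, 100)
  expect_equal(m$fg_std, 0); expect_equal(m$bg_std, 0)

  px2 <- matrix(c(10, 20, 0), 1, 3)
  mask2 <- matrix(c(TRUE, TRUE, FALSE), 1, 3)
  m2 <- extract_metric(px2, mask2, use_std = TRUE)
  expect_equal(m2$fg_mean, 15); expect_equal(m2$bg_mean, 0)
  expect_equal(m2$fg_std, 5)   # population sd of {10, 20}

  raw <- rand_u8(8, 8)
  mask3 <- raw > 128
  if (any(mask3) && !all(mask3)) {
    ident <- render_chain(raw, adjust_chain())
    expect_equal(extract_metric(ident, mask3), extract_metric(raw, mask3))
  }
})

test_that("an empty region flags the metric degenerate and searches skip", {
  px <- rand_u8(6, 6)
  m <- extract_metric(px, matrix(TRUE, 6, 6))
  expect_true(m$degenerate)
  tgt <- semantic_metric(10, 100)
  expect_warning(ch <- sp_gamma_search(px, matrix(TRUE, 6, 6), tgt),
                 "degenerate")
  expect_length(ch, 0)
  tgt4 <- semantic_metric(10, 100, 5, 5)
  expect_warning(ch2 <- gd_search(px, matrix(FALSE, 6, 6), tgt4),
                 "degenerate")
  expect_length(ch2, 0)
})

test_that("sp gamma search stops immediately at the target", {
  set.seed(41)
  sec <- generate_section(clean_spec(), "s", seed = 4)
  mask <- otsu_binary(sec$nuclear)
  target <- extract_metric(sec$nuclear, mask)
  ch <- sp_gamma_search(sec$nuclear, mask, target)
  expect_length(ch, 0)
})

test_that("sp gamma search undoes a known gamma perturbation", {
  sec <- generate_section(clean_spec(), "s", seed = 8)
  mask <- otsu_binary(sec$nuclear)
  target <- extract_metric(sec$nuclear, mask)
  raw <- apply_gamma(sec$nuclear$pixels, 1.05^5)
  d_raw <- metric_distance(extract_metric(raw, mask), target)
  ch <- sp_gamma_search(raw, mask, target)
  expect_length(ch, 1)
  # within one multiplicative 5% step of the true inverse 1.05^-5
  ratio <- ch$amounts / 1.05^-5
  expect_true(ratio <= 1.05 + 1e-9 && ratio >= 0.95 - 1e-9)
  d_adj <- metric_distance(
    extract_metric(render_chain(raw, ch, quantize = FALSE), mask), target)
  expect_lte(d_adj, d_raw)
})

test_that("gradient descent search matches an independent greedy oracle", {
  set.seed(55)
  sec <- generate_section(clean_spec(64L), "s", seed = 12)
  mask <- otsu_binary(sec$nuclear)
  target <- extract_metric(sec$nuclear, mask, use_std = TRUE)
  for (amt in c(0.2, -0.15)) {
    raw <- apply_brightness(sec$nuclear$pixels, amt)
    got <- gd_search(raw, mask, target)
    want <- oracle_gd(raw, mask, target)
    expect_identical(got$ops, want$chain$ops)
    expect_equal(got$amounts, want$chain$amounts)
  }
})

test_that("gradient descent reaches the 1%-step lattice optimum from raw", {
  sec <- generate_section(clean_spec(), "s", seed = 21)
  mask <- otsu_binary(sec$nuclear)
  target <- extract_metric(sec$nuclear, mask, use_std = TRUE)
  raw <- apply_brightness(sec$nuclear$pixels, 0.20)
  d0 <- metric_distance(extract_metric(raw, mask, use_std = TRUE), target)
  ch <- gd_search(raw, mask, target)
  d1 <- metric_distance(
    extract_metric(render_chain(raw, ch, quantize = FALSE), mask,
                   use_std = TRUE), target)
  expect_lte(d1, d0)
  # no better single move at the finest 1% step from the raw image
  best_single <- min(vapply(
    list(c("brightness", 0.01), c("brightness", -0.01),
         c("contrast", 0.01), c("contrast", -0.01),
         c("gamma", 1.01), c("gamma", 0.99)),
    function(cd) {
      adj <- render_chain(raw, adjust_chain(cd[1], as.numeric(cd[2])),
                          quantize = FALSE)
      metric_distance(extract_metric(adj, mask, use_std = TRUE), target)
    }, numeric(1)))
  expect_lte(d1, best_single)
  tr <- attr(ch, "trace")
  expect_true(all(diff(tr$distance) <= 1e-9))
})

test_that("gamma-only descent walks the sp search lattice", {
  sec <- generate_section(clean_spec(64L), "s", seed = 33)
  mask <- otsu_binary(sec$nuclear)
  target <- extract_metric(sec$nuclear, mask)
  for (g0 in c(1.05^3, 0.95^4)) {
    raw <- apply_gamma(sec$nuclear$pixels, g0)
    cfg <- sp_config(gamma_step = 0.05, gd_initial_step = 0.05,
                     gd_step_decrement = 0.05)
    via_gd <- gd_search(raw, mask, target, cfg, ops = "gamma")
    via_sp <- sp_gamma_search(raw, mask, target, cfg)
    g_gd <- prod(via_gd$amounts)
    g_sp <- if (length(via_sp)) via_sp$amounts else 1
    expect_equal(g_gd, g_sp, tolerance = 1e-12)
  }
})

test_that("class maps compose from the two binary channel masks", {
  n <- matrix(FALSE, 4, 8); n[, 1:4] <- TRUE     # left half tissue
  l <- matrix(FALSE, 4, 8); l[, 1:2] <- TRUE     # left quarter perfused
  cm <- compose_class_map(n, l)
  expect_true(all(cm$labels[, 1:2] == 2))
  expect_true(all(cm$labels[, 3:4] == 1))
  expect_true(all(cm$labels[, 5:8] == 0))
  z <- matrix(FALSE, 3, 3)
  expect_true(all(compose_class_map(z, z)$labels == 0))
  expect_error(compose_class_map(n, matrix(FALSE, 2, 2)), "mismatched")
})

test_that("bootstrap with an oracle segmenter is a fixed point at the target", {
  sec <- generate_section(clean_spec(), "s", seed = 44)
  oracle <- function(nuclear, lectin) sec$truth
  target <- list(
    nuclear = extract_metric(sec$nuclear, otsu_binary(sec$nuclear)),
    lectin = extract_metric(sec$lectin, otsu_binary(sec$lectin)))
  out <- bsp_iterate(sec$nuclear, sec$lectin, oracle, target,
                     sp_config(bootstrap_iters = 3L))
  expect_equal(nrow(out$trace), 3L)
  expect_length(out$chains$nuclear, 0)   # already at its own metric
  expect_identical(out$map$labels, sec$truth$labels)
})

test_that("bootstrap reduces metric distance on a perturbed section", {
  sec <- generate_section(clean_spec(), "s", seed = 47)
  pert <- adjust_chain(c("gamma", "brightness"), c(0.8, 0.08))
  nuc <- section_image(render_chain(sec$nuclear$pixels, pert), "nuclear")
  lec <- section_image(render_chain(sec$lectin$pixels, pert), "lectin")
  oracle <- function(nuclear, lectin) sec$truth
  target <- list(
    nuclear = extract_metric(sec$nuclear,
                             semprep:::masks_from_map(sec$truth)$nuclear),
    lectin = extract_metric(sec$lectin,
                            semprep:::masks_from_map(sec$truth)$lectin))
  out <- bsp_iterate(nuc, lec, oracle, target,
                     sp_config(bootstrap_iters = 4L))
  tr <- out$trace
  expect_equal(nrow(tr), 4L)
  # after the first model-corrected masks, the distances stabilize or drop
  expect_true(all(diff(tr$nuclear_distance[-1]) <= 1e-6))
  # chains agree once masks are oracle-corrected (fixed point)
  expect_equal(tr$nuclear_chain[3], tr$nuclear_chain[4])
  d0 <- metric_distance(
    extract_metric(nuc, otsu_binary(nuc)), target$nuclear)
  expect_lte(tr$nuclear_distance[4], d0 + 1e-9)
})

test_that("segmenter failure propagates with its bootstrap iteration", {
  sec <- generate_section(clean_spec(64L), "s", seed = 3)
  bad <- function(nuclear, lectin) stop("boom")
  target <- list(
    nuclear = extract_metric(sec$nuclear, otsu_binary(sec$nuclear)),
    lectin = extract_metric(sec$lectin, otsu_binary(sec$lectin)))
  expect_error(
    bsp_iterate(sec$nuclear, sec$lectin, bad, target,
                sp_config(bootstrap_iters = 2L)),
    "iteration 1.*boom")
})
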