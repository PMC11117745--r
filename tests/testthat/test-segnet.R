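test_that("the default architecture lands near the 2M-parameter budget", {
  m <- build_model()
  expect_gte(n_parameters(m), 1.5e6)
  expect_lte(n_parameters(m), 2.5e6)
  expect_error(build_model(params_budget = -5), "positive")
  expect_error(build_model(params_budget = 10), "budget")
})

test_that("predictions are per-pixel distributions and deterministic", {
  m <- build_model(width = 3L, depth = 2L, seed = 9)
  set.seed(1)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  p1 <- predict(m, x)
  expect_equal(dim(p1), c(16, 16, 3))
  expect_equal(apply(p1, c(1, 2), sum), matrix(1, 16, 16))
  m2 <- build_model(width = 3L, depth = 2L, seed = 9)
  expect_identical(p1, predict(m2, x))
  expect_error(predict(m, array(0, c(15, 16, 2))), "divisible")
  expect_error(predict(m, matrix(0, 16, 16)), "input array")
})

test_that("snapshot training descends and tags its members", {
  set.seed(2)
  # two-section toy: labels follow the input intensity bands
  inputs <- lapply(1:2, function(i) {
    n <- matrix(runif(256, 0, 1), 16, 16)
    l <- matrix(runif(256, 0, 1), 16, 16)
    array(c(n, l), c(16, 16, 2))
  })
  labels <- lapply(inputs, function(x)
    matrix(ifelse(x[, , 2] > 0.6, 2L, ifelse(x[, , 1] > 0.4, 1L, 0L)),
           16, 16))
  m <- build_model(width = 3L, depth = 1L, seed = 4)
  ens <- train_snapshots(m, inputs, labels,
                         train_config(10L, c(8L, 9L, 10L), lr = 8,
                                      seed = 6))
  expect_named(ens$members, c("M8", "M9", "M10"))
  expect_equal(ens$final$epoch, 10L)
  expect_lte(ens$metrics$train_loss[10], ens$metrics$train_loss[1])
  expect_error(train_snapshots(m, list(), list()), "empty")
})

test_that("training is reproducible under a fixed seed", {
  set.seed(3)
  inputs <- list(array(runif(16 * 16 * 2), c(16, 16, 2)))
  labels <- list(matrix(sample(0:2, 256, TRUE), 16, 16))
  cfg <- train_config(3L, 3L, lr = 2, seed = 12)
  e1 <- train_snapshots(build_model(width = 2L, depth = 1L, seed = 5),
                        inputs, labels, cfg)
  e2 <- train_snapshots(build_model(width = 2L, depth = 1L, seed = 5),
                        inputs, labels, cfg)
  expect_identical(e1$members$M3$params, e2$members$M3$params)
})

test_that("a noiseless separable toy trains to high validation Dice", {
  set.seed(8)
  # per-pixel rule with an intensity margin and no spatial structure:
  # the optimum is the pixelwise threshold rule itself
  make_pair <- function() {
    n <- matrix(sample(c(0.10, 0.75), 256, TRUE), 16, 16)
    l <- matrix(sample(c(0.15, 0.85), 256, TRUE), 16, 16)
    lab <- ifelse(l > 0.5, 2L, ifelse(n > 0.5, 1L, 0L))
    list(x = array(c(n, l), c(16, 16, 2)), y = lab)
  }
  pairs <- replicate(12, make_pair(), simplify = FALSE)
  inputs <- lapply(pairs, `[[`, "x"); labels <- lapply(pairs, `[[`, "y")
  val <- replicate(4, make_pair(), simplify = FALSE)
  ens <- train_snapshots(
    build_model(width = 4L, depth = 1L, seed = 2),
    inputs, labels,
    train_config(40L, c(38L, 39L, 40L), lr = 8, seed = 3),
    val_inputs = lapply(val, `[[`, "x"),
    val_labels = lapply(val, `[[`, "y"))
  expect_gte(ens$metrics$val_dice[40], 0.95)
})

test_that("ensemble voting matches the exhaustive per-pixel oracle", {
  combos <- as.matrix(expand.grid(0:2, 0:2, 0:2))  # all 27 vote patterns
  maps <- lapply(1:3, function(v) matrix(combos[, v], nrow = 27, ncol = 1))
  got <- ensemble_vote(maps)
  for (px in 1:27) {
    votes <- combos[px, ]
    counts <- tabulate(votes + 1, 3)
    top <- max(counts)
    winners <- which(counts == top) - 1
    want <- unname(if (votes[3] %in% winners) votes[3] else max(winners))
    expect_equal(got$map$labels[px, 1], want)
    expect_equal(got$conf$proportions[px, 1], top / 3)
  }
  expect_true(all(got$conf$proportions %in% c(1 / 3, 2 / 3, 1)))
})

test_that("three-way ties resolve to the final snapshot's class", {
  maps <- list(matrix(0L, 1, 1), matrix(2L, 1, 1), matrix(1L, 1, 1))
  v <- ensemble_vote(maps)
  expect_equal(v$map$labels[1, 1], 1L)      # M_final voted risk
  expect_equal(v$conf$proportions[1, 1], 1 / 3)
})

test_that("unanimous members give unit confidence and identical map", {
  m <- matrix(sample(0:2, 64, TRUE), 8, 8)
  v <- ensemble_vote(list(m, m, m))
  expect_identical(v$map$labels, m)
  expect_true(all(v$conf$proportions == 1))
  expect_equal(v$conf$mean_confidence, 1)
  expect_error(ensemble_vote(list(m, m)), "odd")
})

test_that("section confidence averages the winning-vote proportions", {
  expect_equal(section_confidence(matrix(1, 4, 4)), 1)
  half <- matrix(c(rep(1, 8), rep(2 / 3, 8)), 4, 4)
  expect_equal(section_confidence(confidence_map(half)), 5 / 6)
})

test_that("threshold choice respects expert capacity and the 90% floor", {
  expect_equal(choose_threshold(c(0.99, 0.98, 0.97), capacity = 2), 0.98)
  expect_equal(choose_threshold(c(0.85, 0.80, 0.89), capacity = 2), 0.90)
  expect_equal(choose_threshold(c(0.95, 0.93), capacity = 12), 0.93)
  expect_error(choose_threshold(numeric(0)), "no confidence")
})

test_that("the least-overfit fold is the lowest test Dice, ties in order", {
  expect_equal(least_overfit_fold(c(A = 0.9, B = 0.8)), "B")
  expect_equal(least_overfit_fold(c(A = 0.7, B = 0.7, C = 0.7)), "A")
  expect_equal(least_overfit_fold(c(only = 0.5)), "only")
})

test_that("fold plans partition sections with disjoint roles", {
  ids <- sprintf("s%02d", 1:11)
  fp <- fold_plan(ids, n_folds = 4, val_size = 2, seed = 3)
  all_tests <- unlist(lapply(fp$folds, `[[`, "test_ids"))
  expect_setequal(all_tests, ids)
  expect_equal(anyDuplicated(all_tests), 0L)
  for (f in fp$folds) {
    expect_length(intersect(f$train_ids, f$val_ids), 0)
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    expect_length(intersect(f$val_ids, f$test_ids), 0)
    expect_setequal(c(f$train_ids, f$val_ids, f$test_ids), ids)
  }
})

test_that("section prediction stitches stub outputs faithfully", {
  g <- patch_grid(32, 16, 8)
  nuc <- rand_u8(48, 80); lec <- rand_u8(48, 80)
  const_stub <- function(x) {
    p <- array(0, c(dim(x)[1], dim(x)[2], 3)); p[, , 2] <- 1; p
  }
  out <- predict_section(const_stub, nuc, lec, g)
  expect_true(all(out$map$labels == 1L))
  expect_identical(dim(out$map$labels), dim(nuc))

  # oracle stub: per-pixel rule on the inputs; stitched map must equal
  # the rule applied to the whole section
  rule_stub <- function(x) {
    lab <- ifelse(x[, , 2] > 0.5, 2L, ifelse(x[, , 1] > 0.3, 1L, 0L))
    probs_from_labels(lab)
  }
  want <- ifelse(lec / 255 > 0.5, 2L, ifelse(nuc / 255 > 0.3, 1L, 0L))
  out2 <- predict_section(rule_stub, nuc, lec, g)
  expect_identical(out2$map$labels, want)
  expect_error(predict_section(const_stub, nuc, rand_u8(2, 2), g),
               "mismatched")
})

test_that("exact probability ties break by class priority normal > risk > none", {
  p <- array(1 / 3, c(2, 2, 3))
  expect_true(all(semprep:::prob_argmax(p) == 2L))
  p2 <- array(0, c(1, 1, 3)); p2[1, 1, 1] <- 0.5; p2[1, 1, 2] <- 0.5
  expect_equal(semprep:::prob_argmax(p2)[1, 1], 1L)
})
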