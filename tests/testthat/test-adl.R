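test_that("dataset growth percentages reproduce the run accounting", {
  expect_equal(dataset_size_pct(4513, 0), 100)
  expect_equal(dataset_size_pct(4513, 8374), 286)
  expect_equal(dataset_size_pct(4513, 7767), 272)
  expect_equal(dataset_size_pct(4513, 3171), 170)
  expect_equal(dataset_size_pct(4513, 3060), 168)
  expect_equal(dataset_size_pct(11, 82), 845)   # section-level full run
  expect_error(dataset_size_pct(0, 5), "positive")
})

test_that("acceptance percentage rounds the accepted fraction", {
  expect_equal(acceptance_pct(82, 89), 92)
  expect_equal(acceptance_pct(0, 89), 0)
  expect_equal(acceptance_pct(89, 89), 100)
})

test_that("expert time follows the 5/1-minute review model", {
  expect_equal(expert_time_hours(12, 0), 1)
  expect_equal(expert_time_hours(0, 0), 0)
  expect_equal(expert_time_hours(10, 10), 1)
})

test_that("time saved compares review hours against manual labeling", {
  expect_equal(time_saved_pct(7.2, 164), 96)
  expect_equal(time_saved_pct(0, 10), 100)
  expect_equal(time_saved_pct(3, 3), 0)
})

test_that("the simulated expert accepts at the Dice bar, inclusively", {
  truth <- class_map(matrix(sample(0:2, 64, TRUE), 8, 8))
  d <- simulated_expert(truth, truth)
  expect_equal(d$verdict, "accept"); expect_equal(d$minutes, 5)
  allnone <- class_map(matrix(0L, 8, 8))
  mixed <- class_map(matrix(rep(c(0L, 1L, 2L), length.out = 64), 8, 8))
  d2 <- simulated_expert(allnone, mixed)
  expect_equal(d2$verdict, "reject"); expect_equal(d2$minutes, 1)
  # boundary: macro dice exactly at the bar is accepted
  d3 <- simulated_expert(truth, truth, accept_dice = 1.0)
  expect_equal(d3$verdict, "accept")
})

test_that("a full desk-scale iteration keeps the active-set ledger consistent", {
  specs <- default_cohort_specs(n1 = 4L, n2 = 1L, n3 = 1L,
                                section_size = 128L, seed = 7)
  ds <- generate_cohorts(specs)
  cfg <- adl_config(method = "raw",
                    train = train_config(3L, c(1L, 2L, 3L), lr = 8, seed = 1),
                    grid = patch_grid(32L, 16L, 8L),
                    n_folds = 2L, model_width = 2L, model_depth = 1L,
                    train_offsets = 0L, seed = 13)
  st <- adl_run(ds, cfg, n_iterations = 1L)
  led <- st$ledger
  expect_equal(nrow(led), 1L)
  expect_equal(led$n_pending, 2L)
  expect_equal(led$n_accepted + led$n_rejected, led$n_presented)
  expect_gte(led$f_thresh, 0.90)
  # accepted + still-active = initial active set
  expect_equal(sum(st$active$state == "accepted") +
                 sum(st$active$state != "accepted"), 2L)
  expect_equal(led$cum_accepted_sections,
               sum(st$active$state == "accepted"))
  # dataset growth consistent with sample bookkeeping
  expect_equal(led$dataset_size_pct,
               dataset_size_pct(st$n_base_samples, st$accepted_samples))
  # accepted sections join every fold's training set next iteration
  if (led$n_accepted > 0) expect_length(st$extra, led$n_accepted)
})

test_that("an unreachable acceptance bar leaves the training set unchanged", {
  specs <- default_cohort_specs(n1 = 4L, n2 = 1L, n3 = 1L,
                                section_size = 128L, seed = 9)
  ds <- generate_cohorts(specs)
  cfg <- adl_config(method = "raw",
                    train = train_config(3L, c(1L, 2L, 3L), lr = 8, seed = 1),
                    grid = patch_grid(32L, 16L, 8L),
                    n_folds = 2L, model_width = 2L, model_depth = 1L,
                    train_offsets = 0L, accept_dice = 2,  # impossible bar
                    seed = 13)
  st <- adl_run(ds, cfg, n_iterations = 1L)
  expect_equal(st$ledger$n_accepted, 0L)
  expect_length(st$extra, 0)
  expect_equal(st$accepted_samples, 0)
  expect_true(all(st$active$state != "accepted"))
})
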