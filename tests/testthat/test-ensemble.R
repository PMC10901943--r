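# 20 patients x 10 tiles x 2 classes = 400 tiles; patient-class groups of
# 10 divide 0.15 * 400 = 60 exactly.
planner_fixture <- function() flat_cohort(n_patients = 20,
                                          tiles_per_class = 10)

test_that("the 15% target yields exactly 60 flips on the 400-tile cohort", {
  co <- planner_fixture()
  for (s in c(1, 2, 3)) {
    plan <- make_member_plan(co, subset_fraction = 1.0,
                             target_noise_rate = 0.15, seed = s)
    expect_length(plan$flipped_tiles, 60)
    expect_equal(plan$realized_noise_rate, 0.15)
    expect_equal(plan$n_train, 400)
  }
})

test_that("a zero-noise plan is identical to the bagging plan at equal seed", {
  co <- planner_fixture()
  bag <- make_member_plan(co, 0.8, target_noise_rate = 0, seed = 11)
  noisy0 <- make_member_plan(co, 0.8, target_noise_rate = 0, seed = 11)
  expect_identical(bag, noisy0)
  expect_length(bag$flipped_tiles, 0)
  expect_equal(nrow(bag$noise_groups), 0)
  # and the noisy plan at the same seed draws the same patient subset
  noisy <- make_member_plan(co, 0.8, target_noise_rate = 0.15, seed = 11)
  expect_identical(noisy$patient_subset, bag$patient_subset)
})

test_that("flips respect the single-class-per-patient structure", {
  co <- planner_fixture()
  for (s in 1:200) {
    plan <- make_member_plan(co, subset_fraction = 0.8,
                             target_noise_rate = 0.15, seed = s)
    expect_equal(anyDuplicated(plan$noise_groups$patient_id), 0)
    flipped <- co[co$tile_id %in% plan$flipped_tiles, ]
    key <- paste(flipped$patient_id, flipped$label)
    group_key <- paste(plan$noise_groups$patient_id,
                       plan$noise_groups$noised_class)
    expect_true(all(key %in% group_key))
    # groups are flipped whole: every group's tiles are all flipped
    expect_equal(sort(unique(key)), sort(group_key))
  }
})

test_that("applying a plan flips labels as an involution and subsets patients", {
  co <- planner_fixture()
  plan <- make_member_plan(co, 0.8, 0.15, seed = 5)
  applied <- apply_member_plan(co, plan)
  expect_setequal(unique(applied$patient_id), plan$patient_subset)
  expect_equal(nrow(applied),
               sum(co$patient_id %in% plan$patient_subset))
  flipped_rows <- applied$tile_id %in% plan$flipped_tiles
  orig <- co[match(applied$tile_id, co$tile_id), ]
  expect_true(all(applied$label[flipped_rows] ==
                    1L - orig$label[flipped_rows]))
  expect_true(all(applied$label[!flipped_rows] ==
                    orig$label[!flipped_rows]))
  # involution: re-applying the flips restores the original labels
  twice <- applied
  twice$label[flipped_rows] <- 1L - twice$label[flipped_rows]
  expect_equal(twice$label, orig$label)

  empty <- make_member_plan(co, 0.8, 0, seed = 5)
  expect_equal(sort(apply_member_plan(co, empty)$label),
               sort(co$label[co$patient_id %in% empty$patient_subset]))

  bad <- plan
  bad$patient_subset <- c(bad$patient_subset, "ghost")
  expect_error(apply_member_plan(co, bad), "absent from cohort")
})

test_that("ensemble plans are seed-deterministic with distinct member subsets", {
  co <- planner_fixture()
  p1 <- make_ensemble_plan(co, n_members = 15, seed = 7)
  p2 <- make_ensemble_plan(co, n_members = 15, seed = 7)
  expect_identical(p1, p2)
  subsets <- lapply(p1$members, `[[`, "patient_subset")
  expect_gt(length(unique(subsets)), 1)
  rates <- sapply(p1$members, `[[`, "realized_noise_rate")
  expect_lte(abs(mean(rates) - 0.15), 0.02)
})

test_that("aggregation averages probabilities with ties going to class 1", {
  agg <- aggregate_members(list(c(0.2), c(0.6), c(1.0)))
  expect_equal(agg$prob, 0.6)
  expect_equal(agg$label, 1L)
  expect_equal(aggregate_members(list(rep(0.7, 3)))$prob, rep(0.7, 3))
  expect_equal(aggregate_members(list(c(0.4), c(0.6)))$label, 1L)  # tie
  # permutation invariance
  members <- list(c(0.1, 0.9), c(0.8, 0.3), c(0.5, 0.5))
  expect_equal(aggregate_members(members), aggregate_members(rev(members)))
  expect_error(aggregate_members(list(c(0.1), c(0.2, 0.3))),
               "differ in length")
  expect_error(aggregate_members(list(c(1.2))), "\\[0, 1\\]")
})

test_that("ensemble plans round-trip through JSON", {
  co <- planner_fixture()
  plan <- make_ensemble_plan(co, n_members = 3, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble_plan(plan, path)
  back <- read_ensemble_plan(path)
  expect_equal(back$seed, plan$seed)
  expect_equal(back$n_members, plan$n_members)
  for (m in 1:3) {
    expect_equal(back$members[[m]]$patient_subset,
                 plan$members[[m]]$patient_subset)
    expect_equal(sort(back$members[[m]]$flipped_tiles),
                 sort(plan$members[[m]]$flipped_tiles))
    expect_equal(back$members[[m]]$realized_noise_rate,
                 plan$members[[m]]$realized_noise_rate)
  }
})
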