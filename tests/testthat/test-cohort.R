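write_demo_manifest <- function(path, labels = c(0, 1, 0, 1)) {
  readr::write_csv(tibble::tibble(
    tile_path = sprintf("tiles/t%d.png", seq_along(labels)),
    patient_id = c("p1", "p1", "p2", "p2")[seq_along(labels)],
    label = labels,
    domain = "A",
    case_id = c("p1", "p1", "p2", "p2")[seq_along(labels)]
  ), path)
  path
}

test_that("manifests load, validate, and round-trip", {
  path <- write_demo_manifest(withr::local_tempfile(fileext = ".csv"))
  co <- load_manifest(path)
  expect_equal(nrow(co), 4)
  expect_true(all(co$label %in% 0:1))

  out <- withr::local_tempfile(fileext = ".csv")
  write_manifest(co, out)
  back <- load_manifest(out)
  expect_equal(dplyr::arrange(back[names(co)], .data$tile_id),
               dplyr::arrange(co, .data$tile_id))
})

test_that("manifest schema violations are reported precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(tile_path = "a.png", patient_id = "p",
                                  label = 0), path)
  expect_error(load_manifest(path), "domain")

  bad_label <- write_demo_manifest(withr::local_tempfile(fileext = ".csv"),
                                   labels = c(0, 2, 0, 1))
  expect_error(load_manifest(bad_label), "row 2")

  dup <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    tile_path = c("a.png", "a.png"), patient_id = "p1", label = c(0, 1),
    domain = "A", case_id = "p1"), dup)
  expect_error(load_manifest(dup), "duplicated tile_path")
})

test_that("patient-stratified splitting partitions patients by fractions", {
  co <- flat_cohort(n_patients = 10, tiles_per_class = 4)
  sp <- patient_stratified_split(co, c(0.6, 0.2, 0.2), seed = 7)
  pids <- lapply(sp, function(s) unique(s$patient_id))
  expect_equal(lengths(pids), c(train = 6, val = 2, test = 2))
  expect_length(Reduce(intersect, pids), 0)
  expect_setequal(unlist(pids), unique(co$patient_id))
  # every tile of a patient lands with its patient
  expect_equal(sum(sapply(sp, nrow)), nrow(co))

  sp2 <- patient_stratified_split(co, c(0.6, 0.2, 0.2), seed = 7)
  expect_identical(lapply(sp, `[[`, "tile_id"), lapply(sp2, `[[`, "tile_id"))
})

test_that("splitting errors on ambiguous or degenerate cohorts", {
  co2 <- flat_cohort(4, 2)
  co2$domain[1] <- "B"
  expect_error(patient_stratified_split(co2), "multiple domains")
  expect_error(patient_stratified_split(flat_cohort(2, 2)),
               "fewer patients")
  expect_error(patient_stratified_split(flat_cohort(10, 2),
                                        fractions = c(0.5, 0.5, 0.5)),
               "summing to 1")
})

test_that("split class balance stays near the cohort balance", {
  # patients carry a single class each, so balance is a real constraint
  co <- flat_cohort(n_patients = 20, tiles_per_class = 5,
                    one_class_patients = TRUE)
  overall <- mean(co$label == 1)
  for (s in 1:10) {
    sp <- patient_stratified_split(co, seed = s, balance_tol = 0.1)
    devs <- sapply(sp, function(x) abs(mean(x$label == 1) - overall))
    expect_lte(max(devs), 0.1)
  }
})

test_that("per-case tile sampling clamps, dedupes, and is seed-stable", {
  co <- flat_cohort(n_patients = 2, tiles_per_class = 200)
  sub <- sample_tiles_per_case(co, 80, seed = 3)
  counts <- dplyr::count(sub, .data$case_id, .data$label)
  expect_true(all(counts$n == 80))
  expect_equal(anyDuplicated(sub$tile_id), 0)

  small <- flat_cohort(n_patients = 2, tiles_per_class = 30)
  expect_equal(nrow(sample_tiles_per_case(small, 80, seed = 1)), nrow(small))

  expect_identical(sample_tiles_per_case(co, 80, seed = 3)$tile_id,
                   sub$tile_id)
})
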