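two_domain_cohorts <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      co <- generate_cohort(12, 3, size = 64, seed = 77)
      memo <<- list(internal = dplyr::filter(co, .data$domain == "A"),
                    external = dplyr::filter(co, .data$domain == "B"))
    }
    memo
  }
})

test_that("accuracy and delta follow their definitions", {
  expect_equal(accuracy(c(1, 0, 1), c(1, 0, 1)), 1.0)
  expect_equal(accuracy(rep(0, 10), c(rep(0, 5), rep(1, 5))), 0.5)
  expect_error(accuracy(c(1, 0), c(1)), "length mismatch")
  expect_error(accuracy(integer(0), integer(0)), "nonempty")

  expect_equal(delta_performance(0.9, 0.8), 0.1)
  expect_equal(delta_performance(0.5, 0.5), 0.0)
  expect_equal(delta_performance(0.4, 0.9), -0.5)
  expect_error(delta_performance(1.2, 0.5), ">= 0|<= 1")
})

test_that("the paired sign test counts signs exactly", {
  res <- paired_sign_test(c(0.1, 0.2, 0.05, -0.01, 0.3))
  expect_equal(res$n_positive, 4L)
  expect_equal(res$n_nonzero, 5L)
  expect_equal(res$p_value, stats::binom.test(4, 5)$p.value)
  expect_equal(paired_sign_test(c(0, 0))$p_value, 1)
})

test_that("the harness rejects leaking or same-domain cohorts", {
  cos <- two_domain_cohorts()
  leaky <- cos$external
  leaky$patient_id[1] <- cos$internal$patient_id[1]
  expect_error(run_normalization_experiment(cos$internal, leaky),
               "share patient")
  same <- cos$internal
  same$patient_id <- paste0("x_", same$patient_id)
  same$tile_id <- paste0("x_", same$tile_id)
  expect_error(run_normalization_experiment(cos$internal, same),
               "different domain")
})

test_that("the normalization experiment reports every mode and dataset", {
  cos <- two_domain_cohorts()
  rep <- run_normalization_experiment(
    cos$internal, cos$external, n_seeds = 2, seed = 5,
    config = fast_config())
  expect_s3_class(rep, "normalization_experiment")
  g <- glance(rep)
  expect_equal(nrow(g), 3 * 2)  # 3 modes x {internal, external}
  expect_setequal(unique(g$mode),
                  c("raw", "stain_normalized", "hsv_augmented"))
  expect_true(all(g$mean_accuracy >= 0 & g$mean_accuracy <= 1))
  runs <- tidy(rep)
  expect_equal(nrow(runs), 3 * 2 * 2)
  # paired design: every mode ran under the same seeds
  expect_equal(dplyr::n_distinct(runs$seed_index), 2)
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})

test_that("the artifact experiment produces coherent paired curves", {
  cos <- two_domain_cohorts()
  rep <- run_artifact_experiment(
    cos$internal, cos$external, family = "brightness",
    strengths = c(0, 40), n_seeds = 2, seed = 5, config = fast_config())
  g <- glance(rep)
  expect_equal(nrow(g), 2 * 2)  # strengths x datasets
  expect_equal(g$delta, g$acc_with - g$acc_without, tolerance = 1e-12)
  # neutral strength: both arms trained on identical data -> identical
  neutral <- dplyr::filter(tidy(rep), .data$strength == 0)
  expect_equal(neutral$acc_with, neutral$acc_without)
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})

test_that("the ensemble experiment pairs all three modes per seed", {
  cos <- two_domain_cohorts()
  rep <- run_ensemble_experiment(
    cos$internal, cos$external, n_members = 3, n_seeds = 2, seed = 5,
    config = fast_config())
  g <- glance(rep)
  expect_setequal(unique(g$mode), c("single", "bagging", "noisy"))
  expect_equal(nrow(g), 3 * 2)
  expect_true(all(c("bagging_minus_single", "noisy_minus_bagging",
                    "sign_p_noisy_vs_bagging") %in% names(rep$paired)))
  runs <- tidy(rep)
  expect_equal(nrow(runs), 3 * 2 * 2)
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})

test_that("reports serialize to JSON and CSV", {
  cos <- two_domain_cohorts()
  rep <- run_artifact_experiment(
    cos$internal, cos$external, family = "brightness", strengths = 40,
    n_seeds = 1, seed = 5, config = fast_config())
  pj <- withr::local_tempfile(fileext = ".json")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, pj, pc)
  parsed <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(parsed$kind, "artifact_experiment")
  expect_equal(nrow(parsed$summary), nrow(rep$summary))
  expect_equal(nrow(readr::read_csv(pc, show_col_types = FALSE)),
               nrow(rep$summary))
})
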