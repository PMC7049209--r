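test_that("patient folds are balanced, exhaustive and deterministic", {
  pats <- sprintf("p%03d", 1:252)
  f <- make_folds(pats, 10, seed = 3)
  sizes <- sort(as.integer(table(f)))
  expect_equal(sizes, c(rep(25L, 8), rep(26L, 2)))
  expect_setequal(names(f), pats)
  expect_equal(f, make_folds(pats, 10, seed = 3))
  expect_false(identical(f, make_folds(pats, 10, seed = 4)))

  # leave-one-patient-out boundary
  loo <- make_folds(sprintf("q%02d", 1:34), 34, seed = 1)
  expect_equal(sort(as.integer(table(loo))), rep(1L, 34))
  expect_error(make_folds(sprintf("q%02d", 1:3), 10), "more folds")
})

test_that("the rank-based AUC matches brute-force pair counting", {
  expect_equal(compute_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(pair_counting_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)

  # perfect separation and complete ties
  expect_equal(compute_auc(c(1, 2, 9, 10), c(0, 0, 1, 1)), 1)
  expect_equal(compute_auc(rep(2, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  expect_error(compute_auc(1:4, c(1, 1, 1, 1)), "both outcome classes")

  # random instances, with ties, against the oracle and an independent
  # reference implementation
  set.seed(42)
  for (i in 1:20) {
    scores <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)
    labels <- rbinom(30, 1, 0.4)
    if (length(unique(labels)) < 2) next
    auc <- compute_auc(scores, labels)
    expect_equal(auc, pair_counting_auc(scores, labels))
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(auc, ref)
    }
  }
})

test_that("random guessing gives exactly 1/k", {
  expect_equal(random_guess_baseline(1), 1)
  expect_equal(random_guess_baseline(2), 0.5)
  expect_equal(random_guess_baseline(6), 1 / 6)
  expect_error(random_guess_baseline(0), "positive")
})

test_that("calibration intervals follow the remainder-to-last rule", {
  ct <- calibration_table(runif(120), rbinom(120, 1, 0.5), bin_size = 50)
  expect_equal(ct$n, c(50L, 70L))

  ct2 <- calibration_table(runif(50), rbinom(50, 1, 0.5), bin_size = 50)
  expect_equal(ct2$n, 50L)

  expect_warning(
    ct3 <- calibration_table(runif(10), rbinom(10, 1, 0.5), bin_size = 50),
    "single interval"
  )
  expect_equal(ct3$n, 10L)
  expect_equal(sum(ct3$n), 10L)

  # intervals are ordered in predicted probability and counts sum to n
  set.seed(7)
  p <- runif(637)
  ct4 <- calibration_table(p, rbinom(637, 1, p), bin_size = 50)
  expect_equal(sum(ct4$n), 637L)
  expect_equal(nrow(ct4), 12)
  expect_true(all(diff(ct4$mean_predicted) > 0))
})

test_that("cross-validation accounts for every patient exactly once", {
  co <- sample_cohort(sim_config(n_patients = 60, signal_scale = 6,
                                 seed = 501))
  ev <- cross_validate(co, eval_control(
    outer_folds = 5, seed = 2,
    boosting = boost_control(max_iterations = 60, inner_cv_folds = 5,
                             seed = 2)
  ))
  pr <- ev$patient_results
  expect_setequal(pr$patient_id, unique(co$patient_id))
  expect_equal(anyDuplicated(pr$patient_id), 0L)
  # held-out fold of each patient matches the fold assignment (no leakage)
  folds <- make_folds(co, 5, seed = 2)
  expect_equal(pr$fold, unname(folds[pr$patient_id]))
  # aggregation identities
  expect_equal(sum(ev$per_fold$correct), sum(pr$correct))
  expect_equal(ev$overall_accuracy,
               sum(ev$stratified_accuracy$correct) /
                 sum(ev$stratified_accuracy$patients))
  expect_equal(ev$overall_accuracy,
               sum(ev$stratified_accuracy$accuracy *
                     ev$stratified_accuracy$patients) /
                 sum(ev$stratified_accuracy$patients))
  expect_equal(ev$stratified_accuracy$baseline,
               1 / ev$stratified_accuracy$k)
})

test_that("a strong score signal beats random guessing in every stratum", {
  co <- sample_cohort(sim_config(n_patients = 150, signal_scale = 6,
                                 seed = 502))
  ev <- cross_validate(co, eval_control(
    seed = 3, boosting = boost_control(max_iterations = 150, seed = 3)
  ))
  s <- ev$stratified_accuracy
  expect_true(all(s$accuracy > s$baseline))
  expect_gt(ev$overall_accuracy, 0.6)
  expect_gt(ev$mean_test_auc, 0.6)
  # overfitting control: held-out AUC does not exceed training AUC by more
  # than Monte-Carlo noise
  expect_lte(ev$mean_test_auc, ev$mean_train_auc + 0.05)
})

test_that("a stratum with a single patient is all-or-nothing", {
  co <- sample_cohort(sim_config(n_patients = 59,
                                 aneurysm_count_weights = c(`2` = 1),
                                 signal_scale = 6, seed = 503))
  six <- mia_cohort(
    patient_id = rep("big", 6), aneurysm_id = paste0("big", 1:6),
    size_mm = c(12, 3, 4, 5, 6, 7),
    location = c("ACOM_AA", "MCA", "PCOM", "POSTERIOR", "ICA_WO_PCOM", "MCA"),
    shape = c("irregular", rep("regular", 5)),
    ruptured = c(1, 0, 0, 0, 0, 0),
    age_years = 55, smoker = 1, hypertension = 1
  )
  both <- mia_cohort(
    c(co$patient_id, six$patient_id), c(co$aneurysm_id, six$aneurysm_id),
    c(co$size_mm, six$size_mm), c(co$location, six$location),
    c(co$shape, six$shape), c(co$ruptured, six$ruptured),
    c(co$age_years, six$age_years), c(co$smoker, six$smoker),
    c(co$hypertension, six$hypertension)
  )
  ev <- cross_validate(both, eval_control(
    outer_folds = 5, seed = 4,
    boosting = boost_control(max_iterations = 60, inner_cv_folds = 5,
                             seed = 4)
  ))
  s6 <- ev$stratified_accuracy[ev$stratified_accuracy$k == 6, ]
  expect_equal(s6$patients, 1)
  expect_true(s6$accuracy %in% c(0, 1))
})

test_that("evaluation preconditions are enforced", {
  co <- sample_cohort(sim_config(n_patients = 30, seed = 504))
  unlab <- co
  unlab$ruptured <- NA
  expect_error(cross_validate(unlab), "labelled")
  umissing <- co
  umissing$shape[1] <- NA
  expect_error(cross_validate(umissing), "imputed")
  single <- co
  single <- rbind(single,
                  mia_cohort("solo", "solo1", 5, "MCA", "regular", 1, 50, 0, 0))
  expect_error(cross_validate(single), "multiple-aneurysm")
})
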