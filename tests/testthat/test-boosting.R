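test_that("the design counts co-located aneurysms and centers on request", {
  co <- mia_cohort(
    patient_id = c("a", "a", "b", "b"),
    aneurysm_id = c("a1", "a2", "b1", "b2"),
    size_mm = c(5, 7, 6, 4),
    location = c("MCA", "MCA", "MCA", "PCOM"),
    shape = c("regular", "regular", "regular", "regular"),
    ruptured = c(1, 0, 0, 1),
    age_years = 50, smoker = 0, hypertension = 1
  )
  d <- build_design(co)
  expect_equal(unname(d$X[, "additional_same_region"]), c(1, 1, 0, 0))
  expect_equal(unname(d$X[, "aneurysms_per_patient"]), c(2, 2, 2, 2))
  expect_equal(unname(d$X[, "loc_MCA"]), c(1, 1, 1, 0))

  co$shape[1] <- NA
  expect_error(build_design(co), "impute")
})

test_that("zero boosting iterations leave the base-rate model", {
  co <- sample_cohort(sim_config(n_patients = 40, seed = 401))
  fit <- boost_fit(co, boost_control(seed = 1), m_stop = 0)
  expect_true(all(fit$coefficients == 0))
  expect_true(all(fit$random_intercepts == 0))
  p <- predict_prob(fit, co)
  expect_equal(unique(p), mean(co$ruptured))
})

test_that("the first iteration selects the brute-force best base learner", {
  for (seed in c(402, 403, 404)) {
    co <- sample_cohort(sim_config(n_patients = 60, signal_scale = 3,
                                   seed = seed))
    for (ranef in c(TRUE, FALSE)) {
      ctl <- boost_control(use_random_effect = ranef, seed = 1)
      fit <- boost_fit(co, ctl, m_stop = 1)
      expect_equal(fit$selection_path, brute_force_selection(co, ctl))
    }
  }
})

test_that("training deviance never increases along the path", {
  co <- sample_cohort(sim_config(n_patients = 80, signal_scale = 2,
                                 seed = 405))
  for (nu in c(0.1, 0.5, 1)) {
    fit <- boost_fit(co, boost_control(nu = nu, seed = 1), m_stop = 150)
    expect_true(all(diff(fit$deviance_path) <= 1e-9))
    expect_equal(length(fit$selection_path), 150L)
  }
})

test_that("coefficients shrink toward zero with earlier stopping", {
  co <- sample_cohort(sim_config(n_patients = 150, signal_scale = 3,
                                 seed = 406))
  ctl <- boost_control(seed = 1)
  early <- boost_fit(co, ctl, m_stop = 30)
  late <- boost_fit(co, ctl, m_stop = 600)
  expect_lte(abs(early$coefficients["size_mm"]),
             abs(late$coefficients["size_mm"]))
  expect_lte(sum(abs(early$coefficients)), sum(abs(late$coefficients)))
  # per-iteration step bound: |beta| <= nu * m * max least-squares step
  expect_lte(abs(early$coefficients["size_mm"]), 0.1 * 30 * 1)
})

test_that("an outcome-independent covariate is rarely selected", {
  co <- sample_cohort(sim_config(n_patients = 200, signal_scale = 4,
                                 seed = 407))
  set.seed(408)
  co$age_years <- sample(co$age_years)   # break any incidental association
  fit <- boost_fit(co, boost_control(seed = 1), m_stop = 50)
  expect_lt(sum(fit$selection_path == "age_years"), 25)
})

test_that("probabilities and the extracted score rank patients identically", {
  co <- sample_cohort(sim_config(n_patients = 120, signal_scale = 3,
                                 seed = 409))
  # candidate set: aneurysm-specific terms plus covariates that are constant
  # within a patient, so the probability ranking is score-driven
  ctl <- boost_control(seed = 1, candidate_covariates = c(
    "size_mm", "loc_PCOM", "loc_POSTERIOR", "loc_MCA", "loc_ICA_WO_PCOM",
    "shape_irregular", "age_years", "smoker", "hypertension",
    "aneurysms_per_patient"
  ))
  fit <- boost_fit(co, ctl, m_stop = 300)
  p <- predict_prob(fit, co, use_random_effects = FALSE)
  s <- compute_score(co$size_mm, co$location, co$shape, extract_score(fit))
  for (rows in split(seq_len(nrow(co)), co$patient_id)) {
    expect_equal(order(p[rows]), order(s[rows]))
  }
  # monotone link: increasing size with a positive slope raises probability
  expect_gt(fit$coefficients["size_mm"], 0)
  co2 <- co
  co2$size_mm <- co2$size_mm + 1
  expect_true(all(predict_prob(fit, co2) > predict_prob(fit, co)))
})

test_that("an all-zero fit extracts an all-zero score", {
  co <- sample_cohort(sim_config(n_patients = 40, seed = 410))
  fit <- boost_fit(co, boost_control(seed = 1), m_stop = 0)
  cf <- extract_score(fit)
  expect_equal(cf$size_slope, 0)
  expect_true(all(cf$location_offset == 0))
  expect_equal(cf$irregular_offset, 0)
})

test_that("stopping-iteration tuning is deterministic and bounded", {
  co <- sample_cohort(sim_config(n_patients = 60, signal_scale = 2,
                                 seed = 411))
  ctl <- boost_control(max_iterations = 60, inner_cv_folds = 5, seed = 9)
  a <- select_mstop(co, ctl)
  b <- select_mstop(co, ctl)
  expect_equal(a$m_stop, b$m_stop)
  expect_equal(a$cv_deviance, b$cv_deviance)
  expect_equal(length(a$cv_deviance), 60)

  ctl1 <- boost_control(max_iterations = 1, inner_cv_folds = 5, seed = 9)
  expect_equal(select_mstop(co, ctl1)$m_stop, 1L)

  tiny <- co[co$patient_id %in% unique(co$patient_id)[1:3], ]
  expect_error(select_mstop(tiny, ctl), "fewer patients")
})

test_that("pure-noise data select an early stopping iteration", {
  co <- sample_cohort(sim_config(n_patients = 120, signal_scale = 0,
                                 seed = 412))
  ctl <- boost_control(max_iterations = 200, inner_cv_folds = 5, seed = 5)
  sel <- select_mstop(co, ctl)
  expect_lt(sel$m_stop, 100)
})

test_that("degenerate outcomes and invalid stopping points are rejected", {
  co <- mini_cohort()
  co$ruptured <- c(1, 1, 1, 1)
  expect_error(boost_fit(co, boost_control(seed = 1), 10), "degenerate")
  expect_error(boost_fit(mini_cohort(), boost_control(max_iterations = 5,
                                                      seed = 1), 10),
               "max_iterations")
})

test_that("a boosting fit round-trips through versioned JSON", {
  co <- sample_cohort(sim_config(n_patients = 50, signal_scale = 2,
                                 seed = 413))
  fit <- boost_fit(co, boost_control(seed = 1), m_stop = 40)
  path <- withr::local_tempfile(fileext = ".json")
  write_boost_fit(fit, path)
  back <- read_boost_fit(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$random_intercepts, fit$random_intercepts)
  expect_equal(back$selection_path, fit$selection_path)
  expect_equal(predict_prob(back, co), predict_prob(fit, co))
})
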