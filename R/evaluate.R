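#' Patient-level fold assignment
#'
#' Splits patients into `k` mutually exclusive, exhaustive folds whose sizes
#' differ by at most one; all aneurysms of a patient share its fold.
#' Deterministic given `seed`.
#'
#' @param patients a `mia_cohort` or a character vector of patient ids.
#' @param k number of folds (at most the number of patients).
#' @param seed integer seed.
#' @return named integer vector, patient_id -> fold in `1:k`.
#' @export
make_folds <- function(patients, k, seed = 1) {
  if (inherits(patients, "mia_cohort") || is.data.frame(patients)) {
    patients <- unique(patients$patient_id)
  }
  patients <- unique(as.character(patients))
  n <- length(patients)
  if (k > n) stop("more folds (", k, ") than patients (", n, ")")
  if (k < 1) stop("k must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(patients)
  folds <- rep(seq_len(k), length.out = n)
  stats::setNames(folds[match(patients, shuffled)], patients)
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Random-guessing baseline
#'
#' Probability of identifying the ruptured aneurysm among `k` candidates by
#' chance: exactly `1/k`.
#'
#' @param k number of aneurysms, a positive integer (vectorized).
#' @return numeric vector.
#' @export
random_guess_baseline <- function(k) {
  if (any(k < 1)) stop("k must be a positive integer")
  1 / k
}

#' Rank-based AUC
#'
#' Mann-Whitney area under the ROC curve with ties counted one half:
#' the proportion of (positive, negative) pairs in which the positive scores
#' higher, ties contributing 1/2.
#'
#' @param scores numeric predictor values.
#' @param labels binary outcomes (0/1 or logical); both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both outcome classes must be present")
  }
  r <- rank(scores)                        # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration table of binned predicted probabilities
#'
#' Orders the fitted probabilities and splits them into `floor(n/bin_size)`
#' intervals of `bin_size` observations, appending the remainder to the last
#' interval. Each interval reports the mean predicted probability, the
#' observed rupture frequency and its size.
#'
#' @param probabilities fitted per-aneurysm probabilities.
#' @param outcomes binary outcomes, same length.
#' @param bin_size observations per interval (the published construction uses
#'   50); if fewer than `bin_size` observations exist, a single interval is
#'   returned with a warning.
#' @return data frame (`bin`, `n`, `mean_predicted`, `observed_rate`), with
#'   attribute `"single_bin_warning"` set when n < bin_size. Counts sum to n.
#' @export
calibration_table <- function(probabilities, outcomes, bin_size = 50) {
  stopifnot(bin_size >= 1, length(probabilities) == length(outcomes))
  n <- length(probabilities)
  if (n < 1) stop("no observations")
  ord <- order(probabilities)
  p <- probabilities[ord]
  y <- as.numeric(outcomes)[ord]
  warn <- n < bin_size
  n_bins <- max(1L, as.integer(floor(n / bin_size)))
  bin <- pmin(ceiling(seq_len(n) / bin_size), n_bins)  # remainder -> last
  out <- data.frame(
    bin = seq_len(n_bins),
    n = as.integer(tabulate(bin, nbins = n_bins)),
    mean_predicted = as.numeric(tapply(p, bin, mean)),
    observed_rate = as.numeric(tapply(y, bin, mean))
  )
  if (warn) {
    warning("fewer observations (", n, ") than bin_size (", bin_size,
            "); returning a single interval")
    attr(out, "single_bin_warning") <- TRUE
  }
  out
}

#' Evaluation configuration
#'
#' @param outer_folds outer patient-level cross-validation folds.
#' @param seed seed for the outer fold assignment; the inner fold seeds are
#'   derived from it deterministically.
#' @param boosting a [boost_control()].
#' @param tie_policy patient-level accuracy counting when the maximal score
#'   is tied: `"non_strict"` (correct if the ruptured aneurysm lies in the
#'   argmax set), `"fractional"` (expected correctness of a uniform random
#'   pick among the tied maxima — the accounting under which a fully
#'   uninformative score scores exactly the 1/k baseline), `"first"`, or
#'   `"error"`.
#' @return list of class `mia_eval_control`.
#' @export
eval_control <- function(outer_folds = 10, seed = 1,
                         boosting = boost_control(),
                         tie_policy = c("non_strict", "fractional", "first",
                                        "error")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(outer_folds >= 2)
  structure(
    list(outer_folds = as.integer(outer_folds), seed = as.integer(seed),
         boosting = boosting, tie_policy = tie_policy),
    class = "mia_eval_control"
  )
}

#' Patient-level cross-validated evaluation
#'
#' For each outer fold: tunes the stopping iteration by inner patient-level
#' cross-validation on the learning sample ([select_mstop()]), fits the
#' boosting model, extracts the aneurysm-specific score ([extract_score()]),
#' ranks the held-out patients' aneurysms by that score and counts a patient
#' as correctly classified when the predicted aneurysm is the true bleeding
#' source (under the configured tie policy). Aneurysm-level AUCs are computed
#' from predicted probabilities (random intercepts excluded, so held-out and
#' training aneurysms are scored on the same terms). A final model is fitted
#' on the complete data for the complete-data AUC and the calibration table.
#'
#' No held-out patient ever enters its fold's learning sample or the inner
#' tuning loop.
#'
#' @param cohort a labelled multiple-aneurysm `mia_cohort`, shapes imputed.
#' @param control an [eval_control()].
#' @return object of class `mia_evaluation`: `per_fold` (fold, patients,
#'   correct, test/train AUC, m_stop), `overall_accuracy`,
#'   `stratified_accuracy` (per aneurysm-count k: n patients, correct,
#'   accuracy, baseline 1/k), `mean_test_auc`, `mean_train_auc`,
#'   `pooled_test_auc`, `complete_data_auc`, `complete_fit`, `calibration`
#'   (50-per-bin table on the complete-data fitted probabilities), `seed`.
#' @export
cross_validate <- function(cohort, control = eval_control()) {
  if (any(is.na(cohort$ruptured))) stop("cohort must be rupture-labelled")
  if (any(is.na(cohort$shape))) stop("shapes must be imputed")
  counts <- aneurysm_counts(cohort)
  if (any(counts < 2)) {
    stop("evaluation requires a multiple-aneurysm cohort (>= 2 per patient)")
  }
  k <- control$outer_folds
  folds <- make_folds(cohort, k, seed = control$seed)
  per_fold <- vector("list", k)
  patient_rows <- vector("list", k)
  pooled_scores <- numeric(0)
  pooled_labels <- numeric(0)
  for (fold in seq_len(k)) {
    held_pat <- names(folds)[folds == fold]
    test <- cohort[cohort$patient_id %in% held_pat, , drop = FALSE]
    train <- cohort[!(cohort$patient_id %in% held_pat), , drop = FALSE]
    inner_ctl <- control$boosting
    inner_ctl$seed <- control$seed * 1000L + fold   # deterministic derivation
    tuned <- select_mstop(train, inner_ctl)
    fit <- boost_fit(train, inner_ctl, tuned$m_stop)
    coeffs <- extract_score(fit)
    pol <- switch(control$tie_policy, non_strict = "report",
                  fractional = "fractional", first = "first", error = "error")
    ranking <- rank_patients(test, coeffs, tie_policy = pol)
    p_test <- predict_prob(fit, test, use_random_effects = FALSE)
    p_train <- predict_prob(fit, train, use_random_effects = FALSE)
    per_fold[[fold]] <- data.frame(
      fold = fold,
      patients = length(held_pat),
      correct = sum(ranking$correct),
      test_auc = compute_auc(p_test, test$ruptured),
      train_auc = compute_auc(p_train, train$ruptured),
      m_stop = tuned$m_stop
    )
    ranking$fold <- fold
    patient_rows[[fold]] <- ranking
    pooled_scores <- c(pooled_scores, p_test)
    pooled_labels <- c(pooled_labels, test$ruptured)
  }
  per_fold <- do.call(rbind, per_fold)
  patient_results <- do.call(rbind, patient_rows)
  patient_results$k <- counts[patient_results$patient_id]

  strata <- sort(unique(patient_results$k))
  stratified <- do.call(rbind, lapply(strata, function(kk) {
    rows <- patient_results[patient_results$k == kk, ]
    data.frame(k = kk, patients = nrow(rows), correct = sum(rows$correct),
               accuracy = mean(rows$correct),
               baseline = random_guess_baseline(kk))
  }))

  # complete-data fit for the complete-data AUC and the calibration table
  complete_ctl <- control$boosting
  complete_ctl$seed <- control$seed * 1000L
  tuned_all <- select_mstop(cohort, complete_ctl)
  complete_fit <- boost_fit(cohort, complete_ctl, tuned_all$m_stop)
  p_all <- predict_prob(complete_fit, cohort, use_random_effects = FALSE)
  calibration <- calibration_table(p_all, cohort$ruptured, bin_size = 50)

  structure(
    list(per_fold = per_fold,
         patient_results = patient_results,
         overall_accuracy = mean(patient_results$correct),
         stratified_accuracy = stratified,
         mean_test_auc = mean(per_fold$test_auc),
         mean_train_auc = mean(per_fold$train_auc),
         pooled_test_auc = compute_auc(pooled_scores, pooled_labels),
         complete_data_auc = compute_auc(p_all, cohort$ruptured),
         complete_fit = complete_fit,
         calibration = calibration,
         seed = control$seed),
    class = "mia_evaluation"
  )
}

#' @export
print.mia_evaluation <- function(x, ...) {
  cat("<mia_evaluation>\n")
  cat(sprintf("  patients correctly classified: %g / %d (%.1f%%)\n",
              sum(x$per_fold$correct), sum(x$per_fold$patients),
              100 * x$overall_accuracy))
  cat(sprintf("  mean AUC  test %.4f | train %.4f | complete data %.4f\n",
              x$mean_test_auc, x$mean_train_auc, x$complete_data_auc))
  cat("  accuracy by aneurysm count (baseline = 1/k):\n")
  s <- x$stratified_accuracy
  for (i in seq_len(nrow(s))) {
    cat(sprintf("    k=%d  %2d patient(s)  %.0f%% (baseline %.0f%%)\n",
                s$k[i], s$patients[i], 100 * s$accuracy[i],
                100 * s$baseline[i]))
  }
  invisible(x)
}
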