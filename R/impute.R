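#' Single imputation of missing aneurysm shape
#'
#' Fits one logistic regression of irregular-vs-regular shape on all other
#' variables (size, location, rupture outcome, patient covariates and the
#' recomputed per-patient counts) over the complete cases, then
#' deterministically assigns each missing shape: `irregular` iff the fitted
#' irregular probability is at least `threshold`. No stochastic draw, no
#' multiple imputation.
#'
#' @param cohort a `mia_cohort`; shape is the only field allowed to be
#'   missing, and at least one complete case of each shape class must exist.
#' @param threshold assignment cut-point in (0, 1); the boundary case (fitted
#'   probability exactly equal to the threshold) is assigned `irregular`.
#' @return list of class `mia_imputation`: `cohort` (no missing shapes; all
#'   non-missing fields untouched) and `report` (`n_missing`,
#'   `n_imputed_regular`, `n_imputed_irregular`, `model_coefficients`,
#'   `threshold`).
#' @export
impute_shape <- function(cohort, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  miss <- is.na(cohort$shape)
  report <- list(n_missing = sum(miss), n_imputed_regular = 0L,
                 n_imputed_irregular = 0L, model_coefficients = NULL,
                 threshold = threshold)
  if (!any(miss)) {
    return(structure(list(cohort = cohort, report = report),
                     class = "mia_imputation"))
  }
  other <- c("size_mm", "location", "ruptured", "age_years", "smoker",
             "hypertension")
  for (v in other) {
    if (anyNA(cohort[[v]])) {
      stop("only shape may be missing; found missing values in ", v)
    }
  }
  df <- as.data.frame(cohort)
  df$location <- factor(df$location, levels = mia_locations)
  df$n_aneurysms <- stats::ave(rep(1, nrow(df)), df$patient_id, FUN = sum)
  df$same_region <- stats::ave(
    rep(1, nrow(df)), paste(df$patient_id, df$location, sep = "\r"),
    FUN = sum
  ) - 1
  df$irr <- as.numeric(df$shape == "irregular")
  complete <- df[!miss, ]
  if (length(unique(complete$irr)) < 2) {
    stop("degenerate imputation model: complete cases contain only one ",
         "shape class")
  }
  model <- stats::glm(
    irr ~ size_mm + location + ruptured + age_years + smoker + hypertension +
      n_aneurysms + same_region,
    data = complete, family = stats::binomial()
  )
  p_irr <- stats::predict(model, newdata = df[miss, ], type = "response")
  imputed <- ifelse(p_irr >= threshold, "irregular", "regular")
  out <- cohort
  out$shape[miss] <- imputed
  report$n_imputed_regular <- sum(imputed == "regular")
  report$n_imputed_irregular <- sum(imputed == "irregular")
  report$model_coefficients <- stats::coef(model)
  structure(list(cohort = out, report = report), class = "mia_imputation")
}

#' @export
print.mia_imputation <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<mia_imputation> %d missing shape(s): %d imputed regular, %d irregular (threshold %.2f)\n",
    r$n_missing, r$n_imputed_regular, r$n_imputed_irregular, r$threshold
  ))
  invisible(x)
}
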