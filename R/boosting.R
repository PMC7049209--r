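#' Boosting configuration
#'
#' Tuning parameters for component-wise gradient boosting of the binomial
#' model with logistic link.
#'
#' @param nu step length in (0, 1]; each selected base-learner fit is added
#'   to the additive predictor scaled by `nu`.
#' @param max_iterations upper bound on the number of boosting iterations
#'   (the search space for the stopping iteration).
#' @param inner_cv_folds folds of the inner patient-level cross-validation
#'   that tunes the stopping iteration.
#' @param random_effect_df effective degrees of freedom of the
#'   ridge-penalized patient-intercept base learner.
#' @param use_random_effect include the patient-intercept learner among the
#'   candidates?
#' @param learner `"componentwise"` (one simple linear learner per covariate,
#'   data-driven selection) or `"joint"` (a single multivariable
#'   least-squares learner over all covariates: selection disabled, the fit
#'   converges to the unpenalized logistic maximum likelihood solution as the
#'   iteration count grows).
#' @param candidate_covariates character vector naming the candidate design
#'   columns; `NULL` means all columns produced by [build_design()].
#' @param seed integer seed consumed by the inner cross-validation.
#' @return list of class `mia_boost_control`.
#' @export
boost_control <- function(nu = 0.1, max_iterations = 1000, inner_cv_folds = 10,
                          random_effect_df = 4, use_random_effect = TRUE,
                          learner = c("componentwise", "joint"),
                          candidate_covariates = NULL, seed = 1) {
  learner <- match.arg(learner)
  stopifnot(nu > 0, nu <= 1, max_iterations >= 1, inner_cv_folds >= 2,
            random_effect_df > 0)
  structure(
    list(nu = nu, max_iterations = as.integer(max_iterations),
         inner_cv_folds = as.integer(inner_cv_folds),
         random_effect_df = random_effect_df,
         use_random_effect = use_random_effect,
         learner = learner,
         candidate_covariates = candidate_covariates,
         seed = as.integer(seed)),
    class = "mia_boost_control"
  )
}

#' Build the analysis design from a cohort
#'
#' One row per aneurysm: size in mm, location dummies with `ACOM_AA` as
#' reference, irregular-shape dummy, patient covariates (age, smoking,
#' hypertension), the recomputed number of aneurysms per patient and the
#' number of the patient's additional aneurysms in the same region. Continuous
#' columns are used centered during fitting; the raw matrix and the centering
#' constants are both carried so held-out data can be centered on the
#' training sample.
#'
#' @param cohort a `mia_cohort`; shapes must be imputed and the covariates
#'   complete.
#' @return list of class `mia_design`: `X` (raw numeric matrix), `y` (0/1
#'   outcome, `NA` if unlabelled), `patient` (grouping key), `covariates`
#'   (column names), `aneurysm_id`.
#' @export
build_design <- function(cohort) {
  if (any(is.na(cohort$shape))) {
    stop("design requires imputed shapes; run impute_shape() first")
  }
  n_per_patient <- stats::ave(rep(1, nrow(cohort)), cohort$patient_id,
                              FUN = sum)
  same_region <- stats::ave(
    rep(1, nrow(cohort)),
    paste(cohort$patient_id, cohort$location, sep = "\r"),
    FUN = sum
  ) - 1
  X <- cbind(
    size_mm = cohort$size_mm,
    loc_PCOM = as.numeric(cohort$location == "PCOM"),
    loc_POSTERIOR = as.numeric(cohort$location == "POSTERIOR"),
    loc_MCA = as.numeric(cohort$location == "MCA"),
    loc_ICA_WO_PCOM = as.numeric(cohort$location == "ICA_WO_PCOM"),
    shape_irregular = as.numeric(cohort$shape == "irregular"),
    age_years = cohort$age_years,
    smoker = cohort$smoker,
    hypertension = cohort$hypertension,
    aneurysms_per_patient = n_per_patient,
    additional_same_region = same_region
  )
  if (anyNA(X)) {
    bad <- colnames(X)[apply(X, 2, anyNA)]
    stop("design has missing values in: ", paste(bad, collapse = ", "))
  }
  structure(
    list(X = X, y = cohort$ruptured, patient = as.character(cohort$patient_id),
         covariates = colnames(X), aneurysm_id = cohort$aneurysm_id),
    class = "mia_design"
  )
}

# ridge penalty giving the patient-intercept learner the requested effective
# degrees of freedom: df(lambda) = sum_g n_g / (n_g + lambda)
ranef_lambda <- function(n_g, df) {
  if (df >= length(n_g)) return(0)
  f <- function(lambda) sum(n_g / (n_g + lambda)) - df
  stats::uniroot(f, lower = 1e-10, upper = 1e10, tol = 1e-9)$root
}

subset_design <- function(design, rows) {
  structure(
    list(X = design$X[rows, , drop = FALSE], y = design$y[rows],
         patient = design$patient[rows], covariates = design$covariates,
         aneurysm_id = design$aneurysm_id[rows]),
    class = "mia_design"
  )
}

binomial_deviance <- function(y, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

# Core boosting loop on a prepared design. Optionally tracks the additive
# predictor of a held-out design (random intercepts of unseen patients are 0),
# returning its deviance after every iteration.
boost_fit_design <- function(design, control, m_stop, holdout = NULL) {
  y <- design$y
  if (anyNA(y)) stop("boosting requires a rupture-labelled cohort")
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate outcome: all aneurysms share the same rupture label")
  }
  covs <- control$candidate_covariates
  if (is.null(covs)) covs <- design$covariates
  stopifnot(all(covs %in% design$covariates))
  Xraw <- design$X[, covs, drop = FALSE]
  centers <- colMeans(Xraw)
  X <- sweep(Xraw, 2, centers)
  n <- nrow(X)
  xss <- colSums(X^2)                     # base-learner normal equations
  constant <- xss < 1e-12                 # constant covariates: never selectable
  pat <- design$patient
  pat_levels <- unique(pat)
  pat_idx <- match(pat, pat_levels)
  n_g <- tabulate(pat_idx, nbins = length(pat_levels))
  lambda <- ranef_lambda(n_g, control$random_effect_df)

  if (!is.null(holdout)) {
    Xh <- sweep(holdout$X[, covs, drop = FALSE], 2, centers)
    f_h <- numeric(nrow(Xh))
    dev_h <- numeric(m_stop)
  }

  f0 <- stats::qlogis(mean(y))            # empirical log-odds offset
  f <- rep(f0, n)
  beta <- stats::setNames(numeric(length(covs)), covs)
  ranef <- stats::setNames(numeric(length(pat_levels)), pat_levels)
  selection_path <- character(m_stop)
  deviance_path <- numeric(m_stop)
  nu <- control$nu

  if (control$learner == "joint") {
    qrX <- qr(cbind(`(intercept)` = 1, X))
    intercept_adj <- 0
    m <- 0L
    while (m < m_stop) {
      m <- m + 1L
      p <- stats::plogis(f)
      u <- y - p                          # negative gradient of the deviance
      cf <- qr.coef(qrX, u)
      cf[is.na(cf)] <- 0
      step <- drop(cbind(1, X) %*% cf)
      f <- f + nu * step
      intercept_adj <- intercept_adj + nu * cf[1]
      beta <- beta + nu * cf[-1]
      selection_path[m] <- "joint"
      deviance_path[m] <- binomial_deviance(y, stats::plogis(f))
      if (!is.null(holdout)) {
        f_h <- f_h + nu * drop(cbind(1, Xh) %*% cf)
        dev_h[m] <- binomial_deviance(holdout$y, stats::plogis(f0 + f_h))
      }
    }
    f0 <- f0 + intercept_adj
  } else {
    m <- 0L
    while (m < m_stop) {
      m <- m + 1L
      p <- stats::plogis(f)
      u <- y - p
      ssu <- sum(u^2)
      b <- drop(crossprod(X, u)) / ifelse(constant, Inf, xss)
      rss <- ssu - b^2 * xss              # RSS of each simple linear learner
      rss[constant] <- Inf
      if (control$use_random_effect) {
        s_g <- drop(rowsum(u, pat_idx))
        b_g <- s_g / (n_g + lambda)
        rss_re <- ssu - 2 * sum(b_g * s_g) + sum(b_g^2 * n_g)
      } else {
        rss_re <- Inf
      }
      if (rss_re < min(rss)) {
        ranef <- ranef + nu * b_g
        f <- f + nu * b_g[pat_idx]
        selection_path[m] <- "(patient)"
      } else {
        j <- which.min(rss)
        beta[j] <- beta[j] + nu * b[j]
        f <- f + nu * b[j] * X[, j]
        selection_path[m] <- covs[j]
        if (!is.null(holdout)) f_h <- f_h + nu * b[j] * Xh[, j]
      }
      deviance_path[m] <- binomial_deviance(y, stats::plogis(f))
      if (!is.null(holdout)) {
        dev_h[m] <- binomial_deviance(holdout$y, stats::plogis(f0 + f_h))
      }
    }
  }

  fit <- structure(
    list(intercept = f0, coefficients = beta, centers = centers,
         random_intercepts = ranef, m_stop = as.integer(m_stop),
         selection_path = selection_path, deviance_path = deviance_path,
         control = control, covariates = covs),
    class = "mia_boost"
  )
  if (!is.null(holdout)) attr(fit, "holdout_deviance") <- dev_h
  fit
}

#' Fit a component-wise gradient boosting model
#'
#' Boosts the binomial deviance under the logistic link with linear base
#' learners: the additive predictor starts at the empirical log-odds of
#' rupture; at each iteration the negative gradient (working residuals
#' `y - p`) is fitted by every candidate learner — one simple linear learner
#' per centered covariate plus a ridge-penalized patient-intercept learner
#' with fixed effective degrees of freedom — and the single component with the
#' smallest residual sum of squares is added to the predictor, scaled by the
#' step length. Early stopping (`m_stop`) is the model's regularizer and is
#' tuned with [select_mstop()].
#'
#' @param cohort a labelled `mia_cohort` with imputed shapes.
#' @param control a [boost_control()].
#' @param m_stop number of boosting iterations (0 returns the intercept-only
#'   initialization; must not exceed `control$max_iterations`).
#' @return object of class `mia_boost`: `intercept` (on the raw covariate
#'   scale the linear predictor is `intercept + sum(beta * (x - centers)) +
#'   random intercept`), `coefficients` (0 for never-selected covariates),
#'   `random_intercepts`, `m_stop`, `selection_path`, `deviance_path`
#'   (training binomial deviance per iteration, non-increasing), `centers`.
#' @export
boost_fit <- function(cohort, control = boost_control(), m_stop) {
  if (m_stop > control$max_iterations) {
    stop("m_stop exceeds control$max_iterations")
  }
  boost_fit_design(build_design(cohort), control, m_stop)
}

#' @export
print.mia_boost <- function(x, ...) {
  cat(sprintf("<mia_boost> %d iteration(s), nu = %g\n", x$m_stop, x$control$nu))
  sel <- x$coefficients[x$coefficients != 0]
  cat("  selected coefficients:\n")
  if (length(sel) == 0) cat("    (none)\n")
  for (nm in names(sel)) cat(sprintf("    %-24s %+.4f\n", nm, sel[[nm]]))
  if (any(x$random_intercepts != 0)) {
    cat(sprintf("  patient random intercepts: sd %.4f\n",
                stats::sd(x$random_intercepts)))
  }
  invisible(x)
}

#' Tune the stopping iteration by inner patient-level cross-validation
#'
#' Splits patients (never single aneurysms) into folds, runs the boosting
#' path on each learning sample and accumulates the held-out binomial
#' deviance after every iteration; returns the iteration minimizing the mean
#' held-out deviance. Deterministic given `control$seed`.
#'
#' @param cohort a labelled `mia_cohort` with imputed shapes.
#' @param control a [boost_control()]; uses `inner_cv_folds`,
#'   `max_iterations` and `seed`.
#' @return list: `m_stop` (selected iteration), `cv_deviance` (mean held-out
#'   deviance per iteration), `fold_deviance` (iterations x folds matrix),
#'   `seed`.
#' @export
select_mstop <- function(cohort, control = boost_control()) {
  design <- build_design(cohort)
  patients <- unique(design$patient)
  k <- control$inner_cv_folds
  if (length(patients) < k) {
    stop("fewer patients (", length(patients), ") than inner folds (", k, ")")
  }
  folds <- make_folds(patients, k, seed = control$seed)
  dev <- matrix(NA_real_, nrow = control$max_iterations, ncol = k)
  for (fold in seq_len(k)) {
    held <- design$patient %in% names(folds)[folds == fold]
    fit <- boost_fit_design(subset_design(design, !held), control,
                            control$max_iterations,
                            holdout = subset_design(design, held))
    dev[, fold] <- attr(fit, "holdout_deviance")
  }
  cv_dev <- rowMeans(dev)
  list(m_stop = which.min(cv_dev), cv_deviance = cv_dev,
       fold_deviance = dev, seed = control$seed)
}

#' Predicted rupture probabilities
#'
#' Inverse-logit of the fitted additive predictor for each aneurysm of a
#' cohort. Covariates are centered with the training constants stored in the
#' fit. Patients unseen during training get a zero random intercept.
#'
#' @param fit a `mia_boost`.
#' @param cohort a `mia_cohort` with imputed shapes.
#' @param use_random_effects add the patient random intercepts?
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(fit, cohort, use_random_effects = TRUE) {
  design <- build_design(cohort)
  X <- sweep(design$X[, fit$covariates, drop = FALSE], 2, fit$centers)
  eta <- fit$intercept + drop(X %*% fit$coefficients)
  if (use_random_effects) {
    re <- fit$random_intercepts[design$patient]
    re[is.na(re)] <- 0
    eta <- eta + unname(re)
  }
  stats::plogis(eta)
}

#' @export
predict.mia_boost <- function(object, newdata, use_random_effects = TRUE, ...) {
  predict_prob(object, newdata, use_random_effects = use_random_effects)
}

#' Extract the aneurysm-specific prediction score from a boosting fit
#'
#' Re-expresses the aneurysm-specific part of the additive predictor (size,
#' location, shape) on the original covariate scale with `ACOM_AA` and
#' regular shape as zero references. Because centering only shifts the
#' intercept, the slopes carry over exactly; dropping the intercept and all
#' patient-level terms leaves within-patient ranking unchanged (they are
#' constant within a patient).
#'
#' @param fit a `mia_boost` whose candidate set contains the size, location
#'   and shape columns.
#' @return a `mia_coefficients`.
#' @export
extract_score <- function(fit) {
  needed <- c("size_mm", "loc_PCOM", "loc_POSTERIOR", "loc_MCA",
              "loc_ICA_WO_PCOM", "shape_irregular")
  if (!all(needed %in% fit$covariates)) {
    stop("fit does not contain the aneurysm-specific covariates: ",
         paste(setdiff(needed, fit$covariates), collapse = ", "))
  }
  b <- fit$coefficients
  score_coefficients(
    size_slope = unname(b["size_mm"]),
    location_offset = c(ACOM_AA = 0,
                        PCOM = unname(b["loc_PCOM"]),
                        POSTERIOR = unname(b["loc_POSTERIOR"]),
                        MCA = unname(b["loc_MCA"]),
                        ICA_WO_PCOM = unname(b["loc_ICA_WO_PCOM"])),
    irregular_offset = unname(b["shape_irregular"])
  )
}

#' Serialize / deserialize a boosting fit
#'
#' Versioned JSON round trip of everything needed to reproduce predictions.
#'
#' @param fit a `mia_boost`.
#' @param path JSON file path.
#' @return `read_boost_fit` returns a `mia_boost`; `write_boost_fit` returns
#'   `path` invisibly.
#' @export
write_boost_fit <- function(fit, path) {
  jsonlite::write_json(
    list(schema_version = 1L,
         intercept = fit$intercept,
         coefficients = as.list(fit$coefficients),
         centers = as.list(fit$centers),
         random_intercepts = as.list(fit$random_intercepts),
         m_stop = fit$m_stop,
         selection_path = fit$selection_path,
         deviance_path = fit$deviance_path,
         covariates = fit$covariates,
         control = unclass(fit$control)),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_boost_fit
#' @export
read_boost_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version) || x$schema_version != 1) {
    stop("unsupported fit schema version")
  }
  ctl <- x$control
  control <- boost_control(
    nu = ctl$nu, max_iterations = ctl$max_iterations,
    inner_cv_folds = ctl$inner_cv_folds,
    random_effect_df = ctl$random_effect_df,
    use_random_effect = ctl$use_random_effect,
    learner = ctl$learner,
    candidate_covariates = ctl$candidate_covariates,
    seed = ctl$seed
  )
  structure(
    list(intercept = x$intercept,
         coefficients = unlist(x$coefficients),
         centers = unlist(x$centers),
         random_intercepts = if (length(x$random_intercepts)) {
           unlist(x$random_intercepts)
         } else {
           stats::setNames(numeric(0), character(0))
         },
         m_stop = as.integer(x$m_stop),
         selection_path = x$selection_path,
         deviance_path = x$deviance_path,
         control = control,
         covariates = x$covariates),
    class = "mia_boost"
  )
}
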