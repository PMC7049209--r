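# small in-code fixtures and independent oracles shared across tests

# two patients, two aneurysms each, fully labelled and covariate-complete
mini_cohort <- function() {
  mia_cohort(
    patient_id = c("a", "a", "b", "b"),
    aneurysm_id = c("a1", "a2", "b1", "b2"),
    size_mm = c(5, 13, 7, 3),
    location = c("ACOM_AA", "MCA", "PCOM", "MCA"),
    shape = c("irregular", "regular", "regular", "regular"),
    ruptured = c(1, 0, 1, 0),
    age_years = c(60, 60, 48, 48),
    smoker = c(1, 1, 0, 0),
    hypertension = c(0, 0, 1, 1)
  )
}

# brute-force AUC over all positive-negative pairs, ties counted one half
pair_counting_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# brute-force base-learner search: refit every candidate learner to the
# residual by explicit (penalized) least squares and return the best name
brute_force_selection <- function(cohort, control) {
  design <- build_design(cohort)
  covs <- design$covariates
  X <- sweep(design$X, 2, colMeans(design$X))
  y <- design$y
  u <- y - mean(y)                       # residual at the log-odds init
  rss <- sapply(seq_along(covs), function(j) {
    x <- X[, j]
    if (sum(x^2) < 1e-12) return(Inf)
    b <- sum(x * u) / sum(x^2)
    sum((u - b * x)^2)
  })
  names(rss) <- covs
  if (control$use_random_effect) {
    pat <- factor(design$patient)
    n_g <- as.numeric(table(pat))
    lam <- tryCatch(
      stats::uniroot(function(l) sum(n_g / (n_g + l)) - control$random_effect_df,
                     c(1e-10, 1e10), tol = 1e-9)$root,
      error = function(e) 0
    )
    s_g <- tapply(u, pat, sum)
    b_g <- s_g / (n_g + lam)
    rss <- c(rss, "(patient)" = sum((u - b_g[pat])^2))
  }
  names(which.min(rss))
}
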