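#' Location regions and shape levels
#'
#' Aneurysm location is collapsed into five vascular regions: anterior
#' cerebral / anterior communicating artery (`ACOM_AA`, the score's reference
#' level), posterior communicating artery (`PCOM`), posterior circulation
#' (`POSTERIOR`: basilar, vertebral, PICA, SCA, P1, vertebrobasilar junction),
#' middle cerebral artery (`MCA`), and internal carotid artery excluding the
#' PcomA segment (`ICA_WO_PCOM`, includes ophthalmic). Shape is dichotomized:
#' a multilobulated aneurysm or one with a bleb is `irregular`, all others are
#' `regular`.
#'
#' @format `mia_locations` is a character vector of length 5; `mia_shapes` of
#'   length 2.
#' @export
mia_locations <- c("ACOM_AA", "PCOM", "POSTERIOR", "MCA", "ICA_WO_PCOM")

#' @rdname mia_locations
#' @export
mia_shapes <- c("regular", "irregular")

# required columns of the cohort CSV interchange schema, in canonical order
cohort_schema <- c(
  "patient_id", "aneurysm_id", "size_mm", "location", "shape",
  "ruptured", "age_years", "smoker", "hypertension"
)

new_cohort <- function(df, provenance = NA_character_) {
  extra <- setdiff(names(df), cohort_schema)
  df <- df[, c(cohort_schema, extra), drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("mia_cohort", "data.frame"), provenance = provenance)
}

#' Assemble a cohort from per-aneurysm fields
#'
#' Low-level constructor used by the reader, the generator and tests. One row
#' per aneurysm; patient covariates are repeated on each of a patient's rows.
#'
#' @param patient_id,aneurysm_id identifiers (character or coercible).
#' @param size_mm maximum aneurysm diameter in millimetres.
#' @param location one of [mia_locations].
#' @param shape `"regular"`, `"irregular"`, or `NA` (missing, pre-imputation).
#' @param ruptured 1, 0 or `NA` (unlabelled cohort).
#' @param age_years,smoker,hypertension patient covariates; may be `NA` for
#'   scoring-only cohorts.
#' @param ... further columns carried along (e.g. `published_score`).
#' @param provenance free-text origin stored as an attribute.
#' @return A `mia_cohort` data frame.
#' @export
mia_cohort <- function(patient_id, aneurysm_id, size_mm, location, shape,
                       ruptured = NA, age_years = NA, smoker = NA,
                       hypertension = NA, ..., provenance = NA_character_) {
  df <- data.frame(
    patient_id = as.character(patient_id),
    aneurysm_id = as.character(aneurysm_id),
    size_mm = as.numeric(size_mm),
    location = as.character(location),
    shape = as.character(shape),
    ruptured = as.numeric(ruptured),
    age_years = as.numeric(age_years),
    smoker = as.numeric(smoker),
    hypertension = as.numeric(hypertension),
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) df[[nm]] <- dots[[nm]]
  new_cohort(df, provenance)
}

#' Read a cohort CSV
#'
#' Reads the one-row-per-aneurysm interchange format (see Details). Hard
#' schema errors (missing column, unparseable location label, duplicated
#' aneurysm id) always abort. Cohort invariants (exactly one rupture per
#' labelled patient, positive size, ...) abort when `strict = TRUE`;
#' otherwise the cohort is returned with the violation report attached as
#' attribute `"validation"`.
#'
#' @details Required columns: `patient_id, aneurysm_id, size_mm, location,
#'   shape, ruptured, age_years, smoker, hypertension`. `location` must be one
#'   of [mia_locations]; `shape` one of `regular`, `irregular`, `NA`;
#'   `ruptured` in `{1, 0, NA}`. Extra columns are preserved.
#'
#' @param path path to a CSV file.
#' @param strict abort on any invariant violation?
#' @return A `mia_cohort`.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(cohort_schema, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_loc <- which(!(df$location %in% mia_locations))
  if (length(bad_loc) > 0) {
    stop("unknown location label ", sQuote(df$location[bad_loc[1]]),
         " in row ", bad_loc[1],
         " (allowed: ", paste(mia_locations, collapse = ", "), ")")
  }
  dup <- df$aneurysm_id[duplicated(df$aneurysm_id)]
  if (length(dup) > 0) {
    stop("integrity error: duplicated aneurysm_id: ",
         paste(unique(dup), collapse = ", "))
  }
  cohort <- mia_cohort(
    df$patient_id, df$aneurysm_id, df$size_mm, df$location, df$shape,
    df$ruptured, df$age_years, df$smoker, df$hypertension,
    provenance = path
  )
  for (nm in setdiff(names(df), cohort_schema)) cohort[[nm]] <- df[[nm]]
  report <- validate_cohort(cohort)
  if (strict && nrow(report) > 0) {
    stop("invalid cohort (", nrow(report), " violation(s)); first: ",
         report$message[1])
  }
  attr(cohort, "validation") <- report
  cohort
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: writes the interchange CSV so that reading it
#' back reproduces the cohort field by field.
#'
#' @param cohort a `mia_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate cohort invariants
#'
#' Never raises: returns a report with one row per violation (empty when the
#' cohort is valid). Checked invariants: size in (0, 100]; known location and
#' shape labels; ruptured in \{1, 0, NA\}; unique patient/aneurysm ids (within
#' the data frame aneurysm ids must be globally unique); in a rupture-labelled
#' cohort exactly one ruptured aneurysm per patient (a single bleeding
#' source); optionally every patient harbors at least two aneurysms.
#'
#' @param cohort a `mia_cohort` or compatible data frame.
#' @param require_multiple require >= 2 aneurysms per patient?
#' @return data frame with columns `scope`, `id`, `message`.
#' @export
validate_cohort <- function(cohort, require_multiple = FALSE) {
  bad <- list()
  note <- function(scope, id, message) {
    bad[[length(bad) + 1L]] <<- data.frame(
      scope = scope, id = as.character(id), message = message,
      stringsAsFactors = FALSE
    )
  }
  sz <- cohort$size_mm
  for (i in which(is.na(sz) | sz <= 0 | sz > 100)) {
    note("aneurysm", cohort$aneurysm_id[i],
         sprintf("aneurysm %s: size_mm must lie in (0, 100], got %s",
                 cohort$aneurysm_id[i], sz[i]))
  }
  for (i in which(!(cohort$location %in% mia_locations))) {
    note("aneurysm", cohort$aneurysm_id[i],
         sprintf("aneurysm %s: unknown location %s",
                 cohort$aneurysm_id[i], cohort$location[i]))
  }
  for (i in which(!(is.na(cohort$shape) | cohort$shape %in% mia_shapes))) {
    note("aneurysm", cohort$aneurysm_id[i],
         sprintf("aneurysm %s: shape must be regular/irregular/NA, got %s",
                 cohort$aneurysm_id[i], cohort$shape[i]))
  }
  for (i in which(!(is.na(cohort$ruptured) | cohort$ruptured %in% c(0, 1)))) {
    note("aneurysm", cohort$aneurysm_id[i],
         sprintf("aneurysm %s: ruptured must be 1/0/NA", cohort$aneurysm_id[i]))
  }
  # one bleeding source per labelled patient
  labelled <- !is.na(cohort$ruptured)
  if (any(labelled)) {
    per_pat <- tapply(cohort$ruptured[labelled],
                      cohort$patient_id[labelled], sum)
    for (pid in names(per_pat)[per_pat != 1]) {
      note("patient", pid,
           sprintf("patient %s: expected exactly one ruptured aneurysm, found %d",
                   pid, per_pat[[pid]]))
    }
  }
  if (require_multiple) {
    counts <- table(cohort$patient_id)
    for (pid in names(counts)[counts < 2]) {
      note("patient", pid,
           sprintf("patient %s: multiple-aneurysm cohort requires >= 2 aneurysms",
                   pid))
    }
  }
  if (length(bad) == 0) {
    data.frame(scope = character(), id = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}

#' The prospective 34-patient validation cohort
#'
#' Returns the packaged prospective cohort: 34 patients harboring 83
#' aneurysms, each with size, five-region location, shape, the bleeding-source
#' label, treatment, and the published per-aneurysm score carried verbatim in
#' the auxiliary column `published_score` (reference values for tests, never
#' used in computation). Patient-level covariates were not published and are
#' `NA`. The bleeding source is the aneurysm confirmed by surgical inspection
#' where one exists, else the one affirmed by expert validation; for patient
#' 24 the surgically confirmed source (MCA) scores below the patient's
#' basilar-tip aneurysm, which the column `published_score` reflects as
#' printed.
#'
#' @return A `mia_cohort` with 83 rows.
#' @export
table2_cohort <- function() {
  path <- system.file("extdata", "table2_prospective.csv",
                      package = "miascore", mustWork = TRUE)
  read_cohort(path, strict = TRUE)
}

#' Per-patient aneurysm counts
#'
#' Recomputed from the rows, never stored.
#'
#' @param cohort a `mia_cohort`.
#' @return named integer vector, patient_id -> number of aneurysms.
#' @export
aneurysm_counts <- function(cohort) {
  tab <- table(cohort$patient_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.mia_cohort <- function(x, ...) {
  cat(sprintf("<mia_cohort> %d aneurysms in %d patients",
              nrow(x), length(unique(x$patient_id))))
  prov <- attr(x, "provenance")
  if (!is.na(prov)) cat(" [", prov, "]", sep = "")
  cat("\n")
  NextMethod()
}
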