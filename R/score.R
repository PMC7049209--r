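#' Score coefficients
#'
#' Container for the closed-form aneurysm-specific prediction score
#'
#' \deqn{\mathrm{score} = \beta_{size}\,\mathrm{size_{mm}} +
#'   \beta_{loc(location)} + \beta_{irr}\,[\mathrm{shape=irregular}]}
#'
#' with the anterior cerebral / anterior communicating region (`ACOM_AA`) and
#' regular shape as zero reference levels. Higher scores mean a higher risk of
#' being the bleeding source; the score is only identified up to
#' within-patient comparison (no intercept, no patient-level terms).
#'
#' @param size_slope score units per millimetre of maximum diameter.
#' @param location_offset named numeric vector over all of [mia_locations];
#'   `ACOM_AA` must be 0.
#' @param irregular_offset score units added for irregular shape.
#' @return An object of class `mia_coefficients`.
#' @export
score_coefficients <- function(size_slope, location_offset, irregular_offset) {
  if (!setequal(names(location_offset), mia_locations)) {
    stop("location_offset must name all five regions: ",
         paste(mia_locations, collapse = ", "))
  }
  location_offset <- location_offset[mia_locations]
  if (location_offset[["ACOM_AA"]] != 0) {
    stop("ACOM_AA is the reference region; its offset must be 0")
  }
  structure(
    list(size_slope = as.numeric(size_slope),
         location_offset = location_offset,
         irregular_offset = as.numeric(irregular_offset),
         regular_offset = 0),
    class = "mia_coefficients"
  )
}

#' The published score coefficients
#'
#' The closed-form score as published: slope 0.0427 per mm; location offsets
#' ACOM_AA 0, PCOM -0.0104, POSTERIOR -0.1831, MCA -0.4055,
#' ICA_WO_PCOM -0.5973; irregular-shape offset 0.5387.
#'
#' @return A `mia_coefficients` object.
#' @export
published_coefficients <- function() {
  score_coefficients(
    size_slope = 0.0427,
    location_offset = c(ACOM_AA = 0, PCOM = -0.0104, POSTERIOR = -0.1831,
                        MCA = -0.4055, ICA_WO_PCOM = -0.5973),
    irregular_offset = 0.5387
  )
}

#' @export
print.mia_coefficients <- function(x, ...) {
  cat("<mia_coefficients>\n")
  cat(sprintf("  size slope       : %+.4f / mm\n", x$size_slope))
  for (loc in mia_locations) {
    cat(sprintf("  location %-11s: %+.4f\n", loc, x$location_offset[[loc]]))
  }
  cat(sprintf("  irregular shape  : %+.4f\n", x$irregular_offset))
  invisible(x)
}

#' Round half away from zero
#'
#' Rounding used for comparisons with the printed 4-decimal score values
#' (internal arithmetic is never rounded).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 4) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Compute the aneurysm-specific prediction score
#'
#' Vectorized over aneurysms. The return is unbounded in both directions and
#' never clamped or rounded; use [round_half_up()] for a 4-decimal view
#' matching the printed tables.
#'
#' @param size_mm positive maximum diameter in millimetres.
#' @param location one of [mia_locations].
#' @param shape `"regular"` or `"irregular"`; missing shape is a precondition
#'   error (impute first, see [impute_shape()]).
#' @param coeffs a `mia_coefficients`; defaults to the published score.
#' @return numeric score vector.
#' @examples
#' compute_score(5, "ACOM_AA", "irregular")   # 0.7522
#' compute_score(13, "MCA", "regular")        # 0.1496
#' @export
compute_score <- function(size_mm, location, shape,
                          coeffs = published_coefficients()) {
  if (any(is.na(shape))) {
    stop("shape is missing for ", sum(is.na(shape)), " aneurysm(s); ",
         "run impute_shape() before scoring")
  }
  if (!all(shape %in% mia_shapes)) {
    stop("shape must be one of: ", paste(mia_shapes, collapse = ", "))
  }
  if (!all(location %in% mia_locations)) {
    stop("unknown location label")
  }
  if (any(is.na(size_mm)) || any(size_mm <= 0)) {
    stop("size_mm must be positive")
  }
  size_mm * coeffs$size_slope +
    unname(coeffs$location_offset[location]) +
    ifelse(shape == "irregular", coeffs$irregular_offset, coeffs$regular_offset)
}

#' Score every aneurysm of a cohort
#'
#' Appends per-aneurysm columns: `score`, `rank_in_patient` (1 = highest,
#' ties share the minimum rank), `is_argmax` (score equals the patient's
#' maximum, exact comparison on unrounded values) and `tie` (the patient's
#' argmax set has more than one member).
#'
#' @param cohort a `mia_cohort` with no missing shapes.
#' @param coeffs a `mia_coefficients`.
#' @return the cohort with the four columns appended.
#' @export
score_cohort <- function(cohort, coeffs = published_coefficients()) {
  cohort$score <- compute_score(cohort$size_mm, cohort$location,
                                cohort$shape, coeffs)
  pmax_score <- stats::ave(cohort$score, cohort$patient_id, FUN = max)
  cohort$rank_in_patient <- stats::ave(
    -cohort$score, cohort$patient_id,
    FUN = function(x) rank(x, ties.method = "min")
  )
  cohort$is_argmax <- cohort$score == pmax_score
  n_arg <- stats::ave(as.numeric(cohort$is_argmax), cohort$patient_id,
                      FUN = sum)
  cohort$tie <- cohort$is_argmax & n_arg > 1
  cohort$tie <- as.logical(stats::ave(as.numeric(cohort$tie),
                                      cohort$patient_id, FUN = max))
  cohort
}

#' Within-patient argmax prediction
#'
#' For each patient, scores all aneurysms and predicts the one with the
#' maximal aneurysm-specific score as the bleeding source. The argmax set is
#' determined by exact equality on unrounded scores.
#'
#' @param cohort a `mia_cohort`.
#' @param coeffs a `mia_coefficients`.
#' @param tie_policy what to do when several aneurysms attain the maximum:
#'   `"report"` (default) keeps the full argmax set and flags the tie
#'   (non-strict correctness: the ruptured aneurysm lies in the argmax set),
#'   `"fractional"` likewise keeps the set but credits correctness as
#'   `|argmax intersect ruptured| / |argmax|` (the expected correctness of a
#'   uniform random pick among the tied maxima, making accuracy comparable
#'   with the 1/k random-guessing baseline), `"first"` resolves to the first
#'   argmax member in row order, `"error"` aborts on any tie.
#' @return data frame with one row per patient: `patient_id`, `n_aneurysms`,
#'   `predicted` (aneurysm id; under `"report"` the first argmax member, the
#'   full set being in `argmax_ids`), `argmax_ids` (`;`-separated), `tie`,
#'   `margin` (best minus runner-up distinct score; 0 for a tied maximum, `NA`
#'   for single-aneurysm patients), and when the cohort is rupture-labelled
#'   `ruptured_id` and `correct` (numeric in \[0, 1\]: 0/1 under `"report"`
#'   and `"first"`, possibly fractional under `"fractional"`).
#' @export
rank_patients <- function(cohort, coeffs = published_coefficients(),
                          tie_policy = c("report", "fractional", "first",
                                         "error")) {
  tie_policy <- match.arg(tie_policy)
  if (nrow(cohort) == 0) stop("empty cohort")
  scored <- score_cohort(cohort, coeffs)
  out <- lapply(split(seq_len(nrow(scored)), scored$patient_id), function(idx) {
    s <- scored[idx, ]
    am <- s$aneurysm_id[s$is_argmax]
    tie <- length(am) > 1
    if (tie && tie_policy == "error") {
      stop("tied maximal score for patient ", s$patient_id[1])
    }
    srt <- sort(unique(s$score), decreasing = TRUE)
    margin <- if (tie) 0 else if (length(srt) >= 2) srt[1] - srt[2] else NA_real_
    labelled <- all(!is.na(s$ruptured))
    rid <- if (labelled) s$aneurysm_id[s$ruptured == 1] else NA_character_
    correct <- if (!labelled) {
      NA_real_
    } else {
      switch(tie_policy,
             report = as.numeric(rid %in% am),
             fractional = as.numeric(rid %in% am) / length(am),
             first = ,
             error = as.numeric(identical(rid, am[1])))
    }
    data.frame(
      patient_id = s$patient_id[1],
      n_aneurysms = nrow(s),
      predicted = am[1],
      argmax_ids = paste(am, collapse = ";"),
      tie = tie,
      margin = margin,
      ruptured_id = if (length(rid) == 1) rid else NA_character_,
      correct = correct,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score grid over size, location and shape
#'
#' Dense grid of score values for heatmap-style visualization of the score
#' surface, from `size_min` to `size_max` millimetres at the given step over
#' all five locations and both shapes.
#'
#' @param coeffs a `mia_coefficients`.
#' @param size_min,size_max grid range in mm (`size_min < size_max`).
#' @param step grid step in mm, positive.
#' @return long-format data frame: `size_mm`, `location`, `shape`, `score`.
#'   Size 0 is scored as the reference limit (pure location + shape offsets).
#' @export
heatmap_grid <- function(coeffs = published_coefficients(),
                         size_min = 0, size_max = 40, step = 1) {
  if (step <= 0) stop("step must be positive")
  if (size_min >= size_max) stop("size_min must be smaller than size_max")
  grid <- expand.grid(
    size_mm = seq(size_min, size_max, by = step),
    location = mia_locations,
    shape = mia_shapes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  # size 0 is allowed on the grid (reference limit), unlike compute_score
  grid$score <- grid$size_mm * coeffs$size_slope +
    unname(coeffs$location_offset[grid$location]) +
    ifelse(grid$shape == "irregular", coeffs$irregular_offset, 0)
  grid
}

#' Plot the score surface
#'
#' Tile heatmap of [heatmap_grid()] (requires ggplot2).
#'
#' @param grid output of [heatmap_grid()].
#' @return a ggplot object.
#' @export
plot_heatmap <- function(grid = heatmap_grid()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_heatmap requires the ggplot2 package")
  }
  grid$panel <- paste(grid$location, grid$shape)
  ggplot2::ggplot(grid,
                  ggplot2::aes(x = .data$size_mm, y = .data$panel,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "risk score") +
    ggplot2::labs(x = "aneurysm size (mm)", y = NULL)
}

#' Serialize / deserialize score coefficients
#'
#' JSON round trip with the exact field names of the coefficient container.
#'
#' @param coeffs a `mia_coefficients`.
#' @param path JSON file path.
#' @return `read_coefficients` returns a `mia_coefficients`;
#'   `write_coefficients` returns `path` invisibly.
#' @export
write_coefficients <- function(coeffs, path) {
  jsonlite::write_json(
    list(size_slope = coeffs$size_slope,
         location_offset = as.list(coeffs$location_offset),
         irregular_offset = coeffs$irregular_offset,
         regular_offset = coeffs$regular_offset),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  score_coefficients(x$size_slope, unlist(x$location_offset),
                     x$irregular_offset)
}

#' Recompute the prospective-cohort scores and ranking
#'
#' Recomputes all 83 scores of the packaged prospective cohort with the
#' published coefficients, diffs them (at 4 decimals, half away from zero)
#' against the `published_score` column as printed, and reports the
#' per-patient argmax ranking against the bleeding-source labels.
#'
#' Three printed values are known to be internally inconsistent with the
#' published formula (the same size/location/shape pattern is printed with a
#' different score elsewhere in the same table); they surface in `mismatches`.
#'
#' @param tie_policy passed to [rank_patients()].
#' @return list with `scores` (per-aneurysm data frame with `recomputed`,
#'   `published_score`, `match`), `n_match`, `mismatches` (rows whose printed
#'   value differs), `ranking` (per-patient data frame), and `n_correct`
#'   (patients whose ruptured aneurysm attains the maximal score).
#' @export
reproduce_table2 <- function(tie_policy = "report") {
  cohort <- table2_cohort()
  scored <- score_cohort(cohort, published_coefficients())
  scores <- data.frame(
    patient_id = scored$patient_id,
    aneurysm_id = scored$aneurysm_id,
    site = scored$site,
    size_mm = scored$size_mm,
    location = scored$location,
    shape = scored$shape,
    published_score = scored$published_score,
    recomputed = round_half_up(scored$score, 4),
    stringsAsFactors = FALSE
  )
  scores$match <- scores$recomputed == scores$published_score
  ranking <- rank_patients(cohort, published_coefficients(),
                           tie_policy = tie_policy)
  list(
    scores = scores,
    n_match = sum(scores$match),
    mismatches = scores[!scores$match, ],
    ranking = ranking,
    n_correct = sum(ranking$correct)
  )
}
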