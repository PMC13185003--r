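#' @importFrom rlang .data abort warn %||%
#' @importFrom stats coef vcov setNames qnorm plogis qlogis sd rnorm runif
#'   rbinom dnorm approx quantile var
NULL

#' Map gestational age to pregnancy trimester
#'
#' Gestational age in weeks is mapped to trimester 1, 2 or 3 using half-open
#' intervals: trimester 1 on \[0, 13), trimester 2 on \[13, 29), trimester 3 on
#' \[29, 41\]. The half-open convention makes the mapping a function at the
#' shared endpoints (week 13 belongs to the second trimester, week 29 to the
#' third).
#'
#' @param ga_weeks Numeric vector of gestational ages in weeks; values must lie
#'   in \[0, 41\].
#' @return Integer vector of trimesters (1, 2 or 3), same length as `ga_weeks`.
#' @examples
#' assign_trimester(c(10, 13, 30))
#' @export
assign_trimester <- function(ga_weeks) {
  if (!is.numeric(ga_weeks)) {
    abort("`ga_weeks` must be numeric.")
  }
  bad <- which(is.na(ga_weeks) | ga_weeks < 0 | ga_weeks > 41)
  if (length(bad) > 0) {
    abort(sprintf(
      "gestational age out of range [0, 41] weeks: %s (position %s)",
      paste(utils::head(ga_weeks[bad], 3), collapse = ", "),
      paste(utils::head(bad, 3), collapse = ", ")
    ))
  }
  tri <- findInterval(ga_weeks, c(0, 13, 29))
  as.integer(tri)
}

#' Construct a cohort object from visit and subject tables
#'
#' Bundles the long visit-level table (one row per Hb measurement) with the
#' subject-level outcome table. Trimesters are (re)derived from `ga_weeks`,
#' basic plausibility checks run on Hb (g/L), and the per-subject visit count
#' `n_visits` is attached to the subject table.
#'
#' @param visits Data frame with columns `subject_id`, `ga_weeks`, `hb_g_l`.
#' @param subjects Data frame with column `subject_id` and any of
#'   `birthweight_g`, `ga_delivery_weeks`, `lbw`, `ptb`, `sga`,
#'   `weight_percentile`.
#' @return An object of class `hb_cohort`: a list with tibbles `visits`
#'   (subject_id, ga_weeks, hb_g_l, trimester) and `subjects`.
#' @export
hb_cohort <- function(visits, subjects) {
  visits <- tibble::as_tibble(visits)
  subjects <- tibble::as_tibble(subjects)
  need <- c("subject_id", "ga_weeks", "hb_g_l")
  miss <- setdiff(need, names(visits))
  if (length(miss) > 0) {
    abort(paste0("visit table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"subject_id" %in% names(subjects)) {
    abort("subject table is missing column `subject_id`")
  }
  if (any(duplicated(subjects$subject_id))) {
    abort("subject table has duplicated subject_id values")
  }
  if (any(visits$hb_g_l <= 0, na.rm = TRUE)) {
    abort("non-positive hemoglobin value found; Hb must be in g/L")
  }
  if (any(visits$hb_g_l < 30 | visits$hb_g_l > 220, na.rm = TRUE)) {
    warn("hemoglobin values outside 30-220 g/L; check that units are g/L, not g/dL")
  }
  orphan <- setdiff(unique(visits$subject_id), subjects$subject_id)
  if (length(orphan) > 0) {
    abort(sprintf(
      "%d subject(s) have visits but no subject-level row (e.g. %s)",
      length(orphan), as.character(orphan[1])
    ))
  }
  visits$trimester <- assign_trimester(visits$ga_weeks)
  visits <- dplyr::arrange(visits, .data$subject_id, .data$ga_weeks)
  counts <- dplyr::count(visits, .data$subject_id, name = "n_visits")
  subjects$n_visits <- NULL
  subjects <- dplyr::left_join(subjects, counts, by = "subject_id")
  subjects$n_visits[is.na(subjects$n_visits)] <- 0L
  structure(list(visits = visits, subjects = subjects), class = "hb_cohort")
}

#' @export
print.hb_cohort <- function(x, ...) {
  cat(sprintf(
    "<hb_cohort> %d subjects, %d Hb measurements\n",
    nrow(x$subjects), nrow(x$visits)
  ))
  tab <- table(factor(x$subjects$n_visits, levels = sort(unique(x$subjects$n_visits))))
  cat("  visits per subject:",
      paste(sprintf("%s visits: n=%d", names(tab), as.integer(tab)), collapse = "; "),
      "\n")
  invisible(x)
}

#' Average repeated measurements within a trimester
#'
#' When a subject has more than one Hb measurement inside the same trimester
#' (a scheduling artefact, not a physiological signal), the measurements are
#' collapsed to a single record whose Hb is their arithmetic mean and whose
#' gestational age is the mean of the original visit times. Per-subject visit
#' counts are recomputed. Subjects with one record per trimester pass through
#' unchanged.
#'
#' @param cohort An `hb_cohort`.
#' @return An `hb_cohort` with at most one visit per (subject, trimester).
#' @export
collapse_within_trimester <- function(cohort) {
  stopifnot(inherits(cohort, "hb_cohort"))
  visits <- cohort$visits |>
    dplyr::group_by(.data$subject_id, .data$trimester) |>
    dplyr::summarise(
      ga_weeks = mean(.data$ga_weeks),
      hb_g_l = mean(.data$hb_g_l),
      .groups = "drop"
    ) |>
    dplyr::select("subject_id", "ga_weeks", "hb_g_l")
  out <- hb_cohort(visits, dplyr::select(cohort$subjects, -"n_visits"))
  out$truth <- cohort$truth
  out$config <- cohort$config
  out
}

#' Derive binary birth outcomes from their continuous determinants
#'
#' Low birth weight is birthweight strictly below 2500 g; preterm birth is
#' delivery strictly before 37 completed weeks; small-for-gestational-age is a
#' birthweight percentile strictly below the 10th (a simplified percentile
#' rule — computing percentiles against an external growth standard is out of
#' scope). A missing determinant yields `NA`, never a silent 0.
#'
#' @param subjects Data frame with any of `birthweight_g`, `ga_delivery_weeks`,
#'   `weight_percentile`.
#' @return The input as a tibble with integer columns `lbw`, `ptb`, `sga`
#'   added (or overwritten where derivable; an existing `sga` column is kept
#'   when `weight_percentile` is absent).
#' @examples
#' derive_outcomes(data.frame(
#'   subject_id = 1:2, birthweight_g = c(2499, 2500),
#'   ga_delivery_weeks = c(37, 36.9)
#' ))
#' @export
derive_outcomes <- function(subjects) {
  subjects <- tibble::as_tibble(subjects)
  chk_pos <- function(x, what) {
    if (any(x <= 0, na.rm = TRUE)) abort(paste0("`", what, "` must be positive where present"))
  }
  if ("birthweight_g" %in% names(subjects)) {
    chk_pos(subjects$birthweight_g, "birthweight_g")
    subjects$lbw <- as.integer(subjects$birthweight_g < 2500)
  } else if (!"lbw" %in% names(subjects)) {
    subjects$lbw <- NA_integer_
  }
  if ("ga_delivery_weeks" %in% names(subjects)) {
    chk_pos(subjects$ga_delivery_weeks, "ga_delivery_weeks")
    subjects$ptb <- as.integer(subjects$ga_delivery_weeks < 37)
  } else if (!"ptb" %in% names(subjects)) {
    subjects$ptb <- NA_integer_
  }
  if ("weight_percentile" %in% names(subjects)) {
    wp <- subjects$weight_percentile
    if (any(wp < 0 | wp > 100, na.rm = TRUE)) {
      abort("`weight_percentile` must lie in [0, 100]")
    }
    subjects$sga <- as.integer(wp < 10)
  } else if (!"sga" %in% names(subjects)) {
    subjects$sga <- NA_integer_
  }
  subjects
}

#' Restrict a cohort to subjects with a given number of visits
#'
#' Several of the methods require one measurement per trimester, i.e. exactly
#' three visits after within-trimester averaging; the additive mixed model
#' uses everyone. This helper subsets on the recomputed visit count and
#' reports the sizes involved.
#'
#' @param cohort An `hb_cohort` (already collapsed within trimester).
#' @param k Required number of visits per subject.
#' @param quiet Suppress the size message.
#' @return An `hb_cohort` containing exactly the subjects with `n_visits == k`.
#' @export
subset_by_visit_count <- function(cohort, k, quiet = FALSE) {
  stopifnot(inherits(cohort, "hb_cohort"), length(k) == 1, k >= 1)
  keep <- cohort$subjects$subject_id[cohort$subjects$n_visits == k]
  if (length(keep) == 0) {
    abort(sprintf("no subjects with exactly %d visits", k))
  }
  if (!quiet) {
    message(sprintf(
      "retained %d of %d subjects with %d visits",
      length(keep), nrow(cohort$subjects), k
    ))
  }
  out <- hb_cohort(
    dplyr::filter(cohort$visits, .data$subject_id %in% keep),
    dplyr::filter(
      dplyr::select(cohort$subjects, -"n_visits"),
      .data$subject_id %in% keep
    )
  )
  if (!is.null(cohort$truth)) {
    out$truth <- dplyr::filter(cohort$truth, .data$subject_id %in% keep)
  }
  out$config <- cohort$config
  out
}

#' Pivot a three-visit cohort to one row per subject
#'
#' Internal helper: after within-trimester averaging and restriction to three
#' visits, returns a tibble with one row per subject and columns `x1`, `x2`,
#' `x3` (Hb by trimester) plus `t1`, `t2`, `t3` (visit times), joined to the
#' outcome columns.
#'
#' @keywords internal
#' @noRd
wide_three_visit <- function(cohort) {
  stopifnot(inherits(cohort, "hb_cohort"))
  if (any(cohort$subjects$n_visits != 3)) {
    abort("cohort must contain only subjects with 3 visits (one per trimester)")
  }
  per_tri <- dplyr::count(cohort$visits, .data$subject_id, .data$trimester)
  if (any(per_tri$n != 1) || any(!1:3 %in% cohort$visits$trimester)) {
    abort("each subject must have exactly one visit per trimester; run collapse_within_trimester() first")
  }
  wide <- cohort$visits |>
    dplyr::select("subject_id", "trimester", "hb_g_l", "ga_weeks") |>
    tidyr::pivot_wider(
      names_from = "trimester",
      values_from = c("hb_g_l", "ga_weeks"),
      names_sep = "_"
    ) |>
    dplyr::rename(
      x1 = "hb_g_l_1", x2 = "hb_g_l_2", x3 = "hb_g_l_3",
      t1 = "ga_weeks_1", t2 = "ga_weeks_2", t3 = "ga_weeks_3"
    )
  dplyr::left_join(wide, cohort$subjects, by = "subject_id")
}

#' Read a cohort from long/subject CSV files
#'
#' @param visits_csv Path to the long CSV (`subject_id, ga_weeks, hb_g_l`).
#' @param subjects_csv Path to the subject CSV (`subject_id, birthweight_g,
#'   ga_delivery_weeks` and/or precomputed `lbw, ptb, sga` flags).
#' @param derive Recompute the binary outcomes from their determinants where
#'   present (default `TRUE`).
#' @return An `hb_cohort`.
#' @export
read_cohort <- function(visits_csv, subjects_csv, derive = TRUE) {
  visits <- readr::read_csv(visits_csv, show_col_types = FALSE)
  subjects <- readr::read_csv(subjects_csv, show_col_types = FALSE)
  if (derive) subjects <- derive_outcomes(subjects)
  hb_cohort(visits, subjects)
}

#' Write a cohort to long/subject CSV files
#'
#' @param cohort An `hb_cohort`.
#' @param visits_csv,subjects_csv Output paths.
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, visits_csv, subjects_csv) {
  stopifnot(inherits(cohort, "hb_cohort"))
  readr::write_csv(dplyr::select(cohort$visits, -"trimester"), visits_csv)
  readr::write_csv(dplyr::select(cohort$subjects, -"n_visits"), subjects_csv)
  invisible(cohort)
}
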