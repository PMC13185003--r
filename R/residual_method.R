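#' Sequential residual features from three Hb measurements
#'
#' To avoid collinearity between repeated Hb measurements, the later visits
#' are sequentially residualized: visit-2 Hb is regressed on visit-1 Hb, and
#' visit-3 Hb on visits 1 and 2, across subjects. The two residual vectors
#' capture the window-specific change in Hb not predicted by earlier levels;
#' each is standardized (mean 0, sample SD 1) so downstream odds ratios read
#' per 1 SD.
#'
#' @param cohort An `hb_cohort` where every subject has one Hb per trimester
#'   (run [collapse_within_trimester()] and [subset_by_visit_count()] first).
#' @return Tibble with `subject_id`, `x1` (first-visit Hb, g/L), `eps1_std`,
#'   `eps2_std`, and the unstandardized residuals `eps1`, `eps2`. Attribute
#'   `fits` holds the two underlying `hb_ols` fits.
#' @export
compute_residual_features <- function(cohort) {
  wide <- wide_three_visit(cohort)
  f1 <- fit_ols(cbind(`(Intercept)` = 1, x1 = wide$x1), wide$x2)
  f2 <- tryCatch(
    fit_ols(cbind(`(Intercept)` = 1, x1 = wide$x1, x2 = wide$x2), wide$x3),
    error = function(e) {
      abort(paste0("degenerate fit in the visit-3 regression: ",
                   conditionMessage(e)))
    }
  )
  s1 <- tryCatch(standardize(f1$residuals), error = function(e) {
    abort("degenerate fit: visit-2 residuals are constant (exact collinearity with visit-1 Hb)")
  })
  s2 <- tryCatch(standardize(f2$residuals), error = function(e) {
    abort("degenerate fit: visit-3 residuals are constant (exact collinearity with earlier visits)")
  })
  out <- tibble::tibble(
    subject_id = wide$subject_id,
    x1 = wide$x1,
    eps1 = f1$residuals, eps2 = f2$residuals,
    eps1_std = s1$values, eps2_std = s2$values
  )
  attr(out, "fits") <- list(visit2 = f1, visit3 = f2)
  out
}

#' Logistic regression of an outcome on first-visit Hb and residuals
#'
#' Fits `logit P(Y=1) = b0 + b1 x1 + b2 eps1_std + b3 eps2_std`. Residual
#' terms are reported per 1 SD (they are already standardized); first-visit
#' Hb is reported per 5 g/L for comparability with the other methods.
#'
#' @param features Output of [compute_residual_features()].
#' @param outcome Binary vector aligned with `features` rows, or the name of
#'   an outcome column if `features` carries one.
#' @return An `hb_logistic` (see [or_table()]).
#' @export
fit_residual_logistic <- function(features, outcome) {
  if (is.character(outcome) && length(outcome) == 1) {
    outcome <- features[[outcome]]
  }
  keep <- !is.na(outcome)
  x <- cbind(
    `(Intercept)` = 1,
    x1 = features$x1[keep],
    eps1_std = features$eps1_std[keep],
    eps2_std = features$eps2_std[keep]
  )
  fit_logistic(
    x, outcome[keep],
    scales = c(x1 = 5),
    scale_labels = c(
      `(Intercept)` = "baseline log-odds", x1 = "per 5 g/L",
      eps1_std = "per 1 SD", eps2_std = "per 1 SD"
    )
  )
}

#' Run the residual method for one or more outcomes
#'
#' @param cohort Three-visit `hb_cohort`.
#' @param outcomes Character subset of `c("lbw", "ptb", "sga")`.
#' @return Tibble of per-outcome odds-ratio rows (`outcome`, `term`, `or`,
#'   `conf.low`, `conf.high`, `scale`); attribute `fits` holds the
#'   `hb_logistic` objects.
#' @export
run_residual_method <- function(cohort, outcomes = c("lbw", "ptb", "sga")) {
  outcomes <- match.arg(outcomes, c("lbw", "ptb", "sga"), several.ok = TRUE)
  features <- compute_residual_features(cohort)
  feat <- dplyr::left_join(features, cohort$subjects, by = "subject_id")
  fits <- lapply(outcomes, function(oc) fit_residual_logistic(feat, oc))
  names(fits) <- outcomes
  out <- purrr::map_dfr(outcomes, function(oc) {
    dplyr::mutate(or_table(fits[[oc]]), outcome = oc, .before = 1)
  })
  attr(out, "fits") <- fits
  out
}
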