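#' @importFrom ggplot2 ggplot aes geom_line geom_ribbon geom_hline labs
#'   autoplot theme_minimal facet_wrap geom_point
NULL

#' Plot a week-specific odds-ratio curve
#'
#' @param curve Tibble from [predict_or_curve()] (optionally with an
#'   `outcome` column for facetting).
#' @return A ggplot: OR with shaded 95% band against gestational week.
#' @export
plot_or_curve <- function(curve) {
  p <- ggplot(curve, aes(x = .data$week, y = .data$or)) +
    geom_ribbon(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                fill = "grey70", alpha = 0.6) +
    geom_line() +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "Gestational week", y = "Odds ratio",
         title = "Odds ratio per +5 g/L Hb vs reference, by week") +
    theme_minimal()
  if ("outcome" %in% names(curve)) p <- p + facet_wrap(~outcome)
  p
}

#' @method autoplot hb_dlnm
#' @export
autoplot.hb_dlnm <- function(object, increment = 5, ...) {
  plot_or_curve(predict_or_curve(object, increment = increment))
}

#' Plot predicted Hb trajectories by outcome status
#'
#' @param trajectories Tibble from [predict_trajectories()] or
#'   `run_gamm_method()$trajectories`.
#' @return A ggplot of the two group curves with shaded bands.
#' @export
plot_trajectories <- function(trajectories) {
  trajectories$group <- factor(trajectories$group, c(0, 1),
                               c("without outcome", "with outcome"))
  p <- ggplot(trajectories,
              aes(x = .data$ga_weeks, y = .data$hb_pred,
                  colour = .data$group, fill = .data$group)) +
    geom_ribbon(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                alpha = 0.25, colour = NA) +
    geom_line() +
    labs(x = "Gestational age (weeks)", y = "Predicted Hb (g/L)",
         colour = NULL, fill = NULL,
         title = "Hb trajectory by outcome status") +
    theme_minimal()
  if ("outcome" %in% names(trajectories)) p <- p + facet_wrap(~outcome)
  p
}

#' @method autoplot hb_gamm
#' @export
autoplot.hb_gamm <- function(object, grid_length = 60, ...) {
  grid <- seq(object$ga_range[1], object$ga_range[2], length.out = grid_length)
  plot_trajectories(dplyr::bind_rows(
    predict_trajectories(object, grid, 0),
    predict_trajectories(object, grid, 1)
  ))
}

#' Plot observed spaghetti and fitted class trajectories
#'
#' @param fit An `hb_gbtm`.
#' @param cohort The cohort the model was fitted to (for the observed lines).
#' @return A ggplot: per-subject observed series coloured by modal class,
#'   with the fitted class mean curves overlaid.
#' @export
plot_gbtm <- function(fit, cohort) {
  assign <- assign_groups(fit, quiet = TRUE)
  v <- dplyr::left_join(cohort$visits, assign, by = "subject_id")
  curves <- gbtm_curves(fit)
  ggplot() +
    geom_line(data = v,
              aes(x = .data$ga_weeks, y = .data$hb_g_l,
                  group = .data$subject_id, colour = factor(.data$class)),
              alpha = 0.15) +
    geom_line(data = curves,
              aes(x = .data$ga_weeks, y = .data$hb_mean,
                  colour = factor(.data$class)),
              linewidth = 1.2) +
    labs(x = "Gestational age (weeks)", y = "Hb (g/L)", colour = "Class",
         title = sprintf("Hb trajectory classes (K = %d)", fit$K)) +
    theme_minimal()
}

#' @method autoplot hb_gbtm
#' @export
autoplot.hb_gbtm <- function(object, cohort, ...) plot_gbtm(object, cohort)
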