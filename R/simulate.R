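#' Simulation configuration for a synthetic pregnancy cohort
#'
#' Collects every knob of the synthetic generator with defaults that mirror
#' the cohort structure the five methods assume: ~10.5% of subjects with
#' three visits (one per trimester, centred at weeks 10/24/32), the rest with
#' two (enrolment in the first or second trimester plus an end-of-gestation
#' visit); trimester-level fixed effects of 119.7 g/L (first trimester),
#' -8.7 g/L (second vs first) and -6.25 g/L (third vs first); subject random
#' intercepts and trimester slopes; Gaussian measurement noise; and marginal
#' outcome prevalences of roughly 19% (LBW), 6% (PTB) and 31% (SGA).
#'
#' @param n_subjects Number of women.
#' @param prop_three_visits Probability a subject has three visits.
#' @param fixed_intercept First-trimester mean Hb, g/L.
#' @param effect_t2,effect_t3 Second- and third-trimester contrasts, g/L.
#' @param sd_random_intercept,sd_random_slope_t2,sd_random_slope_t3 Standard
#'   deviations of the subject-level random intercept and trimester slopes,
#'   g/L (independent effects).
#' @param sd_noise Residual measurement SD, g/L.
#' @param visit_time_centers Visit-time centres in weeks (length 3).
#' @param visit_time_jitter Half-width of the triangular jitter around each
#'   centre, weeks; jittered times are truncated to stay inside the centre's
#'   trimester.
#' @param u_shape Add a smooth quadratic U-shape in gestational age on top of
#'   the trimester means (used when a continuous-time trend is wanted).
#' @param u_curvature Quadratic coefficient of the U-shape, g/L per week^2.
#' @param u_nadir Week of the U-shape nadir.
#' @param outcome_model One of `"null"` (outcomes independent of Hb),
#'   `"random_effect_link"` (log-odds linear in the true random effects),
#'   `"class_link"` (log-odds shifted by latent class), `"group_shift"`
#'   (outcome drawn first; the outcome group's Hb is shifted by
#'   `group_shift_g_l` before `group_shift_until_week`).
#' @param outcome_prevalence Named marginal prevalences for `lbw`, `ptb`, `sga`.
#' @param outcome_coefs For `random_effect_link`: named list per outcome of
#'   numeric length-3 vectors (log-odds per g/L of the random intercept and
#'   the two trimester slopes). For `class_link`: named list per outcome of
#'   length-`n_classes` log-odds shifts (first class usually 0).
#' @param n_classes Number of latent trajectory classes.
#' @param class_proportions Mixing proportions (sum to 1).
#' @param class_polynomials `n_classes` x 3 matrix of quadratic coefficients
#'   (intercept, linear, quadratic in weeks) giving each class's mean Hb
#'   curve; required when `n_classes > 1`.
#' @param group_shift_g_l,group_shift_until_week Shift (g/L) applied to the
#'   outcome group's Hb mean, smoothly switched off around the stated week
#'   (`outcome_model = "group_shift"` only).
#' @param group_shift_outcome Which outcome's group carries the shift.
#' @param seed Integer seed; one RNG stream drives the whole cohort.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 6452,
                       prop_three_visits = 0.105,
                       fixed_intercept = 119.7,
                       effect_t2 = -8.7,
                       effect_t3 = -6.25,
                       sd_random_intercept = 10,
                       sd_random_slope_t2 = 6,
                       sd_random_slope_t3 = 6,
                       sd_noise = 7,
                       visit_time_centers = c(10, 24, 32),
                       visit_time_jitter = 2,
                       u_shape = FALSE,
                       u_curvature = 0.04,
                       u_nadir = 24,
                       outcome_model = c("null", "random_effect_link",
                                         "class_link", "group_shift"),
                       outcome_prevalence = c(lbw = 0.19, ptb = 0.06, sga = 0.31),
                       outcome_coefs = NULL,
                       n_classes = 1,
                       class_proportions = NULL,
                       class_polynomials = NULL,
                       group_shift_g_l = -5,
                       group_shift_until_week = 20,
                       group_shift_outcome = "ptb",
                       seed = 1L) {
  outcome_model <- match.arg(outcome_model)
  if (length(n_subjects) != 1 || n_subjects < 1) abort("`n_subjects` must be a positive integer")
  if (prop_three_visits < 0 || prop_three_visits > 1) abort("`prop_three_visits` must lie in [0, 1]")
  sds <- c(sd_random_intercept, sd_random_slope_t2, sd_random_slope_t3, sd_noise)
  if (any(sds < 0)) abort("standard deviations must be non-negative")
  if (length(visit_time_centers) != 3) abort("`visit_time_centers` must have length 3")
  if (!all(c("lbw", "ptb", "sga") %in% names(outcome_prevalence))) {
    abort("`outcome_prevalence` must name lbw, ptb and sga")
  }
  if (n_classes < 1) abort("`n_classes` must be >= 1")
  if (is.null(class_proportions)) class_proportions <- rep(1 / n_classes, n_classes)
  if (length(class_proportions) != n_classes ||
      abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions < 0)) {
    abort("`class_proportions` must be non-negative, length n_classes, and sum to 1")
  }
  if (n_classes > 1) {
    if (is.null(class_polynomials)) abort("`class_polynomials` required when n_classes > 1")
    class_polynomials <- as.matrix(class_polynomials)
    if (!all(dim(class_polynomials) == c(n_classes, 3))) {
      abort("`class_polynomials` must be an n_classes x 3 matrix")
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), prop_three_visits = prop_three_visits,
      fixed_intercept = fixed_intercept, effect_t2 = effect_t2, effect_t3 = effect_t3,
      sd_random_intercept = sd_random_intercept,
      sd_random_slope_t2 = sd_random_slope_t2,
      sd_random_slope_t3 = sd_random_slope_t3,
      sd_noise = sd_noise,
      visit_time_centers = visit_time_centers, visit_time_jitter = visit_time_jitter,
      u_shape = u_shape, u_curvature = u_curvature, u_nadir = u_nadir,
      outcome_model = outcome_model,
      outcome_prevalence = outcome_prevalence, outcome_coefs = outcome_coefs,
      n_classes = as.integer(n_classes), class_proportions = class_proportions,
      class_polynomials = class_polynomials,
      group_shift_g_l = group_shift_g_l,
      group_shift_until_week = group_shift_until_week,
      group_shift_outcome = match.arg(group_shift_outcome, c("ptb", "lbw", "sga")),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# trimester bounds used to truncate jittered visit times
.tri_bounds <- function(trimester) {
  lo <- c(0, 13, 29)[trimester]
  hi <- c(13, 29, 41)[trimester]
  cbind(lo, hi)
}

# triangular jitter around a centre, truncated inside the centre's trimester
.jitter_times <- function(centers, jitter) {
  n <- length(centers)
  t_raw <- centers + jitter * (runif(n) + runif(n) - 1)
  tri <- assign_trimester(pmin(pmax(centers, 0), 41))
  b <- .tri_bounds(tri)
  pmin(pmax(t_raw, b[, 1] + 0.1), b[, 2] - 0.1)
}

#' Simulate a synthetic pregnancy cohort with known ground truth
#'
#' Generates visit times around the configured centres, Hb as trimester-level
#' fixed effects (optionally a smooth U-shape, optionally latent-class mean
#' curves) plus subject random effects and Gaussian noise, and Bernoulli
#' outcomes from the configured logistic link. The returned cohort carries a
#' `truth` tibble (random effects, class labels, per-outcome linear
#' predictors) so recovery can be checked exactly.
#'
#' @param config A [sim_config()].
#' @return An `hb_cohort` with an extra element `truth`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_subjects = 50, seed = 7))
#' coh
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  id <- seq_len(n)

  three <- runif(n) < config$prop_three_visits
  # two-visit women enrol in trimester 1 or 2, then return near term
  enrol_t1 <- runif(n) < 0.5
  centers <- config$visit_time_centers

  klass <- if (config$n_classes > 1) {
    sample.int(config$n_classes, n, replace = TRUE, prob = config$class_proportions)
  } else rep(1L, n)

  b0 <- rnorm(n, 0, config$sd_random_intercept)
  b2 <- rnorm(n, 0, config$sd_random_slope_t2)
  b3 <- rnorm(n, 0, config$sd_random_slope_t3)

  visit_centers <- lapply(id, function(i) {
    if (three[i]) centers
    else if (enrol_t1[i]) centers[c(1, 3)] else centers[c(2, 3)]
  })
  nv <- lengths(visit_centers)
  vid <- rep(id, nv)
  vcenters <- unlist(visit_centers)
  t_ij <- .jitter_times(vcenters, config$visit_time_jitter)
  tri <- assign_trimester(t_ij)

  mean_hb <- if (config$n_classes > 1) {
    P <- config$class_polynomials[klass[vid], , drop = FALSE]
    P[, 1] + P[, 2] * t_ij + P[, 3] * t_ij^2
  } else {
    config$fixed_intercept +
      config$effect_t2 * (tri == 2) + config$effect_t3 * (tri == 3)
  }
  if (config$u_shape) {
    mean_hb <- mean_hb + config$u_curvature * ((t_ij - config$u_nadir)^2 -
                                                 (centers[1] - config$u_nadir)^2)
  }
  hb <- mean_hb + b0[vid] + b2[vid] * (tri == 2) + b3[vid] * (tri == 3)

  prev <- config$outcome_prevalence
  lp <- sapply(c("lbw", "ptb", "sga"), function(oc) {
    base <- qlogis(prev[[oc]])
    cf <- config$outcome_coefs[[oc]]
    switch(config$outcome_model,
      null = rep(base, n),
      group_shift = rep(base, n),
      random_effect_link = {
        if (is.null(cf)) cf <- c(0, 0, 0)
        base + cf[1] * b0 + cf[2] * b2 + cf[3] * b3
      },
      class_link = {
        if (is.null(cf)) cf <- rep(0, config$n_classes)
        base + cf[klass]
      }
    )
  })
  y <- apply(lp, 2, function(l) rbinom(n, 1, plogis(l)))
  colnames(y) <- c("lbw", "ptb", "sga")

  if (config$outcome_model == "group_shift") {
    # reverse link: Hb of the affected group is shifted early in gestation
    w <- plogis((config$group_shift_until_week - t_ij) / 1.5)
    hb <- hb + config$group_shift_g_l * w * y[vid, config$group_shift_outcome]
  }
  hb <- hb + rnorm(length(hb), 0, config$sd_noise)

  subjects <- tibble::tibble(
    subject_id = id,
    birthweight_g = ifelse(y[, "lbw"] == 1,
                           pmin(rnorm(n, 2200, 200), 2480),
                           pmax(rnorm(n, 3100, 350), 2510)),
    ga_delivery_weeks = ifelse(y[, "ptb"] == 1,
                               pmin(pmax(rnorm(n, 35, 1.5), 28), 36.8),
                               pmin(pmax(rnorm(n, 39.2, 1.1), 37.1), 41)),
    weight_percentile = ifelse(y[, "sga"] == 1, runif(n, 0, 9.99), runif(n, 10.01, 100))
  )
  subjects <- derive_outcomes(subjects)
  stopifnot(all(subjects$lbw == y[, "lbw"]), all(subjects$ptb == y[, "ptb"]),
            all(subjects$sga == y[, "sga"]))

  cohort <- hb_cohort(
    tibble::tibble(subject_id = vid, ga_weeks = t_ij, hb_g_l = hb),
    subjects
  )
  cohort$truth <- tibble::tibble(
    subject_id = id, three_visit = three, class = klass,
    b0 = b0, b_t2 = b2, b_t3 = b3,
    lp_lbw = lp[, "lbw"], lp_ptb = lp[, "ptb"], lp_sga = lp[, "sga"]
  )
  cohort$config <- config
  cohort
}

#' Simulate a cohort with a critical-window exposure effect
#'
#' Each subject gets a smooth latent weekly Hb curve over gestational weeks
#' 1-39 (a population U-shaped quadratic through the trimester means plus a
#' subject random intercept and slope). The outcome's log-odds depend only on
#' the subject's mean centred Hb inside `effect_window`; observed visits are
#' noisy samples of the latent curve at the three jittered visit times. Used
#' to check that the distributed-lag model localises the window.
#'
#' @param config A [sim_config()]; `prop_three_visits` is ignored (all
#'   subjects get three visits so the weekly profile is identifiable).
#' @param effect_window Integer week interval, within 1-39.
#' @param effect_per_5g Log-odds change per +5 g/L of window-mean Hb.
#' @param outcome Which outcome carries the effect (default `"lbw"`).
#' @return An `hb_cohort` with elements `truth` (random effects, window-mean
#'   exposure, linear predictor) and `latent_curves` (subjects x 39 matrix).
#' @export
simulate_window_effect_cohort <- function(config = sim_config(),
                                          effect_window = c(30, 39),
                                          effect_per_5g = -0.2,
                                          outcome = "lbw") {
  stopifnot(inherits(config, "sim_config"))
  if (length(effect_window) != 2 || effect_window[1] > effect_window[2] ||
      effect_window[1] < 1 || effect_window[2] > 39) {
    abort("`effect_window` must be a non-empty interval inside weeks 1-39")
  }
  outcome <- match.arg(outcome, c("lbw", "ptb", "sga"))
  set.seed(config$seed)
  n <- config$n_subjects
  id <- seq_len(n)
  centers <- config$visit_time_centers

  # population quadratic through the three trimester means at the visit centres
  tri_means <- config$fixed_intercept + c(0, config$effect_t2, config$effect_t3)
  qc <- solve(cbind(1, centers, centers^2), tri_means)
  weeks <- 1:39
  pop_curve <- qc[1] + qc[2] * weeks + qc[3] * weeks^2

  b0 <- rnorm(n, 0, config$sd_random_intercept)
  b1 <- rnorm(n, 0, config$sd_random_slope_t2 / 10)  # slope per week
  curves <- outer(b0, rep(1, 39)) + outer(b1, weeks - 20) +
    matrix(pop_curve, n, 39, byrow = TRUE)

  win <- weeks >= effect_window[1] & weeks <= effect_window[2]
  exposure <- rowMeans(curves[, win, drop = FALSE])
  exposure_centered <- exposure - mean(pop_curve[win])
  base <- qlogis(config$outcome_prevalence[[outcome]])
  lp <- base + (effect_per_5g / 5) * exposure_centered
  yy <- rbinom(n, 1, plogis(lp))

  t_ij <- .jitter_times(rep(centers, n), config$visit_time_jitter)
  vid <- rep(id, each = 3)
  latent_at_t <- qc[1] + qc[2] * t_ij + qc[3] * t_ij^2 +
    b0[vid] + b1[vid] * (t_ij - 20)
  hb <- latent_at_t + rnorm(length(t_ij), 0, config$sd_noise)

  y <- matrix(rbinom(3 * n, 1, rep(unname(config$outcome_prevalence), each = n)),
              n, 3, dimnames = list(NULL, c("lbw", "ptb", "sga")))
  y[, outcome] <- yy
  subjects <- tibble::tibble(subject_id = id,
                             lbw = y[, "lbw"], ptb = y[, "ptb"], sga = y[, "sga"])

  cohort <- hb_cohort(
    tibble::tibble(subject_id = vid, ga_weeks = t_ij, hb_g_l = hb),
    subjects
  )
  cohort$truth <- tibble::tibble(
    subject_id = id, b0 = b0, b1 = b1,
    window_mean_hb = exposure, linear_predictor = lp, y = yy
  )
  cohort$latent_curves <- curves
  cohort$config <- config
  cohort
}
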