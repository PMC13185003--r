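make_profile_cohort <- function(hb_by_subject, weeks = c(10, 24, 32)) {
  n <- length(hb_by_subject)
  visits <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(subject_id = i, ga_weeks = weeks, hb_g_l = hb_by_subject[[i]])
  })
  hb_cohort(visits, tibble::tibble(subject_id = seq_len(n),
                                   lbw = rep_len(c(0L, 1L), n)))
}

test_that("weekly profiles interpolate linearly and extrapolate constantly", {
  coh <- make_profile_cohort(list(c(100, 100, 100), c(100, 114, 120)))
  prof <- build_exposure_profiles(coh)
  p1 <- dplyr::filter(prof, subject_id == "1")
  expect_true(all(p1$hb_g_l == 100))
  p2 <- dplyr::filter(prof, subject_id == "2")
  # midpoint of the 10 -> 24 segment
  expect_equal(p2$hb_g_l[p2$week == 17], 107)
  # constant extrapolation before the first visit
  expect_equal(p2$hb_g_l[p2$week == 5], 100)
  expect_equal(p2$hb_g_l[p2$week == 39], 120)
  # provenance flags
  expect_equal(p2$source[p2$week == 10], "observed")
  expect_equal(p2$source[p2$week == 17], "interpolated")
  expect_equal(p2$source[p2$week == 5], "extrapolated")
  expect_equal(nrow(p1), 39)
})

test_that("subjects with fewer than two distinct visit weeks are excluded", {
  visits <- tibble::tibble(
    subject_id = c(1, 1, 2, 2),
    ga_weeks = c(10, 10, 10, 30),
    hb_g_l = c(100, 104, 110, 112)
  )
  coh <- hb_cohort(visits, tibble::tibble(subject_id = c(1, 2)))
  expect_message(prof <- build_exposure_profiles(coh), "excluded 1")
  expect_equal(attr(prof, "excluded"), "1")
  expect_setequal(unique(prof$subject_id), "2")
})

test_that("linear-exposure constant-lag cross-basis equals the cumulative covariate", {
  hbs <- list(c(100, 110, 120), c(115, 115, 115), c(90, 130, 105))
  coh <- make_profile_cohort(hbs)
  prof <- build_exposure_profiles(coh)
  spec <- cross_basis_spec("linear", lag_type = "constant")
  Q <- build_cross_basis(prof, spec, reference = 110)
  # hand-computed: sum over weeks of (Hb(w) - 110)
  for (i in 1:3) {
    p <- dplyr::filter(prof, subject_id == as.character(i))
    expect_equal(unname(Q[as.character(i), 1]), sum(p$hb_g_l - 110),
                 tolerance = 1e-10)
  }
  # identical profiles give identical rows
  coh2 <- make_profile_cohort(list(c(100, 110, 120), c(100, 110, 120)))
  Q2 <- build_cross_basis(build_exposure_profiles(coh2), spec)
  expect_equal(Q2[1, ], Q2[2, ])
  # a profile constant at the reference maps to an all-zero row, any spec
  cohr <- make_profile_cohort(list(c(110, 110, 110), c(95, 120, 130),
                                   c(120, 100, 115), c(105, 125, 98)))
  for (sp in list(spec, cross_basis_spec("ns", 2, "ns", 2))) {
    Qr <- build_cross_basis(build_exposure_profiles(cohr), sp, reference = 110)
    expect_lt(max(abs(Qr["1", ])), 1e-10)
    expect_gt(max(abs(Qr["2", ])), 1)
  }
})

test_that("a one-column cross-basis DLNM equals plain logistic on the collapsed covariate", {
  coh <- sim_three_visit(n = 250, seed = 33)
  prof <- build_exposure_profiles(coh)
  spec <- cross_basis_spec("linear", lag_type = "constant")
  fit <- fit_dlnm(coh, "lbw", spec)
  Q <- build_cross_basis(prof, spec, reference = 110)
  y <- coh$subjects$lbw[match(rownames(Q), as.character(coh$subjects$subject_id))]
  oracle <- fit_logistic(cbind(1, q = drop(Q)), y)
  expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
               tolerance = 1e-8)
  # stored linear predictor reconstructs from profiles + spec + coefficients
  lp <- drop(cbind(1, Q) %*% fit$coefficients)
  expect_equal(unname(fit$linear_predictor), unname(lp), tolerance = 1e-10)
})

test_that("the OR curve is exactly 1 at zero increment and bands behave", {
  coh <- sim_three_visit(n = 300, seed = 44)
  fit <- fit_dlnm(coh, "lbw", cross_basis_spec("ns", 2, "ns", 2))
  c0 <- predict_or_curve(fit, increment = 0)
  expect_true(all(c0$or == 1))
  c5 <- predict_or_curve(fit, increment = 5)
  expect_equal(nrow(c5), 39)
  expect_true(all(c5$conf.low <= c5$or & c5$or <= c5$conf.high))
  expect_equal(c5$or, exp(c5$log_or))
})

test_that("AIC selection is definitionally consistent and breaks ties deterministically", {
  coh <- sim_three_visit(n = 300, seed = 55)
  sel <- select_model_aic(coh, "lbw")
  tab <- sel$table
  expect_true(all(tab$converged))
  # AIC = 2k - 2 loglik with k including the intercept
  f <- sel$fit
  expect_equal(f$aic, 2 * (f$spec$dim + 1) - 2 * f$loglik, tolerance = 1e-8)
  expect_equal(min(tab$aic), f$aic)
  # duplicate specs: tie broken to the first by label order, same AIC
  dup <- list(cross_basis_spec("linear", lag_type = "constant", label = "a"),
              cross_basis_spec("linear", lag_type = "constant", label = "b"))
  sel2 <- select_model_aic(coh, "lbw", specs = dup)
  expect_equal(sel2$table$aic[1], sel2$table$aic[2], tolerance = 1e-10)
  expect_equal(sel2$best_label, "a")
  expect_error(select_model_aic(coh, "lbw", specs = dup[1]), "at least 2")
})

test_that("AIC prefers the linear spec when the truth is linear cumulative exposure", {
  # outcome generated from the window-mean (all weeks) of the latent curve:
  # a linear-exposure constant-lag truth
  wins <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    coh <- simulate_window_effect_cohort(
      sim_config(n_subjects = 2000, seed = 600 + r),
      effect_window = c(1, 39), effect_per_5g = 0.25
    )
    coh <- collapse_within_trimester(coh)
    sel <- select_model_aic(
      coh, "lbw",
      specs = list(cross_basis_spec("linear", lag_type = "constant"),
                   cross_basis_spec("ns", 3, "ns", 2))
    )
    if (sel$best_label == "exp=linear,lag=constant") wins <- wins + 1
  }
  expect_gte(wins / reps, 0.9)
})

test_that("an over-parameterized cross-basis is rejected", {
  coh <- sim_three_visit(n = 15, seed = 2)
  expect_error(fit_dlnm(coh, "lbw", cross_basis_spec("ns", 3, "ns", 3)),
               "over-parameterized")
})
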