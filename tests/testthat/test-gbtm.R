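# two well-separated quadratic classes (means ~20 g/L apart at every week)
two_class_cohort <- function(n = 400, seed = 1, prop = c(0.7, 0.3)) {
  simulate_cohort(sim_config(
    n_subjects = n, prop_three_visits = 1, seed = seed,
    n_classes = 2, class_proportions = prop,
    class_polynomials = rbind(c(128, -0.5, 0.01), c(108, -0.5, 0.01)),
    sd_random_intercept = 3, sd_random_slope_t2 = 0, sd_random_slope_t3 = 0,
    sd_noise = 4
  ))
}

test_that("K = 1 equals a single pooled polynomial regression", {
  coh <- sim_three_visit(n = 150, seed = 3)
  fit <- fit_gbtm(coh, K = 1, degree = 2, n_restarts = 3, seed = 9)
  lmfit <- stats::lm(hb_g_l ~ ga_weeks + I(ga_weeks^2), data = coh$visits)
  expect_equal(unname(fit$coefficients[1, ]), unname(coef(lmfit)),
               tolerance = 1e-8)
  # mixture loglik with one class = Gaussian loglik at the MLE sigma
  n <- nrow(coh$visits)
  s2 <- mean(residuals(lmfit)^2)
  ll <- sum(dnorm(residuals(lmfit), 0, sqrt(s2), log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  expect_equal(fit$pi, 1)
  expect_true(all(fit$posterior == 1))
})

test_that("well-separated two-class structure is recovered almost exactly", {
  coh <- two_class_cohort(n = 400, seed = 21)
  c3 <- subset_by_visit_count(collapse_within_trimester(coh), 3, quiet = TRUE)
  fit <- fit_gbtm(c3, K = 2, degree = 2, n_restarts = 10, seed = 5)
  # canonical class 1 is the high-Hb class = generator class 1
  agree <- mean(assign_groups(fit, quiet = TRUE)$class == c3$truth$class)
  expect_gte(agree, 0.99)
  se_pi <- sqrt(0.7 * 0.3 / 400)
  expect_lt(abs(fit$pi[1] - 0.7), 3 * se_pi)
  # average max posterior is high on this separation
  expect_gt(mean(assign_groups(fit, quiet = TRUE)$max_posterior), 0.95)
  # posterior rows sum to one
  expect_lt(max(abs(rowSums(fit$posterior) - 1)), 1e-10)
  # EM log-likelihood trace is non-decreasing
  expect_true(all(diff(fit$em$loglik_trace) > -1e-6))
})

test_that("subject order permutation leaves the canonical fit invariant", {
  coh <- two_class_cohort(n = 200, seed = 31)
  c3 <- subset_by_visit_count(collapse_within_trimester(coh), 3, quiet = TRUE)
  fit1 <- fit_gbtm(c3, K = 2, degree = 2, n_restarts = 5, seed = 7)
  perm <- c3
  set.seed(42)
  o <- sample(nrow(perm$visits))
  perm$visits <- perm$visits[o, ]
  perm <- hb_cohort(perm$visits, perm$subjects[sample(nrow(perm$subjects)), ])
  fit2 <- fit_gbtm(perm, K = 2, degree = 2, n_restarts = 5, seed = 7)
  expect_equal(fit2$pi, fit1$pi, tolerance = 1e-6)
  expect_equal(fit2$coefficients, fit1$coefficients, tolerance = 1e-5)
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-6)
})

test_that("BIC is definitionally consistent and selection applies the 5% floor", {
  coh <- two_class_cohort(n = 300, seed = 41)
  c3 <- subset_by_visit_count(collapse_within_trimester(coh), 3, quiet = TRUE)
  fit <- fit_gbtm(c3, K = 2, degree = 2, n_restarts = 5, seed = 3)
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_params * log(fit$n_subjects),
               tolerance = 1e-10)
  sel <- select_gbtm(c3, K_range = 1:3, n_restarts = 5, seed = 3)
  expect_true(all(c("K", "bic", "min_class_share", "meets_floor") %in%
                    names(sel$table)))
  # any candidate whose smallest modal class is under 5% must be ineligible
  under <- sel$table$min_class_share < 0.05 & sel$table$converged
  expect_false(any(sel$table$meets_floor[under]))
  picked <- sel$table[sel$table$K == sel$fit$K, ]
  eligible <- sel$table[sel$table$meets_floor, ]
  expect_equal(picked$bic, min(eligible$bic))
})

test_that("selection recovers the true K for separated classes and K=1 for one class", {
  # truths that satisfy the GBTM assumption of iid within-class residuals
  # (no subject random effects): a mixture model is selection-consistent here,
  # whereas residual within-subject correlation is known to inflate K
  hits <- 0
  reps <- 5
  for (r in seq_len(reps)) {
    coh <- simulate_cohort(sim_config(
      n_subjects = 500, prop_three_visits = 1, seed = 700 + r,
      n_classes = 3, class_proportions = c(0.5, 0.3, 0.2),
      class_polynomials = rbind(c(132, -0.5, 0), c(112, -0.5, 0),
                                c(92, -0.5, 0)),
      sd_random_intercept = 0, sd_random_slope_t2 = 0, sd_random_slope_t3 = 0,
      sd_noise = 4
    ))
    c3 <- subset_by_visit_count(collapse_within_trimester(coh), 3, quiet = TRUE)
    sel <- select_gbtm(c3, K_range = 1:4, n_restarts = 8, seed = r)
    if (sel$fit$K == 3) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
  # single-class truth
  ones <- 0
  for (r in seq_len(reps)) {
    coh <- simulate_cohort(sim_config(
      n_subjects = 300, prop_three_visits = 1, seed = 800 + r,
      n_classes = 2, class_proportions = c(0.5, 0.5),
      class_polynomials = rbind(c(120, -0.4, 0.008), c(120, -0.4, 0.008)),
      sd_random_intercept = 0, sd_random_slope_t2 = 0, sd_random_slope_t3 = 0,
      sd_noise = 5
    ))
    c1 <- subset_by_visit_count(collapse_within_trimester(coh), 3, quiet = TRUE)
    sel <- select_gbtm(c1, K_range = 1:3, n_restarts = 5, seed = r)
    if (sel$fit$K == 1) ones <- ones + 1
  }
  expect_gte(ones / reps, 0.8)
})

test_that("modal assignment breaks exact ties toward the lower canonical label", {
  coh <- two_class_cohort(n = 200, seed = 51)
  c3 <- subset_by_visit_count(collapse_within_trimester(coh), 3, quiet = TRUE)
  fit <- fit_gbtm(c3, K = 2, degree = 2, n_restarts = 5, seed = 1)
  fit$posterior[1, ] <- c(0.5, 0.5)
  fit$posterior[2, ] <- c(0.6, 0.4)
  a <- assign_groups(fit, quiet = TRUE)
  expect_equal(a$class[1], 1L)
  expect_true(a$tie[1])
  expect_equal(a$class[2], 1L)
  expect_false(a$tie[2])
})

test_that("group-outcome regression recovers a doubled risk and matches modes", {
  coh <- simulate_cohort(sim_config(
    n_subjects = 2000, prop_three_visits = 1, seed = 61,
    n_classes = 2, class_proportions = c(0.7, 0.3),
    class_polynomials = rbind(c(128, -0.5, 0.01), c(108, -0.5, 0.01)),
    sd_random_intercept = 3, sd_random_slope_t2 = 0, sd_random_slope_t3 = 0,
    sd_noise = 4,
    outcome_model = "class_link",
    outcome_coefs = list(lbw = c(0, log(2.5)))
  ))
  c3 <- subset_by_visit_count(collapse_within_trimester(coh), 3, quiet = TRUE)
  fit <- fit_gbtm(c3, K = 2, degree = 2, n_restarts = 8, seed = 2)
  y <- c3$subjects$lbw[match(fit$subject_id, c3$subjects$subject_id)]
  fm <- fit_group_outcome(fit, y, mode = "modal")
  tab <- or_table(fm)
  est <- tab$estimate[tab$term == "class2"]
  se <- tab$std.error[tab$term == "class2"]
  expect_lt(abs(est - log(2.5)), 3 * se)
  # with hard posteriors the two modes coincide
  hard <- fit
  cls <- assign_groups(fit, quiet = TRUE)$class
  hard$posterior <- matrix(0, nrow(fit$posterior), 2,
                           dimnames = dimnames(fit$posterior))
  hard$posterior[cbind(seq_along(cls), cls)] <- 1
  fp <- fit_group_outcome(hard, y, mode = "posterior")
  fm2 <- fit_group_outcome(hard, y, mode = "modal")
  expect_equal(unname(fp$coefficients), unname(fm2$coefficients),
               tolerance = 1e-8)
  expect_error(fit_group_outcome(fit_gbtm(c3, K = 1, n_restarts = 2, seed = 1), y),
               "at least 2")
})

test_that("null class-outcome association gives nominal coverage", {
  covered <- 0
  reps <- 30
  coh <- two_class_cohort(n = 500, seed = 71)
  c3 <- subset_by_visit_count(collapse_within_trimester(coh), 3, quiet = TRUE)
  fit <- fit_gbtm(c3, K = 2, degree = 2, n_restarts = 8, seed = 4)
  set.seed(99)
  for (r in seq_len(reps)) {
    y <- rbinom(length(fit$subject_id), 1, 0.25)
    tab <- or_table(fit_group_outcome(fit, y, mode = "modal"))
    row <- tab[tab$term == "class2", ]
    if (row$conf.low <= 1 && 1 <= row$conf.high) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.85)
})
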