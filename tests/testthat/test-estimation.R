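test_that("OLS matches a normal-equations oracle and basic identities", {
  set.seed(101)
  X <- cbind(1, rnorm(20), runif(20))
  colnames(X) <- c("b0", "b1", "b2")
  y <- rnorm(20)
  fit <- fit_ols(X, y)
  # independent dense solve of X'X beta = X'y
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients), unname(drop(oracle)), tolerance = 1e-8)
  # residual orthogonality to every design column
  expect_lt(max(abs(t(X) %*% fit$residuals)), 1e-8)
  # intercept-only model returns the sample mean
  m <- fit_ols(matrix(1, 20, 1), y)
  expect_equal(unname(m$coefficients), mean(y))
  # exact linear data -> zero residuals
  yz <- 2 + 3 * X[, 2]
  expect_lt(max(abs(fit_ols(X[, 1:2], yz)$residuals)), 1e-10)
  # rank deficiency rejected
  expect_error(fit_ols(cbind(X, X[, 2]), y), "singular")
})

test_that("logistic MLE on saturated 2x2 data equals the cross-product odds ratio", {
  # exposed: 10 events / 10 non-events; unexposed: 5 events / 15 non-events
  x <- c(rep(1, 20), rep(0, 20))
  y <- c(rep(1, 10), rep(0, 10), rep(1, 5), rep(0, 15))
  fit <- fit_logistic(cbind(1, exposed = x), y)
  expect_equal(exp(fit$coefficients[["exposed"]]), 3.0, tolerance = 1e-6)
  tab <- or_table(fit)
  expect_true(all(tab$conf.low < tab$or & tab$or < tab$conf.high))
})

test_that("logistic MLE beats every point on a surrounding coefficient grid", {
  set.seed(7)
  n <- 50
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
  X <- cbind(1, x = x)
  fit <- fit_logistic(X, y)
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  b_hat <- fit$coefficients
  expect_equal(ll(b_hat), fit$loglik, tolerance = 1e-8)
  grid <- expand.grid(db0 = seq(-1, 1, by = 0.25), db1 = seq(-1, 1, by = 0.25))
  lls <- apply(grid, 1, function(d) ll(b_hat + d))
  expect_true(all(lls <= fit$loglik + 1e-10))
  # score at the MLE vanishes
  p <- plogis(drop(X %*% b_hat))
  expect_lt(max(abs(t(X) %*% (y - p))), 1e-6)
})

test_that("logistic fit rejects one-class responses and flags separation", {
  x <- cbind(1, x = rnorm(30))
  expect_error(fit_logistic(x, rep(0, 30)), "one-class")
  # complete separation: outcome is a threshold of x
  z <- seq(-2, 2, length.out = 40)
  expect_error(
    fit_logistic(cbind(1, z = z), as.numeric(z > 0)),
    "separation.*z"
  )
})

test_that("balanced random-intercept LMM matches the closed-form REML estimator", {
  # m subjects x r replicates, intercept-only: REML variance components have
  # the one-way ANOVA closed form sigma2 = MSE, tau2 = (MSA - MSE) / r
  set.seed(55)
  m <- 40; r <- 3
  u <- rnorm(m, 0, 3)
  d <- tibble::tibble(
    subject_id = rep(seq_len(m), each = r),
    y = 100 + rep(u, each = r) + rnorm(m * r, 0, 2)
  )
  fit <- fit_lmm(d, y ~ 1, ~ 1 | subject_id)
  ybar_i <- tapply(d$y, d$subject_id, mean)
  mse <- sum((d$y - rep(ybar_i, each = r))^2) / (m * (r - 1))
  msa <- r * sum((ybar_i - mean(d$y))^2) / (m - 1)
  vc <- as.data.frame(fit$varcorr)
  tau2 <- vc$vcov[vc$grp == "subject_id"]
  expect_equal(fit$sigma^2, mse, tolerance = 1e-6)
  expect_equal(tau2, (msa - mse) / r, tolerance = 1e-6)
  # BLUPs have mean ~ 0 (empirical-Bayes shrinkage around the fixed mean)
  expect_lt(abs(mean(fit$blups[[2]])), 1e-8)
})

test_that("zero random-effect variance shrinks all BLUPs to zero", {
  set.seed(66)
  d <- tibble::tibble(
    subject_id = rep(1:30, each = 3),
    t = rep(0:2, 30)
  )
  d$y <- 10 + 2 * d$t + rnorm(90, 0, 1)  # no subject effect
  fit <- fit_lmm(d, y ~ t, ~ 1 | subject_id)
  vc <- as.data.frame(fit$varcorr)
  expect_lt(vc$vcov[vc$grp == "subject_id"], 0.3)
  expect_lt(max(abs(fit$blups[[2]])), 1)
})

test_that("REML optimum beats random perturbations of the variance components", {
  set.seed(77)
  d <- tibble::tibble(
    subject_id = rep(1:50, each = 3),
    t = rep(0:2, 50)
  )
  d$y <- 5 + rep(rnorm(50, 0, 2), each = 3) + rnorm(150, 0, 1.5)
  fit <- fit_lmm(d, y ~ t, ~ 1 | subject_id)
  dev <- lme4::devfun2(fit$model, useSc = TRUE, signames = FALSE)
  opt <- environment(dev)$pp$theta
  sig <- stats::sigma(fit$model)
  base <- dev(c(opt * sig, sig))
  set.seed(1)
  for (i in 1:50) {
    cand <- c(opt * sig, sig) * exp(rnorm(2, 0, 0.3))
    expect_gte(dev(cand), base - 1e-6)
  }
})

test_that("natural cubic basis is linear beyond the boundary knots", {
  nsb <- natural_cubic_basis(seq(0, 10, by = 0.1), interior_knots = c(3, 5, 7),
                             boundary_knots = c(1, 9))
  expect_equal(nsb$dim, 4)
  # second differences vanish outside the boundary
  out <- nsb$eval(seq(10, 20, by = 0.5))
  d2 <- diff(out, differences = 2)
  expect_lt(max(abs(d2)), 1e-8)
  lo <- nsb$eval(seq(-10, 0, by = 0.5))
  expect_lt(max(abs(diff(lo, differences = 2))), 1e-8)
  # zero interior knots -> affine basis spanning x
  aff <- natural_cubic_basis(1:10, interior_knots = numeric(),
                             boundary_knots = c(1, 10))
  expect_equal(aff$dim, 1)
  expect_equal(ncol(aff$basis), 1)
  expect_lt(max(abs(diff(aff$basis[, 1], differences = 2))), 1e-10)
  expect_error(natural_cubic_basis(1:10, interior_knots = c(3, 3)), "duplicate")
})

test_that("functions in the spline span are reproduced by projection", {
  x <- seq(0, 10, length.out = 200)
  nsb <- natural_cubic_basis(x, interior_knots = c(3, 7), boundary_knots = c(0, 10))
  B <- cbind(1, nsb$basis)
  set.seed(3)
  f <- drop(B %*% c(2, -1, 0.5, 3))  # a function in the span
  coefs <- solve(t(B) %*% B, t(B) %*% f)
  expect_equal(drop(B %*% coefs), f, tolerance = 1e-8)
})

test_that("standardize centres, scales, round-trips and is idempotent", {
  s <- standardize(c(1, 2, 3))
  expect_equal(mean(s$values), 0)
  expect_equal(sd(s$values), 1)
  expect_equal(s$center, 2)
  set.seed(9)
  x <- rnorm(50, 7, 3)
  s <- standardize(x)
  s2 <- standardize(s$values)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_equal(s$values * s$scale + s$center, x, tolerance = 1e-12)
  expect_error(standardize(rep(4, 10)), "constant")
})
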