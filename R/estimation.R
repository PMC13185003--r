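#' Ordinary least squares on an explicit design matrix
#'
#' Thin wrapper around R's QR least-squares solve that enforces a full-rank
#' design, keeps column names on the coefficients, and returns the raw
#' (unstandardized) residuals.
#'
#' @param x Numeric design matrix (include an intercept column yourself).
#' @param y Numeric response.
#' @return An object of class `hb_ols`: list with `coefficients`, `residuals`,
#'   `fitted`, `sigma` (residual SD on n - p df) and `terms` (column names).
#' @export
fit_ols <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) != length(y)) abort("nrow(x) must equal length(y)")
  if (nrow(x) <= ncol(x)) abort("need more observations than design columns")
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    abort(sprintf("singular design: rank %d < %d columns", qrx$rank, ncol(x)))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(x %*% beta)
  res <- y - fitted
  structure(
    list(
      coefficients = setNames(as.numeric(beta), colnames(x)),
      residuals = res, fitted = fitted,
      sigma = sqrt(sum(res^2) / (nrow(x) - ncol(x))),
      terms = colnames(x)
    ),
    class = "hb_ols"
  )
}

#' Logistic regression with Wald inference and separation guards
#'
#' Maximum-likelihood logistic regression (binomial IRLS through
#' [stats::glm.fit()]) on an explicit design matrix. The fit refuses one-class
#' responses, flags non-convergence, and detects complete or quasi-complete
#' separation: a coefficient beyond +/-15 on the per-SD-standardized scale
#' together with fitted probabilities pinned at 0/1 aborts with the name of
#' the separating column. Wald covariance comes from the final weighted
#' information matrix.
#'
#' @param x Numeric design matrix (include the intercept column).
#' @param y Binary response in \{0, 1\}.
#' @param scales Optional named numeric vector: per-term unit multipliers used
#'   when reporting odds ratios (e.g. `c(x1 = 5)` for "per 5 g/L"); terms not
#'   named get scale 1.
#' @param scale_labels Optional named character vector of annotations (e.g.
#'   `c(eps1_std = "per 1 SD")`).
#' @return Object of class `hb_logistic`: `coefficients`, `vcov`, `loglik`,
#'   `aic`, `converged`, `n`, plus the reporting metadata.
#' @export
fit_logistic <- function(x, y, scales = NULL, scale_labels = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!all(y %in% c(0, 1))) abort("response must be coded 0/1")
  if (length(unique(y)) < 2) {
    abort("one-class response: logistic regression needs both outcome classes")
  }
  if (ncol(x) >= nrow(x)) abort("over-parameterized: p >= n")
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial(), control = stats::glm.control(maxit = 100))
  )
  beta <- coef(fit)
  # separation check on the standardized scale (intercept-like columns exempt)
  col_sd <- apply(x, 2, sd)
  varying <- col_sd > 0
  std_beta <- abs(beta[varying] * col_sd[varying])
  pinned <- mean(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  if (any(std_beta > 15, na.rm = TRUE) && pinned > 0) {
    worst <- names(std_beta)[which.max(std_beta)]
    abort(sprintf("complete or quasi-complete separation detected (column `%s`)", worst))
  }
  if (!fit$converged) {
    abort(sprintf(
      "IRLS did not converge in 100 iterations (deviance %.4f, max |coef| %.2f)",
      fit$deviance, max(abs(beta))
    ))
  }
  R <- qr.R(fit$qr)
  vc <- chol2inv(R)
  dimnames(vc) <- list(colnames(x), colnames(x))
  p <- fit$fitted.values
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  sc <- setNames(rep(1, ncol(x)), colnames(x))
  if (!is.null(scales)) sc[names(scales)] <- scales
  lab <- setNames(paste0("per ", signif(sc, 3), " unit"), colnames(x))
  if (!is.null(scale_labels)) lab[names(scale_labels)] <- scale_labels
  structure(
    list(
      coefficients = beta, vcov = vc, loglik = ll, aic = -2 * ll + 2 * ncol(x),
      converged = fit$converged, n = nrow(x),
      scales = sc, scale_labels = lab,
      fitted = fit$fitted.values, x = x, y = y
    ),
    class = "hb_logistic"
  )
}

#' Odds-ratio table from a logistic fit
#'
#' @param fit An `hb_logistic`.
#' @param level Confidence level (Wald, on the log-odds scale).
#' @return Tibble with `term`, `estimate` (log-odds per reporting unit), `or`,
#'   `conf.low`, `conf.high`, `scale`.
#' @export
or_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "hb_logistic"))
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(fit$vcov))
  b <- fit$coefficients * fit$scales
  s <- se * fit$scales
  tibble::tibble(
    term = names(fit$coefficients),
    estimate = unname(b),
    std.error = unname(s),
    or = exp(unname(b)),
    conf.low = exp(unname(b - z * s)),
    conf.high = exp(unname(b + z * s)),
    scale = unname(fit$scale_labels)
  )
}

#' Linear mixed model with subject-level BLUPs
#'
#' REML fit through [lme4::lmer()] of a Gaussian linear mixed model, returning
#' the fixed effects with Wald intervals, the estimated variance components,
#' and the per-subject best linear unbiased predictors (BLUPs, empirical-Bayes
#' estimates of the random effects) that downstream models use as predictors.
#'
#' @param data Long data frame.
#' @param fixed One-sided or two-sided formula for the fixed effects, e.g.
#'   `hb_g_l ~ tri2 + tri3`.
#' @param random Random-effects term as a one-sided formula, e.g.
#'   `~ tri2 + tri3 | subject_id` (unstructured covariance).
#' @return Object of class `hb_lmm`: `fixef` tibble (estimate, se, Wald CI),
#'   `blups` tibble keyed by subject, `varcorr`, `sigma`, `loglik`,
#'   `converged`, `singular`, and the underlying `lme4` model as `model`.
#' @export
fit_lmm <- function(data, fixed, random) {
  rnd <- as.character(random)[2]
  full <- stats::as.formula(
    paste(deparse(fixed), "+ (", rnd, ")"),
    env = environment()
  )
  # with one observation per random-effect level the subject covariance and
  # the residual variance are only jointly identified; REML settles at the
  # boundary and the fit is flagged singular rather than refused
  model <- lme4::lmer(full, data = data, REML = TRUE,
                      control = lme4::lmerControl(
                        calc.derivs = FALSE,
                        check.conv.singular = "ignore",
                        check.nobs.vs.nRE = "ignore",
                        check.nobs.vs.rankZ = "ignore"
                      ))
  conv <- is.null(model@optinfo$conv$opt) || model@optinfo$conv$opt == 0
  fe <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(vcov(model))))
  grp <- names(lme4::ranef(model))[1]
  re <- lme4::ranef(model)[[grp]]
  blups <- tibble::as_tibble(re, rownames = "subject_id")
  names(blups) <- c("subject_id", paste0("blup_", make.names(names(re))))
  structure(
    list(
      fixef = tibble::tibble(
        term = names(fe), estimate = unname(fe), std.error = unname(se),
        conf.low = unname(fe - qnorm(0.975) * se),
        conf.high = unname(fe + qnorm(0.975) * se)
      ),
      blups = blups,
      varcorr = lme4::VarCorr(model),
      sigma = stats::sigma(model),
      loglik = as.numeric(stats::logLik(model)),
      converged = conv,
      singular = lme4::isSingular(model),
      model = model
    ),
    class = "hb_lmm"
  )
}

#' Natural cubic spline basis
#'
#' Natural (restricted) cubic regression-spline basis: cubic between knots,
#' constrained to be linear beyond the boundary knots. Dimension is
#' (number of interior knots + 1), excluding the intercept. Evaluation is a
#' deterministic function of the knot set, so the basis can be re-evaluated
#' at new points (prediction, contrasts) without refitting.
#'
#' @param x Values at which to evaluate.
#' @param interior_knots Strictly increasing knots inside the boundary;
#'   may be empty (gives the affine basis spanning x).
#' @param boundary_knots Length-2 boundary; defaults to `range(x)`.
#' @return List of class `hb_ns`: `basis` (evaluated matrix), `eval` (function
#'   of new x), `interior_knots`, `boundary_knots`, `dim`.
#' @export
natural_cubic_basis <- function(x, interior_knots = numeric(),
                                boundary_knots = range(x)) {
  if (anyDuplicated(interior_knots)) abort("duplicate interior knots")
  if (length(interior_knots) > 0) {
    if (is.unsorted(interior_knots, strictly = TRUE)) abort("interior knots must be strictly increasing")
    if (any(interior_knots <= boundary_knots[1] | interior_knots >= boundary_knots[2])) {
      abort("interior knots must lie strictly inside the boundary knots")
    }
  }
  evalfun <- function(newx) {
    m <- splines::ns(newx, knots = interior_knots, Boundary.knots = boundary_knots)
    unclass(m)[, , drop = FALSE]
  }
  structure(
    list(
      basis = evalfun(x), eval = evalfun,
      interior_knots = interior_knots, boundary_knots = boundary_knots,
      dim = length(interior_knots) + 1L
    ),
    class = "hb_ns"
  )
}

#' Standardize a numeric vector to mean 0, sample SD 1
#'
#' @param x Numeric vector with at least two distinct values.
#' @return List: `values` (standardized), `center` (mean), `scale`
#'   (sample, n-1, SD).
#' @export
standardize <- function(x) {
  if (length(unique(x)) < 2) {
    abort("cannot standardize: fewer than 2 distinct values (constant input)")
  }
  m <- mean(x)
  s <- sd(x)
  list(values = (x - m) / s, center = m, scale = s)
}
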