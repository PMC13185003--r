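#' Weekly Hb exposure profiles from sparse visits
#'
#' Expands each subject's 2-3 Hb measurements into a weekly exposure history
#' on the integer grid of gestational weeks 1-39: linear interpolation
#' between observed visits, constant (nearest-value) extrapolation before the
#' first and after the last visit. Each grid value carries a provenance flag
#' so sensitivity analyses can down-weight extrapolated weeks.
#'
#' @param cohort An `hb_cohort`; visit weeks must lie within 1-39.
#' @param weeks Integer grid (default `1:39`).
#' @return Tibble with `subject_id`, `week`, `hb_g_l`, `source`
#'   (observed/interpolated/extrapolated). Subjects with fewer than two
#'   distinct visit weeks are excluded with a message; excluded ids are in
#'   attribute `excluded`.
#' @export
build_exposure_profiles <- function(cohort, weeks = 1:39) {
  stopifnot(inherits(cohort, "hb_cohort"))
  v <- cohort$visits
  if (any(v$ga_weeks < min(weeks) | v$ga_weeks > max(weeks))) {
    abort(sprintf("visit weeks outside the %d-%d grid", min(weeks), max(weeks)))
  }
  by_subj <- split(v[c("ga_weeks", "hb_g_l")], v$subject_id)
  ok <- vapply(by_subj, function(d) length(unique(d$ga_weeks)) >= 2, logical(1))
  excluded <- names(by_subj)[!ok]
  if (length(excluded) > 0) {
    message(sprintf(
      "excluded %d subject(s) with < 2 distinct visit weeks from profile construction",
      length(excluded)
    ))
  }
  prof <- purrr::map_dfr(by_subj[ok], function(d) {
    hb <- approx(d$ga_weeks, d$hb_g_l, xout = weeks, rule = 2, ties = mean)$y
    src <- ifelse(
      weeks < min(d$ga_weeks) | weeks > max(d$ga_weeks), "extrapolated",
      ifelse(vapply(weeks, function(w) any(abs(d$ga_weeks - w) < 1e-8), logical(1)),
             "observed", "interpolated")
    )
    tibble::tibble(week = weeks, hb_g_l = hb, source = src)
  }, .id = "subject_id")
  attr(prof, "excluded") <- excluded
  attr(prof, "weeks") <- weeks
  prof
}

# subjects x weeks matrix from a profile tibble
.profile_matrix <- function(profiles) {
  wide <- tidyr::pivot_wider(
    profiles[c("subject_id", "week", "hb_g_l")],
    names_from = "week", values_from = "hb_g_l"
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$subject_id
  m
}

#' Specify an exposure-by-lag cross-basis
#'
#' The cross-basis parameterizes a time-varying, possibly non-linear effect
#' of weekly Hb on the outcome as the tensor product of an exposure-dimension
#' basis (linear, or natural cubic spline with knots at exposure quantiles)
#' and a lag-dimension basis (constant, linear, or natural cubic spline over
#' the lag range). Knot positions are resolved from the data at build time.
#'
#' @param exposure_type `"linear"` or `"ns"`.
#' @param exposure_knots Number of interior knots for the exposure spline.
#' @param lag_type `"constant"`, `"linear"` or `"ns"`.
#' @param lag_knots Number of interior knots for the lag spline.
#' @param label Optional label used in AIC tables (auto-generated otherwise).
#' @return List of class `hb_cb_spec`.
#' @export
cross_basis_spec <- function(exposure_type = c("linear", "ns"),
                             exposure_knots = 2,
                             lag_type = c("constant", "linear", "ns"),
                             lag_knots = 2,
                             label = NULL) {
  exposure_type <- match.arg(exposure_type)
  lag_type <- match.arg(lag_type)
  dx <- if (exposure_type == "linear") 1L else as.integer(exposure_knots) + 1L
  dl <- switch(lag_type, constant = 1L, linear = 2L,
               ns = as.integer(lag_knots) + 2L)
  if (is.null(label)) {
    label <- paste0(
      "exp=", if (exposure_type == "linear") "linear" else paste0("ns", exposure_knots),
      ",lag=", if (lag_type == "ns") paste0("ns", lag_knots) else lag_type
    )
  }
  structure(
    list(exposure_type = exposure_type, exposure_knots = exposure_knots,
         lag_type = lag_type, lag_knots = lag_knots,
         dx = dx, dl = dl, dim = dx * dl, label = label),
    class = "hb_cb_spec"
  )
}

#' Default candidate grid of cross-basis specifications
#'
#' Exposure basis: linear, or natural spline with 2 or 3 interior knots at
#' exposure quantiles. Lag basis: constant, linear, or natural spline with 2
#' interior knots at equally spaced weeks.
#'
#' @return List of `hb_cb_spec`.
#' @export
default_cross_basis_grid <- function() {
  specs <- list()
  for (et in list(list("linear", 0), list("ns", 2), list("ns", 3))) {
    for (lt in c("constant", "linear", "ns")) {
      specs[[length(specs) + 1]] <- cross_basis_spec(
        exposure_type = et[[1]], exposure_knots = et[[2]],
        lag_type = lt, lag_knots = 2
      )
    }
  }
  specs
}

# resolve the two marginal basis evaluators for a spec against observed data
.resolve_bases <- function(spec, hb_values, weeks, reference) {
  if (spec$exposure_type == "linear") {
    exp_eval <- function(x) matrix(x - reference, ncol = 1,
                                   dimnames = list(NULL, "exp_lin"))
  } else {
    probs <- seq_len(spec$exposure_knots) / (spec$exposure_knots + 1)
    kn <- unname(quantile(hb_values, probs))
    bk <- range(hb_values)
    bk <- c(min(bk[1], reference), max(bk[2], reference))
    nsb <- natural_cubic_basis(hb_values[1], interior_knots = kn, boundary_knots = bk)
    ref_row <- nsb$eval(reference)
    exp_eval <- function(x) {
      m <- sweep(nsb$eval(x), 2, as.numeric(ref_row))
      colnames(m) <- paste0("exp_ns", seq_len(ncol(m)))
      m
    }
  }
  lag <- max(weeks) - weeks
  lag_basis <- switch(spec$lag_type,
    constant = matrix(1, length(lag), 1, dimnames = list(NULL, "lag_const")),
    linear = cbind(lag_const = 1, lag_lin = lag / max(lag)),
    ns = {
      lkn <- seq(min(lag), max(lag), length.out = spec$lag_knots + 2)
      lkn <- lkn[-c(1, length(lkn))]
      nsl <- natural_cubic_basis(lag, interior_knots = lkn, boundary_knots = range(lag))
      cbind(lag_const = 1, nsl$basis)
    }
  )
  list(exp_eval = exp_eval, lag_basis = lag_basis, lag = lag)
}

#' Build cross-basis covariate rows from weekly profiles
#'
#' For subject i the cross-basis row has entries
#' `q[i, (k,l)] = sum_w B_exp,k(Hb_i(w)) * B_lag,l(lag(w))`, with lag defined
#' as weeks before the end of the week-1-to-39 window (`lag = 39 - week`).
#' The exposure basis is centred at the reference so that a profile constant
#' at the reference maps to an all-zero row and reference contrasts are
#' exact.
#'
#' @param profiles Output of [build_exposure_profiles()].
#' @param spec An `hb_cb_spec`.
#' @param reference Centring/reference Hb, g/L (default 110).
#' @return Matrix (subjects x `spec$dim`) with attribute `bases` (resolved
#'   marginal bases) and rownames = subject ids.
#' @export
build_cross_basis <- function(profiles, spec, reference = 110) {
  stopifnot(inherits(spec, "hb_cb_spec"))
  H <- .profile_matrix(profiles)
  weeks <- as.integer(colnames(H))
  bases <- .resolve_bases(spec, as.numeric(H), weeks, reference)
  E_all <- bases$exp_eval(as.numeric(H))  # (n*W) x dx, column-major over H
  n <- nrow(H); W <- ncol(H)
  Q <- matrix(0, n, spec$dx * spec$dl)
  cn <- character(spec$dx * spec$dl)
  idx <- 0
  for (k in seq_len(spec$dx)) {
    Ek <- matrix(E_all[, k], n, W)
    M <- Ek %*% bases$lag_basis  # n x dl
    for (l in seq_len(spec$dl)) {
      idx <- idx + 1
      Q[, idx] <- M[, l]
      cn[idx] <- paste0("cb_", colnames(E_all)[k], "_", colnames(bases$lag_basis)[l])
    }
  }
  colnames(Q) <- cn
  rownames(Q) <- rownames(H)
  attr(Q, "bases") <- bases
  attr(Q, "weeks") <- weeks
  attr(Q, "reference") <- reference
  Q
}

#' Fit a distributed lag non-linear logistic model
#'
#' Logistic regression of a binary birth outcome on the cross-basis summary
#' of each subject's weekly Hb profile. The constrained coefficient structure
#' of the cross-basis yields a week-specific log-odds effect surface from
#' `spec$dim` parameters.
#'
#' @param cohort Three-visit `hb_cohort`.
#' @param outcome Outcome name (`"lbw"`, `"ptb"`, `"sga"`).
#' @param spec An `hb_cb_spec`.
#' @param reference Reference Hb, g/L.
#' @param profiles Optionally precomputed [build_exposure_profiles()] output.
#' @return Object of class `hb_dlnm`: the logistic fit plus the spec,
#'   resolved bases, AIC and stored linear predictor.
#' @export
fit_dlnm <- function(cohort, outcome, spec, reference = 110, profiles = NULL) {
  outcome <- match.arg(outcome, c("lbw", "ptb", "sga"))
  if (is.null(profiles)) profiles <- build_exposure_profiles(cohort)
  Q <- build_cross_basis(profiles, spec, reference)
  ids <- rownames(Q)
  subj <- cohort$subjects
  y <- subj[[outcome]][match(ids, as.character(subj$subject_id))]
  keep <- !is.na(y)
  if (spec$dim + 1 >= sum(keep)) {
    abort(sprintf("over-parameterized cross-basis: dimension %d with n = %d",
                  spec$dim, sum(keep)))
  }
  X <- cbind(`(Intercept)` = 1, Q[keep, , drop = FALSE])
  fit <- fit_logistic(X, y[keep])
  structure(
    list(
      spec = spec, reference = reference, outcome = outcome,
      coefficients = fit$coefficients, vcov = fit$vcov,
      loglik = fit$loglik, aic = fit$aic, n = fit$n,
      converged = fit$converged,
      linear_predictor = drop(X %*% fit$coefficients),
      bases = attr(Q, "bases"), weeks = attr(Q, "weeks"),
      subject_id = ids[keep]
    ),
    class = "hb_dlnm"
  )
}

#' Select a cross-basis specification by AIC
#'
#' Fits every candidate specification and returns the converged one with the
#' smallest AIC; ties are broken by smaller cross-basis dimension, then by
#' label order.
#'
#' @param cohort Three-visit `hb_cohort`.
#' @param outcome Outcome name.
#' @param specs List of `hb_cb_spec` (default [default_cross_basis_grid()]).
#' @param reference Reference Hb, g/L.
#' @return List: `fit` (best `hb_dlnm`) and `table` (tibble label, dim, aic,
#'   converged, error message for failures).
#' @export
select_model_aic <- function(cohort, outcome, specs = default_cross_basis_grid(),
                             reference = 110) {
  if (length(specs) < 2) abort("need at least 2 candidate specifications")
  profiles <- build_exposure_profiles(cohort)
  fits <- lapply(specs, function(sp) {
    tryCatch(fit_dlnm(cohort, outcome, sp, reference, profiles = profiles),
             error = function(e) structure(list(message = conditionMessage(e)),
                                           class = "hb_dlnm_failure"))
  })
  tab <- purrr::map2_dfr(specs, fits, function(sp, f) {
    failed <- inherits(f, "hb_dlnm_failure")
    tibble::tibble(
      label = sp$label, dim = sp$dim,
      aic = if (failed) NA_real_ else f$aic,
      converged = !failed,
      error = if (failed) f$message else NA_character_
    )
  })
  ok <- which(tab$converged)
  if (length(ok) == 0) abort("all candidate cross-basis fits failed")
  o <- ok[order(tab$aic[ok], tab$dim[ok], tab$label[ok])]
  list(fit = fits[[o[1]]], table = tab, best_label = tab$label[o[1]])
}

#' Week-specific odds-ratio curve from a fitted DLNM
#'
#' For each gestational week w, contrasts a profile equal to the reference
#' everywhere except `reference + increment` at week w against the
#' all-reference profile. The log-OR is the contrast applied to the
#' cross-basis coefficients; the 95% band comes from the delta method on the
#' log scale.
#'
#' @param fit An `hb_dlnm`.
#' @param increment Hb increment, g/L (default +5).
#' @param reference Reference Hb, g/L; defaults to the fit's reference. A
#'   reference outside the observed exposure range triggers a warning.
#' @param level Confidence level.
#' @return Tibble: `week`, `log_or`, `se`, `or`, `conf.low`, `conf.high`.
#' @export
predict_or_curve <- function(fit, increment = 5, reference = NULL, level = 0.95) {
  stopifnot(inherits(fit, "hb_dlnm"))
  if (is.null(reference)) reference <- fit$reference
  b <- fit$bases
  de <- b$exp_eval(reference + increment) - b$exp_eval(reference)  # 1 x dx
  dx <- ncol(de); dl <- ncol(b$lag_basis)
  beta <- fit$coefficients[-1]
  V <- fit$vcov[-1, -1, drop = FALSE]
  z <- qnorm(1 - (1 - level) / 2)
  purrr::map_dfr(seq_along(fit$weeks), function(wi) {
    # contrast in the same (k,l) column order as build_cross_basis
    cvec <- as.numeric(t(outer(as.numeric(de), b$lag_basis[wi, ])))
    lo <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tibble::tibble(
      week = fit$weeks[wi], log_or = lo, se = se, or = exp(lo),
      conf.low = exp(lo - z * se), conf.high = exp(lo + z * se)
    )
  })
}
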