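#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy hb_logistic
#' @export
tidy.hb_logistic <- function(x, ...) or_table(x, ...)

#' @method glance hb_logistic
#' @export
glance.hb_logistic <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, nobs = x$n,
                 converged = x$converged)
}

#' @method tidy hb_ols
#' @export
tidy.hb_ols <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @method glance hb_ols
#' @export
glance.hb_ols <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, nobs = length(x$residuals))
}

#' @method tidy hb_lmm
#' @export
tidy.hb_lmm <- function(x, ...) x$fixef

#' @method glance hb_lmm
#' @export
glance.hb_lmm <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, sigma = x$sigma,
                 converged = x$converged, singular = x$singular)
}

#' @method tidy hb_two_stage
#' @export
tidy.hb_two_stage <- function(x, stage = 2, ...) {
  if (stage == 1) x$stage1_table else x$stage2_table
}

#' @method glance hb_two_stage
#' @export
glance.hb_two_stage <- function(x, ...) {
  tibble::tibble(n = x$n, stage1_logLik = x$stage1$loglik,
                 stage1_singular = x$stage1$singular)
}

#' @method tidy hb_dlnm
#' @export
tidy.hb_dlnm <- function(x, increment = 5, ...) {
  predict_or_curve(x, increment = increment)
}

#' @method glance hb_dlnm
#' @export
glance.hb_dlnm <- function(x, ...) {
  tibble::tibble(label = x$spec$label, dim = x$spec$dim, AIC = x$aic,
                 logLik = x$loglik, nobs = x$n, reference = x$reference)
}

#' @method tidy hb_gamm
#' @export
tidy.hb_gamm <- function(x, ...) x$edf

#' @method glance hb_gamm
#' @export
glance.hb_gamm <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, edf_difference = x$edf_difference,
                 k = x$k, n_subjects = x$n_subjects, n_visits = x$n_visits)
}

#' @method tidy hb_gbtm
#' @export
tidy.hb_gbtm <- function(x, ...) {
  co <- tibble::as_tibble(x$coefficients, rownames = "class")
  co$proportion <- x$pi
  co$modal_count <- x$modal_counts
  co
}

#' @method glance hb_gbtm
#' @export
glance.hb_gbtm <- function(x, ...) {
  tibble::tibble(K = x$K, degree = x$degree, logLik = x$loglik, BIC = x$bic,
                 AIC = x$aic, sigma = x$sigma, n = x$n_subjects)
}
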