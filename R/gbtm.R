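#' Group-based trajectory modeling of Hb over gestation
#'
#' Finite mixture of polynomial mean trajectories: each latent class k has a
#' polynomial mean curve in gestational age (degree 1 or 2) and subjects are
#' soft-assigned via posterior class probabilities. Fitting is by EM over
#' class responsibilities and weighted polynomial regressions, with a shared
#' residual SD, multi-start initialization (k-means on per-subject level and
#' slope features), and convergence when the relative log-likelihood change
#' falls below `tol`. Class labels are canonicalized by fitted mean Hb at
#' week 24, descending, so labelling is deterministic under subject
#' permutation and restart order.
#'
#' @param cohort An `hb_cohort`.
#' @param K Number of latent classes (>= 1).
#' @param degree Polynomial degree of the class curves (1 or 2).
#' @param n_restarts EM restarts (best likelihood kept).
#' @param seed Seed for the restart stream.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return Object of class `hb_gbtm`: `K`, `degree`, `coefficients`
#'   (K x (degree+1)), `pi`, `sigma`, `posterior` (subjects x K, rows sum to
#'   1), `loglik`, `bic`, `aic`, `modal_counts`, `subject_id`, `em`
#'   (iterations, restarts, empty-class restarts, log-likelihood trace).
#' @export
fit_gbtm <- function(cohort, K, degree = 2, n_restarts = 20, seed = 1,
                     max_iter = 500, tol = 1e-8) {
  stopifnot(inherits(cohort, "hb_cohort"), K >= 1, degree %in% 1:2)
  v <- cohort$visits
  ids <- sort(unique(v$subject_id))
  n <- length(ids)
  if (n < 10 * K) abort(sprintf("need at least %d subjects for K = %d classes", 10 * K, K))
  si <- match(v$subject_id, ids)
  X <- stats::poly(v$ga_weeks, degree = degree, raw = TRUE)
  X <- cbind(`(Intercept)` = 1, X)
  colnames(X) <- c("(Intercept)", paste0("ga^", seq_len(degree)))
  x <- v$hb_g_l
  nv <- length(x)

  # per-subject level/slope features for k-means initialization
  feat <- cbind(
    tapply(x, si, mean),
    tapply(seq_len(nv), si, function(ix) {
      o <- order(v$ga_weeks[ix])
      dt <- diff(range(v$ga_weeks[ix]))
      if (dt < 1e-8) 0 else (x[ix][o[length(o)]] - x[ix][o[1]]) / dt
    })
  )

  mstep <- function(R) {
    # R: n x K responsibilities
    W <- R[si, , drop = FALSE]
    beta <- matrix(0, K, ncol(X))
    for (k in seq_len(K)) {
      wk <- W[, k]
      f <- stats::lm.wfit(X, x, w = pmax(wk, 1e-12))
      beta[k, ] <- f$coefficients
    }
    mu <- X %*% t(beta)            # nv x K
    s2 <- sum(W * (x - mu)^2) / nv
    list(beta = beta, sigma = sqrt(s2), pi = colMeans(R), mu = mu)
  }
  estep <- function(beta, sigma, pi) {
    mu <- X %*% t(beta)
    lv <- dnorm(x, mu, sigma, log = TRUE)   # nv x K
    ls <- rowsum(lv, si)                    # n x K (subjects sorted by id)
    ls <- sweep(ls, 2, log(pi), "+")
    m <- apply(ls, 1, max)
    w <- exp(ls - m)
    den <- rowSums(w)
    list(R = w / den, loglik = sum(m + log(den)))
  }

  run_once <- function(rseed) {
    set.seed(rseed)
    if (K == 1) {
      R <- matrix(1, n, 1)
    } else {
      km <- tryCatch(
        stats::kmeans(scale(feat), centers = K, nstart = 1, iter.max = 30),
        error = function(e) NULL
      )
      cl <- if (is.null(km)) sample.int(K, n, replace = TRUE) else km$cluster
      R <- matrix(1e-3, n, K)
      R[cbind(seq_len(n), cl)] <- 1
      R <- R / rowSums(R)
    }
    trace <- numeric(0)
    ll_old <- -Inf
    empty_restart <- FALSE
    for (it in seq_len(max_iter)) {
      m <- mstep(R)
      if (any(m$pi < 1e-8)) return(list(ok = FALSE, empty = TRUE))
      e <- estep(m$beta, m$sigma, m$pi)
      trace <- c(trace, e$loglik)
      R <- e$R
      if (is.finite(ll_old) &&
          abs(e$loglik - ll_old) < tol * (abs(ll_old) + 1)) {
        ll_old <- e$loglik
        break
      }
      ll_old <- e$loglik
    }
    m <- mstep(R)
    e <- estep(m$beta, m$sigma, m$pi)
    list(ok = TRUE, empty = FALSE, beta = m$beta, sigma = m$sigma, pi = m$pi,
         R = e$R, loglik = e$loglik, iter = length(trace), trace = trace)
  }

  best <- NULL
  n_empty <- 0L
  for (r in seq_len(n_restarts)) {
    res <- run_once(seed + r - 1L)
    if (!res$ok) { n_empty <- n_empty + 1L; next }
    if (is.null(best) || res$loglik > best$loglik) {
      best <- res
      best$restart <- r
    }
    if (K == 1) break  # deterministic, no need for more starts
  }
  if (is.null(best)) abort("all EM restarts failed (empty classes throughout)")
  if (length(best$trace) > 1) {
    incr <- diff(best$trace)
    stopifnot("EM log-likelihood decreased" = all(incr > -1e-6 * (abs(best$trace[-1]) + 1)))
  }

  # canonical label order: fitted mean Hb at week 24, descending
  t24 <- vapply(0:degree, function(p) 24^p, numeric(1))
  mean24 <- as.numeric(best$beta %*% t24)
  ord <- order(mean24, decreasing = TRUE)
  beta <- best$beta[ord, , drop = FALSE]
  pi <- best$pi[ord]
  R <- best$R[, ord, drop = FALSE]
  rownames(beta) <- paste0("class", seq_len(K))
  colnames(beta) <- colnames(X)
  rownames(R) <- as.character(ids)

  p <- K * (degree + 1) + (K - 1) + 1
  loglik <- best$loglik
  modal <- max.col(R, ties.method = "first")
  structure(
    list(
      K = K, degree = degree, coefficients = beta, pi = pi,
      sigma = best$sigma, posterior = R, loglik = loglik,
      bic = -2 * loglik + p * log(n), aic = -2 * loglik + 2 * p,
      n_params = p, n_subjects = n, subject_id = ids,
      modal_counts = tabulate(modal, nbins = K),
      em = list(iterations = best$iter, best_restart = best$restart,
                empty_class_restarts = n_empty, loglik_trace = best$trace)
    ),
    class = "hb_gbtm"
  )
}

#' @export
print.hb_gbtm <- function(x, ...) {
  cat(sprintf("<hb_gbtm> K = %d classes, degree %d, n = %d subjects\n",
              x$K, x$degree, x$n_subjects))
  cat(sprintf("  log-likelihood %.2f, BIC %.2f\n", x$loglik, x$bic))
  cat("  mixing proportions:", paste(sprintf("%.3f", x$pi), collapse = ", "), "\n")
  invisible(x)
}

#' Select the trajectory model: polynomial degree, then number of classes
#'
#' The polynomial degree (linear vs quadratic) is chosen first on the
#' one-class model by BIC; the number of classes is then the smallest-BIC
#' model whose every modal class contains at least 5% of subjects. If no
#' candidate satisfies the floor, falls back to K = 1 with a warning.
#'
#' @param cohort An `hb_cohort`.
#' @param K_range Candidate class counts (default 1:7).
#' @param degrees Candidate polynomial degrees (default `c(1, 2)`).
#' @param membership_floor Minimum modal class share (default 0.05).
#' @param ... Passed to [fit_gbtm()] (restarts, seed, tolerances).
#' @return List: `fit` (selected `hb_gbtm`), `table` (selection tibble),
#'   `degree` (chosen degree).
#' @export
select_gbtm <- function(cohort, K_range = 1:7, degrees = c(1, 2),
                        membership_floor = 0.05, ...) {
  stopifnot(1 %in% K_range || length(K_range) > 0)
  deg_fits <- lapply(degrees, function(d) fit_gbtm(cohort, K = 1, degree = d, ...))
  degree <- degrees[which.min(vapply(deg_fits, function(f) f$bic, numeric(1)))]
  fits <- lapply(K_range, function(K) {
    tryCatch(fit_gbtm(cohort, K = K, degree = degree, ...),
             error = function(e) NULL)
  })
  tab <- purrr::map2_dfr(K_range, fits, function(K, f) {
    if (is.null(f)) {
      return(tibble::tibble(K = K, degree = degree, loglik = NA_real_,
                            bic = NA_real_, aic = NA_real_,
                            min_class_share = NA_real_, meets_floor = FALSE,
                            converged = FALSE))
    }
    share <- min(f$modal_counts) / f$n_subjects
    tibble::tibble(K = K, degree = degree, loglik = f$loglik, bic = f$bic,
                   aic = f$aic, min_class_share = share,
                   meets_floor = share >= membership_floor, converged = TRUE)
  })
  eligible <- which(tab$meets_floor & tab$converged)
  if (length(eligible) == 0) {
    warn("no class count satisfies the membership floor; falling back to K = 1")
    k1 <- which(K_range == 1)
    fit <- if (length(k1) == 1 && !is.null(fits[[k1]])) fits[[k1]] else
      fit_gbtm(cohort, K = 1, degree = degree, ...)
    return(list(fit = fit, table = tab, degree = degree))
  }
  best <- eligible[which.min(tab$bic[eligible])]
  list(fit = fits[[best]], table = tab, degree = degree)
}

#' Modal class assignment from posterior probabilities
#'
#' Assigns each subject to the class with the highest posterior probability;
#' exact ties go to the lower canonical label and are flagged. The average
#' maximum posterior is reported as a classification-quality diagnostic.
#'
#' @param fit An `hb_gbtm`.
#' @param quiet Suppress the diagnostic message.
#' @return Tibble: `subject_id`, `class`, `max_posterior`, `tie`.
#' @export
assign_groups <- function(fit, quiet = FALSE) {
  stopifnot(inherits(fit, "hb_gbtm"))
  R <- fit$posterior
  mx <- apply(R, 1, max)
  cls <- apply(R, 1, function(r) which(r >= max(r) - 1e-12)[1])
  tie <- apply(R, 1, function(r) sum(r >= max(r) - 1e-12) > 1)
  if (!quiet) {
    message(sprintf("average maximum posterior probability: %.3f", mean(mx)))
  }
  tibble::tibble(
    subject_id = fit$subject_id, class = as.integer(cls),
    max_posterior = unname(mx), tie = unname(tie)
  )
}

#' Logistic regression of an outcome on trajectory-class membership
#'
#' Modal mode regresses the outcome on class indicator variables with the
#' largest class as reference; posterior mode uses the K-1 posterior
#' probability columns (reference class dropped) as continuous predictors,
#' propagating assignment uncertainty. With degenerate hard (0/1) posteriors
#' the two modes coincide.
#'
#' @param fit An `hb_gbtm`.
#' @param outcome Binary vector aligned with `fit$subject_id` (NAs dropped).
#' @param mode `"modal"` or `"posterior"`.
#' @return An `hb_logistic`; odds ratios via [or_table()].
#' @export
fit_group_outcome <- function(fit, outcome, mode = c("modal", "posterior")) {
  stopifnot(inherits(fit, "hb_gbtm"))
  mode <- match.arg(mode)
  if (fit$K < 2) abort("outcome regression needs at least 2 classes")
  keep <- !is.na(outcome)
  ref <- which.max(fit$modal_counts)
  other <- setdiff(seq_len(fit$K), ref)
  if (mode == "modal") {
    cls <- assign_groups(fit, quiet = TRUE)$class
    if (length(unique(cls[keep])) < 2) abort("fewer than 2 classes represented")
    Xc <- sapply(other, function(k) as.numeric(cls == k))
  } else {
    Xc <- fit$posterior[, other, drop = FALSE]
  }
  Xc <- as.matrix(Xc)
  colnames(Xc) <- paste0("class", other)
  X <- cbind(`(Intercept)` = 1, Xc[keep, , drop = FALSE])
  labels <- setNames(
    c("baseline log-odds", rep(sprintf("vs class %d", ref), length(other))),
    c("(Intercept)", colnames(Xc))
  )
  fit_logistic(X, outcome[keep], scale_labels = labels)
}

#' Class mean curves over a gestational-age grid
#'
#' @param fit An `hb_gbtm`.
#' @param ga_grid Gestational ages in weeks.
#' @return Tibble: `class`, `ga_weeks`, `hb_mean`.
#' @export
gbtm_curves <- function(fit, ga_grid = seq(6, 40, by = 0.5)) {
  stopifnot(inherits(fit, "hb_gbtm"))
  Tm <- vapply(0:fit$degree, function(p) ga_grid^p, numeric(length(ga_grid)))
  mu <- Tm %*% t(fit$coefficients)
  purrr::map_dfr(seq_len(fit$K), function(k) {
    tibble::tibble(class = k, ga_weeks = ga_grid, hb_mean = mu[, k])
  })
}
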