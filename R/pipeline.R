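#' Run the five-method analysis pipeline on a cohort
#'
#' Preprocesses the cohort (within-trimester averaging, visit counts),
#' applies each requested method to its appropriate subset — the additive
#' mixed model to the full cohort, the other four to the subjects with one
#' measurement per trimester — and collects tidy result tables. A failing
#' method is recorded and skipped, never silently absorbed.
#'
#' @param cohort An `hb_cohort`.
#' @param methods Subset of `c("residual", "two_stage", "dlnm", "gamm",
#'   "gbtm")`.
#' @param outcomes Subset of `c("lbw", "ptb", "sga")`.
#' @param seed Seed recorded in the results and used by the GBTM restarts.
#' @param dlnm_specs Candidate cross-basis grid (default
#'   [default_cross_basis_grid()]).
#' @param gbtm_K_range Candidate class counts for GBTM selection.
#' @param gamm_k Basis-dimension cap for the additive model smooths.
#' @return List of class `hb_run`: per-method results, `log` (subset sizes,
#'   per-method timing and n), `errors`, `seed`.
#' @export
run_methods <- function(cohort,
                        methods = c("residual", "two_stage", "dlnm", "gamm", "gbtm"),
                        outcomes = c("lbw", "ptb", "sga"),
                        seed = 1L,
                        dlnm_specs = default_cross_basis_grid(),
                        gbtm_K_range = 1:7,
                        gamm_k = 5) {
  methods <- match.arg(methods, c("residual", "two_stage", "dlnm", "gamm", "gbtm"),
                       several.ok = TRUE)
  outcomes <- match.arg(outcomes, c("lbw", "ptb", "sga"), several.ok = TRUE)
  miss <- setdiff(outcomes, names(cohort$subjects))
  if (length(miss) > 0) {
    abort(paste0("requested outcome column(s) missing from cohort: ",
                 paste(miss, collapse = ", ")))
  }
  cohort <- collapse_within_trimester(cohort)
  need3 <- intersect(methods, c("residual", "two_stage", "dlnm", "gbtm"))
  cohort3 <- if (length(need3) > 0) subset_by_visit_count(cohort, 3, quiet = TRUE) else NULL
  log <- list(
    seed = seed,
    n_total = nrow(cohort$subjects),
    n_three_visit = if (is.null(cohort3)) NA_integer_ else nrow(cohort3$subjects),
    methods = list()
  )
  results <- list()
  errors <- list()
  run1 <- function(name, n_used, fun) {
    t0 <- proc.time()["elapsed"]
    out <- tryCatch(fun(), error = function(e) e)
    elapsed <- unname(proc.time()["elapsed"] - t0)
    if (inherits(out, "error")) {
      warn(sprintf("method `%s` failed: %s", name, conditionMessage(out)))
      errors[[name]] <<- conditionMessage(out)
    } else {
      results[[name]] <<- out
    }
    log$methods[[name]] <<- list(n = n_used, seconds = round(elapsed, 2))
  }
  if ("residual" %in% methods) {
    run1("residual", nrow(cohort3$subjects),
         function() run_residual_method(cohort3, outcomes))
  }
  if ("two_stage" %in% methods) {
    run1("two_stage", nrow(cohort3$subjects),
         function() run_two_stage(cohort3, outcomes))
  }
  if ("dlnm" %in% methods) {
    run1("dlnm", nrow(cohort3$subjects), function() {
      sel <- lapply(outcomes, function(oc) {
        select_model_aic(cohort3, oc, specs = dlnm_specs)
      })
      names(sel) <- outcomes
      curves <- purrr::map_dfr(outcomes, function(oc) {
        dplyr::mutate(predict_or_curve(sel[[oc]]$fit), outcome = oc, .before = 1)
      })
      list(selection = sel, or_curves = curves)
    })
  }
  if ("gamm" %in% methods) {
    run1("gamm", nrow(cohort$subjects),
         function() run_gamm_method(cohort, outcomes, k = gamm_k))
  }
  if ("gbtm" %in% methods) {
    run1("gbtm", nrow(cohort3$subjects), function() {
      sel <- select_gbtm(cohort3, K_range = gbtm_K_range, seed = seed)
      assignments <- assign_groups(sel$fit, quiet = TRUE)
      subj <- cohort3$subjects
      ors <- NULL
      if (sel$fit$K >= 2) {
        ors <- purrr::map_dfr(outcomes, function(oc) {
          y <- subj[[oc]][match(sel$fit$subject_id, subj$subject_id)]
          f <- tryCatch(fit_group_outcome(sel$fit, y, mode = "modal"),
                        error = function(e) NULL)
          if (is.null(f)) return(tibble::tibble())
          dplyr::mutate(or_table(f), outcome = oc, .before = 1)
        })
      }
      list(selection = sel, assignments = assignments, outcome_ors = ors)
    })
  }
  if (length(results) == 0 && length(errors) > 0) {
    abort(paste0("all requested methods failed: ",
                 paste(names(errors), collapse = ", ")))
  }
  structure(list(results = results, errors = errors, log = log, seed = seed),
            class = "hb_run")
}

#' @export
print.hb_run <- function(x, ...) {
  cat(sprintf("<hb_run> %d method(s) completed, %d failed\n",
              length(x$results), length(x$errors)))
  cat(sprintf("  cohort: %d subjects (%s with 3 visits)\n",
              x$log$n_total,
              ifelse(is.na(x$log$n_three_visit), "?", x$log$n_three_visit)))
  for (m in names(x$log$methods)) {
    cat(sprintf("  %-10s n = %-6d %6.2fs%s\n", m, x$log$methods[[m]]$n,
                x$log$methods[[m]]$seconds,
                if (m %in% names(x$errors)) "  FAILED" else ""))
  }
  invisible(x)
}

# reduce an hb_run to plain lists/tables for JSON serialization
.run_to_list <- function(run) {
  out <- list(seed = run$seed, log = run$log, errors = run$errors)
  r <- run$results
  if (!is.null(r$residual)) out$residual <- as.data.frame(r$residual)
  if (!is.null(r$two_stage)) {
    out$two_stage <- list(
      stage1 = as.data.frame(r$two_stage$stage1_table),
      stage2 = as.data.frame(r$two_stage$stage2_table)
    )
  }
  if (!is.null(r$dlnm)) {
    out$dlnm <- list(
      aic_tables = lapply(r$dlnm$selection, function(s) as.data.frame(s$table)),
      best = lapply(r$dlnm$selection, function(s) s$best_label),
      or_curves = as.data.frame(r$dlnm$or_curves)
    )
  }
  if (!is.null(r$gamm)) {
    out$gamm <- list(
      edf = as.data.frame(r$gamm$edf),
      trajectories = as.data.frame(r$gamm$trajectories)
    )
  }
  if (!is.null(r$gbtm)) {
    out$gbtm <- list(
      selection = as.data.frame(r$gbtm$selection$table),
      K = r$gbtm$selection$fit$K,
      degree = r$gbtm$selection$fit$degree,
      proportions = r$gbtm$selection$fit$pi,
      coefficients = as.data.frame(tidy(r$gbtm$selection$fit)),
      outcome_ors = if (!is.null(r$gbtm$outcome_ors)) as.data.frame(r$gbtm$outcome_ors)
    )
  }
  out
}

#' Write pipeline results to a JSON file
#'
#' Serializes the tidy result tables of an [run_methods()] run, embedding the
#' seed and a hash of the content so reruns can be compared.
#'
#' @param run An `hb_run`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(run, path) {
  stopifnot(inherits(run, "hb_run"))
  payload <- .run_to_list(run)
  stable <- payload
  stable$log$methods <- lapply(stable$log$methods, function(m) m["n"])
  payload$content_hash <- rlang::hash(stable)  # timing-independent
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
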