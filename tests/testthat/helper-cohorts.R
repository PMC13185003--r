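# small deterministic fixtures used across test files

# a hand-built cohort: 3 subjects, one visit per trimester, integer weeks
tiny_three_visit_cohort <- function(hb = NULL) {
  if (is.null(hb)) hb <- c(120, 110, 113, 125, 115, 118, 115, 106, 108)
  visits <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 3),
    ga_weeks = rep(c(10, 24, 32), 3),
    hb_g_l = hb
  )
  subjects <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    lbw = c(0L, 1L, 0L), ptb = c(0L, 0L, 1L), sga = c(1L, 0L, 0L)
  )
  hb_cohort(visits, subjects)
}

# simulated three-visit cohort of n subjects (defaults, all three visits)
sim_three_visit <- function(n = 200, seed = 11, ...) {
  coh <- simulate_cohort(sim_config(n_subjects = n, prop_three_visits = 1,
                                    seed = seed, ...))
  subset_by_visit_count(collapse_within_trimester(coh), 3, quiet = TRUE)
}
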