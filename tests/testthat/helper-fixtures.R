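# Shared fixtures, all built in code.

toy_ref <- synthetic_growth_reference()

# Constant-LMS reference: interpolation returns exactly (L, M, S) at any age.
flat_ref <- function(L, M, S) {
  data.frame(sex = rep(c("female", "male"), each = 2),
             age_months = rep(c(24, 240), 2), L = L, M = M, S = S)
}

# Records drawn from a known truth, classified and ready for fitting.
fitted_synthetic <- function(n = 4000, scenario = "early_peak", seed = 1,
                             cycles = "c1", weight_sd = 0.4, ...) {
  tr <- make_truth(scenario)
  des <- survey_design_spec(n = n, weight_sd = weight_sd, cycles = cycles)
  rec <- if (length(cycles) > 1) sample_cycles(tr, des, seed = seed) else
    sample_cross_section(tr, des, cycle = cycles, seed = seed)
  cls <- combine_cycles(assign_categories(apply_exclusions(rec)$eligible, toy_ref))
  list(truth = tr, records = cls)
}

# Random probability 3-vectors (flat Dirichlet).
rprob3 <- function(n) {
  g <- matrix(stats::rexp(3 * n), n, 3)
  g / rowSums(g)
}

expect_tables_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$net_prob, b$net_prob, tolerance = tol)
  expect_identical(a$boundary, b$boundary)
  expect_identical(a$direction, b$direction)
}
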