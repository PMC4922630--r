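worked_example_records <- function() {
  # 100 normal-weight 18-year-olds, 10 moving up by 19; 50 overweight,
  # 3 moving down
  k18 <- c(rep(1L, 100), rep(2L, 50))
  k19 <- c(rep(2L, 10), rep(1L, 90), rep(1L, 3), rep(2L, 47))
  data.frame(id = rep(sprintf("p%03d", 1:150), each = 2),
             age = rep(c(18L, 19L), 150),
             k = as.vector(rbind(k18, k19)))
}

test_that("the longitudinal worked example yields exactly 7%", {
  emp <- empirical_net_from_longitudinal(worked_example_records(), 18)
  up <- emp[emp$boundary == "normal_overweight" & emp$direction == "up", ]
  expect_equal(up$net_flow, 7)
  expect_equal(up$n_origin, 100)
  expect_equal(up$net_prob, 0.07, tolerance = 1e-15)
  down <- emp[emp$boundary == "normal_overweight" & emp$direction == "down", ]
  expect_equal(down$net_prob, 0)
})

test_that("empirical nets agree with a hand count including a two-step move", {
  rec <- data.frame(
    id = rep(c("a", "b", "c", "d"), each = 2),
    age = rep(c(30L, 31L), 4),
    k = c(1L, 3L,   # a: normal -> obese, crosses both boundaries
          2L, 1L,   # b: overweight -> normal
          2L, 2L,   # c: static
          3L, 3L))  # d: static
  emp <- empirical_net_from_longitudinal(rec, 30)
  b1 <- emp[emp$boundary == "normal_overweight", ]
  expect_equal(b1$n_cross[b1$direction == "up"], 1)
  expect_equal(b1$n_cross[b1$direction == "down"], 1)
  expect_equal(b1$net_prob, c(0, 0))  # net zero at boundary 1
  b2u <- emp[emp$boundary == "overweight_obese" & emp$direction == "up", ]
  expect_equal(b2u$net_flow, 1)
  expect_equal(b2u$n_origin, 2)  # overweight at age 30: b and c
  expect_equal(b2u$net_prob, 0.5)
})

test_that("static trajectories give all-zero nets and unpaired ages give NA", {
  rec <- data.frame(id = rep(c("a", "b"), each = 3),
                    age = rep(40:42, 2), k = c(1L, 1L, 1L, 3L, 3L, 3L))
  emp <- empirical_net_from_longitudinal(rec, 40)
  expect_equal(emp$net_prob, rep(0, 4))
  none <- empirical_net_from_longitudinal(rec, 70)
  expect_true(all(is.na(none$net_prob)))
})

test_that("empirical nets from simulated Markov trajectories match the truth", {
  tr <- make_truth("early_peak")
  traj <- simulate_trajectories(tr, n = 40000, visits = 2, seed = 77)
  for (a in c(5, 25, 60)) {
    emp <- empirical_net_from_longitudinal(traj, a)
    true_rows <- tr$net[tr$net$age == a, ]
    for (r in seq_len(nrow(emp))) {
      tru <- true_rows$net_prob[true_rows$boundary == emp$boundary[r] &
                                  true_rows$direction == emp$direction[r]]
      if (is.na(emp$net_prob[r]) || emp$n_origin[r] == 0) next
      se <- sqrt(max(tru * (1 - tru), 0.25 / emp$n_origin[r]) / emp$n_origin[r])
      expect_lt(abs(emp$net_prob[r] - tru), 3 * se + 0.02)
    }
  }
})

test_that("valid cost candidates tie and the first wins; invalid ones are flagged", {
  fx <- fitted_synthetic(n = 3000, seed = 13)
  cv <- fit_prevalence(fx$records)
  traj <- simulate_trajectories(fx$truth, n = 3000, visits = 2, seed = 14)
  nets <- do.call(rbind, lapply(c(10, 30, 50),
                                function(a) empirical_net_from_longitudinal(traj, a)))
  res <- calibrate_costs(nets, cv,
                         grid = data.frame(c1 = c(1, 6, 10, 6),
                                           c2 = c(3, 17, 25, 11)))
  expect_equal(res$profile$valid, c(TRUE, TRUE, TRUE, FALSE))
  mse <- res$profile$mse[res$profile$valid]
  expect_lt(max(mse) - min(mse), 1e-9)   # flat profile among valid candidates
  expect_equal(res$selected, 1)          # tie-break: first in grid order
  expect_true(is.na(res$profile$mse[4])) # invalid candidate never fitted
  expect_error(calibrate_costs(nets, cv, grid = data.frame(c1 = 6, c2 = 11)),
               "no valid")
})

test_that("horizon zero predicts the earlier cycle itself and is stable", {
  fx <- fitted_synthetic(n = 2000, seed = 15)
  cv <- fit_prevalence(fx$records)
  rep0 <- validate_stability(cv, cv, horizon = 0, se_replicates = 50, seed = 1)
  expect_true(rep0$stable)
  expect_equal(rep0$max_abs_discrepancy, 0, tolerance = 1e-12)
  expect_equal(rep0$per_cycle[[1]]$predicted, rep0$per_cycle[[1]]$observed)
})

test_that("stability is confirmed under a shared regime and rejected under drift", {
  tr <- make_truth("early_peak")
  des <- survey_design_spec(n = 2500, weight_sd = 0.4)
  fit1 <- function(rec) {
    fit_prevalence(combine_cycles(assign_categories(apply_exclusions(rec)$eligible,
                                                    toy_ref)))
  }
  early <- fit1(sample_cross_section(tr, des, cycle = "c1", seed = 501))
  same <- fit1(sample_cross_section(tr, des, cycle = "c2", seed = 502))
  shifted_truth <- make_truth("early_peak", drift = 0.5)
  shifted <- fit1(sample_cross_section(shifted_truth, des, cycle = "c2", seed = 503))
  rep_null <- validate_stability(early, same, horizon = 2,
                                 se_replicates = 150, seed = 7)
  rep_alt <- validate_stability(early, shifted, horizon = 2,
                                se_replicates = 150, seed = 7)
  expect_true(rep_null$stable)
  expect_false(rep_alt$stable)
  expect_gt(rep_alt$chi2_ratio, rep_null$chi2_ratio)
  expect_true(all(abs(rep_null$per_cycle[[1]]$discrepancy) <= 1))
})

test_that("stability checking demands a matching age grid", {
  fx <- fitted_synthetic(n = 1500, seed = 16)
  cv <- fit_prevalence(fx$records)
  cv2 <- fit_prevalence(fx$records[fx$records$age <= 60, ],
                        spec = prevalence_spec(age_range = c(2, 60)))
  expect_error(validate_stability(cv, cv2, horizon = 2, se_replicates = 20),
               "grid")
})
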