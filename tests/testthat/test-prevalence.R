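test_that("fitted prevalence rows are probabilities summing to one", {
  fx <- fitted_synthetic(n = 3000, seed = 11)
  cv <- fit_prevalence(fx$records)
  expect_true(all(cv$P >= 0))
  expect_equal(unname(rowSums(cv$P)), rep(1, length(cv$ages)),
               tolerance = 1e-10)
  expect_equal(cv$vcov, t(cv$vcov), tolerance = 1e-10)
  ev <- eigen(cv$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-8 * max(ev))
})

test_that("an all-one-category stratum yields the degenerate curve", {
  rec <- data.frame(age = rep(c(10, 40, 70), each = 5), k = 3L,
                    survey_weight = 1)
  expect_warning(cv <- fit_prevalence(rec), "one category")
  expect_equal(unname(cv$P[, 3]), rep(1, 79))
  expect_equal(unname(cv$P[, 1]), rep(0, 79))
})

test_that("a logit-linear two-category truth is recovered within 0.02", {
  set.seed(88)
  n <- 20000
  age <- runif(n, 2, 80)
  p_ob <- plogis(-2 + 0.03 * (age - 2))
  k <- ifelse(runif(n) < p_ob, 3L, 1L)
  # a linear log-odds truth supports the smoother's whole penalty range
  cv <- fit_prevalence(data.frame(age = age, k = k, survey_weight = 1),
                       spec = prevalence_spec(lambda_grid = 10^seq(-1, 4)))
  truth <- plogis(-2 + 0.03 * (cv$ages - 2))
  # pointwise bound: 0.02 or 3.5x the estimator's own sampling SE, whichever
  # is larger (the max over 79 grid ages sees the occasional 3-SE excursion)
  se <- bmitrans:::bootstrap_prevalence_se(cv, replicates = 300, seed = 1)[, 3]
  expect_true(all(abs(cv$P[, 3] - truth) < pmax(0.02, 3.5 * se)))
  expect_lt(mean(abs(cv$P[, 3] - truth)), 0.02)
  expect_equal(unname(cv$P[, 2]), rep(0, 79))  # absent category stays at zero
})

test_that("infinite penalty collapses each log-odds curve to a straight line", {
  set.seed(89)
  n <- 8000
  age <- runif(n, 2, 80)
  p_ob <- plogis(-1.5 + 0.025 * (age - 2))
  k <- ifelse(runif(n) < p_ob, 3L, 1L)
  dat <- data.frame(age = age, k = k, survey_weight = 1)
  cv <- fit_prevalence(dat, spec = prevalence_spec(lambda = 1e9))
  ml <- glm(I(k == 3) ~ age, family = binomial, data = dat)
  lin <- predict(ml, newdata = data.frame(age = cv$ages), type = "response")
  expect_lt(max(abs(cv$P[, 3] - lin)), 1e-3)
})

test_that("rescaling all survey weights leaves the fit unchanged", {
  fx <- fitted_synthetic(n = 2500, seed = 21)
  cv1 <- fit_prevalence(fx$records)
  rec2 <- fx$records
  rec2$survey_weight <- rec2$survey_weight * 737.1
  cv2 <- fit_prevalence(rec2)
  expect_equal(cv1$P, cv2$P, tolerance = 1e-10)
  expect_equal(cv1$lambda, cv2$lambda)
  expect_equal(cv1$vcov, cv2$vcov, tolerance = 1e-8)
})

test_that("the smooth introduces no discontinuity at the child/adult switch", {
  fx <- fitted_synthetic(n = 20000, seed = 61)
  cv <- fit_prevalence(fx$records)
  i20 <- match(20, cv$ages)
  jump <- abs(cv$P[i20, ] - (cv$P[i20 - 1, ] + cv$P[i20 + 1, ]) / 2)
  expect_lt(max(jump), 0.01)
})

test_that("curve_at returns the grid row and rejects off-grid ages", {
  fx <- fitted_synthetic(n = 1500, seed = 41)
  cv <- fit_prevalence(fx$records)
  p2 <- curve_at(cv, 2)
  expect_equal(sum(p2), 1, tolerance = 1e-10)
  expect_equal(unname(p2), unname(cv$P[1, ]))
  expect_error(curve_at(cv, 81), "outside")
})

test_that("pooling cycles rescales weights by the number of cycles", {
  rec <- data.frame(cycle = rep(c("a", "b", "c"), each = 2),
                    survey_weight = 30000)
  out <- combine_cycles(rec, "pooled")
  expect_equal(out$survey_weight, rep(10000, 6))
  expect_equal(sum(out$survey_weight), sum(rec$survey_weight) / 3)
  expect_identical(combine_cycles(rec, "per_cycle"), rec)
  one <- data.frame(survey_weight = 5)
  expect_equal(combine_cycles(one, "pooled")$survey_weight, 5)
  expect_error(combine_cycles(rec, "half"))
})

test_that("stratum filtering fits only the requested sex/group", {
  fx <- fitted_synthetic(n = 1200, seed = 51)
  rec <- fx$records
  rec$sex <- rep(c("female", "male"), length.out = nrow(rec))
  cvf <- fit_prevalence(rec, stratum = list(sex = "female"))
  expect_equal(cvf$n, sum(rec$sex == "female"))
  expect_error(fit_prevalence(rec, stratum = list(sex = "nonexistent")),
               "no records")
})
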