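test_that("adult BMI cut-points use half-open intervals and fold underweight into normal", {
  got <- classify_adult(c(17, 24.999, 25, 29.99, 30, 45))
  expect_equal(as.character(got),
               c("normal", "normal", "overweight", "overweight", "obese", "obese"))
  expect_true(is.ordered(got))
  expect_error(classify_adult(-1), "absurd|nonpositive")
  expect_error(classify_adult(200), "absurd|nonpositive")
})

test_that("child percentile classes include both the 85th and 95th in overweight", {
  got <- classify_child(c(50, 84.99, 85, 95, 95.01))
  expect_equal(as.character(got),
               c("normal", "normal", "overweight", "overweight", "obese"))
  expect_error(classify_child(101), "percentile")
  expect_error(classify_child(-0.1), "percentile")
})

test_that("classification is monotone in BMI and percentile", {
  bmi <- sort(runif(200, 10, 60))
  expect_true(!is.unsorted(classify_adult(bmi)))
  pct <- sort(runif(200, 0, 100))
  expect_true(!is.unsorted(classify_child(pct)))
})

test_that("LMS percentile matches hand-computed values on both branches", {
  # z = ((20/16)^-2 - 1) / (-2 * 0.1) = 1.8
  ref <- flat_ref(L = -2, M = 16, S = 0.1)
  expect_equal(percentile_from_lms(20, "female", 120, ref),
               100 * pnorm(1.8), tolerance = 1e-12)
  # bmi at the median is the 50th percentile regardless of L
  expect_equal(percentile_from_lms(16, "male", 60, ref), 50, tolerance = 1e-12)
  # log branch: L = 0, bmi = M * exp(S) gives z = 1
  ref0 <- flat_ref(L = 0, M = 20, S = 0.08)
  expect_equal(percentile_from_lms(20 * exp(0.08), "female", 100, ref0),
               100 * pnorm(1), tolerance = 1e-10)
  expect_error(percentile_from_lms(18, "female", 12, ref), "span")
})

test_that("LMS percentile is strictly increasing in BMI and inverts exactly", {
  bmi <- seq(14, 35, by = 0.5)
  pct <- percentile_from_lms(bmi, "male", 90, toy_ref)
  expect_true(all(diff(pct) > 0))
  back <- bmi_from_percentile(pct, "male", 90, toy_ref)
  expect_equal(back, bmi, tolerance = 1e-8)
})

test_that("exclusions remove flagged and incomplete records with one reason each", {
  rec <- data.frame(
    id = paste0("r", 1:7),
    age = c(40, 30, 1, 25, 50, 85, 10),
    sex = "female", group = "GroupA",
    bmi = c(22, 28, 15, NA, 31, 24, NA),
    weight_kg = c(NA, NA, NA, NA, 31 * 1.6^2, NA, NA),
    height_m = c(NA, NA, NA, NA, 1.6, NA, NA),
    survey_weight = 1,
    pregnant_or_recent = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    amputation = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  out <- apply_exclusions(rec)
  expect_setequal(out$eligible$id, c("r1", "r5"))
  expect_equal(out$log$pregnancy, 1)
  expect_equal(out$log$`age<2`, 1)
  expect_equal(out$log$`age>80`, 1)
  expect_equal(out$log$missing_bmi, 2)
  expect_equal(out$log$n_eligible, 2)
  # every record either keeps a category path or gets exactly one reason
  expect_equal(out$log$n_input,
               out$log$n_eligible + out$log$pregnancy + out$log$`age<2` +
                 out$log$`age>80` + out$log$missing_bmi)
})

test_that("bmi column must agree with weight/height when all present", {
  rec <- data.frame(id = "x", age = 40, sex = "f", group = "g",
                    bmi = 30, weight_kg = 60, height_m = 1.7,
                    survey_weight = 1)
  expect_error(apply_exclusions(rec), "disagrees")
})

test_that("category assignment switches from percentile to BMI rules at age 20", {
  ref <- flat_ref(L = 0, M = 20, S = 0.1)
  rec <- data.frame(
    id = c("child", "adult"), age = c(10, 20), sex = "female", group = "g",
    bmi = c(26, 26), survey_weight = 1)
  out <- assign_categories(rec, ref)
  # child: z = log(26/20)/0.1 = 2.62 -> >95th percentile -> obese
  expect_equal(as.character(out$category), c("obese", "overweight"))
  # children without percentile need a reference
  expect_error(assign_categories(rec[1, , drop = FALSE], NULL),
               "growth reference")
})

test_that("record reader handles CSV and enforces positive weights", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,age,sex,group,bmi,survey_weight",
               "a,30,female,G,24,2.5"), f)
  rec <- read_records(f)
  expect_equal(rec$bmi, 24)
  writeLines(c("id,age,sex,group,bmi,survey_weight",
               "a,30,female,G,24,0"), f)
  expect_error(read_records(f), "positive")
})
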