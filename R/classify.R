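#' Classify adult BMI into the three ordered weight categories
#'
#' Adults (age >= 20) are classified on standard BMI cut-points: normal
#' weight below 25 kg/m^2, overweight 25 to below 30 kg/m^2, obese 30 kg/m^2
#' and above. Underweight (BMI < 18.5) is folded into normal weight: the
#' analysis is a three-state model and underweight is rare (well under 1%
#' in the populations this method targets); the fold is logged by
#' [apply_exclusions()] rather than dropped.
#'
#' @param bmi Numeric vector of BMI values in kg/m^2. Must be positive and
#'   at most 150; values outside that range are rejected with an error.
#' @return An ordered factor with levels `normal < overweight < obese`.
#' @examples
#' classify_adult(c(17, 24.999, 25, 29.99, 30))
#' @export
classify_adult <- function(bmi) {
  stopifnot(is.numeric(bmi))
  bad <- !is.na(bmi) & (bmi <= 0 | bmi > 150)
  if (any(bad)) {
    stop("nonpositive or absurd BMI (must be in (0, 150]) at position(s): ",
         paste(which(bad), collapse = ", "))
  }
  cut_to_category(ifelse(is.na(bmi), NA_real_, bmi),
                  lower = 25, upper = 30, upper_inclusive = FALSE)
}

#' Classify a child BMI percentile into the three ordered weight categories
#'
#' Children and adolescents (ages 2-19) are classified on the percentile of
#' BMI relative to a sex- and age-specific growth reference: normal weight
#' below the 85th percentile, overweight from the 85th through the 95th
#' percentile (both boundaries inclusive), obese strictly above the 95th.
#'
#' @param percentile Numeric vector of BMI percentiles in `[0, 100]`.
#' @return An ordered factor with levels `normal < overweight < obese`.
#' @examples
#' classify_child(c(50, 84.99, 85, 95, 95.01))
#' @export
classify_child <- function(percentile) {
  stopifnot(is.numeric(percentile))
  bad <- !is.na(percentile) & (percentile < 0 | percentile > 100)
  if (any(bad)) {
    stop("percentile outside [0, 100] at position(s): ",
         paste(which(bad), collapse = ", "))
  }
  cut_to_category(percentile, lower = 85, upper = 95, upper_inclusive = TRUE)
}

# Shared three-bin cut. upper_inclusive distinguishes the adult convention
# (30 is obese) from the child convention (95th is still overweight).
cut_to_category <- function(x, lower, upper, upper_inclusive) {
  k <- ifelse(x < lower, 1L, ifelse(
    if (upper_inclusive) x <= upper else x < upper, 2L, 3L))
  weight_category(k)
}

#' Construct the ordered weight-category factor
#'
#' @param k Integer codes 1 (normal), 2 (overweight), 3 (obese), or the
#'   corresponding category names.
#' @return Ordered factor `normal < overweight < obese`.
#' @export
weight_category <- function(k) {
  lev <- c("normal", "overweight", "obese")
  if (is.character(k) || is.factor(k)) {
    k <- match(as.character(k), lev)
  }
  factor(lev[as.integer(k)], levels = lev, ordered = TRUE)
}

#' Read an LMS growth reference table
#'
#' The reference is a CSV with columns `sex`, `age_months`, `L`, `M`, `S`
#' (the CDC growth-chart layout: Box-Cox power, median BMI and coefficient
#' of variation by sex and age in months). It is an input file, not bundled
#' truth; a synthetic reference for testing is available from
#' [synthetic_growth_reference()].
#'
#' @param path Path to the CSV file.
#' @return A data frame validated against the LMS invariants (positive M
#'   and S, strictly increasing age within sex).
#' @export
read_growth_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_growth_reference(ref)
}

validate_growth_reference <- function(ref) {
  need <- c("sex", "age_months", "L", "M", "S")
  miss <- setdiff(need, names(ref))
  if (length(miss)) stop("growth reference missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(ref$M <= 0) || any(ref$S <= 0)) stop("growth reference requires M > 0 and S > 0")
  for (s in unique(ref$sex)) {
    a <- ref$age_months[ref$sex == s]
    if (any(diff(a) <= 0)) stop("age_months must be strictly increasing within sex ", s)
  }
  ref
}

# Interpolate L, M, S at age_months for one sex; errors outside the span.
lms_at <- function(sex, age_months, ref) {
  sub <- ref[ref$sex == sex, ]
  if (!nrow(sub)) stop("growth reference has no rows for sex '", sex, "'")
  rng <- range(sub$age_months)
  out <- age_months < rng[1] | age_months > rng[2]
  if (any(out)) {
    stop("age ", paste(age_months[out], collapse = ", "),
         " months outside the reference span [", rng[1], ", ", rng[2], "]")
  }
  list(L = stats::approx(sub$age_months, sub$L, age_months)$y,
       M = stats::approx(sub$age_months, sub$M, age_months)$y,
       S = stats::approx(sub$age_months, sub$S, age_months)$y)
}

#' BMI percentile of a child from an LMS growth reference
#'
#' Computes the LMS z-score, `z = ((bmi/M)^L - 1) / (L * S)` when `L != 0`
#' and `z = log(bmi/M) / S` when `L = 0`, with L, M, S linearly interpolated
#' to the requested age in months, and returns `100 * pnorm(z)`.
#'
#' @param bmi Numeric vector of BMI values (kg/m^2).
#' @param sex Sex label(s) matching the reference's `sex` column.
#' @param age_months Age(s) in months; must lie within the reference span
#'   (at least 24-240 months for the bundled synthetic reference).
#' @param ref Growth reference data frame (see [read_growth_reference()]).
#' @return Numeric vector of percentiles in `[0, 100]`.
#' @export
percentile_from_lms <- function(bmi, sex, age_months, ref) {
  n <- max(length(bmi), length(sex), length(age_months))
  bmi <- rep_len(bmi, n); sex <- rep_len(sex, n)
  age_months <- rep_len(age_months, n)
  z <- numeric(n)
  for (s in unique(sex)) {
    i <- which(sex == s)
    par <- lms_at(s, age_months[i], ref)
    z[i] <- lms_z(bmi[i], par$L, par$M, par$S)
  }
  100 * stats::pnorm(z)
}

lms_z <- function(bmi, L, M, S) {
  ifelse(abs(L) < 1e-12,
         log(bmi / M) / S,
         ((bmi / M)^L - 1) / (L * S))
}

#' Invert the LMS transform: BMI at a given percentile
#'
#' Used by the synthetic cohort simulator to emit child BMI values that
#' round-trip through [percentile_from_lms()] and [classify_child()].
#'
#' @inheritParams percentile_from_lms
#' @param percentile Percentile(s) in (0, 100).
#' @return Numeric BMI values.
#' @export
bmi_from_percentile <- function(percentile, sex, age_months, ref) {
  n <- max(length(percentile), length(sex), length(age_months))
  percentile <- rep_len(percentile, n); sex <- rep_len(sex, n)
  age_months <- rep_len(age_months, n)
  z <- stats::qnorm(percentile / 100)
  out <- numeric(n)
  for (s in unique(sex)) {
    i <- which(sex == s)
    par <- lms_at(s, age_months[i], ref)
    out[i] <- ifelse(abs(par$L) < 1e-12,
                     par$M * exp(par$S * z[i]),
                     par$M * (1 + par$L * par$S * z[i])^(1 / par$L))
  }
  out
}

#' Apply the eligibility filters to individual records
#'
#' Removes records that are pregnant or recently pregnant, have a limb
#' amputation, are under 2 years of age, or lack the variables needed to
#' compute BMI (neither a BMI value nor both weight and height). Each
#' removal is logged with a single reason; reasons are checked in the order
#' pregnancy, amputation, age, missing BMI, so a record failing several
#' filters is counted once under the first.
#'
#' @param records Data frame of individual records (see [read_records()] for
#'   the schema).
#' @return A list with `eligible` (the retained rows, with a `bmi` column
#'   filled in from weight/height where absent) and `log` (a named list of
#'   exclusion counts by reason, plus `n_input`, `n_eligible` and the count
#'   of underweight adults folded into normal weight downstream).
#' @export
apply_exclusions <- function(records) {
  records <- as.data.frame(records)
  n0 <- nrow(records)
  flag <- function(col, default = FALSE) {
    if (col %in% names(records)) {
      v <- records[[col]]
      if (is.character(v)) v <- tolower(v) %in% c("true", "1", "yes")
      v[is.na(v)] <- default
      as.logical(v)
    } else rep(default, n0)
  }
  bmi <- derive_bmi(records)
  reason <- rep(NA_character_, n0)
  take <- function(cond, lab) reason <<- ifelse(is.na(reason) & cond, lab, reason)
  take(flag("pregnant_or_recent"), "pregnancy")
  take(flag("amputation"), "amputation")
  age <- records$age
  take(is.na(age) | age < 2, "age<2")
  take(age > 80, "age>80")
  take(is.na(bmi), "missing_bmi")

  eligible <- records[is.na(reason), , drop = FALSE]
  eligible$bmi <- bmi[is.na(reason)]
  log <- as.list(table(reason[!is.na(reason)]))
  log$n_input <- n0
  log$n_eligible <- nrow(eligible)
  log$underweight_folded <- sum(eligible$age >= 20 & eligible$bmi < 18.5,
                                na.rm = TRUE)
  if (!nrow(eligible)) warning("no eligible records remain after exclusions")
  list(eligible = eligible, log = log)
}

# BMI from the bmi column where present, else weight/height^2; checks the
# two agree to 1e-6 when all three are present.
derive_bmi <- function(records) {
  n <- nrow(records)
  bmi <- if ("bmi" %in% names(records)) as.numeric(records$bmi) else rep(NA_real_, n)
  if (all(c("weight_kg", "height_m") %in% names(records))) {
    calc <- as.numeric(records$weight_kg) / as.numeric(records$height_m)^2
    both <- !is.na(bmi) & !is.na(calc)
    off <- both & abs(bmi - calc) > 1e-6 * pmax(1, calc)
    if (any(off)) {
      ids <- if ("id" %in% names(records)) records$id[off] else which(off)
      stop("bmi column disagrees with weight/height^2 for record(s): ",
           paste(utils::head(ids, 5), collapse = ", "))
    }
    bmi[is.na(bmi)] <- calc[is.na(bmi)]
  }
  bmi
}

#' Assign weight categories to eligible records
#'
#' Adults (age >= 20) are classified from BMI via [classify_adult()];
#' children (ages 2-19) from the BMI percentile via [percentile_from_lms()]
#' and [classify_child()]. When a `bmi_percentile` column is already present
#' for a child it is used directly; otherwise a growth reference must be
#' supplied. Age in months for children is taken as `12 * age + 6` (midpoint
#' convention) unless an `age_months` column is present.
#'
#' @param records Eligible records from [apply_exclusions()].
#' @param growth_ref Growth reference data frame, required if any child rows
#'   lack `bmi_percentile`.
#' @param adult_age Age (years) at which the adult cut-points take over;
#'   default 20.
#' @return The records with added columns `bmi_percentile` (children) and
#'   `category` (ordered factor).
#' @export
assign_categories <- function(records, growth_ref = NULL, adult_age = 20) {
  records <- as.data.frame(records)
  if (!nrow(records)) {
    records$category <- weight_category(integer(0))
    return(records)
  }
  bmi <- derive_bmi(records)
  is_adult <- records$age >= adult_age
  cat <- weight_category(rep(NA_integer_, nrow(records)))
  if (any(is_adult)) cat[is_adult] <- classify_adult(bmi[is_adult])
  if (any(!is_adult)) {
    pct <- if ("bmi_percentile" %in% names(records)) {
      as.numeric(records$bmi_percentile)
    } else rep(NA_real_, nrow(records))
    need <- !is_adult & is.na(pct)
    if (any(need)) {
      if (is.null(growth_ref)) {
        stop("growth reference required: ", sum(need),
             " child record(s) lack bmi_percentile")
      }
      months <- if ("age_months" %in% names(records)) {
        as.numeric(records$age_months[need])
      } else 12 * records$age[need] + 6
      pct[need] <- percentile_from_lms(bmi[need], records$sex[need],
                                       months, growth_ref)
    }
    cat[!is_adult] <- classify_child(pct[!is_adult])
    records$bmi_percentile <- pct
  }
  records$bmi <- bmi
  records$category <- cat
  records
}

#' Read individual records from a delimited text file
#'
#' Expected columns: `id`, `age` (integer years, 2-80; ages above 80 must
#' have been collapsed to 80 upstream), `sex`, `group`, and at least one of
#' `bmi` or the pair `weight_kg`/`height_m`. Optional: `bmi_percentile`,
#' `survey_weight` (defaults to 1), `stratum`, `psu`, `cycle`,
#' `pregnant_or_recent`, `amputation`.
#'
#' @param path CSV or TSV path (delimiter inferred from the extension).
#' @return Data frame of records.
#' @export
read_records <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  rec <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!"survey_weight" %in% names(rec)) rec$survey_weight <- 1
  if (any(rec$survey_weight <= 0, na.rm = TRUE)) {
    stop("survey_weight must be positive")
  }
  rec
}
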