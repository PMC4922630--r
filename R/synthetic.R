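#' Synthetic LMS growth reference
#'
#' A smooth, internally consistent LMS table (Box-Cox power L, median BMI M,
#' coefficient of variation S) spanning 24-240 months for both sexes. It is
#' a synthetic stand-in with the same file layout and qualitative shape as a
#' real growth reference (median BMI dipping through mid-childhood then
#' rising into adolescence); it is not a published reference and carries no
#' population meaning.
#'
#' @param by Spacing of the age grid in months (default 6).
#' @return Data frame with columns `sex`, `age_months`, `L`, `M`, `S`.
#' @export
synthetic_growth_reference <- function(by = 6) {
  months <- seq(24, 240, by = by)
  one <- function(sex, m_shift) {
    t <- (months - 24) / 216
    M <- 16.5 - 1.2 * exp(-((months - 60) / 30)^2) + 5.5 * t^1.6 + m_shift
    L <- -1.8 + 0.8 * t
    S <- 0.085 + 0.05 * t
    data.frame(sex = sex, age_months = months, L = L, M = M, S = S)
  }
  rbind(one("female", 0.2), one("male", 0))
}

#' Construct a known age-varying transition regime
#'
#' Builds the generating truth for the synthetic cohort: one-year 3x3
#' transition matrices `T(a)` for ages 2..79, an initial category
#' distribution at age 2, the implied marginal prevalences
#' `p(a) = pi(2) %*% prod T`, and the implied true per-boundary net flows
#' and net transition probabilities. Presets encode the qualitative life-
#' course patterns the estimator targets:
#' * `"early_peak"` — the overweight-to-obese net transition peaks at age 2
#'   and declines with age, while the normal-to-overweight net peaks in the
#'   early 20s (the pattern reported for U.S. populations).
#' * `"adult_peak"` — upward movement concentrated in the 20s only.
#' * `"identity"` — no movement at all; all true nets are 0.
#'
#' Two-step (normal to obese or back) one-year entries are capped at
#' `two_step_cap` (default 0.01): crossing both category boundaries within
#' a single year is biologically unlikely.
#'
#' @param scenario Preset name, or a list with elements `up1(a)`, `down1(a)`,
#'   `up2(a)`, `down2(a)` (vectorized rate functions) and `pi2` (length-3
#'   initial distribution).
#' @param drift Multiplier applied to all upward one-year movement rates
#'   (`0` = the preset as-is; `0.5` = a +50% secular shift, used to test the
#'   stability check's power).
#' @param two_step_cap Cap on one-year two-step transition entries.
#' @param ages Age grid (default 2:80).
#' @return Object of class `synthetic_truth`: `ages`, `T` (list of 3x3
#'   matrices indexed by source age), `pi2`, `prevalence` (matrix over
#'   ages), `net` (true net-transition table with `net_flow`, `net_prob`).
#' @export
make_truth <- function(scenario = "early_peak", drift = 0,
                       two_step_cap = 0.01, ages = 2:80) {
  sc <- if (is.list(scenario)) scenario else truth_preset(scenario)
  src <- ages[-length(ages)]
  up1 <- pmin(sc$up1(src) * (1 + drift), 0.9)
  dn1 <- sc$down1(src)
  up2 <- pmin(sc$up2(src) * (1 + drift), 0.9)
  dn2 <- sc$down2(src)
  u13 <- pmin(sc$two_step %||% 0.002, two_step_cap) * (1 + drift)
  u13 <- pmin(rep_len(u13, length(src)), two_step_cap)
  d31 <- pmin(rep_len(sc$two_step_down %||% 0.001, length(src)), two_step_cap)
  Tm <- lapply(seq_along(src), function(i) {
    M <- rbind(
      c(1 - up1[i] - u13[i], up1[i], u13[i]),
      c(dn1[i], 1 - dn1[i] - up2[i], up2[i]),
      c(d31[i], dn2[i], 1 - dn2[i] - d31[i]))
    if (any(M < 0)) stop("invalid rates at age ", src[i], ": row sums exceed 1")
    dimnames(M) <- list(c("normal", "overweight", "obese"),
                        c("normal", "overweight", "obese"))
    M
  })
  names(Tm) <- src
  P <- matrix(NA_real_, length(ages), 3,
              dimnames = list(ages, c("normal", "overweight", "obese")))
  P[1, ] <- sc$pi2
  for (i in seq_along(src)) P[i + 1, ] <- drop(P[i, ] %*% Tm[[i]])
  net <- do.call(rbind, lapply(seq_along(src), function(i) {
    net_probabilities(closed_form_net(P[i, ], P[i + 1, ]), P[i, ],
                      age = src[i])
  }))
  structure(list(scenario = if (is.character(scenario)) scenario else "custom",
                 drift = drift, ages = ages, T = Tm, pi2 = sc$pi2,
                 prevalence = P, net = net),
            class = "synthetic_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

truth_preset <- function(name) {
  switch(name,
    early_peak = list(
      # ow->ob net peaks at age 2 (~12% of the overweight) and declines;
      # nw->ow peaks in the early 20s; modest downward churn throughout
      up1  = function(a) 0.02 + 0.035 * exp(-((a - 22)^2) / (2 * 14^2)),
      down1 = function(a) rep(0.015, length(a)),
      up2  = function(a) 0.015 + 0.115 * exp(-(a - 2) / 9),
      down2 = function(a) rep(0.012, length(a)),
      two_step = 0.002, two_step_down = 0.001,
      pi2 = c(0.78, 0.11, 0.11)),
    adult_peak = list(
      up1  = function(a) 0.01 + 0.05 * exp(-((a - 24)^2) / (2 * 8^2)),
      down1 = function(a) rep(0.012, length(a)),
      up2  = function(a) 0.008 + 0.03 * exp(-((a - 28)^2) / (2 * 10^2)),
      down2 = function(a) rep(0.01, length(a)),
      two_step = 0.002, two_step_down = 0.001,
      pi2 = c(0.85, 0.09, 0.06)),
    identity = list(
      up1 = function(a) rep(0, length(a)), down1 = function(a) rep(0, length(a)),
      up2 = function(a) rep(0, length(a)), down2 = function(a) rep(0, length(a)),
      two_step = 0, two_step_down = 0,
      pi2 = c(0.8, 0.12, 0.08)),
    stop("unknown scenario preset '", name, "'"))
}

#' Simulate longitudinal weight-category trajectories from a truth
#'
#' Each individual enters at a uniformly drawn age, receives an initial
#' category from the truth's marginal prevalence at that age, and evolves
#' by the age-specific one-year transition matrices for `visits - 1`
#' further annual observations.
#'
#' @param truth A [make_truth()] object.
#' @param n Number of individuals.
#' @param visits Observations per individual (annual; default 3).
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `age`, `k` (1..3) and `category`,
#'   the longitudinal-record schema the calibration step consumes.
#' @export
simulate_trajectories <- function(truth, n, visits = 3, seed = 1) {
  old <- withr_seed(seed)
  on.exit(restore_seed(old))
  amin <- truth$ages[1]
  amax <- truth$ages[length(truth$ages)]
  entry <- sample(amin:(amax - visits + 1), n, replace = TRUE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- entry[i]
    kk <- integer(visits)
    kk[1] <- sample.int(3, 1, prob = truth$prevalence[match(a, truth$ages), ])
    for (v in seq_len(visits - 1)) {
      Tm <- truth$T[[as.character(a + v - 1)]]
      kk[v + 1] <- sample.int(3, 1, prob = Tm[kk[v], ])
    }
    out[[i]] <- data.frame(id = sprintf("traj%06d", i),
                           age = a + seq_len(visits) - 1L, k = kk)
  }
  res <- do.call(rbind, out)
  res$category <- weight_category(res$k)
  res
}

#' Survey design specification for synthetic cross-sections
#'
#' @param n_strata Number of design strata per cycle (default 15, the
#'   order of a national survey cycle's pseudo-strata; stratum labels are
#'   cycle-specific, so pooling cycles multiplies the cluster count).
#' @param psus_per_stratum PSUs per stratum (default 2; at least 2 when a
#'   clustered variance is wanted).
#' @param psu_sd Standard deviation of the PSU-level random intercept added
#'   to the category log-odds (0 = no cluster effect).
#' @param weight_sd Log-scale standard deviation of the survey weights
#'   (lognormal; 0 = equal weights).
#' @param n Records per cycle (default 5000).
#' @param cycles Character vector of cycle labels.
#' @param drift_per_cycle Upward-rate drift multiplier applied cumulatively
#'   per successive cycle (0 = same regime every cycle).
#' @return List of class `survey_design_spec`.
#' @export
survey_design_spec <- function(n_strata = 15, psus_per_stratum = 2,
                               psu_sd = 0, weight_sd = 0.4, n = 5000,
                               cycles = "cycle1", drift_per_cycle = 0) {
  stopifnot(n_strata >= 1, psus_per_stratum >= 1)
  structure(list(n_strata = n_strata, psus_per_stratum = psus_per_stratum,
                 psu_sd = psu_sd, weight_sd = weight_sd, n = n,
                 cycles = cycles, drift_per_cycle = drift_per_cycle),
            class = "survey_design_spec")
}

#' Draw a synthetic cross-sectional survey from a truth
#'
#' Ages are uniform over the truth's grid; categories are drawn from the
#' truth's marginal prevalence at each age, optionally perturbed by a
#' mean-zero PSU random intercept on the log-odds scale; strata, PSUs and
#' lognormal survey weights emulate a multistage design (weights are drawn
#' independently of category, so the weighted category distribution stays
#' unbiased for the truth). BMI values consistent with the drawn category
#' are emitted — uniform within the adult BMI band, or a within-band
#' percentile pushed through the inverse LMS transform for children — so
#' the classification stage can be exercised end-to-end.
#'
#' @param truth A [make_truth()] object.
#' @param design A [survey_design_spec()].
#' @param cycle Cycle label for the emitted records.
#' @param seed Integer seed.
#' @param growth_ref Growth reference used to emit child BMIs (default the
#'   bundled synthetic reference).
#' @param sex,group Labels stamped on every record (one stratum at a time).
#' @param boundary_margin Margin (in BMI or percentile units) kept clear of
#'   the category boundaries so emitted values round-trip through
#'   classification (default 0.05).
#' @return Data frame in the individual-record schema of [read_records()].
#' @export
sample_cross_section <- function(truth, design = survey_design_spec(),
                                 cycle = "cycle1", seed = 1,
                                 growth_ref = synthetic_growth_reference(),
                                 sex = "female", group = "GroupA",
                                 boundary_margin = 0.05) {
  old <- withr_seed(seed)
  on.exit(restore_seed(old))
  n <- design$n
  ages <- sample(truth$ages, n, replace = TRUE)
  stratum <- sample.int(design$n_strata, n, replace = TRUE)
  psu <- sample.int(design$psus_per_stratum, n, replace = TRUE)
  psu_id <- (stratum - 1) * design$psus_per_stratum + psu
  psu_eff <- stats::rnorm(design$n_strata * design$psus_per_stratum,
                          0, design$psu_sd)
  k <- integer(n)
  cell <- if (design$psu_sd > 0) paste(ages, psu_id) else as.character(ages)
  for (cc in unique(cell)) {
    i <- which(cell == cc)
    p <- truth$prevalence[match(ages[i[1]], truth$ages), ]
    if (design$psu_sd > 0) {
      eta <- log(pmax(p, 1e-12)) + c(0, rep(psu_eff[psu_id[i[1]]], 2))
      p <- exp(eta - max(eta)); p[truth$prevalence[match(ages[i[1]], truth$ages), ] == 0] <- 0
      p <- p / sum(p)
    }
    k[i] <- sample.int(3, length(i), replace = TRUE, prob = p)
  }
  w <- stats::rlnorm(n, meanlog = 10, sdlog = design$weight_sd)
  rec <- data.frame(
    id = sprintf("%s_%06d", cycle, seq_len(n)), age = ages,
    sex = sex, group = group, stringsAsFactors = FALSE)
  bmi <- numeric(n)
  is_adult <- ages >= 20
  m <- boundary_margin
  lo <- c(18.5, 25, 30)[k]; hi <- c(25 - m, 30 - m, 45)[k]
  bmi[is_adult] <- stats::runif(sum(is_adult), lo[is_adult], hi[is_adult])
  if (any(!is_adult)) {
    plo <- c(2, 85 + m, 95 + m)[k]; phi <- c(85 - m, 95 - m, 99.7)[k]
    pct <- stats::runif(sum(!is_adult), plo[!is_adult], phi[!is_adult])
    bmi[!is_adult] <- bmi_from_percentile(pct, rec$sex[!is_adult],
                                          12 * ages[!is_adult] + 6, growth_ref)
  }
  rec$height_m <- round(ifelse(is_adult, 1.68,
                               pmin(0.85 + 0.052 * ages, 1.68)), 3)
  rec$weight_kg <- round(bmi * rec$height_m^2, 4)
  rec$survey_weight <- w
  rec$stratum <- paste0(cycle, "_S", stratum)  # strata are cycle-specific
  rec$psu <- paste0("P", psu)
  rec$cycle <- cycle
  rec$pregnant_or_recent <- FALSE
  rec$amputation <- FALSE
  rec$true_k <- k
  rec
}

#' Draw several cycles from one (possibly drifting) regime
#'
#' @inheritParams sample_cross_section
#' @param design A [survey_design_spec()]; its `cycles` and
#'   `drift_per_cycle` fields control how many cross-sections are drawn and
#'   whether successive cycles come from an upward-shifted regime.
#' @return A single data frame of records across all cycles.
#' @export
sample_cycles <- function(truth, design = survey_design_spec(), seed = 1,
                          growth_ref = synthetic_growth_reference(),
                          sex = "female", group = "GroupA") {
  recs <- lapply(seq_along(design$cycles), function(i) {
    tr <- if (design$drift_per_cycle != 0 && i > 1) {
      make_truth(truth$scenario, drift = design$drift_per_cycle * (i - 1))
    } else truth
    sample_cross_section(tr, design, cycle = design$cycles[i],
                         seed = seed + 7919L * i, growth_ref = growth_ref,
                         sex = sex, group = group)
  })
  do.call(rbind, recs)
}
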