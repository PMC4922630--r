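#' Empirical net transitions from longitudinal trajectories
#'
#' Counts one-year weight-category moves among individuals observed at both
#' age `a` and age `a + 1`. A move crosses a boundary `b` upward when the
#' category at `a` is at or below `b` and the category at `a + 1` is above
#' it (so a rare two-step move crosses both boundaries). The net flow at a
#' boundary is upward crossings minus downward crossings; the net
#' probability divides by the count in the favored direction's origin
#' category at age `a` — e.g. 100 normal-weight 18-year-olds with 10 up
#' moves and 3 down moves give a net of 7 people and a net normal-to-
#' overweight transition probability of 7%.
#'
#' @param records Longitudinal data frame with columns `id`, `age`, and
#'   `category` (or `k`); ages strictly increasing within `id`.
#' @param age Source age `a`.
#' @return Data frame with one row per (boundary, direction): counts of
#'   crossings, origin-category count, signed `net_flow` (persons) and
#'   `net_prob`; `NA` rows when no paired observations span `(a, a+1)`.
#' @export
empirical_net_from_longitudinal <- function(records, age) {
  records <- as.data.frame(records)
  k <- category_codes(records)
  ord <- order(records$id, records$age)
  id <- records$id[ord]; a <- records$age[ord]; k <- k[ord]
  if (any(duplicated(paste(id, a)))) stop("duplicate (id, age) observations")
  i <- which(a == age)
  i <- i[id[i] == id[pmin(i + 1, length(id))] & a[pmin(i + 1, length(a))] == age + 1]
  out <- data.frame(age = age,
                    boundary = rep(boundary_labels, each = 2),
                    direction = rep(c("up", "down"), 2),
                    n_cross = NA_real_, n_origin = NA_real_,
                    net_flow = NA_real_, net_prob = NA_real_,
                    stringsAsFactors = FALSE)
  if (!length(i)) return(out)
  k0 <- k[i]; k1 <- k[i + 1]
  origin_up <- c(1, 2); origin_down <- c(2, 3)
  for (b in 1:2) {
    up <- sum(k0 <= b & k1 > b)
    down <- sum(k0 > b & k1 <= b)
    net <- up - down
    for (dir in c("up", "down")) {
      r <- which(out$boundary == boundary_labels[b] & out$direction == dir)
      n_cross <- if (dir == "up") up else down
      origin <- sum(k0 == (if (dir == "up") origin_up[b] else origin_down[b]))
      flow <- if (dir == "up") max(0, net) else max(0, -net)
      out$n_cross[r] <- n_cross
      out$n_origin[r] <- origin
      out$net_flow[r] <- if (dir == "up") max(0, net) else -max(0, -net)
      out$net_prob[r] <- if (origin > 0) flow / origin else
        if (flow == 0) 0 else NA_real_
    }
  }
  out
}

#' Calibrate the economy-of-movement cost constants
#'
#' Sweeps a candidate grid of `(c1, c2)` step costs (with `c0 = 0`), solves
#' the transportation problem at each age of the cross-sectional prevalence
#' under each valid candidate, and scores candidates by the mean squared
#' difference between the LP net transition probabilities and the empirical
#' longitudinal nets. Candidates violating the economy-of-movement
#' constraints (`c0 < c1`, `2*c1 < c2`) are flagged invalid and not fitted.
#' Because net flows are invariant to the cost constants whenever the
#' constraints hold, the fitted profile is expected to be flat and the
#' selection falls to the documented tie-break: the first valid candidate in
#' grid order.
#'
#' @param longitudinal_nets Data frame from stacking
#'   [empirical_net_from_longitudinal()] over ages.
#' @param prevalence A `prevalence_curve` (or per-age probability matrix)
#'   for the same population.
#' @param grid Data frame or matrix with columns `c1`, `c2`.
#' @param tie_tol Ties within this MSE tolerance resolve to grid order.
#' @return List with `best` (a [cost_matrix()]), `profile` (the grid with
#'   `valid` flags and `mse`), and `selected` (row index).
#' @export
calibrate_costs <- function(longitudinal_nets, prevalence,
                            grid = data.frame(c1 = c(1, 6, 10),
                                              c2 = c(3, 17, 25)),
                            tie_tol = 1e-9) {
  grid <- as.data.frame(grid)
  P <- if (inherits(prevalence, "prevalence_curve")) prevalence$P else
    as.matrix(prevalence)
  grid_ages <- if (inherits(prevalence, "prevalence_curve")) prevalence$ages else
    as.integer(rownames(P))
  emp <- longitudinal_nets[!is.na(longitudinal_nets$net_prob), ]
  if (!nrow(emp)) stop("no usable empirical nets")
  profile <- grid
  profile$valid <- vapply(seq_len(nrow(grid)), function(i)
    cost_constants_valid(c(0, grid$c1[i], grid$c2[i])), TRUE)
  profile$mse <- NA_real_
  for (i in which(profile$valid)) {
    cm <- cost_matrix(c(0, grid$c1[i], grid$c2[i]))
    err <- vapply(seq_len(nrow(emp)), function(r) {
      a <- emp$age[r]
      ia <- match(a, grid_ages)
      if (is.na(ia) || ia >= length(grid_ages)) return(NA_real_)
      plan <- solve_transport(P[ia, ], P[ia + 1, ], cm)
      tab <- net_probabilities(plan, age = a)
      est <- tab$net_prob[tab$boundary == emp$boundary[r] &
                            tab$direction == emp$direction[r]]
      est - emp$net_prob[r]
    }, 0)
    profile$mse[i] <- mean(err^2, na.rm = TRUE)
  }
  if (!any(profile$valid)) stop("no valid cost candidates in the grid")
  best_mse <- min(profile$mse, na.rm = TRUE)
  sel <- which(profile$valid & profile$mse <= best_mse + tie_tol)[1]
  list(best = cost_matrix(c(0, grid$c1[sel], grid$c2[sel])),
       profile = profile, selected = sel)
}

#' Validate transition stability across survey cycles
#'
#' Tests the stationarity assumption behind cross-sectional net-transition
#' estimation: net transitions estimated in an earlier cycle, chained
#' forward with [project_forward()] for `horizon` one-year steps (aging the
#' cohort, so the prediction at age `a + h` uses the earlier cycle's nets at
#' ages `a .. a+h-1`), should reproduce the prevalence observed in a later
#' independent cycle. Each later-cycle age/category discrepancy is
#' standardized by the bootstrap standard error of the difference
#' (prediction and observation SEs combined in quadrature).
#'
#' The stability decision is based on the mean squared standardized
#' discrepancy per cycle (a reduced chi-square): under a stable regime it
#' sits near 1, and the cycle is flagged unstable when it exceeds
#' `chi2_bound`. A mean-based statistic is used for the decision because a
#' secular shift moves the whole prevalence surface coherently, whereas a
#' maximum over hundreds of correlated age-by-category cells trips over
#' multiplicity even under stability. Per-cell `z_bound` exceedances are
#' still reported, as diagnostics that localize where a flagged shift acts.
#'
#' @param earlier A `prevalence_curve` from the earlier cycle.
#' @param later A `prevalence_curve` (or list of curves) from later
#'   cycle(s), on the same age grid.
#' @param horizon Years between the cycles (one value per later curve);
#'   horizon 0 compares the earlier curve with itself.
#' @param z_bound Multiple of the combined bootstrap SE beyond which an
#'   individual cell is marked in the `exceeds` diagnostic column
#'   (default 3).
#' @param chi2_bound Decision bound on the per-cycle mean squared
#'   standardized discrepancy (default 3: the average squared discrepancy
#'   must stay below three times its stability-hypothesis expectation).
#' @param se_replicates Bootstrap draws for the SE surfaces (default 200).
#' @param seed Seed for the SE bootstrap.
#' @return List of class `stability_report`: per later cycle a data frame of
#'   (age, category, predicted, observed, discrepancy, se, exceeds), the
#'   max/mean absolute discrepancies, the per-cycle `chi2_ratio`, and
#'   `stable` (no cycle's ratio above `chi2_bound`).
#' @export
validate_stability <- function(earlier, later, horizon, z_bound = 3,
                               chi2_bound = 3, se_replicates = 200,
                               seed = 1) {
  if (inherits(later, "prevalence_curve")) later <- list(later)
  stopifnot(length(horizon) == length(later), all(horizon >= 0))
  nets <- net_transition_table(earlier)
  se_pred <- stability_projection_se(earlier, max(horizon), se_replicates, seed)
  reports <- vector("list", length(later))
  for (ci in seq_along(later)) {
    obs_curve <- later[[ci]]
    if (!identical(obs_curve$ages, earlier$ages)) {
      stop("later-cycle curve is on a different age grid")
    }
    h <- horizon[ci]
    pred <- project_curve(earlier$P, nets, h, earlier$ages)
    se_obs <- bootstrap_prevalence_se(obs_curve, se_replicates, seed + ci)
    keep <- which(earlier$ages >= earlier$ages[1] + h)
    d <- pred[keep, , drop = FALSE] - obs_curve$P[keep, , drop = FALSE]
    se <- sqrt(se_pred[[paste0("h", h)]][keep, , drop = FALSE]^2 +
                 se_obs[keep, , drop = FALSE]^2)
    z <- d / pmax(se, 1e-12)
    reports[[ci]] <- data.frame(
      age = rep(earlier$ages[keep], 3),
      category = rep(colnames(earlier$P), each = length(keep)),
      predicted = as.vector(pred[keep, ]),
      observed = as.vector(obs_curve$P[keep, ]),
      discrepancy = as.vector(d),
      se = as.vector(se),
      exceeds = as.vector(abs(z) > z_bound))
  }
  chi2 <- vapply(reports, function(r) mean((r$discrepancy / r$se)^2), 0)
  structure(list(
    per_cycle = reports, horizon = horizon, z_bound = z_bound,
    chi2_bound = chi2_bound, chi2_ratio = chi2,
    max_abs_discrepancy = vapply(reports, function(r) max(abs(r$discrepancy)), 0),
    mean_abs_discrepancy = vapply(reports, function(r) mean(abs(r$discrepancy)), 0),
    stable = all(chi2 <= chi2_bound)),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Cross-cycle stability report:",
      if (x$stable) "stable" else "UNSTABLE", "\n")
  for (i in seq_along(x$per_cycle)) {
    cat(sprintf("  horizon %d: chi2 ratio = %.2f (bound %.1f), max |disc| = %.4f, mean |disc| = %.4f, cells |z|>%g: %d\n",
                x$horizon[i], x$chi2_ratio[i], x$chi2_bound,
                x$max_abs_discrepancy[i], x$mean_abs_discrepancy[i],
                x$z_bound, sum(x$per_cycle[[i]]$exceeds)))
  }
  invisible(x)
}

# Chain project_forward h steps across the whole grid: predicted prevalence
# at age a + h from the age-a prevalence and nets at ages a..a+h-1. One
# projection step is linear in the signed net flows, so an h-step chain is a
# windowed cumulative sum.
project_curve <- function(P, nets, h, ages) {
  if (h == 0) return(P)
  flows <- flows_from_nets(nets, ages)
  project_curve_flows(P, flows, h)
}

# Signed per-boundary flows (ages[-last] x 2) from a net table.
flows_from_nets <- function(nets, ages) {
  src <- ages[-length(ages)]
  f <- matrix(0, length(src), 2)
  for (b in 1:2) {
    r <- nets[nets$boundary == boundary_labels[b], ]
    f[, b] <- as.vector(rowsum(r$net_flow, r$age))[match(src, sort(unique(r$age)))]
  }
  f
}

project_curve_flows <- function(P, flows, h) {
  out <- P; out[] <- NA_real_
  n <- nrow(P)
  cs1 <- cumsum(c(0, flows[, 1])); cs2 <- cumsum(c(0, flows[, 2]))
  i <- (h + 1):n
  q1 <- P[i - h, 1] - (cs1[i] - cs1[i - h])
  q3 <- P[i - h, 3] + (cs2[i] - cs2[i - h])
  out[i, 1] <- q1; out[i, 3] <- q3; out[i, 2] <- 1 - q1 - q3
  out
}

# Bootstrap SE of the h-step projected surface as a function of the earlier
# curve's coefficient uncertainty.
stability_projection_se <- function(curve, hmax, replicates, seed) {
  hs <- unique(c(0, seq_len(hmax)))
  if (!length(curve$coef)) {
    z <- matrix(0, length(curve$ages), 3, dimnames = dimnames(curve$P))
    out <- lapply(hs, function(h) z)
    names(out) <- paste0("h", hs)
    return(out)
  }
  V <- nearest_psd(curve$vcov)
  old <- withr_seed(seed)
  on.exit(restore_seed(old))
  coefs <- MASS::mvrnorm(replicates, mu = curve$coef, Sigma = V)
  acc <- lapply(hs, function(h) array(NA_real_, c(replicates, length(curve$ages), 3)))
  names(acc) <- paste0("h", hs)
  n <- length(curve$ages)
  for (r in seq_len(replicates)) {
    P <- curve_probs(curve, coefs[r, ])
    flows <- cbind(P[-n, 1] - P[-1, 1], P[-1, 3] - P[-n, 3])
    for (h in hs) acc[[paste0("h", h)]][r, , ] <- project_curve_flows(P, flows, h)
  }
  out <- lapply(acc, function(a) {
    se <- apply(a, c(2, 3), stats::sd, na.rm = TRUE)
    dimnames(se) <- dimnames(curve$P)
    se
  })
  out
}
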