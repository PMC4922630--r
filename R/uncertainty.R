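#' Bootstrap configuration
#'
#' @param replicates Number of parametric-bootstrap replicates (default
#'   1000; a warning is issued below 100, where percentile intervals are
#'   unreliable).
#' @param seed Integer seed; mandatory so that intervals are reproducible.
#' @param ci_level Confidence level (default 0.95).
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(replicates = 1000, seed = 1, ci_level = 0.95) {
  stopifnot(replicates >= 1, ci_level > 0, ci_level < 1)
  if (replicates < 100) {
    warning("fewer than 100 replicates: percentile CIs will be unstable")
  }
  structure(list(replicates = as.integer(replicates), seed = as.integer(seed),
                 ci_level = ci_level, method = "percentile"),
            class = "bootstrap_config")
}

# Clip negative eigenvalues so MASS::mvrnorm accepts the matrix.
nearest_psd <- function(V, tol = 1e-10) {
  if (!length(V)) return(V)
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) >= -tol * max(abs(e$values), 1)) return(V)
  warning("covariance not PSD; clipping negative eigenvalues")
  lam <- pmax(e$values, 0)
  e$vectors %*% (lam * t(e$vectors))
}

#' Parametric-bootstrap confidence intervals for net transition probabilities
#'
#' Simulates the smoothed age-specific prevalence from its asymptotic
#' distribution — spline coefficients drawn from a multivariate normal with
#' the fitted mean and cluster-robust covariance — and recomputes the net
#' transition probabilities for every draw. Sampling in coefficient space
#' keeps each simulated surface a proper probability vector after the
#' inverse-logit map. Intervals are percentile intervals per (age, boundary,
#' direction); the point estimate remains the plug-in value, so for skewed
#' replicate distributions near 0 the point estimate may fall outside the
#' interval.
#'
#' @param curve A fitted `prevalence_curve` carrying `coef` and `vcov`.
#' @param cost A [cost_matrix()] (net flows are cost-invariant for valid
#'   constants; kept for interface symmetry and auditability).
#' @param cfg A [bootstrap_config()].
#' @param keep_draws If `TRUE`, attach the replicate-by-row matrix of net
#'   probabilities as attribute `"draws"` for audit.
#' @return A `net_transition_table` with `ci_low` and `ci_high` columns.
#' @export
bootstrap_nets <- function(curve, cost = cost_matrix(),
                           cfg = bootstrap_config(), keep_draws = FALSE) {
  stopifnot(inherits(curve, "prevalence_curve"))
  tab <- net_transition_table(curve)
  R <- cfg$replicates
  if (!length(curve$coef)) {  # degenerate curve: no sampling distribution
    tab$ci_low <- tab$net_prob
    tab$ci_high <- tab$net_prob
    return(tab)
  }
  V <- nearest_psd(curve$vcov)
  draws <- matrix(NA_real_, R, nrow(tab))
  old <- withr_seed(cfg$seed)
  on.exit(restore_seed(old))
  coefs <- MASS::mvrnorm(R, mu = curve$coef, Sigma = V)
  if (R == 1) coefs <- matrix(coefs, 1)
  for (r in seq_len(R)) {
    P <- curve_probs(curve, coefs[r, ])
    tb <- net_transition_table_fast(P, curve$ages)
    draws[r, ] <- tb
  }
  alpha <- (1 - cfg$ci_level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7)
  tab$ci_low <- pmin(pmax(qs[1, ], 0), 1)
  tab$ci_high <- pmin(pmax(qs[2, ], 0), 1)
  if (keep_draws) attr(tab, "draws") <- draws
  tab
}

# net_prob column only, in net_transition_table row order, vectorized over
# ages for bootstrap speed.
net_transition_table_fast <- function(P, ages) {
  n <- nrow(P) - 1
  p1 <- P[1:n, 1]; p2 <- P[1:n, 2]; p3 <- P[1:n, 3]
  q1 <- P[2:(n + 1), 1]; q3 <- P[2:(n + 1), 3]
  net1 <- p1 - q1          # signed up-flow, normal/overweight boundary
  net2 <- q3 - p3          # signed up-flow, overweight/obese boundary
  up1 <- ifelse(p1 > 1e-12, pmax(0, net1) / p1, 0)
  down1 <- ifelse(p2 > 1e-12, pmax(0, -net1) / p2, 0)
  up2 <- ifelse(p2 > 1e-12, pmax(0, net2) / p2, 0)
  down2 <- ifelse(p3 > 1e-12, pmax(0, -net2) / p3, 0)
  # row order per age: (b1 up, b1 down, b2 up, b2 down)
  as.vector(t(cbind(pmin(up1, 1), pmin(down1, 1), pmin(up2, 1), pmin(down2, 1))))
}

# Seed handling that restores the caller's RNG state.
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Pointwise bootstrap SEs of the prevalence surface itself (used by the
# cross-cycle stability check).
bootstrap_prevalence_se <- function(curve, replicates = 200, seed = 1) {
  if (!length(curve$coef)) {
    return(matrix(0, length(curve$ages), 3, dimnames = dimnames(curve$P)))
  }
  V <- nearest_psd(curve$vcov)
  old <- withr_seed(seed)
  on.exit(restore_seed(old))
  coefs <- MASS::mvrnorm(replicates, mu = curve$coef, Sigma = V)
  acc <- array(NA_real_, c(replicates, length(curve$ages), 3))
  for (r in seq_len(replicates)) acc[r, , ] <- curve_probs(curve, coefs[r, ])
  se <- apply(acc, c(2, 3), stats::sd)
  dimnames(se) <- dimnames(curve$P)
  se
}
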