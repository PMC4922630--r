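#' Smoothing and basis configuration for the prevalence model
#'
#' @param n_knots Number of equally spaced interior knots over the age span
#'   (default 20).
#' @param degree B-spline degree (default 3, cubic).
#' @param penalty_order Order of the difference penalty on adjacent spline
#'   coefficients (default 2: as the penalty grows, each log-odds curve
#'   approaches a straight line in age).
#' @param lambda Fixed smoothing parameter; `NULL` (default) selects it by
#'   AIC over `lambda_grid`.
#' @param lambda_grid Candidate smoothing parameters for the AIC search. The
#'   default grid is deliberately light: the downstream estimand is the
#'   year-over-year *increment* of the prevalence surface, and
#'   prediction-optimal smoothing (which balances squared bias against
#'   variance) leaves a bias that is first-order for increments, flattening
#'   the early-childhood peak and invalidating bootstrap intervals.
#'   Undersmoothing relative to the prediction optimum keeps that bias
#'   negligible against the sampling error; the penalty's job here is to
#'   stabilize an ample basis, not to shrink the curve.
#' @param age_range Age span of the basis, default `c(2, 80)`.
#' @param transform Scale on which the equally spaced knots are placed:
#'   `"identity"` (default) spaces knots uniformly in years; `"log"`
#'   concentrates flexibility at young ages at the price of far noisier
#'   early-childhood estimates when ages are sampled uniformly.
#' @param max_iter,tol Newton iteration controls.
#' @return A list of class `prevalence_spec`.
#' @export
prevalence_spec <- function(n_knots = 20, degree = 3, penalty_order = 2,
                            lambda = NULL,
                            lambda_grid = 10^seq(-2, 0.5, by = 0.5),
                            age_range = c(2, 80),
                            transform = c("identity", "log"),
                            max_iter = 200, tol = 1e-9) {
  structure(list(n_knots = n_knots, degree = degree,
                 penalty_order = penalty_order, lambda = lambda,
                 lambda_grid = lambda_grid, age_range = age_range,
                 transform = match.arg(transform),
                 max_iter = max_iter, tol = tol),
            class = "prevalence_spec")
}

# Full (boundary-padded) knot vector and design matrix for ages x, on the
# configured scale.
basis_design <- function(x, spec) {
  tf <- if (identical(spec$transform, "identity")) identity else log
  a <- tf(spec$age_range)
  inner <- seq(a[1], a[2], length.out = spec$n_knots + 2)
  h <- inner[2] - inner[1]
  knots <- c(a[1] - h * (spec$degree:1), inner, a[2] + h * (1:spec$degree))
  splines::splineDesign(knots, tf(x), ord = spec$degree + 1, outer.ok = FALSE)
}

#' Fit smoothed age-specific category prevalence for one stratum
#'
#' Maximizes a survey-weighted multinomial log-likelihood for the three
#' ordered weight categories, with each category's log-odds (versus normal
#' weight) modeled as a B-spline in age carrying a difference penalty
#' (a P-spline). The smoothing parameter is chosen by AIC unless fixed in
#' `spec`. The returned covariance of the spline coefficients is a
#' cluster-robust sandwich, clustered on PSU within stratum when those
#' design columns are present (each record is its own cluster otherwise),
#' so that the parametric bootstrap reflects the survey design.
#'
#' @param records Data frame with columns `age`, `category` (or integer
#'   `k` 1..3), `survey_weight` (defaults to 1), and optionally `stratum`
#'   and `psu`. Typically the output of [assign_categories()].
#' @param stratum Optional list or named vector identifying the sex/group
#'   stratum; if it has `sex`/`group` entries matching record columns the
#'   records are filtered, otherwise it is carried as a label only.
#' @param spec A [prevalence_spec()].
#' @return An object of class `prevalence_curve`: smoothed probabilities `P`
#'   on the integer age grid, spline coefficients `coef`, sandwich `vcov`,
#'   the selected `lambda`, effective degrees of freedom and fit metadata.
#' @export
fit_prevalence <- function(records, stratum = NULL, spec = prevalence_spec()) {
  records <- as.data.frame(records)
  for (v in c("sex", "group")) {
    if (!is.null(stratum[[v]]) && v %in% names(records)) {
      records <- records[records[[v]] == stratum[[v]], , drop = FALSE]
    }
  }
  if (!nrow(records)) stop("no records in the requested stratum")
  k <- category_codes(records)
  w <- if ("survey_weight" %in% names(records)) {
    as.numeric(records$survey_weight)
  } else rep(1, nrow(records))
  if (any(!is.finite(w)) || any(w <= 0)) stop("survey weights must be positive")
  w <- w * length(w) / sum(w)  # scale invariance: estimates depend on relative weights only
  age <- as.numeric(records$age)
  if (length(unique(age)) < 2 && length(unique(k)) > 1) {
    stop("need records at >= 2 distinct ages")
  }

  cluster <- if (all(c("stratum", "psu") %in% names(records))) {
    interaction(records$stratum, records$psu, drop = TRUE)
  } else factor(seq_along(age))

  grid <- spec$age_range[1]:spec$age_range[2]
  Bgrid <- basis_design(grid, spec)
  cats <- sort(unique(k))

  if (length(cats) == 1) {
    warning("all records fall in one category; returning a degenerate curve")
    P <- matrix(0, length(grid), 3,
                dimnames = list(grid, c("normal", "overweight", "obese")))
    P[, cats] <- 1
    return(new_prevalence_curve(stratum, grid, P, coef = numeric(0),
                                vcov = matrix(0, 0, 0), lambda = NA_real_,
                                spec = spec, Bgrid = Bgrid, cats = cats,
                                edf = 0, loglik = 0, n = length(k)))
  }

  # exact aggregation: the likelihood and clustered scores depend on the
  # data only through summed weights per (age, category, cluster)
  key <- paste(age, k, as.integer(cluster), sep = "\r")
  first <- !duplicated(key)
  rs <- rowsum(w, key)
  agg <- data.frame(age = age[first], k = k[first],
                    cl = as.integer(cluster)[first])
  agg$w <- rs[match(key[first], rownames(rs)), 1]

  B <- basis_design(agg$age, spec)
  m <- ncol(B)
  D <- diff(diag(m), differences = spec$penalty_order)
  Pen <- crossprod(D)
  free <- cats[-1]  # reference = lowest present category
  nf <- length(free)

  fit_one <- function(lambda, beta0) {
    pmfit_newton(B, agg$k, agg$w, free, Pen, lambda, beta0,
                 max_iter = spec$max_iter, tol = spec$tol)
  }
  beta0 <- matrix(0, m, nf)
  if (is.null(spec$lambda)) {
    best <- NULL
    for (lam in sort(spec$lambda_grid)) {
      f <- fit_one(lam, beta0)
      beta0 <- f$beta  # warm start up the grid
      if (is.null(best) || f$aic < best$aic) best <- f
    }
    fit <- best
  } else {
    fit <- fit_one(spec$lambda, beta0)
  }

  V <- sandwich_vcov(B, agg$k, agg$w, agg$cl, free, fit$beta, fit$Hpen_inv)
  eta <- Bgrid %*% fit$beta
  P <- expand_probs(eta, free, length(grid))
  dimnames(P) <- list(grid, c("normal", "overweight", "obese"))
  coef <- as.vector(fit$beta)
  names(coef) <- paste0("cat", rep(free, each = m), "_b", rep(seq_len(m), nf))
  dimnames(V) <- list(names(coef), names(coef))
  new_prevalence_curve(stratum, grid, P, coef, V, fit$lambda, spec, Bgrid,
                       cats, fit$edf, fit$loglik, length(k))
}

category_codes <- function(records) {
  if ("k" %in% names(records)) return(as.integer(records$k))
  if (!"category" %in% names(records)) stop("records need a 'category' or 'k' column")
  k <- as.integer(weight_category(records$category))
  if (anyNA(k)) stop("unrecognized category labels")
  k
}

# Penalized Newton for the multinomial logit over the present categories.
pmfit_newton <- function(B, k, w, free, Pen, lambda, beta, max_iter, tol) {
  m <- ncol(B); nf <- length(free); n <- nrow(B)
  Y <- matrix(0, n, nf)
  for (j in seq_len(nf)) Y[, j] <- as.numeric(k == free[j])
  Slam <- lambda * Pen
  loglik_at <- function(beta) {
    eta <- B %*% beta
    denom <- log1p(rowSums(exp(eta)))
    sum(w * (rowSums(Y * eta) - denom))
  }
  pen_at <- function(beta) 0.5 * lambda * sum(vapply(
    seq_len(nf), function(j) drop(crossprod(beta[, j], Pen %*% beta[, j])), 0))
  ll <- loglik_at(beta); obj <- ll - pen_at(beta)
  for (it in seq_len(max_iter)) {
    eta <- B %*% beta
    E <- exp(eta)
    p <- E / (1 + rowSums(E))
    G <- crossprod(B, w * (Y - p)) - sapply(seq_len(nf), function(j)
      Slam %*% beta[, j])
    G <- matrix(G, m, nf)
    H <- matrix(0, m * nf, m * nf)
    for (a in seq_len(nf)) for (b in a:nf) {
      wab <- w * (p[, a] * ((a == b) - p[, b]))
      blk <- crossprod(B, B * wab)
      ia <- (a - 1) * m + seq_len(m); ib <- (b - 1) * m + seq_len(m)
      H[ia, ib] <- blk; H[ib, ia] <- t(blk)
    }
    Hpen <- H
    for (a in seq_len(nf)) {
      ia <- (a - 1) * m + seq_len(m)
      Hpen[ia, ia] <- Hpen[ia, ia] + Slam
    }
    # small ridge keeps the step well-posed when the basis outruns the data
    Hpen_r <- Hpen + diag(1e-10 * max(diag(Hpen)), nrow(Hpen))
    step <- solve(Hpen_r, as.vector(G))
    if (max(abs(as.vector(G))) < tol * max(1, abs(obj))) break
    sz <- 1
    repeat {
      beta_new <- beta + matrix(sz * step, m, nf)
      ll_new <- loglik_at(beta_new)
      obj_new <- ll_new - pen_at(beta_new)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-10) { obj_new <- obj; beta_new <- beta; ll_new <- ll; break }
    }
    conv <- abs(obj_new - obj) < tol * (abs(obj) + 1)
    beta <- beta_new; obj <- obj_new; ll <- ll_new
    if (conv && it > 1) break
  }
  if (max(abs(as.vector(G))) > 1e-4 * max(1, abs(obj))) {
    stop("prevalence fit did not converge; gradient norm ",
         format(max(abs(as.vector(G)))))
  }
  edf <- sum(diag(solve(Hpen_r, H)))
  list(beta = beta, lambda = lambda, loglik = ll, edf = edf,
       aic = -2 * ll + 2 * edf, Hpen_inv = solve(Hpen_r))
}

# Cluster-robust sandwich over the penalized information.
sandwich_vcov <- function(B, k, w, cl, free, beta, Hpen_inv) {
  m <- ncol(B); nf <- length(free)
  eta <- B %*% beta
  E <- exp(eta)
  p <- E / (1 + rowSums(E))
  S <- matrix(0, nrow(B), m * nf)
  for (j in seq_len(nf)) {
    S[, (j - 1) * m + seq_len(m)] <- B * (w * ((k == free[j]) - p[, j]))
  }
  G <- rowsum(S, cl)
  meat <- crossprod(G)
  V <- Hpen_inv %*% meat %*% Hpen_inv
  (V + t(V)) / 2
}

expand_probs <- function(eta, free, n) {
  E <- exp(eta)
  denom <- 1 + rowSums(E)
  P <- matrix(0, n, 3)
  ref <- setdiff(1:3, free)[1]
  P[, ref] <- 1 / denom
  for (j in seq_along(free)) P[, free[j]] <- E[, j] / denom
  P
}

new_prevalence_curve <- function(stratum, ages, P, coef, vcov, lambda, spec,
                                 Bgrid, cats, edf, loglik, n) {
  structure(list(stratum = stratum, ages = ages, P = P, coef = coef,
                 vcov = vcov, lambda = lambda, spec = spec,
                 basis_grid = Bgrid, cats_present = cats, edf = edf,
                 loglik = loglik, n = n),
            class = "prevalence_curve")
}

#' @export
print.prevalence_curve <- function(x, ...) {
  lab <- if (is.null(x$stratum)) "(unlabelled)" else
    paste(unlist(x$stratum), collapse = "/")
  cat("Smoothed prevalence curve, stratum", lab, "\n")
  cat(sprintf("  ages %d-%d, n = %d, lambda = %s, edf = %.1f\n",
              min(x$ages), max(x$ages), x$n, format(x$lambda), x$edf))
  invisible(x)
}

# Rebuild the probability surface from an arbitrary coefficient vector
# (used by the parametric bootstrap).
curve_probs <- function(curve, coef = curve$coef) {
  if (!length(coef)) return(curve$P)
  m <- ncol(curve$basis_grid)
  free <- curve$cats_present[-1]
  beta <- matrix(coef, m, length(free))
  P <- expand_probs(curve$basis_grid %*% beta, free, length(curve$ages))
  dimnames(P) <- dimnames(curve$P)
  P
}

#' Probabilities at one age
#'
#' @param curve A `prevalence_curve`.
#' @param age Integer age within the curve's grid.
#' @return Named probability vector over the three categories.
#' @export
curve_at <- function(curve, age) {
  i <- match(age, curve$ages)
  if (is.na(i)) stop("age ", age, " outside the curve grid [",
                     min(curve$ages), ", ", max(curve$ages), "]")
  curve$P[i, ]
}

#' Pool records across survey cycles
#'
#' In `pooled` mode each cycle's survey weights are divided by the number of
#' cycles present, the standard convention when concatenating several
#' equal-length release cycles of a survey so that the pooled weights still
#' sum to (one copy of) the target population. `per_cycle` passes records
#' through untouched.
#'
#' @param records Data frame with a `cycle` column (absent = one cycle).
#' @param mode `"pooled"` or `"per_cycle"`.
#' @return Records with rescaled `survey_weight`.
#' @export
combine_cycles <- function(records, mode = c("pooled", "per_cycle")) {
  mode <- match.arg(mode)
  if (mode == "per_cycle") return(records)
  ncyc <- if ("cycle" %in% names(records)) {
    length(unique(records$cycle))
  } else 1L
  records$survey_weight <- records$survey_weight / ncyc
  records
}
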