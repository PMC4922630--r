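#' Banded "economy of movement" cost matrix
#'
#' Costs depend only on the number of category steps moved: `c0` for staying
#' put, `c1` for a one-step move, `c2` for a two-step move. Validity
#' requires staying to be cheapest (`c0 < c1`) and two one-step moves to be
#' cheaper than one two-step move (`2*c1 < c2`), the structure that forces
#' parsimonious transport plans in which mass cascades through the middle
#' category instead of jumping across it. The default constants (0, 6, 17)
#' come from calibration against longitudinal weight-category trajectories.
#'
#' @param constants Numeric vector `(c0, c1, c2)`; for general `K`
#'   categories, length-`K` step costs.
#' @param K Number of ordered categories (default 3).
#' @return A list of class `cost_matrix` with the `K x K` matrix `C` and the
#'   step `constants`.
#' @export
cost_matrix <- function(constants = c(0, 6, 17), K = 3) {
  if (length(constants) < K) stop("need a cost constant for each step size 0..K-1")
  constants <- constants[seq_len(K)]
  if (!cost_constants_valid(constants)) {
    stop("invalid cost constants: require c0 < c1 and strict convexity in ",
         "step size (e.g. 2*c1 < c2)")
  }
  C <- outer(seq_len(K), seq_len(K), function(i, j) constants[abs(i - j) + 1])
  structure(list(C = C, constants = constants, K = K), class = "cost_matrix")
}

#' Check validity of economy-of-movement step costs
#'
#' @param constants Step-cost vector `(c0, c1, ..., c_{K-1})`.
#' @return `TRUE` if `c0 < c1` and the step costs are strictly convex
#'   (`c_{s-1} + c_{s+1} > 2 c_s`), so longer jumps are penalized more than
#'   the equivalent chain of one-step moves.
#' @export
cost_constants_valid <- function(constants) {
  if (length(constants) < 2) return(FALSE)
  if (!(constants[1] < constants[2])) return(FALSE)
  if (length(constants) == 2) return(TRUE)
  s <- seq(2, length(constants) - 1)
  all(constants[s - 1] + constants[s + 1] > 2 * constants[s])
}

check_marginals <- function(p, q, tol = 1e-6) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < -1e-12) || any(q < -1e-12)) stop("marginals must be nonnegative")
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol) {
    stop("marginals must each sum to 1 (off by ",
         format(max(abs(sum(p) - 1), abs(sum(q) - 1))), ")")
  }
  list(p = pmax(p, 0) / sum(pmax(p, 0)), q = pmax(q, 0) / sum(pmax(q, 0)))
}

# Monotone (comonotone / northwest-corner on ordered categories) coupling of
# p and q: the unique non-crossing plan, optimal for any convex banded cost.
monotone_plan <- function(p, q) {
  K <- length(p)
  x <- matrix(0, K, K)
  i <- 1; j <- 1
  pi <- p[1]; qj <- q[1]
  while (i <= K && j <= K) {
    m <- min(pi, qj)
    x[i, j] <- x[i, j] + m
    pi <- pi - m; qj <- qj - m
    if (pi <= 1e-15 && i < K) { i <- i + 1; pi <- p[i] }
    else if (qj <= 1e-15 && j < K) { j <- j + 1; qj <- q[j] }
    else if (pi <= 1e-15 && qj <= 1e-15) break
    else if (pi <= 1e-15 || qj <= 1e-15) break
  }
  x
}

#' Solve the one-year minimum-cost transportation problem
#'
#' Finds the nonnegative flow matrix `x[i, j]` (mass in category `i` at age
#' `a` moving to category `j` at age `a + 1`) that minimizes total cost
#' `sum(C * x)` subject to the row marginals matching the age-`a` prevalence
#' `p` and the column marginals matching the age-`a+1` prevalence `q`. The
#' linear program is solved by the simplex method; when multiple optimal
#' plans exist the monotone (non-crossing) plan is reported, which leaves
#' the net flows unchanged but makes plans reproducible.
#'
#' @param p,q Probability vectors at ages `a` and `a + 1`; must each sum to
#'   1 within `tol` (renormalized inside that tolerance, error beyond it).
#' @param cost A [cost_matrix()].
#' @param tol Marginal-sum tolerance (default `1e-6`).
#' @return A list of class `transport_plan` with the flow matrix `x`, the
#'   marginals, the optimal `cost`, and the cost matrix used.
#' @export
solve_transport <- function(p, q, cost = cost_matrix(), tol = 1e-6) {
  K <- cost$K
  pq <- check_marginals(p, q, tol)
  p <- pq$p; q <- pq$q
  if (length(p) != K) stop("marginal length does not match the cost matrix")
  # simplex LP; the last column-sum constraint is implied by the others and
  # is dropped so the equality system has full rank
  A3 <- matrix(0, 2 * K - 1, K * K)
  for (i in seq_len(K)) A3[i, (i - 1) * K + seq_len(K)] <- 1       # row sums
  for (j in seq_len(K - 1)) A3[K + j, seq(j, K * K, by = K)] <- 1  # column sums
  b3 <- c(p, q[seq_len(K - 1)])
  lp <- boot::simplex(a = as.vector(t(cost$C)), A3 = A3, b3 = b3,
                      maxi = FALSE, eps = 1e-12)
  if (lp$solved != 1) stop("transport LP did not solve (status ", lp$solved, ")")
  x <- monotone_plan(p, q)
  opt <- sum(cost$C * x)
  if (opt > lp$value + 1e-8) {
    stop("internal error: monotone plan cost exceeds the LP optimum")
  }
  structure(list(x = x, p = p, q = q, cost = opt, cost_matrix = cost),
            class = "transport_plan")
}

#' Closed-form per-boundary net flows for three ordered categories
#'
#' For any valid economy-of-movement cost matrix the optimal transport plan
#' moves mass across each adjacent-category boundary in one direction only,
#' and the signed net flow is determined by the marginals alone: across the
#' normal/overweight boundary it is `p[1] - q[1]` (positive = upward, into
#' overweight) and across the overweight/obese boundary it is `q[3] - p[3]`
#' (positive = upward, into obesity). This is the analytic oracle for
#' [solve_transport()] and the fast path used inside the bootstrap.
#'
#' @inheritParams solve_transport
#' @return Named numeric vector of signed net flows
#'   `c(normal_overweight, overweight_obese)`.
#' @export
closed_form_net <- function(p, q, tol = 1e-6) {
  if (length(p) != 3) stop("closed form supports K = 3 only")
  pq <- check_marginals(p, q, tol)
  c(normal_overweight = pq$p[1] - pq$q[1],
    overweight_obese = pq$q[3] - pq$p[3])
}

# Signed net flows of a transport plan: upward crossings minus downward
# crossings of each adjacent-category boundary.
plan_net_flows <- function(x) {
  K <- nrow(x)
  vapply(seq_len(K - 1), function(b) {
    up <- sum(x[row(x) <= b & col(x) > b])
    down <- sum(x[row(x) > b & col(x) <= b])
    up - down
  }, 0)
}

boundary_labels <- c("normal_overweight", "overweight_obese")

#' Net transition probabilities at one age from net flows
#'
#' Converts signed per-boundary net flows into net transition probabilities
#' by dividing by the prevalence of the origin category of the favored
#' direction: an upward net at the normal/overweight boundary divides by
#' `p[1]`, an upward net at the overweight/obese boundary by `p[2]`;
#' downward nets divide by `p[2]` and `p[3]` respectively. The disfavored
#' direction of each boundary is recorded as probability 0, so at most one
#' direction per boundary is positive.
#'
#' @param net Signed net flow vector from [closed_form_net()] or a
#'   `transport_plan` (positive = upward).
#' @param p Prevalence vector at the source age.
#' @param age Optional age label attached to the rows.
#' @return Data frame with columns `age`, `boundary`, `direction`,
#'   `net_prob` (in `[0, 1]`) and `net_flow` (signed, boundary-level).
#' @export
net_probabilities <- function(net, p, age = NA_integer_) {
  if (inherits(net, "transport_plan")) {
    p <- net$p
    net <- plan_net_flows(net$x)
  }
  if (length(net) != 2 || length(p) != 3) stop("expected K = 3 inputs")
  origin_up <- c(1, 2); origin_down <- c(2, 3)
  rows <- list()
  for (b in 1:2) {
    for (dir in c("up", "down")) {
      flow <- if (dir == "up") max(0, net[b]) else max(0, -net[b])
      origin <- p[if (dir == "up") origin_up[b] else origin_down[b]]
      if (flow > 1e-12 && origin <= 1e-12) {
        stop("nonzero net flow out of an empty category at boundary ",
             boundary_labels[b], " (", dir, ")")
      }
      prob <- if (origin <= 1e-12) 0 else flow / origin
      rows[[length(rows) + 1]] <- data.frame(
        age = age, boundary = boundary_labels[b], direction = dir,
        net_prob = min(prob, 1), net_flow = unname(flow) * if (dir == "up") 1 else -1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Net transition table across all consecutive ages of a prevalence curve
#'
#' Applies [closed_form_net()] / [net_probabilities()] to every consecutive
#' age pair of the smoothed prevalence surface. [solve_transport()] gives
#' identical nets (a tested equivalence); the closed form is used here so
#' that the bootstrap can rebuild the table cheaply.
#'
#' @param curve A `prevalence_curve` (or a matrix of per-age probabilities
#'   with an `ages` attribute supplied via `ages`).
#' @param ages Optional integer vector of source ages (default: all but the
#'   last grid age).
#' @return Data frame of class `net_transition_table` with one row per
#'   (age, boundary, direction).
#' @export
net_transition_table <- function(curve, ages = NULL) {
  P <- if (inherits(curve, "prevalence_curve")) curve$P else as.matrix(curve)
  grid <- if (inherits(curve, "prevalence_curve")) curve$ages else
    as.integer(rownames(P))
  if (is.null(ages)) ages <- grid[-length(grid)]
  out <- do.call(rbind, lapply(ages, function(a) {
    i <- match(a, grid)
    if (is.na(i) || i >= length(grid)) {
      stop("age ", a, " has no successor on the grid")
    }
    net <- closed_form_net(P[i, ], P[i + 1, ])
    net_probabilities(net, P[i, ], age = a)
  }))
  class(out) <- c("net_transition_table", class(out))
  out
}

#' Project prevalence one year forward from net transitions
#'
#' Reconstructs the age-`a+1` prevalence vector from the age-`a` prevalence
#' and that age's net transition rows; the exact inverse of estimation, so
#' projecting with the table built from `(p, q)` returns `q`.
#'
#' @param p Prevalence vector at age `a`.
#' @param rows The `net_transition_table` rows for age `a` (4 rows), or a
#'   signed net-flow vector of length 2.
#' @return Prevalence vector at age `a + 1`.
#' @export
project_forward <- function(p, rows) {
  net <- if (is.numeric(rows)) rows else {
    vapply(boundary_labels, function(b) {
      r <- rows[rows$boundary == b, ]
      sum(r$net_flow)
    }, 0)
  }
  q <- c(p[1] - net[1], p[2] + net[1] - net[2], p[3] + net[2])
  names(q) <- c("normal", "overweight", "obese")
  q
}
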