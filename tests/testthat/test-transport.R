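# Expected plans/costs below were frozen from an independent LP solver
# (interior-point/HiGHS) run on the same instances.

test_that("cost matrix enforces the economy-of-movement constraints", {
  cm <- cost_matrix()
  expect_equal(cm$constants, c(0, 6, 17))
  expect_equal(cm$C, rbind(c(0, 6, 17), c(6, 0, 6), c(17, 6, 0)))
  expect_true(cost_constants_valid(c(0, 6, 17)))
  expect_false(cost_constants_valid(c(0, 6, 11)))  # one two-step cheaper than two one-steps
  expect_false(cost_constants_valid(c(5, 3, 17)))  # staying not cheapest
  expect_error(cost_matrix(c(0, 6, 12)), "invalid")
})

test_that("identity transport: equal marginals stay on the diagonal at zero cost", {
  p <- c(0.4, 0.35, 0.25)
  pl <- solve_transport(p, p)
  expect_equal(pl$x, diag(p), tolerance = 1e-12)
  expect_equal(pl$cost, 0, tolerance = 1e-12)
})

test_that("transport plan matches the frozen LP oracle on worked instances", {
  pl <- solve_transport(c(0.6, 0.3, 0.1), c(0.55, 0.32, 0.13))
  expect_equal(pl$x, rbind(c(0.55, 0.05, 0), c(0, 0.27, 0.03), c(0, 0, 0.1)),
               tolerance = 1e-9)
  expect_equal(pl$cost, 0.48, tolerance = 1e-9)

  pl2 <- solve_transport(c(0.2, 0.3, 0.5), c(0.3, 0.3, 0.4))
  expect_equal(pl2$x, rbind(c(0.2, 0, 0), c(0.1, 0.2, 0), c(0, 0.1, 0.4)),
               tolerance = 1e-9)
  expect_equal(pl2$cost, 1.2, tolerance = 1e-9)

  # mass cascades through the middle category rather than jumping
  pl3 <- solve_transport(c(0.5, 0.5, 0), c(0, 0.5, 0.5))
  expect_equal(pl3$x, rbind(c(0, 0.5, 0), c(0, 0, 0.5), c(0, 0, 0)),
               tolerance = 1e-9)
  expect_equal(pl3$cost, 6, tolerance = 1e-9)
})

test_that("closed-form nets agree with the LP and with hand values", {
  expect_equal(unname(closed_form_net(c(0.6, 0.3, 0.1), c(0.55, 0.32, 0.13))),
               c(0.05, 0.03), tolerance = 1e-12)
  expect_equal(unname(closed_form_net(c(0.5, 0.5, 0), c(0, 0.5, 0.5))),
               c(0.5, 0.5), tolerance = 1e-12)
  p <- c(0.3, 0.4, 0.3)
  expect_equal(unname(closed_form_net(p, p)), c(0, 0), tolerance = 1e-15)
})

test_that("LP and closed-form nets agree on random instances across valid cost triples", {
  set.seed(421)
  P <- rprob3(400); Q <- rprob3(400)
  triples <- list(c(0, 6, 17), c(0, 1, 3), c(0, 10, 25))
  for (i in seq_len(nrow(P))) {
    ref <- closed_form_net(P[i, ], Q[i, ])
    for (tr in triples) {
      pl <- solve_transport(P[i, ], Q[i, ], cost_matrix(tr))
      nets <- bmitrans:::plan_net_flows(pl$x)
      expect_equal(nets, unname(ref), tolerance = 1e-9)
    }
  }
})

test_that("marginal validation renormalizes small drift and rejects large", {
  p <- c(0.6, 0.3, 0.1) * (1 + 2e-7)
  pl <- solve_transport(p, c(0.55, 0.32, 0.13))
  expect_equal(sum(pl$x), 1, tolerance = 1e-9)
  expect_error(solve_transport(c(0.6, 0.3, 0.2), c(0.55, 0.32, 0.13)),
               "sum to 1")
})

test_that("net probabilities divide by the favored origin category", {
  # 100 normal-weight 18-year-olds, a net of 7 moving up: 7%
  p <- c(100, 50, 0) / 150
  q <- c(93, 57, 0) / 150
  tab <- net_probabilities(closed_form_net(p, q), p, age = 18)
  up1 <- tab[tab$boundary == "normal_overweight" & tab$direction == "up", ]
  expect_equal(up1$net_prob, 0.07, tolerance = 1e-12)
  down1 <- tab[tab$boundary == "normal_overweight" & tab$direction == "down", ]
  expect_equal(down1$net_prob, 0)

  tab2 <- net_probabilities(closed_form_net(c(0.6, 0.3, 0.1), c(0.55, 0.32, 0.13)),
                            c(0.6, 0.3, 0.1))
  expect_equal(tab2$net_prob[tab2$boundary == "normal_overweight" &
                               tab2$direction == "up"], 0.05 / 0.6,
               tolerance = 1e-12)
  expect_equal(tab2$net_prob[tab2$boundary == "overweight_obese" &
                               tab2$direction == "up"], 0.03 / 0.3,
               tolerance = 1e-12)
})

test_that("per boundary, at most one direction is ever nonzero", {
  set.seed(77)
  P <- rprob3(200); Q <- rprob3(200)
  for (i in seq_len(nrow(P))) {
    tab <- net_probabilities(closed_form_net(P[i, ], Q[i, ]), P[i, ])
    expect_true(all(tab$net_prob >= 0 & tab$net_prob <= 1))
    for (b in unique(tab$boundary)) {
      expect_equal(min(tab$net_prob[tab$boundary == b]), 0)
    }
  }
})

test_that("projection inverts estimation exactly and chains across the grid", {
  set.seed(5)
  p <- as.vector(rprob3(1)); q <- as.vector(rprob3(1))
  tab <- net_probabilities(closed_form_net(p, q), p, age = 30)
  expect_equal(unname(project_forward(p, tab)), q, tolerance = 1e-12)
  expect_equal(unname(project_forward(p, c(0, 0))), p)

  # chained projection from p(2) reproduces the whole fitted surface
  fx <- fitted_synthetic(n = 2000, seed = 31)
  cv <- fit_prevalence(fx$records)
  tab <- net_transition_table(cv)
  p <- cv$P[1, ]
  for (a in cv$ages[-length(cv$ages)]) {
    p <- project_forward(p, tab[tab$age == a, ])
    expect_equal(unname(p), unname(cv$P[match(a + 1, cv$ages), ]),
                 tolerance = 1e-12)
  }
})

test_that("degenerate ties resolve to the monotone plan", {
  # p and q permuted mass: many optimal plans share the cost; the monotone
  # plan is the one with no crossing flows
  pl <- solve_transport(c(0.5, 0, 0.5), c(0, 0.5, 0.5), cost_matrix(c(0, 1, 3)))
  x <- pl$x
  expect_equal(x[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(x[3, 3], 0.5, tolerance = 1e-12)
  # no simultaneous up and down flows across the same boundary
  up1 <- x[1, 2] + x[1, 3]; down1 <- x[2, 1] + x[3, 1]
  expect_equal(min(up1, down1), 0, tolerance = 1e-12)
})

test_that("general K transport works with banded convex costs", {
  p <- c(0.4, 0.3, 0.2, 0.1); q <- c(0.1, 0.2, 0.3, 0.4)
  cm <- cost_matrix(c(0, 1, 3, 7), K = 4)
  pl <- solve_transport(p, q, cm)
  expect_equal(rowSums(pl$x), p, tolerance = 1e-9)
  expect_equal(colSums(pl$x), q, tolerance = 1e-9)
})
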