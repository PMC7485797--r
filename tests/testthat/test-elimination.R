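test_that("degenerate two-cause inputs return crude = net", {
  expect_equal(solve_two_cause(0.5, 0), c(q1 = 0.5, q2 = 0))
  expect_equal(solve_two_cause(0, 0.4), c(q1 = 0, q2 = 0.4))
  expect_equal(solve_two_cause(0, 0), c(q1 = 0, q2 = 0))
})

test_that("symmetric crude proportions give the closed-form net probability", {
  q <- solve_two_cause(0.3, 0.3)
  expect_equal(unname(q["q1"]), 1 - sqrt(0.4), tolerance = 1e-14)
  expect_equal(unname(q["q2"]), 1 - sqrt(0.4), tolerance = 1e-14)
})

test_that("the quadratic solution matches the bisection oracle", {
  # the pooled-table headline pair: cannibalism against everything else
  q <- solve_two_cause(0.701, 0.236)
  oracle <- bisect_two_cause(0.701, 0.236)
  expect_equal(unname(q["q2"]), unname(oracle["q2"]), tolerance = 1e-10)
  expect_equal(unname(q["q1"]), unname(oracle["q1"]), tolerance = 1e-10)
  expect_equal(unname(round(q["q2"], 3)), 0.306)
})

test_that("no survivors is a domain error", {
  expect_error(solve_two_cause(0.6, 0.4), "no survivors")
  expect_error(solve_two_cause(0.7, 0.5), "no survivors")
  expect_error(solve_two_cause(-0.1, 0.2), "non-negative")
})

test_that("roots satisfy the quadratic and joint-survival system on a grid", {
  vals <- seq(0.025, 0.95, length.out = 20)
  for (D1 in vals) for (D2 in vals) {
    if (D1 + D2 >= 0.99) next
    q <- solve_two_cause(D1, D2)
    q1 <- unname(q["q1"]); q2 <- unname(q["q2"])
    # root of the quadratic itself
    expect_lt(abs(D1 * q2^2 - (D1 + D2) * q2 + D2 * (D1 + D2)), 1e-10)
    # joint survival
    expect_lt(abs((1 - q1) * (1 - q2) - (1 - D1 - D2)), 1e-10)
    # risk proportionality
    expect_lt(abs(q1 / q2 - D1 / D2), 1e-8 * (1 + D1 / D2))
    # probabilities
    expect_true(q1 >= 0 && q1 < 1 && q2 >= 0 && q2 < 1)
    # net dominates crude
    expect_gte(q1, D1 - 1e-12)
    expect_gte(q2, D2 - 1e-12)
    # independent bisection oracle
    oracle <- bisect_two_cause(D1, D2)
    expect_lt(abs(q2 - unname(oracle["q2"])), 1e-10)
    # symmetry: swapping the causes swaps the roots
    qs <- solve_two_cause(D2, D1)
    expect_equal(unname(qs["q1"]), q2, tolerance = 1e-12)
    expect_equal(unname(qs["q2"]), q1, tolerance = 1e-12)
  }
})

test_that("net probabilities reduce to crude for a single operating cause", {
  expect_equal(unname(net_probabilities(c(a = 0.4, b = 0))), c(0.4, 0))
  q <- net_probabilities(c(a = 0.3, b = 0.3))
  expect_equal(unname(q), rep(1 - sqrt(0.4), 2), tolerance = 1e-12)
})

test_that("net probabilities for the pooled totals match the oracle", {
  q <- net_probabilities(table1_totals)
  for (i in seq_along(table1_totals)) {
    oracle <- bisect_two_cause(table1_totals[i],
                               sum(table1_totals[-i]))
    expect_equal(unname(q[i]), unname(oracle["q1"]), tolerance = 1e-9,
                 label = names(table1_totals)[i])
  }
  # the two-cause case of the simultaneous proportional-risk system agrees
  pair <- c(cannibalism = 0.701, rest = 0.236)
  expect_equal(unname(net_probabilities(pair)),
               unname(simultaneous_net(pair)), tolerance = 1e-9)
})

test_that("joint mortality is the complement of the survival product", {
  expect_identical(joint_mortality(numeric(0)), 0)
  expect_equal(joint_mortality(c(0.5, 0.5)), 0.75)
  expect_equal(joint_mortality(0.3), 0.3)
  set.seed(7)
  q <- runif(5, 0, 0.9)
  expect_equal(joint_mortality(q), 1 - prod(1 - q), tolerance = 1e-15)
  expect_error(joint_mortality(c(0.5, 1)), "\\[0, 1\\)")
})

test_that("crude combinations reproduce the printed whole-percent claims", {
  expect_equal(
    crude_combination(table1_totals,
                      c("cannibalism", "unknown", "plant_defense")), 92)
  expect_equal(crude_combination(table1_totals, "plant_defense"), 17)
  expect_equal(crude_combination(table1_totals, names(table1_totals)), 94)
  expect_error(crude_combination(table1_totals, character(0)), "non-empty")
  expect_error(crude_combination(table1_totals, "weather"), "unknown cause")
})

test_that("irreplaceable mortality is bounded by the crude proportion", {
  # removing a cause that kills nothing changes nothing
  D <- c(a = 0, b = 0.4, c = 0.2)
  expect_equal(irreplaceable(D, "a"), 0)
  # a lone cause is wholly irreplaceable
  expect_equal(irreplaceable(c(a = 0.35, b = 0), "a"), 0.35, tolerance = 1e-12)

  set.seed(99)
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    D <- stats::runif(k)
    D <- D / sum(D) * stats::runif(1, 0.05, 0.98)
    D[sample.int(k, 1)] <- 0  # always include a zero-D cause
    names(D) <- paste0("c", seq_len(k))
    e <- eliminate(D)
    expect_true(all(e$irreplaceable >= 0))
    expect_true(all(e$irreplaceable <= e$D + 1e-9))
    expect_equal(e$irreplaceable[e$D == 0], rep(0, sum(e$D == 0)))
  }
})

test_that("irreplaceable mortality grows with the focal crude proportion", {
  others <- 0.3
  grid <- seq(0.01, 0.6, by = 0.01)
  irr <- vapply(grid, function(d) {
    irreplaceable(c(focal = d, rest = others), "focal")
  }, numeric(1))
  expect_true(all(diff(irr) > -1e-12))
})

test_that("per-stage elimination agrees with totals on a one-stage table", {
  counts <- data.frame(stage = "egg", l_x = 1000, d_parasitism = 0,
                       d_plant_defense = 300, d_cannibalism = 200,
                       d_unknown = 0, d_pathogens = 0)
  fit <- suppressWarnings(mdlt(counts, skip_empty_stages = TRUE))
  for (cs in c("plant_defense", "cannibalism")) {
    expect_equal(irreplaceable(fit, cs, mode = "per_stage"),
                 irreplaceable(fit, cs, mode = "totals"), tolerance = 1e-12,
                 label = cs)
  }
})

test_that("eliminate() on a fitted table reports both modes within bounds", {
  fit <- mdlt_from_aq(table1_aq, decrements = table1_decrements)
  for (mode in c("totals", "per_stage")) {
    e <- eliminate(fit, mode = mode)
    expect_identical(attr(e, "mode"), mode)
    expect_true(all(e$irreplaceable >= 0))
    expect_true(all(e$q >= 0 & e$q < 1))
    expect_output(print(e), "Elimination-of-cause")
    if (mode == "totals") {
      # the per-cause ceiling is a totals-mode property; stage-wise
      # elimination lets replacement act across stages
      expect_true(all(e$irreplaceable <= e$D + 1e-9))
      expect_true(all(e$q >= e$D - 1e-12))  # net dominates crude
    } else {
      expect_true(all(e$irreplaceable <= attr(e, "total_mortality") + 1e-9))
    }
  }
  # cannibalism dominates the irreplaceable ranking in the pooled table
  e <- eliminate(fit, mode = "totals")
  expect_identical(e$cause[which.max(e$irreplaceable)], "cannibalism")
})

test_that("combination tables report crude and net joint mortality", {
  tab <- combination_table(table1_totals,
                           subsets = list(trio = c("cannibalism", "unknown",
                                                   "plant_defense"),
                                          all = names(table1_totals)))
  expect_equal(tab["trio", "crude_pct"], 92)
  expect_equal(tab["all", "crude_pct"], 94)
  expect_true(all(tab$net_joint >= 0 & tab$net_joint < 1))
  q <- net_probabilities(table1_totals)
  expect_equal(tab["all", "net_joint"], 1 - prod(1 - q), tolerance = 1e-12)
})
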