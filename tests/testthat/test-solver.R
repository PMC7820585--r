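test_that("terminal fitness is the stated increasing linear function", {
  p <- model_params()
  g <- build_grids(p)
  f <- terminal_fitness(g, p)
  expect_equal(f$values[gi(g$s, 10), 1], 10)
  expect_equal(f$values[gi(g$s, -50), 50], -50)
  f2 <- terminal_fitness(g, p, slope = 2, intercept = 1)
  expect_equal(f2$values[gi(g$s, 0), 1], 1)
  expect_error(terminal_fitness(g, p, slope = 0), "positive")
  expect_error(terminal_fitness(g, p, slope = -1), "positive")
})

test_that("transition kernel rows are the stated outcome mixtures", {
  p0 <- model_params(r = 0)
  g <- build_grids(p0)
  law0 <- perturbation_law(p0, 0, p0$sigma^2)
  # alone, r = 0: point mass at the current state
  row <- build_kernel("alone", 3, 0, p0, law0)
  expect_equal(row[gi(g$s, 3)], 1)
  expect_equal(sum(row), 1)
  # exploit, r = 0, from s = -2: 2/3 at 3, 1/3 at -12
  row <- build_kernel("exploit", -2, 0, p0, law0)
  expect_equal(row[gi(g$s, 3)], 2 / 3)
  expect_equal(row[gi(g$s, -12)], 1 / 3)
  # cooperate, r = 0, s = 0, p = 0.5: half at +0.2, half at -1
  row <- build_kernel("cooperate", 0, 0.5, p0, law0)
  expect_equal(row[gi(g$s, 0.2)], 0.5)
  expect_equal(row[gi(g$s, -1)], 0.5)

  # with noise, rows integrate to exactly 1 (CDF discretisation) and
  # out-of-range mass accumulates at the boundary
  p <- model_params(r = 0.5)
  law <- perturbation_law(p, 0, p$sigma^2)
  for (s in c(-49, -10, 0, 25, 49.5)) {
    for (a in action_labels()) {
      row <- build_kernel(a, s, 0.3, p, law)
      expect_equal(sum(row), 1, tolerance = 1e-9)
    }
  }
  # a law whose noise is centred far below the grid pushes most mass out of
  # range; it must be folded into the lowest cell, not lost
  law_low <- perturbation_law(p, -80, p$sigma^2)
  row <- build_kernel("alone", -49.5, 0, p, law_low)
  expect_gt(row[1], 0.9)
  expect_equal(sum(row), 1, tolerance = 1e-9)
})

test_that("backward induction equals exhaustive path enumeration at r = 0", {
  # tiny grids, short horizons: the oracle enumerates every outcome tree
  cfgs <- list(
    model_params(r = 0, s_min = -2, s_max = 2, s_steps = 5, p_steps = 3,
                 T = 3, omega = 2),
    model_params(r = 0, s_min = -2, s_max = 2, s_steps = 5, p_steps = 5,
                 T = 3, beta = 2, pi = 1, gamma = 0.5, omega = 1),
    model_params(r = 0, s_min = -1, s_max = 1, s_steps = 3, p_steps = 3,
                 T = 2, alpha = 1.5))
  for (p in cfgs) {
    pol <- solve_policy(p, mu0 = 0, sigma0 = 0)
    ora <- oracle_solve(p)
    expect_equal(pol$values, ora$values, tolerance = 1e-12)
    expect_identical(pol$actions, ora$actions)
  }
})

test_that("identity parameters collapse every action to foraging alone", {
  # alpha = 1, beta = pi = 0, omega = 0, r = 0: all payoffs are 0, so the
  # value function reproduces terminal fitness and ties resolve to alone
  p <- model_params(r = 0, alpha = 1, beta = 0, pi = 0, omega = 0,
                    s_steps = 101, p_steps = 11, T = 5)
  pol <- solve_policy(p)
  g <- build_grids(p)
  expect_equal(pol$values, terminal_fitness(g, p)$values)
  expect_true(all(pol$actions == 1L))
})

test_that("value function never decreases with resources", {
  pol <- default_policy()
  expect_true(all(diff(pol$values) > -1e-9))
})

test_that("policies are invariant to the terminal intercept and to joint
           scaling of slope and penalty", {
  p <- coarse_params()
  base <- solve_policy(p)
  shifted <- solve_policy(p, intercept = 7)
  expect_identical(base$actions, shifted$actions)
  p2 <- coarse_params(omega = 10) # omega doubled with the slope
  scaled <- solve_policy(p2, slope = 2)
  expect_identical(base$actions, scaled$actions)
})

test_that("default policy reproduces the three-region map", {
  pol <- default_policy()
  cr <- exploitation_critical_resource(pol)
  # unconditional exploit band ends in the vicinity of the threshold
  expect_true(cr$band_edge >= -5 && cr$band_edge <= 5)
  # exploit at desperately low resources at EVERY trustworthiness
  i <- gi(pol$s, -10)
  expect_true(all(pol$actions[i, ] == 3L))
  # high resources: cooperate when trustworthy, forage alone when not
  i <- gi(pol$s, 40)
  expect_identical(pol$actions[i, gi(pol$q, 1)], 2L)
  expect_identical(pol$actions[i, gi(pol$q, 0.2)], 1L)
  # the map stabilises well before t = 1
  expect_true(is.na(pol$last_change_t) || pol$last_change_t > 1)
})

test_that("cooperation frontier sits at 1/alpha and falls as alpha rises", {
  fr <- cooperation_frontier(default_policy(), s_probe = 40)
  expect_lt(abs(fr - 1 / 1.2), 0.01 + 1e-9)
  fr_low <- cooperation_frontier(cached_policy(
    "alpha1.05", model_params(alpha = 1.05)), s_probe = 40)
  fr_high <- cooperation_frontier(cached_policy(
    "alpha1.3", model_params(alpha = 1.3)), s_probe = 40)
  expect_gt(fr_low, fr)   # weaker cooperation needs more trust
  expect_lt(fr_high, fr)  # stronger cooperation needs less
})

test_that("exact payoff ties resolve to the sentinel, not exploitation", {
  # pi = 0, gamma = 1: exploitation is certain to 'fail' at zero cost, an
  # exact tie with foraging alone, resolved by the alone-first preference
  p <- coarse_params(pi = 0, gamma = 1)
  pol <- solve_policy(p)
  expect_equal(sum(pol$actions == 3L), 0)
  cr <- exploitation_critical_resource(pol)
  expect_true(is.na(cr$band_edge))
  expect_true(all(is.na(cr$per_trust)))
})

test_that("positive expected exploitation payoff puts exploit at both
           resource extremes with a safe interval between", {
  # gamma = 0.25: (1 - gamma) * beta = 3.75 > gamma * pi = 2.5
  pol <- cached_policy("gamma0.25", model_params(gamma = 0.25))
  j <- gi(pol$q, 1)
  col <- pol$actions[, j]
  expect_identical(col[gi(pol$s, -20)], 3L) # desperately low: exploit
  expect_identical(col[gi(pol$s, 35)], 3L)  # comfortably high: exploit
  expect_identical(col[gi(pol$s, 10)], 2L)  # in between: play safe
})

test_that("high social mobility pushes the exploit band far left", {
  pol8 <- cached_policy("r0.8", model_params(r = 0.8))
  cr8 <- exploitation_critical_resource(pol8)
  cr1 <- exploitation_critical_resource(default_policy())
  expect_true(is.na(cr8$band_edge) || cr8$band_edge < cr1$band_edge - 1)
})

test_that("grid mismatches are caught", {
  p <- coarse_params()
  g <- build_grids(p)
  law <- perturbation_law(p, 0, p$sigma^2)
  kern <- desperation:::transition_kernels(g, p, law)
  f_bad <- terminal_fitness(build_grids(model_params()), model_params())
  expect_error(backward_step(f_bad, p, kern, g), "dimensions")
})
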