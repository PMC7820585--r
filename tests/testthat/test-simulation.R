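test_that("population initialisation draws the stated distribution", {
  p <- model_params()
  pop <- init_population(p, mu = 5.5, sigma = 4, seed = 11)
  expect_length(pop$resources, 500)
  expect_lt(abs(mean(pop$resources) - 5.5), 3 * 4 / sqrt(500))
  expect_true(all(pop$trust == 1))
  # degenerate spread: everyone exactly at the mean
  pop0 <- init_population(p, mu = 7, sigma = 0, seed = 1)
  expect_true(all(pop0$resources == 7))
  # determinism
  expect_equal(init_population(p, seed = 3), init_population(p, seed = 3))
  expect_error(init_population(model_params(N = 501), seed = 1),
               "divisible")
})

test_that("agents follow the policy at their state and trust estimate", {
  pol <- default_policy()
  p <- model_params()
  pop <- init_population(p, seed = 1)
  pop$resources[1:3] <- c(-10, 40, 40)
  pop$trust[1:3] <- c(0.5, 1, 0.2)
  acts <- choose_actions(pop, pol)
  expect_identical(acts[1], 3L) # desperate: exploit at any trust
  expect_identical(acts[2], 2L) # rich and trusting: cooperate
  expect_identical(acts[3], 1L) # rich and distrustful: forage alone
})

test_that("group payoff resolution follows the interaction rules", {
  p <- model_params()
  groups <- matrix(1:10, nrow = 5) # two groups of five
  # all cooperators: each nets x * (alpha - 1)
  res <- resolve_groups(rep(2L, 10), groups, p)
  expect_equal(res$payoff, rep(0.2, 10))
  expect_equal(res$active_exploiters, 0L)
  # all exploiters: nothing to take, everyone nets 0
  res <- resolve_groups(rep(3L, 10), groups, p)
  expect_equal(res$payoff, rep(0, 10))
  expect_equal(res$active_exploiters, 0L)
  # 2 exploiters + 3 cooperators, punishment off: exactly one exploiter
  # collects beta, the other is demoted to 0, cooperators pay x
  pg0 <- model_params(gamma = 0)
  set.seed(5)
  res <- resolve_groups(c(3L, 3L, 2L, 2L, 2L, rep(1L, 5)), groups, pg0)
  expect_equal(sort(res$payoff[1:2]), c(0, 5))
  expect_equal(res$payoff[3:5], rep(-1, 3))
  expect_equal(res$payoff[6:10], rep(0, 5))
  expect_equal(res$active_exploiters, 1L)
})

test_that("group payoffs satisfy the resolution invariants on random
           configurations", {
  p <- model_params(N = 50, n = 5, K = 20)
  set.seed(99)
  for (rep in 1:20) {
    acts <- sample(1:3, 50, replace = TRUE)
    groups <- desperation:::form_groups(50, 5)
    res <- resolve_groups(acts, groups, p)
    for (g in seq_len(ncol(groups))) {
      idx <- groups[, g]
      a <- acts[idx]
      pay <- res$payoff[idx]
      expect_true(all(pay[a == 1L] == 0)) # aloners always net zero
      if (!any(a == 2L)) {
        expect_true(all(pay == 0)) # no cooperator: nothing happens
      } else if (any(a == 3L)) {
        # one active exploiter nets beta or -pi, the rest demoted to 0
        expect_true(all(pay[a == 2L] == -p$x))
        epay <- pay[a == 3L]
        expect_lte(sum(epay != 0), 1)
        expect_true(all(epay %in% c(0, p$beta, -p$pi)))
      } else {
        expect_true(all(pay[a == 2L] == p$x * (p$alpha - 1)))
      }
    }
  }
})

test_that("trust estimation applies the sampling combinatorics", {
  p <- model_params()
  pop <- init_population(p, seed = 1)
  # nobody exploits: k = 0 for every agent, full trust
  set.seed(2)
  expect_true(all(update_trust(pop, rep(1L, 500), p) == 1))
  # everybody exploits: k = K, zero trust
  expect_true(all(update_trust(pop, rep(3L, 500), p) == 0))
  p_bad <- model_params()
  p_bad$K <- 500 # bypass constructor validation to hit the guard
  expect_error(update_trust(pop, rep(1L, 500), p_bad), "exceed")
  # k'=50 of N=500, n=5: p-hat = 1 - C(449,4)/C(499,4), about 0.345
  phat <- desperation:::prob_group_exploited(50, 500, 5)
  oracle <- 1 - (449 / 499) * (448 / 498) * (447 / 497) * (446 / 496)
  expect_equal(phat, oracle, tolerance = 1e-12)
  expect_equal(round(phat, 3), 0.345)
  # saturation: more exploiters than non-partners forces p-hat = 1
  expect_equal(desperation:::prob_group_exploited(497, 500, 5), 1)
})

test_that("observation samples are unbiased for the exploiter fraction", {
  set.seed(7)
  is_expl <- rep(c(TRUE, FALSE), c(100, 400)) # true fraction 0.2
  ks <- replicate(40, desperation:::sample_exploit_counts(is_expl, 50))
  khat <- mean(ks) / 50
  se <- sd(ks / 50) / sqrt(length(ks))
  expect_lt(abs(khat - 0.2), 3 * se)
})

test_that("perturbation moves and clamps resources as specified", {
  p0 <- model_params(r = 0)
  pop <- init_population(p0, seed = 4)
  expect_equal(apply_perturbation(pop, p0)$resources, pop$resources)
  # variance-preserving shuffle holds the moments of a large population
  pbig <- model_params(r = 0.3, N = 1e5)
  pop <- init_population(pbig, mu = 5, sigma = 3, seed = 8)
  out <- apply_perturbation(pop, pbig)
  expect_lt(abs(mean(out$resources) - mean(pop$resources)),
            3 * 3 / sqrt(1e5))
  expect_lt(abs(var(out$resources) - var(pop$resources)),
            3 * sqrt(2 / 1e5) * 9)
  # anchored reference: variance relaxes towards the anchor
  out2 <- apply_perturbation(pop, pbig, sigma_ref = 6)
  expected <- (1 - 0.3)^2 * var(pop$resources) + (1 - (1 - 0.3)^2) * 36
  expect_equal(var(out2$resources), expected, tolerance = 0.05)
  # complete mobility: next resources uncorrelated with current
  p1 <- model_params(r = 1, N = 1e5)
  out3 <- apply_perturbation(init_population(p1, mu = 5, sigma = 3,
                                             seed = 9), p1)
  expect_lt(abs(cor(out3$resources,
                    init_population(p1, mu = 5, sigma = 3,
                                    seed = 9)$resources)),
            3 / sqrt(1e5))
})

test_that("inequality shocks rescale dispersion exactly about the mean", {
  p <- model_params()
  pop <- init_population(p, seed = 10)
  m <- mean(pop$resources)
  same <- apply_shock(pop, sd(pop$resources))
  expect_equal(same$resources, pop$resources)
  shocked <- apply_shock(pop, 2)
  expect_equal(mean(shocked$resources), m)
  expect_equal(sd(shocked$resources), 2)
  flat <- apply_shock(pop, 0)
  expect_true(all(abs(flat$resources - m) < 1e-12))
  expect_error(apply_shock(flat, 1), "degenerate")
})

test_that("one step of an all-rich trusting population is pure cooperation
           with the exact surplus", {
  p <- model_params(r = 0)
  pop <- init_population(p, mu = 40, sigma = 0, seed = 1)
  pol <- default_policy()
  out <- sim_step(pop, pol, p)
  st <- attr(out, "step_stats")
  expect_equal(st$n_coop, 500)
  expect_equal(out$resources, rep(40.2, 500)) # +x*(alpha-1) each, no noise
  expect_true(all(out$trust == 1))
})

test_that("an all-desperate population exploits with nothing to take", {
  p <- model_params(r = 0)
  pop <- init_population(p, mu = -20, sigma = 0, seed = 1)
  out <- sim_step(pop, default_policy(), p)
  st <- attr(out, "step_stats")
  expect_equal(st$n_exploit, 500)
  expect_equal(st$active_exploiters, 0L) # no cooperator anywhere
  expect_equal(out$resources, rep(-20, 500)) # all demoted, nothing changes
  expect_true(all(out$trust == 0))
})

test_that("traces are deterministic given the seed and internally
           consistent", {
  p <- model_params()
  pol <- default_policy()
  tr1 <- run_simulation(p, policy = pol, steps = 12, seed = 21)
  tr2 <- run_simulation(p, policy = pol, steps = 12, seed = 21)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_true(all(tr1$n_coop + tr1$n_exploit + tr1$n_alone == 500))
  expect_true(all(tr1$frac_below_threshold >= 0 &
                  tr1$frac_below_threshold <= 1))
  tr3 <- run_simulation(p, policy = pol, steps = 12, seed = 22)
  expect_false(identical(tr1$mean_s, tr3$mean_s))
})
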