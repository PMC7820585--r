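#' Initialise a population of agents
#'
#' Draws `N` agents whose resources are Gaussian with mean `mu` and standard
#' deviation `sigma` (clamped to the resource grid bounds). Agents start with
#' no observations of others, so their trust estimate is set to
#' `params$initial_trust` (default 1: before seeing any exploitation there is
#' no reason to distrust; the first round of observed behaviour then updates
#' it).
#'
#' @param params a [model_params()] object; `N` must be divisible by `n`.
#' @param mu,sigma initial resource distribution (default: from `params`).
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `population`: list with numeric vectors
#'   `resources` and `trust`, integer vector `last_action` (`NA` before the
#'   first step), and the step counter `t = 0`.
#' @export
init_population <- function(params, mu = params$mu, sigma = params$sigma,
                            seed = NULL) {
  validate_params(params)
  if (params$N %% params$n != 0)
    stop("population size N must be divisible by the group size n ",
         "(partial interaction groups are not supported)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- stats::rnorm(params$N, mu, sigma)
  res <- pmin(pmax(res, params$s_min), params$s_max)
  structure(list(resources = res,
                 trust = rep(params$initial_trust, params$N),
                 last_action = rep(NA_integer_, params$N),
                 t = 0L),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Population of %d agents at t = %d\n", length(x$resources), x$t))
  cat(sprintf("  resources: mean %.3f, sd %.3f; below 0: %.1f%%\n",
              mean(x$resources), stats::sd(x$resources),
              100 * mean(x$resources < 0)))
  cat(sprintf("  trust: mean %.3f\n", mean(x$trust)))
  invisible(x)
}

#' Look up each agent's optimal action
#'
#' Each agent follows the optimal policy for its current resources and its
#' own trust estimate, snapping both to the nearest grid point of the policy
#' map.
#'
#' @param pop a [init_population()] object.
#' @param policy a [solve_policy()] result.
#' @return Integer vector of action codes (1 = alone, 2 = cooperate,
#'   3 = exploit), one per agent.
#' @export
choose_actions <- function(pop, policy) {
  i <- snap_index(pop$resources, policy$s)
  j <- snap_index(pop$trust, policy$q)
  policy$actions[cbind(i, j)]
}

# Random partition of the N agents into N/n interaction groups, re-formed
# every step to avoid assortment. Columns of the returned matrix are groups.
form_groups <- function(N, n) matrix(sample.int(N), nrow = n)

#' Resolve interaction-group payoffs
#'
#' Applies the group interaction rules to chosen actions. Per group: agents
#' foraging alone net 0. If the group contains at least one exploiter and at
#' least one cooperator, one exploiter chosen uniformly at random is active
#' (the rest are deemed to forage alone: there is nothing left to take); the
#' active exploiter nets `beta` with probability `1 - gamma` and `-pi`
#' otherwise, and every cooperator in the group nets `-x` (an exploiter's
#' presence spoils the cooperative surplus whether or not the exploiter is
#' punished). With no exploiter, cooperators each net `x * (alpha - 1)`.
#' With no cooperator, all exploiters are deemed to forage alone (net 0).
#'
#' @param actions integer action codes per agent (from [choose_actions()]).
#' @param groups group matrix from the current step (one column per group).
#' @param params a [model_params()] object.
#' @return List with `payoff` (numeric per agent) and
#'   `active_exploiters` (count of exploiters that actually attempted
#'   exploitation this step).
#' @export
resolve_groups <- function(actions, groups, params) {
  payoff <- numeric(length(actions))
  active <- 0L
  for (g in seq_len(ncol(groups))) {
    idx <- groups[, g]
    a <- actions[idx]
    coop <- idx[a == ACT_COOPERATE]
    expl <- idx[a == ACT_EXPLOIT]
    if (length(coop) == 0) next # exploiters with no-one to rob forage alone
    if (length(expl) > 0) {
      who <- if (length(expl) == 1) expl else sample(expl, 1)
      payoff[who] <- if (stats::runif(1) < params$gamma) -params$pi
                     else params$beta
      payoff[coop] <- -params$x
      active <- active + 1L
    } else {
      payoff[coop] <- params$x * (params$alpha - 1)
    }
  }
  list(payoff = payoff, active_exploiters = active)
}

# Probability that at least one of an agent's n-1 prospective partners,
# drawn from the N-1 other agents of whom k' are exploiters, is an
# exploiter: 1 - C(N-1-k', n-1) / C(N-1, n-1). Vectorised over k'.
prob_group_exploited <- function(kprime, N, n) {
  p <- 1 - exp(lchoose(N - 1 - kprime, n - 1) - lchoose(N - 1, n - 1))
  p[kprime > N - 1 - (n - 1)] <- 1
  pmin(pmax(p, 0), 1)
}

#' Update social trust by finite sampling
#'
#' Each agent observes the decisions (the chosen actions of the
#' just-completed step) of `K` other agents sampled without replacement,
#' counts the `k` exploiters among them, scales up to an unbiased population
#' estimate `k' = round(k * N / K)`, and converts it by combinatorics into
#' the probability `p-hat` that a cooperating group of size `n` would contain
#' at least one exploiter. Trust is `1 - p-hat`.
#'
#' @param pop a `population` object.
#' @param actions the chosen action codes of the completed step.
#' @param params a [model_params()] object.
#' @return Numeric vector of updated trust values in `[0, 1]`.
#' @export
update_trust <- function(pop, actions, params) {
  N <- params$N
  K <- params$K
  if (K > N - 1)
    stop("'K' cannot exceed N - 1", call. = FALSE)
  k <- sample_exploit_counts(actions == ACT_EXPLOIT, K)
  kprime <- pmin(pmax(round(k * N / K), 0), N)
  1 - prob_group_exploited(kprime, N, params$n)
}

# For each agent, the number of exploiters among K distinct other agents
# sampled without replacement (self excluded).
sample_exploit_counts <- function(is_expl, K) {
  N <- length(is_expl)
  vapply(seq_len(N), function(i) {
    obs <- sample.int(N - 1L, K)
    obs <- obs + (obs >= i) # skip self
    sum(is_expl[obs])
  }, integer(1))
}

#' Apply the resource perturbation to a population
#'
#' Shuffles every agent's resources towards the current population mean:
#' `s' = (1 - r) * s + r * eps`, with `eps` drawn i.i.d. per agent from the
#' [perturbation_law()] evaluated at the current population mean and, by
#' default, the current population variance. Results are clamped to the
#' resource grid bounds.
#'
#' When `sigma_ref` is supplied, the noise scale is anchored to that
#' reference sd instead of the realised variance. The current-variance form
#' preserves whatever variance the step's payoffs injected, so dispersion
#' performs a one-sided random walk under repeated punishments; the anchored
#' form makes the perturbation an Ornstein-Uhlenbeck-style restoring force
#' (population variance relaxes geometrically to `sigma_ref^2` while the
#' mean is free to drift with the cooperative surplus), which is what
#' [run_simulation()] uses.
#'
#' @param pop a `population` object.
#' @param params a [model_params()] object.
#' @param sigma_ref optional reference sd anchoring the noise scale.
#' @return The population with updated resources.
#' @export
apply_perturbation <- function(pop, params, sigma_ref = NULL) {
  if (params$r == 0) return(pop)
  law <- perturbation_law(params, mean(pop$resources),
                          if (is.null(sigma_ref)) stats::var(pop$resources)
                          else sigma_ref^2)
  eps <- stats::rnorm(length(pop$resources), law$noise_mean, law$noise_sd)
  s <- law$persistence * pop$resources + law$r * eps
  pop$resources <- pmin(pmax(s, params$s_min), params$s_max)
  pop
}

#' Advance the population by one time step
#'
#' Phase order: form interaction groups; every agent chooses the policy
#' action for its resources and its trust estimate from the end of the
#' previous step; group payoffs are resolved and added to resources
#' (clamped); the mean-reverting perturbation is applied; finally each agent
#' re-estimates trust from the decisions just observed.
#'
#' @param pop a `population` object.
#' @param policy a [solve_policy()] result.
#' @param params a [model_params()] object.
#' @param sigma_ref optional anchored noise scale passed to
#'   [apply_perturbation()].
#' @return The updated `population`, with an attribute `step_stats` (named
#'   list: chosen action counts, active exploiter count).
#' @export
sim_step <- function(pop, policy, params, sigma_ref = NULL) {
  groups <- form_groups(params$N, params$n)
  acts <- choose_actions(pop, policy)
  res <- resolve_groups(acts, groups, params)
  pop$resources <- pmin(pmax(pop$resources + res$payoff,
                             params$s_min), params$s_max)
  pop <- apply_perturbation(pop, params, sigma_ref)
  pop$trust <- update_trust(pop, acts, params)
  pop$last_action <- acts
  pop$t <- pop$t + 1L
  attr(pop, "step_stats") <- list(
    n_alone = sum(acts == ACT_ALONE),
    n_coop = sum(acts == ACT_COOPERATE),
    n_exploit = sum(acts == ACT_EXPLOIT),
    active_exploiters = res$active_exploiters)
  pop
}

#' Rescale population inequality (exogenous shock)
#'
#' Rescales resources about the current population mean so that the standard
#' deviation becomes exactly `new_sigma` while the mean is preserved:
#' `s' = m + (s - m) * new_sigma / sd(s)`. Used to impose an exogenous change
#' in inequality mid-simulation.
#'
#' @param pop a `population` object.
#' @param new_sigma target standard deviation (>= 0).
#' @return The rescaled population.
#' @export
apply_shock <- function(pop, new_sigma) {
  if (new_sigma < 0) stop("'new_sigma' must be >= 0", call. = FALSE)
  m <- mean(pop$resources)
  s <- stats::sd(pop$resources)
  if (s == 0)
    stop("cannot rescale a degenerate population (sd = 0)", call. = FALSE)
  pop$resources <- m + (pop$resources - m) * new_sigma / s
  pop
}

#' Run a population simulation
#'
#' Initialises a population and advances it for `steps` time steps under the
#' optimal policy, recording per-step action counts, resource moments, mean
#' trust and the fraction of agents below the desperation threshold. The
#' policy is solved once from `params` (threshold-centred noise of scale
#' `sigma`; see [solve_policy()]) unless one is supplied; optionally it can
#' be re-solved periodically at the drifting population moments.
#'
#' The between-step perturbation is always centred on the current population
#' mean. Its scale is by default anchored to the run's input inequality
#' `sigma` (and to `shock_sigma` after a shock), so the resource
#' distribution has a well-defined stationary dispersion while the mean
#' drifts with the population's net payoffs;
#' `perturbation_variance = "current"` instead re-reads the realised
#' population variance every step (see [apply_perturbation()] for why that
#' lets dispersion ratchet upward under punishment noise).
#'
#' @param params a [model_params()] object.
#' @param policy optional pre-computed [solve_policy()] result (saves the
#'   solve when running many replicates at the same parameters).
#' @param mu,sigma initial resource distribution (default from `params`).
#' @param steps number of time steps (default `params$T`).
#' @param seed integer seed; the whole trace is deterministic given it.
#' @param shock_step,shock_sigma if supplied, after `shock_step` completed
#'   steps the population's resource sd is rescaled to `shock_sigma`
#'   (see [apply_shock()]).
#' @param perturbation_variance `"anchored"` (default) or `"current"`; see
#'   Details.
#' @param recompute_policy_every if > 0, the policy is re-solved every that
#'   many steps using the current population mean and sd as the
#'   perturbation's parameters (sensitivity analysis; default 0 = fixed
#'   policy throughout).
#' @return A `sim_trace`: data frame with one row per step and columns `t`,
#'   `n_coop`, `n_exploit`, `n_alone`, `active_exploiters`, `mean_s`, `sd_s`,
#'   `mean_trust`, `frac_below_threshold`; attributes carry `params`, `mu`,
#'   `sigma`, `seed`, the initial moments, and any shock annotation.
#' @examples
#' \donttest{
#' pol <- solve_policy(model_params())
#' tr <- run_simulation(model_params(), policy = pol, sigma = 3, seed = 1)
#' tail(tr, 3)
#' }
#' @export
run_simulation <- function(params, policy = NULL, mu = params$mu,
                           sigma = params$sigma, steps = params$T,
                           seed = NULL, shock_step = NULL, shock_sigma = NULL,
                           perturbation_variance = c("anchored", "current"),
                           recompute_policy_every = 0) {
  validate_params(params)
  perturbation_variance <- match.arg(perturbation_variance)
  if (steps < 1) stop("'steps' must be at least 1", call. = FALSE)
  if (!is.null(shock_step) && shock_step >= steps)
    stop("'shock_step' must be below 'steps'", call. = FALSE)
  if (is.null(policy)) {
    sp <- params
    sp$sigma <- sigma
    policy <- solve_policy(sp) # threshold-centred noise of scale sigma
  }
  if (!is.null(seed)) set.seed(seed)
  pop <- init_population(params, mu, sigma)
  init_mean <- mean(pop$resources)
  init_sd <- stats::sd(pop$resources)
  sigma_ref <- if (perturbation_variance == "anchored") sigma else NULL
  rows <- vector("list", steps)
  for (t in seq_len(steps)) {
    pop <- sim_step(pop, policy, params, sigma_ref)
    st <- attr(pop, "step_stats")
    rows[[t]] <- data.frame(
      t = t, n_coop = st$n_coop, n_exploit = st$n_exploit,
      n_alone = st$n_alone, active_exploiters = st$active_exploiters,
      mean_s = mean(pop$resources), sd_s = stats::sd(pop$resources),
      mean_trust = mean(pop$trust),
      frac_below_threshold = mean(pop$resources < params$threshold))
    if (!is.null(shock_step) && t == shock_step) {
      pop <- apply_shock(pop, shock_sigma)
      if (!is.null(sigma_ref)) sigma_ref <- shock_sigma
    }
    if (recompute_policy_every > 0 && t %% recompute_policy_every == 0) {
      sp <- params
      sp$mu <- mean(pop$resources)
      sp$sigma <- stats::sd(pop$resources)
      policy <- solve_policy(sp)
    }
  }
  tr <- do.call(rbind, rows)
  attr(tr, "params") <- params
  attr(tr, "mu") <- mu
  attr(tr, "sigma") <- sigma
  attr(tr, "seed") <- seed
  attr(tr, "initial_mean") <- init_mean
  attr(tr, "initial_sd") <- init_sd
  if (!is.null(shock_step))
    attr(tr, "shock") <- c(step = shock_step, sigma = shock_sigma)
  class(tr) <- c("sim_trace", "data.frame")
  tr
}
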