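#' Model parameters
#'
#' Constructs and validates the full parameter set for the
#' desperation-threshold model: the structural parameters of the decision
#' problem (payoffs, punishment, social mobility), the discretisation of the
#' state space, and the input parameters describing the resource distribution
#' of the surrounding population.
#'
#' Agents choose at each time step between three actions: foraging alone
#' (invest `x`, get `x` back, net 0), cooperating (net `x * (alpha - 1)` if no
#' group member exploits, net `-x` if one does), and exploiting (net `beta`
#' with probability `1 - gamma`, net `-pi` if punished, probability `gamma`).
#' Falling below the desperation threshold (resources < `threshold`, fixed at
#' 0) costs a fixed fitness penalty `omega` per time step. Between steps,
#' resources are perturbed by a mean-reverting shuffle whose strength is the
#' social mobility `r`; see [perturbation_law()].
#'
#' @param r social mobility in `[0, 1]`: one minus the temporal
#'   autocorrelation of resources under the perturbation.
#' @param x cost (and return) of foraging, in resource units.
#' @param omega fitness penalty per step spent below the desperation
#'   threshold.
#' @param alpha efficiency of cooperation; must exceed 1 for cooperation to
#'   beat foraging alone.
#' @param beta reward for a successful exploitation, resource units.
#' @param pi punishment for a failed exploitation, resource units.
#' @param gamma probability that an exploiter is punished, in `[0, 1]`.
#' @param T number of time steps for the backward induction.
#' @param N population size for simulations.
#' @param n interaction group size; must divide `N`.
#' @param K number of other agents each agent observes when estimating
#'   trustworthiness.
#' @param threshold location of the desperation threshold on the resource
#'   axis (fixed at 0 in the model; kept explicit for clarity).
#' @param s_min,s_max,s_steps bounds and resolution of the resource grid.
#'   Defaults give 1001 points from -50 to 50, spacing 0.1.
#' @param p_steps resolution of the trustworthiness grid on `[0, 1]`.
#' @param mu,sigma mean and standard deviation of the population resource
#'   distribution. These are input parameters: the policy solver treats them
#'   as fixed exogenous features of the perturbation, while simulations update
#'   them endogenously each step.
#' @param perturbation_variant `"variance_preserving"` (default) or
#'   `"paper"`; see [perturbation_law()] for the difference.
#' @param initial_trust trust estimate assigned to agents before they have
#'   made any observation (default 1: full trust).
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params()
#' p$alpha
#' model_params(gamma = 2/3, pi = 10) # punishment regime of the gamma sweep
#' @export
model_params <- function(r = 0.1, x = 1, omega = 5, alpha = 1.2, beta = 5,
                         pi = 10, gamma = 1 / 3, T = 50, N = 500, n = 5,
                         K = 50, threshold = 0,
                         s_min = -50, s_max = 50, s_steps = 1001,
                         p_steps = 101, mu = 5.5, sigma = 4,
                         perturbation_variant = c("variance_preserving",
                                                  "paper"),
                         initial_trust = 1) {
  perturbation_variant <- match.arg(perturbation_variant)
  p <- list(r = r, x = x, omega = omega, alpha = alpha, beta = beta,
            pi = pi, gamma = gamma, T = T, N = N, n = n, K = K,
            threshold = threshold, s_min = s_min, s_max = s_max,
            s_steps = s_steps, p_steps = p_steps, mu = mu, sigma = sigma,
            perturbation_variant = perturbation_variant,
            initial_trust = initial_trust)
  class(p) <- "model_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  num1 <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v)
  for (f in c("r", "x", "omega", "alpha", "beta", "pi", "gamma", "T", "N",
              "n", "K", "threshold", "s_min", "s_max", "s_steps", "p_steps",
              "mu", "sigma", "initial_trust"))
    chk(num1(p[[f]]), sprintf("parameter '%s' must be a finite number", f))
  chk(p$r >= 0 && p$r <= 1, "'r' (social mobility) must be in [0, 1]")
  chk(p$gamma >= 0 && p$gamma <= 1,
      "'gamma' (punishment probability) must be in [0, 1]")
  chk(p$omega >= 0, "'omega' (threshold penalty) must be >= 0")
  chk(p$sigma >= 0, "'sigma' must be >= 0")
  chk(p$x > 0, "'x' (foraging cost) must be > 0")
  chk(p$n >= 2, "'n' (group size) must be at least 2")
  chk(p$N >= p$n, "'N' must be at least the group size 'n'")
  chk(p$K >= 1 && p$K <= p$N - 1,
      "'K' (observation sample size) must be in [1, N - 1]")
  chk(p$T >= 2, "'T' must be at least 2")
  chk(p$s_steps >= 2 && p$p_steps >= 2,
      "grid resolutions 's_steps' and 'p_steps' must be at least 2")
  chk(p$s_min < p$s_max, "'s_min' must be below 's_max'")
  chk(p$threshold > p$s_min && p$threshold < p$s_max,
      "'threshold' must lie strictly inside (s_min, s_max)")
  chk(p$initial_trust >= 0 && p$initial_trust <= 1,
      "'initial_trust' must be in [0, 1]")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Desperation-threshold model parameters\n")
  cat(sprintf("  payoffs: x = %g, alpha = %g, beta = %g, pi = %g, gamma = %g\n",
              x$x, x$alpha, x$beta, x$pi, x$gamma))
  cat(sprintf("  threshold at s = %g, penalty omega = %g\n",
              x$threshold, x$omega))
  cat(sprintf("  mobility r = %g (%s perturbation), mu = %g, sigma = %g\n",
              x$r, x$perturbation_variant, x$mu, x$sigma))
  cat(sprintf("  horizon T = %d; population N = %d, groups of n = %d, K = %d\n",
              as.integer(x$T), as.integer(x$N), as.integer(x$n),
              as.integer(x$K)))
  cat(sprintf("  grids: s in [%g, %g] x %d, trustworthiness [0, 1] x %d\n",
              x$s_min, x$s_max, as.integer(x$s_steps),
              as.integer(x$p_steps)))
  invisible(x)
}

#' Build the state-space grids
#'
#' @param params a [model_params()] object.
#' @return A list with `s`, the resource grid (`s_steps` equally spaced
#'   points from `s_min` to `s_max`), and `q`, the trustworthiness grid
#'   (`p_steps` equally spaced points covering `[0, 1]`; `q = 1 - p`).
#' @examples
#' g <- build_grids(model_params())
#' length(g$s)    # 1001
#' diff(g$s)[1]   # 0.1
#' @export
build_grids <- function(params) {
  validate_params(params)
  list(s = seq(params$s_min, params$s_max, length.out = params$s_steps),
       q = seq(0, 1, length.out = params$p_steps))
}

# Action coding used throughout: integer codes in tie-break preference order.
ACT_ALONE <- 1L
ACT_COOPERATE <- 2L
ACT_EXPLOIT <- 3L
ACTION_LABELS <- c("alone", "cooperate", "exploit")

#' Action labels
#'
#' The three actions of the model in the package's canonical order
#' (`"alone"`, `"cooperate"`, `"exploit"`), which is also the preference
#' order used to break exact ties in the policy argmax.
#' @return Character vector of length 3.
#' @export
action_labels <- function() ACTION_LABELS

#' Per-action payoff distributions
#'
#' Returns the net-payoff lottery an agent faces when taking `action` in a
#' population where a cooperating group is exploited with probability `p`.
#' Cooperation nets `x * (alpha - 1)` if no group member exploits
#' (probability `1 - p`) and `-x` if one does; exploitation nets `beta` with
#' probability `1 - gamma` and `-pi` with probability `gamma` (independent of
#' `p`); foraging alone nets exactly 0.
#'
#' @param action one of `"alone"`, `"cooperate"`, `"exploit"`.
#' @param params a [model_params()] object.
#' @param p probability that a cooperating group contains an exploiter
#'   (`1 - p` is the trustworthiness of the population).
#' @return An object of class `action_outcomes`: list with `action`,
#'   `payoff` (numeric vector) and `prob` (matching probabilities summing to
#'   1). Zero-probability outcomes are dropped.
#' @examples
#' action_outcomes("cooperate", model_params(), p = 0)   # certain +0.2
#' action_outcomes("exploit", model_params(), p = 0.5)   # (5, 2/3), (-10, 1/3)
#' @export
action_outcomes <- function(action, params, p = 0) {
  validate_params(params)
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("'p' must be a single probability in [0, 1]", call. = FALSE)
  action <- match.arg(action, ACTION_LABELS)
  out <- switch(action,
    alone = list(payoff = 0, prob = 1),
    cooperate = list(payoff = c(params$x * (params$alpha - 1), -params$x),
                     prob = c(1 - p, p)),
    exploit = list(payoff = c(params$beta, -params$pi),
                   prob = c(1 - params$gamma, params$gamma)))
  keep <- out$prob > 0
  structure(list(action = action, payoff = out$payoff[keep],
                 prob = out$prob[keep]),
            class = "action_outcomes")
}

#' The mean-reverting resource perturbation
#'
#' Between time steps every agent's resources are shuffled towards the
#' population mean: `s' = (1 - r) * s + r * eps` with
#' `eps ~ N(noise_mean, noise_sd^2)`. The intent of the construction is that
#' the population mean and variance of resources are left unchanged while the
#' temporal autocorrelation of an individual's resources is `1 - r`, so that
#' `r` acts as social mobility.
#'
#' Two variants of the noise scale are provided. `"variance_preserving"`
#' (the default) sets `noise_sd = sigma * sqrt(1 - (1 - r)^2) / r`, which
#' makes `Var(s') = sigma^2` exactly and `Cor(s, s') = 1 - r`. `"paper"`
#' uses `noise_sd = sigma * sqrt((1 - r^2) / (1 - r)^2)`, an alternative
#' printed form that slightly shrinks the variance for intermediate `r` and
#' is undefined at `r = 1`; it is retained for fidelity comparisons.
#' For `r = 0` both variants reduce to the identity (no noise).
#'
#' @param params a [model_params()] object (supplies `r` and the variant).
#' @param pop_mean current mean resources in the population.
#' @param pop_var current population variance of resources.
#' @return A list of class `perturbation_law` with `persistence` (`1 - r`),
#'   `r`, `noise_mean`, `noise_sd` and `variant`.
#' @examples
#' perturbation_law(model_params(r = 0.1), 5.5, 16)
#' @export
perturbation_law <- function(params, pop_mean, pop_var) {
  validate_params(params)
  if (!is.numeric(pop_var) || length(pop_var) != 1 || is.na(pop_var) ||
      pop_var < 0)
    stop("'pop_var' must be a single non-negative number", call. = FALSE)
  r <- params$r
  if (r == 0) {
    sd_eps <- 0
  } else if (params$perturbation_variant == "paper") {
    if (r == 1)
      stop("the 'paper' perturbation variant is undefined at r = 1 ",
           "(division by zero); use perturbation_variant = ",
           "'variance_preserving'", call. = FALSE)
    sd_eps <- sqrt(pop_var) * sqrt((1 - r^2) / (1 - r)^2)
  } else {
    sd_eps <- sqrt(pop_var) * sqrt(1 - (1 - r)^2) / r
  }
  structure(list(persistence = 1 - r, r = r, noise_mean = pop_mean,
                 noise_sd = sd_eps,
                 variant = params$perturbation_variant),
            class = "perturbation_law")
}

# Short stable identifier for a parameter set (used to tag policies and
# output artifacts so a policy can be matched to the params that made it).
params_hash <- function(params) {
  s <- paste(names(params), vapply(params, function(v)
    paste(format(v, digits = 17), collapse = ","), ""), sep = "=",
    collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}
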