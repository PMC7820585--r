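#' Terminal fitness
#'
#' Terminal condition of the backward induction: at the final time step
#' fitness is an increasing linear function of resources, `a * s + b`,
#' identical at every trustworthiness level. The threshold penalty is not
#' applied at the terminal step itself; it enters through the recurrence.
#' Computed policies are invariant to positive affine transforms of this
#' terminal function, so the default slope 1 / intercept 0 is innocuous.
#'
#' @param grids grids from [build_grids()].
#' @param params a [model_params()] object.
#' @param slope,intercept coefficients of the terminal fitness line;
#'   `slope` must be positive.
#' @return A `value_function`: list with `values` (matrix, resources by
#'   trustworthiness) and `t = params$T`.
#' @export
terminal_fitness <- function(grids, params, slope = 1, intercept = 0) {
  if (!is.numeric(slope) || length(slope) != 1 || !is.finite(slope) ||
      slope <= 0)
    stop("terminal fitness slope must be a positive number", call. = FALSE)
  v <- matrix(slope * grids$s + intercept,
              nrow = length(grids$s), ncol = length(grids$q))
  structure(list(values = v, t = as.integer(params$T)),
            class = "value_function")
}

# Discretised Gaussian transition matrix for one deterministic net payoff d:
# row i gives the distribution of the next resource state when the current
# state is s_grid[i], the payoff is d, and the perturbation law applies:
#   s' ~ N((1-r) * (s + d) + r * noise_mean, (r * noise_sd)^2).
# Each Gaussian component is integrated over grid-cell intervals via the CDF
# (edges at cell midpoints), and mass outside [s_min, s_max] is accumulated
# into the boundary cells, so every row sums to 1 by construction. With
# r = 0 (or zero noise) the row is a point mass at the nearest grid cell.
payoff_kernel <- function(s_grid, d, law) {
  ns <- length(s_grid)
  m <- law$persistence * (s_grid + d) + law$r * law$noise_mean
  sd_eff <- law$r * law$noise_sd
  if (sd_eff == 0) {
    j <- snap_index(m, s_grid)
    W <- matrix(0, ns, ns)
    W[cbind(seq_len(ns), j)] <- 1
    return(W)
  }
  edges <- c(-Inf, (s_grid[-ns] + s_grid[-1]) / 2, Inf)
  P <- stats::pnorm(outer(-m, edges, `+`) / sd_eff)
  W <- P[, -1, drop = FALSE] - P[, -(ns + 1), drop = FALSE]
  W
}

# Nearest-grid-cell index with clamping (grid must be equally spaced).
snap_index <- function(x, grid) {
  step <- (grid[length(grid)] - grid[1]) / (length(grid) - 1)
  pmin(pmax(as.integer(round((x - grid[1]) / step)) + 1L, 1L), length(grid))
}

#' Transition-kernel row for one action and state
#'
#' Builds the discretised distribution of next-step resources for an agent
#' with resources `s` taking `action` when the exploitation probability is
#' `p`: a mixture of Gaussian components, one per action outcome, each with
#' weight equal to the outcome probability, mean
#' `(1 - r) * (s + payoff) + r * noise_mean` and standard deviation
#' `r * noise_sd`. Mass falling outside the resource grid is accumulated in
#' the boundary cells, so the row sums to 1.
#'
#' @param action `"alone"`, `"cooperate"` or `"exploit"`.
#' @param s current resource level (snapped to the nearest grid point).
#' @param p probability that a cooperating group is exploited.
#' @param params a [model_params()] object.
#' @param law a [perturbation_law()]; defaults to the solver's standard
#'   anchor (noise centred at the desperation threshold, scale
#'   `params$sigma`; see [solve_policy()]).
#' @return Numeric vector over the resource grid, summing to 1.
#' @export
build_kernel <- function(action, s, p, params,
                         law = perturbation_law(params, params$threshold,
                                                params$sigma^2)) {
  grids <- build_grids(params)
  i <- snap_index(s, grids$s)
  out <- action_outcomes(action, params, p)
  row <- numeric(length(grids$s))
  for (k in seq_along(out$payoff))
    row <- row + out$prob[k] * payoff_kernel(grids$s, out$payoff[k], law)[i, ]
  row
}

# Pre-computes the per-payoff kernels the backward induction needs. The
# exploit kernel can be pre-mixed over success/failure (its outcome weights
# do not depend on p); cooperation keeps its two components separate because
# their weights (1-p, p) vary along the trustworthiness axis.
transition_kernels <- function(grids, params, law) {
  list(alone = payoff_kernel(grids$s, 0, law),
       coop_win = payoff_kernel(grids$s, params$x * (params$alpha - 1), law),
       coop_lose = payoff_kernel(grids$s, -params$x, law),
       exploit = (1 - params$gamma) * payoff_kernel(grids$s, params$beta, law) +
         params$gamma * payoff_kernel(grids$s, -params$pi, law))
}

#' One step of backward induction
#'
#' Computes `f_t` from `f_{t+1}` by the dynamic-programming recurrence: for
#' each action the expected value of `f_{t+1}` under that action's transition
#' kernel, minus `omega` times the probability of landing below the
#' desperation threshold; `f_t` is the maximum over actions and the policy at
#' `t` the argmax. Exact ties (within `1e-12`) are broken by the fixed
#' preference order alone > cooperate > exploit, for reproducibility.
#'
#' @param f_next `value_function` at `t + 1`.
#' @param params a [model_params()] object.
#' @param kernels pre-computed kernels (internal; built by [solve_policy()]).
#' @param grids grids from [build_grids()].
#' @return List with `f` (the `value_function` at `t`) and `actions`
#'   (integer matrix of argmax actions, codes 1 = alone, 2 = cooperate,
#'   3 = exploit).
#' @export
backward_step <- function(f_next, params, kernels, grids) {
  ns <- length(grids$s)
  np <- length(grids$q)
  if (!all(dim(f_next$values) == c(ns, np)))
    stop("value function dimensions do not match the grids", call. = FALSE)
  # penalised continuation value: f_{t+1}(x) - omega * 1{x < threshold}
  G <- f_next$values - params$omega * (grids$s < params$threshold)
  EA <- kernels$alone %*% G
  EH <- kernels$exploit %*% G
  Ewin <- kernels$coop_win %*% G
  Elose <- kernels$coop_lose %*% G
  q <- rep(grids$q, each = ns) # trustworthiness 1 - p, by column
  EC <- Ewin * q + Elose * (1 - q)
  tol <- 1e-12
  act <- matrix(ACT_ALONE, ns, np)
  best <- EA
  idx <- EC > best + tol
  act[idx] <- ACT_COOPERATE
  best[idx] <- EC[idx]
  idx <- EH > best + tol
  act[idx] <- ACT_EXPLOIT
  best[idx] <- EH[idx]
  f <- structure(list(values = pmax(EA, EC, EH), t = f_next$t - 1L),
                 class = "value_function")
  list(f = f, actions = act)
}

#' Solve for the optimal action policy
#'
#' Runs the backward induction from the terminal step `T` down to `t = 1`
#' and returns the `t = 1` policy map over (resources, trustworthiness),
#' together with the `t = 1` value function. Policies stabilise rapidly as
#' the computation moves away from `T`; the returned object records the last
#' time index at which the policy map still changed, as a stability
#' diagnostic.
#'
#' During policy computation the perturbation's mean and scale are fixed
#' exogenous inputs `(mu0, sigma0)`. By default the noise is centred at the
#' desperation threshold (`mu0 = params$threshold`) with scale
#' `sigma0 = params$sigma`: absent action payoffs, the environment
#' random-walks an agent around the survival line rather than bailing it out
#' towards a wealthy population mean. This neutral anchor places the
#' unconditional-exploit band edge at the threshold itself; anchoring at a
#' mean well above the threshold (e.g. `mu0 = 5.5`) lets the drift
#' self-rescue near-desperate agents and moves the edge down by one to two
#' resource units. Simulations update the realised population mean
#' endogenously; see [run_simulation()].
#'
#' @param params a [model_params()] object.
#' @param slope,intercept terminal fitness coefficients
#'   (see [terminal_fitness()]).
#' @param mu0 centre of the exogenous perturbation noise (default: the
#'   desperation threshold).
#' @param sigma0 scale of the exogenous perturbation noise (default:
#'   `params$sigma`).
#' @return An object of class `policy`: list with `actions` (integer matrix,
#'   resources by trustworthiness), `values` (the `t = 1` value function),
#'   grids `s` and `q`, the generating `params` and `params_hash`, and
#'   `last_change_t` (largest `t` below `T` at which the map last changed;
#'   `NA` if it never changed).
#' @examples
#' \donttest{
#' pol <- solve_policy(model_params())
#' table(action_labels()[pol$actions])
#' }
#' @export
solve_policy <- function(params, slope = 1, intercept = 0,
                         mu0 = params$threshold, sigma0 = params$sigma) {
  validate_params(params)
  grids <- build_grids(params)
  law <- perturbation_law(params, mu0, sigma0^2)
  kernels <- transition_kernels(grids, params, law)
  f <- terminal_fitness(grids, params, slope, intercept)
  actions <- NULL
  last_change <- NA_integer_
  for (t in seq(params$T - 1, 1)) {
    stp <- backward_step(f, params, kernels, grids)
    f <- stp$f
    if (!is.null(actions) && !identical(stp$actions, actions))
      last_change <- as.integer(t)
    actions <- stp$actions
  }
  structure(list(actions = actions, values = f$values,
                 s = grids$s, q = grids$q, t = 1L,
                 params = params, params_hash = params_hash(params),
                 anchor = c(mu0 = mu0, sigma0 = sigma0),
                 terminal = c(slope = slope, intercept = intercept),
                 last_change_t = last_change),
            class = "policy")
}

#' @export
print.policy <- function(x, ...) {
  tab <- table(factor(ACTION_LABELS[x$actions], levels = ACTION_LABELS))
  cat(sprintf("Optimal policy at t = %d on a %d x %d (s x trustworthiness) grid\n",
              x$t, nrow(x$actions), ncol(x$actions)))
  cat(sprintf("  cells: %d alone, %d cooperate, %d exploit\n",
              tab[["alone"]], tab[["cooperate"]], tab[["exploit"]]))
  if (is.na(x$last_change_t))
    cat("  policy map identical at every backward step\n")
  else
    cat(sprintf("  policy map last changed at t = %d (stable below)\n",
                x$last_change_t))
  cat(sprintf("  params hash %s\n", x$params_hash))
  invisible(x)
}

#' Critical resource level for exploitation
#'
#' Below some resource level agents should exploit regardless of the
#' trustworthiness of the population. For each trustworthiness level this
#' returns the largest grid resource value such that every state at or below
#' it maps to exploit; the minimum of these over trustworthiness levels is
#' the edge of the unconditional-exploit band.
#'
#' @param policy a [solve_policy()] result.
#' @return List with `per_trust` (named numeric vector over the
#'   trustworthiness grid; `NA` where no exploit region starts at the bottom
#'   of the resource axis) and `band_edge` (the minimum; `NA` if any level
#'   has no exploit region).
#' @export
exploitation_critical_resource <- function(policy) {
  stopifnot(inherits(policy, "policy"))
  per <- apply(policy$actions == ACT_EXPLOIT, 2, function(col) {
    if (!col[1]) return(NA_real_)
    run <- which(!col)
    top <- if (length(run)) run[1] - 1L else length(col)
    policy$s[top]
  })
  names(per) <- format(policy$q, trim = TRUE)
  list(per_trust = per,
       band_edge = if (anyNA(per)) NA_real_ else min(per))
}

#' Cooperation/alone frontier at high resources
#'
#' For resources far above the desperation threshold the choice is between
#' cooperating and foraging alone, and cooperation pays on average iff the
#' trustworthiness `1 - p` exceeds `1 / alpha`. This extracts the realised
#' frontier from a computed policy: the smallest grid trustworthiness at
#' which the action at `s_probe` is cooperate.
#'
#' @param policy a [solve_policy()] result.
#' @param s_probe resource level at which to probe (default 40, well above
#'   the threshold).
#' @return The frontier trustworthiness (a point of the trustworthiness
#'   grid), or `NA` if cooperation is never chosen at `s_probe`.
#' @export
cooperation_frontier <- function(policy, s_probe = 40) {
  stopifnot(inherits(policy, "policy"))
  i <- snap_index(s_probe, policy$s)
  j <- which(policy$actions[i, ] == ACT_COOPERATE)
  if (!length(j)) return(NA_real_)
  policy$q[min(j)]
}
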