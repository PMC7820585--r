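# Shared fixtures: a coarse, fast parameterisation for machinery tests, a
# policy cache so full-resolution policies are solved once per test run, and
# an independent brute-force oracle for the backward induction.

# Coarse model: 0.5-unit resource grid, small population. Fast enough for
# simulation/experiment machinery tests while keeping both equilibria.
coarse_params <- function(...) {
  base <- list(s_steps = 201, p_steps = 51, T = 20, N = 100, n = 5, K = 20)
  do.call(model_params, utils::modifyList(base, list(...)))
}

.policy_cache <- new.env(parent = emptyenv())

cached_policy <- function(key, params, ...) {
  if (is.null(.policy_cache[[key]]))
    assign(key, solve_policy(params, ...), envir = .policy_cache)
  get(key, envir = .policy_cache)
}

# Full-resolution default policy (Table-1 parameters), shared across files.
default_policy <- function() cached_policy("default", model_params())

# Nearest-grid-point index, robust to floating-point grid representation.
gi <- function(grid, v) which.min(abs(grid - v))

# Brute-force oracle: exhaustive recursion over every action/outcome path,
# valid for r = 0 (point-mass transitions). Independent of the matrix
# solver: no kernels, no matrix algebra; it re-derives values cell by cell.
oracle_solve <- function(params, slope = 1, intercept = 0) {
  stopifnot(params$r == 0)
  grids <- build_grids(params)
  step <- (params$s_max - params$s_min) / (params$s_steps - 1)
  snap <- function(x)
    grids$s[min(max(round((x - params$s_min) / step) + 1, 1),
                length(grids$s))]
  tol <- 1e-12
  ev_actions <- function(s, p, t) {
    vapply(c("alone", "cooperate", "exploit"), function(a) {
      out <- action_outcomes(a, params, p)
      ev <- 0
      for (k in seq_along(out$payoff)) {
        land <- snap(s + out$payoff[k])
        ev <- ev + out$prob[k] *
          (vfun(land, p, t + 1) - params$omega * (land < params$threshold))
      }
      ev
    }, numeric(1))
  }
  vfun <- function(s, p, t) {
    if (t == params$T) return(slope * s + intercept)
    max(ev_actions(s, p, t))
  }
  values <- matrix(NA_real_, length(grids$s), length(grids$q))
  actions <- matrix(NA_integer_, length(grids$s), length(grids$q))
  for (i in seq_along(grids$s)) {
    for (j in seq_along(grids$q)) {
      evs <- ev_actions(grids$s[i], 1 - grids$q[j], 1)
      best <- evs[["alone"]]
      act <- 1L
      if (evs[["cooperate"]] > best + tol) {
        best <- evs[["cooperate"]]
        act <- 2L
      }
      if (evs[["exploit"]] > best + tol) act <- 3L
      values[i, j] <- max(evs)
      actions[i, j] <- act
    }
  }
  list(values = values, actions = actions)
}

# Distance from the analytic frontier q* to the measured transition
# interval: cooperation_frontier() returns the first grid point at which
# cooperation is chosen, so the true frontier lies in the half-open grid
# step below it. Within-one-step agreement means this distance <= step.
frontier_distance <- function(measured, analytic, step) {
  lo <- measured - step
  if (analytic >= lo && analytic <= measured) 0
  else min(abs(analytic - lo), abs(analytic - measured))
}
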