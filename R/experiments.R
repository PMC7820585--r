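#' Classify the absorbing equilibrium of a simulation trace
#'
#' Simulated populations settle into one of two absorbing states: the
#' poverty trap (negligible cooperation, a standing mix of attempted
#' exploitation and lone foraging, stagnant resources) or the virtuous
#' circle (near-universal cooperation, high trust, growing resources). This
#' labels a trace from its final window: `"poverty_trap"` if the mean
#' cooperation fraction in the window is below `trap_coop_frac` and some
#' exploitation occurred in it; `"virtuous_circle"` if the mean cooperation
#' fraction exceeds `coop_frac` and mean resources grew over the run;
#' otherwise `"undetermined"` (e.g. an all-alone population, which neither
#' cooperates nor exploits, or a slow transient between basins).
#'
#' The window and thresholds are package choices, exposed as arguments, set
#' to separate the two absorbing states robustly. `trap_coop_frac` is not 0
#' because finite-sample trust puts a noise floor under cooperation even in
#' a fully trapped population: an agent whose `K`-sample happens to contain
#' almost no exploiters estimates trust above the cooperation frontier and
#' cooperates that step, so a trapped population still shows isolated
#' cooperation blips an order of magnitude below the virtuous level.
#'
#' @param trace a [run_simulation()] trace.
#' @param window number of final steps to inspect (default 10).
#' @param coop_frac cooperation fraction above which the window counts as
#'   cooperative (default 0.5).
#' @param trap_coop_frac cooperation fraction below which the window counts
#'   as trapped (default 0.05).
#' @return An object of class `equilibrium_label`: list with `label` and
#'   diagnostics (`final_coop_frac`, `final_exploit_frac`,
#'   `final_mean_trust`, `resource_growth`).
#' @export
classify_equilibrium <- function(trace, window = 10, coop_frac = 0.5,
                                 trap_coop_frac = 0.05) {
  stopifnot(inherits(trace, "sim_trace"))
  if (nrow(trace) < window)
    stop("trace is shorter than the classification window", call. = FALSE)
  params <- attr(trace, "params")
  N <- params$N
  w <- trace[seq(nrow(trace) - window + 1, nrow(trace)), ]
  growth <- trace$mean_s[nrow(trace)] - attr(trace, "initial_mean")
  diag <- list(final_coop_frac = mean(w$n_coop) / N,
               final_exploit_frac = mean(w$n_exploit) / N,
               final_mean_trust = mean(w$mean_trust),
               resource_growth = growth)
  label <-
    if (diag$final_coop_frac < trap_coop_frac && any(w$n_exploit > 0))
      "poverty_trap"
    else if (diag$final_coop_frac > coop_frac && growth > 0) "virtuous_circle"
    else "undetermined"
  structure(c(list(label = label), diag), class = "equilibrium_label")
}

#' @export
print.equilibrium_label <- function(x, ...) {
  cat(sprintf("%s (final coop %.2f, exploit %.2f, trust %.2f, growth %+.2f)\n",
              x$label, x$final_coop_frac, x$final_exploit_frac,
              x$final_mean_trust, x$resource_growth))
  invisible(x)
}

# Most frequent label; exact ties resolve to "undetermined".
majority_label <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) "undetermined" else names(tab)[1]
}

set_param <- function(params, name, value) {
  if (!name %in% names(params) || name == "perturbation_variant")
    stop(sprintf("unknown sweep parameter '%s'", name), call. = FALSE)
  params[[name]] <- value
  validate_params(params)
  params
}

#' Phase-diagram parameter sweep
#'
#' Maps the basins of attraction of the two equilibria over a
#' two-dimensional grid of parameters (e.g. initial inequality `sigma`
#' against punishment severity `pi`). For every cell the optimal policy is
#' re-solved for that parameter set, `reps` replicate simulations are run
#' with distinct derived seeds, each is classified, and the cell is labelled
#' by majority vote (replicates near a basin boundary are stochastic).
#'
#' @param params base [model_params()]; cells modify it.
#' @param axis1,axis2 lists with `name` (a `model_params` field, e.g.
#'   `"sigma"`, `"pi"`, `"gamma"`, `"r"`) and `values` (numeric grid).
#' @param reps replicate simulations per cell (default 5).
#' @param seed master seed; all replicate seeds derive from it.
#' @param steps simulation length per run (default `params$T`).
#' @param window classification window (see [classify_equilibrium()]).
#' @return An object of class `sweep_result`: list with `runs` (data frame:
#'   axis1_value, axis2_value, rep, seed, label, final_coop_frac,
#'   final_mean_trust) and `cells` (data frame with the majority label per
#'   cell), plus the axis names.
#' @examples
#' \donttest{
#' sw <- phase_sweep(model_params(), list(name = "sigma", values = c(3, 4)),
#'                   list(name = "pi", values = c(1, 10)), reps = 3, seed = 1)
#' sw$cells
#' }
#' @export
phase_sweep <- function(params, axis1, axis2, reps = 5, seed = 1,
                        steps = params$T, window = 10) {
  if (reps < 1) stop("'reps' must be at least 1", call. = FALSE)
  set.seed(seed)
  cells <- expand.grid(a1 = axis1$values, a2 = axis2$values,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- matrix(sample.int(.Machine$integer.max, nrow(cells) * reps),
                  nrow = nrow(cells))
  runs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p2 <- set_param(params, axis1$name, cells$a1[i])
    p2 <- set_param(p2, axis2$name, cells$a2[i])
    pol <- solve_policy(p2)
    rr <- vector("list", reps)
    for (k in seq_len(reps)) {
      tr <- run_simulation(p2, policy = pol, steps = steps,
                           seed = seeds[i, k])
      cl <- classify_equilibrium(tr, window = window)
      rr[[k]] <- data.frame(axis1_value = cells$a1[i],
                            axis2_value = cells$a2[i],
                            rep = k, seed = seeds[i, k], label = cl$label,
                            first_round_exploit_frac =
                              tr$n_exploit[1] / p2$N,
                            final_coop_frac = cl$final_coop_frac,
                            final_mean_trust = cl$final_mean_trust)
    }
    runs[[i]] <- do.call(rbind, rr)
  }
  runs <- do.call(rbind, runs)
  cells_out <- stats::aggregate(label ~ axis1_value + axis2_value, runs,
                                majority_label)
  names(cells_out)[3] <- "majority_label"
  structure(list(runs = runs, cells = cells_out,
                 axis1 = axis1$name, axis2 = axis2$name, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Phase sweep over %s x %s (%d cells, %d runs)\n",
              x$axis1, x$axis2, nrow(x$cells), nrow(x$runs)))
  print(table(x$cells$majority_label))
  invisible(x)
}

#' Critical first-round exploitation fraction
#'
#' The poverty trap is entered when enough of the population attempts
#' exploitation in the first round to collapse social trust. This estimates
#' the minimum first-round exploitation fraction that tips the population:
#' initial inequality `sigma` is varied over a grid spanning both basins;
#' for each `sigma` the realised first-round exploitation fraction and the
#' final equilibrium label are recorded over `reps` seeded runs; the
#' estimate is the smallest mean first-round fraction among `sigma` values
#' whose majority outcome is the poverty trap, with a bootstrap interval
#' from the replicate fractions at that boundary.
#'
#' @param params base [model_params()].
#' @param sigma_grid numeric grid of initial resource standard deviations;
#'   must bracket the basin boundary.
#' @param reps replicate runs per `sigma` value.
#' @param seed master seed.
#' @param steps simulation length per run.
#' @param window classification window.
#' @param boot bootstrap resamples for the interval (default 1000).
#' @return List with `fraction` (the estimate, in `[0, 1]`), `ci` (95%
#'   bootstrap interval), `sigma_boundary`, `by_sigma` (per-sigma summary)
#'   and `runs` (all individual runs).
#' @export
critical_exploitation_fraction <- function(params, sigma_grid, reps = 5,
                                           seed = 1, steps = params$T,
                                           window = 10, boot = 1000) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max,
                             length(sigma_grid) * reps),
                  nrow = length(sigma_grid))
  runs <- vector("list", length(sigma_grid))
  for (i in seq_along(sigma_grid)) {
    p2 <- set_param(params, "sigma", sigma_grid[i])
    pol <- solve_policy(p2)
    rr <- vector("list", reps)
    for (k in seq_len(reps)) {
      tr <- run_simulation(p2, policy = pol, steps = steps,
                           seed = seeds[i, k])
      cl <- classify_equilibrium(tr, window = window)
      rr[[k]] <- data.frame(sigma = sigma_grid[i], rep = k,
                            seed = seeds[i, k],
                            first_round_frac = tr$n_exploit[1] / p2$N,
                            label = cl$label)
    }
    runs[[i]] <- do.call(rbind, rr)
  }
  runs <- do.call(rbind, runs)
  by_sigma <- do.call(rbind, lapply(split(runs, runs$sigma), function(d)
    data.frame(sigma = d$sigma[1],
               mean_first_round_frac = mean(d$first_round_frac),
               majority = majority_label(d$label))))
  by_sigma <- by_sigma[order(by_sigma$sigma), ]
  if (length(unique(by_sigma$majority)) == 1)
    stop("sigma grid does not bracket the basin boundary: every value ",
         "gives the same majority outcome ('", by_sigma$majority[1], "')",
         call. = FALSE)
  trap <- by_sigma[by_sigma$majority == "poverty_trap", ]
  if (nrow(trap) == 0)
    stop("no sigma value reaches a poverty-trap majority", call. = FALSE)
  j <- which.min(trap$mean_first_round_frac)
  sigma_b <- trap$sigma[j]
  fracs <- runs$first_round_frac[runs$sigma == sigma_b]
  bs <- replicate(boot, mean(sample(fracs, replace = TRUE)))
  list(fraction = trap$mean_first_round_frac[j],
       ci = unname(stats::quantile(bs, c(0.025, 0.975))),
       sigma_boundary = sigma_b,
       by_sigma = by_sigma, runs = runs)
}

#' Group-size experiment
#'
#' For each interaction group size `n`, locates the inequality level at
#' which the population tips from the virtuous circle into the poverty
#' trap. Smaller groups are less likely to contain at least one exploiter at
#' a given exploitation prevalence, which enlarges the basin of attraction
#' of the virtuous circle. The optimal policy does not depend on `n` (the
#' exploitation probability `p` is the state variable), so one policy per
#' `sigma` is shared across group sizes.
#'
#' @param params base [model_params()].
#' @param n_values group sizes to compare; each must divide `N`.
#' @param sigma_grid inequality grid to scan.
#' @param reps replicates per (n, sigma) cell.
#' @param seed master seed.
#' @param steps,window as elsewhere.
#' @return List with `runs` (per-run data frame), `cells` (majority label
#'   per (n, sigma)) and `boundary` (per `n`, the largest sigma whose
#'   majority is the virtuous circle; `NA` if none).
#' @export
group_size_experiment <- function(params, n_values = c(3, 5),
                                  sigma_grid, reps = 5, seed = 1,
                                  steps = params$T, window = 10) {
  for (n in n_values)
    if (params$N %% n != 0 || n < 2)
      stop(sprintf("group size n = %s must be >= 2 and divide N = %d",
                   n, params$N), call. = FALSE)
  set.seed(seed)
  seeds <- array(sample.int(.Machine$integer.max,
                            length(sigma_grid) * length(n_values) * reps),
                 dim = c(length(sigma_grid), length(n_values), reps))
  runs <- list()
  for (i in seq_along(sigma_grid)) {
    p_sig <- set_param(params, "sigma", sigma_grid[i])
    pol <- solve_policy(p_sig)
    for (j in seq_along(n_values)) {
      p2 <- set_param(p_sig, "n", n_values[j])
      for (k in seq_len(reps)) {
        tr <- run_simulation(p2, policy = pol, steps = steps,
                             seed = seeds[i, j, k])
        cl <- classify_equilibrium(tr, window = window)
        runs[[length(runs) + 1]] <-
          data.frame(n = n_values[j], sigma = sigma_grid[i], rep = k,
                     seed = seeds[i, j, k], label = cl$label,
                     final_coop_frac = cl$final_coop_frac)
      }
    }
  }
  runs <- do.call(rbind, runs)
  cells <- stats::aggregate(label ~ n + sigma, runs, majority_label)
  names(cells)[3] <- "majority_label"
  boundary <- do.call(rbind, lapply(split(cells, cells$n), function(d) {
    ok <- d$sigma[d$majority_label == "virtuous_circle"]
    data.frame(n = d$n[1],
               boundary_sigma = if (length(ok)) max(ok) else NA_real_)
  }))
  rownames(boundary) <- NULL
  list(runs = runs, cells = cells, boundary = boundary, seed = seed)
}

#' Inequality-shock experiment
#'
#' Runs a simulation in which, after `shock_step` completed steps, the
#' population's resource dispersion is exogenously rescaled to
#' `sigma_after` (mean preserved). A reduction in inequality imposed on a
#' poverty-trap population produces a staged phase transition: exploiters
#' lifted over the threshold first switch to lone foraging, observed
#' exploitation falls, trust recovers, and cooperation then spreads.
#'
#' @param params base [model_params()].
#' @param mu initial mean resources.
#' @param sigma_initial initial resource sd (also the policy's exogenous
#'   sigma).
#' @param sigma_after sd imposed at the shock.
#' @param shock_step step after which the shock is applied (default 16).
#' @param steps total simulation length.
#' @param seed integer seed.
#' @return A `sim_trace` with a `shock` attribute.
#' @export
shock_experiment <- function(params, mu = params$mu, sigma_initial = 4,
                             sigma_after = 3, shock_step = 16, steps = 50,
                             seed = 1) {
  run_simulation(params, mu = mu, sigma = sigma_initial, steps = steps,
                 seed = seed, shock_step = shock_step,
                 shock_sigma = sigma_after)
}
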