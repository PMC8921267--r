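#' Optimizer configuration
#'
#' Shared configuration of the four derivative-free maximizers. Population
#' sizes default to the benchmark settings: Nelder-Mead uses `Dim + 1`
#' simplex vertices, particle swarm 60 particles, CMA-ES 24 samples per
#' generation, Bayesian optimization an initial design of 5 (2Dim) or 10
#' (3Dim) points. All methods stop at `max_iterations` (80); the
#' population-based methods additionally stop when the incumbent best has
#' not strictly improved for `stall_window` (50) consecutive iterations.
#' Coefficients not pinned down by the benchmark protocol (PSO constriction
#' weights, the Nelder-Mead edge tolerance, the CMA-ES initial step, the BO
#' surrogate) are exposed here as configuration with standard literature
#' defaults.
#'
#' @param method One of `"nma"`, `"pso"`, `"cmaes"`, `"bo"`.
#' @param lambda Population size; `NULL` uses the method default.
#' @param max_iterations Iteration cap (80).
#' @param stall_window Stall rule for PSO and CMA-ES (50 iterations).
#' @param nma_edge_tol Normalized simplex-edge stopping tolerance.
#' @param nma_step Axis perturbation of the initial simplex (normalized).
#' @param pso_inertia,pso_c1,pso_c2 PSO velocity coefficients (constriction
#'   defaults 0.7298 / 1.49618 / 1.49618).
#' @param cmaes_step CMA-ES initial step size in normalized coordinates.
#' @param bo_initial Initial-design size for BO; `NULL` gives 5 in 2Dim and
#'   10 in 3Dim.
#' @return Object of class `optimizer_config`.
#' @export
optimizer_config <- function(method = c("nma", "pso", "cmaes", "bo"),
                             lambda = NULL, max_iterations = 80L,
                             stall_window = 50L, nma_edge_tol = 0.01,
                             nma_step = 0.05, pso_inertia = 0.7298,
                             pso_c1 = 1.49618, pso_c2 = 1.49618,
                             cmaes_step = 0.3, bo_initial = NULL) {
  method <- match.arg(method)
  stopifnot(max_iterations >= 1, stall_window >= 1,
            stall_window <= max_iterations)
  structure(list(method = method, lambda = lambda,
                 max_iterations = as.integer(max_iterations),
                 stall_window = as.integer(stall_window),
                 nma_edge_tol = nma_edge_tol, nma_step = nma_step,
                 pso_inertia = pso_inertia, pso_c1 = pso_c1, pso_c2 = pso_c2,
                 cmaes_step = cmaes_step, bo_initial = bo_initial),
            class = "optimizer_config")
}

#' Default CMA-ES population size
#'
#' The standard rule `4 + floor(3 * ln(Dim))`; the benchmark enlarges it to
#' 24.
#'
#' @param dim Problem dimension.
#' @return Integer population size.
#' @export
cmaes_default_lambda <- function(dim) 4L + as.integer(floor(3 * log(dim)))

optimizer_run <- function(method, best_point, best_fit, n_iterations,
                          n_evaluations, termination_reason, history, seed,
                          notes = character()) {
  structure(list(method = method, best_point = as.numeric(best_point),
                 best_fit = best_fit, n_iterations = as.integer(n_iterations),
                 n_evaluations = as.integer(n_evaluations),
                 termination_reason = termination_reason,
                 history = as.numeric(history), seed = as.integer(seed),
                 notes = notes),
            class = "optimizer_run")
}

#' @export
print.optimizer_run <- function(x, ...) {
  cat(sprintf("<optimizer_run:%s> best fit %.4f at (%s); %d iterations, %d evaluations (%s)\n",
              x$method, x$best_fit,
              paste(signif(x$best_point, 4), collapse = ", "),
              x$n_iterations, x$n_evaluations, x$termination_reason))
  invisible(x)
}

#' Run one optimizer
#'
#' Dispatches to [nelder_mead()], [particle_swarm()], [cmaes()] or
#' [bayesian_opt()].
#'
#' @param method Method name.
#' @param goal Goal closure (physical coordinates in, fit out).
#' @param bounds A [box_bounds()].
#' @param config An [optimizer_config()] (default config for the method if
#'   `NULL`).
#' @param seed Integer seed.
#' @return An `optimizer_run`.
#' @export
run_optimizer <- function(method, goal, bounds, config = NULL, seed = 1L) {
  if (is.null(config)) config <- optimizer_config(method)
  switch(method,
         nma = nelder_mead(goal, bounds, config, seed),
         pso = particle_swarm(goal, bounds, config, seed),
         cmaes = cmaes(goal, bounds, config, seed),
         bo = bayesian_opt(goal, bounds, config, seed),
         stop(sprintf("unknown method '%s'", method)))
}

#' Replicated optimizer executions for one subject
#'
#' Executes a method `n_runs` times from different random initial data
#' (distinct child seeds of `master_seed`) and assembles the per-subject run
#' set: the vector of goodness-of-fit values, the matrix of optimal points
#' (normalized to the unit box) and the per-run evaluation counts used as
#' the hardware-independent time proxy.
#'
#' @inheritParams run_optimizer
#' @param n_runs Number of replicates (15 in the full protocol).
#' @param master_seed Master seed for the replicate seeds.
#' @param subject_id Optional label carried through to the evaluation stage.
#' @return Object of class `run_set`: `method`, `fits`, `points`
#'   (normalized n_runs x Dim), `points_phys`, `time_proxy`, `runs`,
#'   `failed`, `subject_id`, `master_seed`.
#' @export
run_replicates <- function(method, goal, bounds, config = NULL, n_runs = 15L,
                           master_seed = 1L, subject_id = NULL) {
  stopifnot(n_runs >= 1)
  if (is.null(config)) config <- optimizer_config(method)
  runs <- vector("list", n_runs)
  failed <- character(n_runs)
  for (i in seq_len(n_runs)) {
    s <- child_seed(master_seed, i)
    runs[[i]] <- tryCatch(run_optimizer(method, goal, bounds, config, s),
                          error = function(e) e)
    if (inherits(runs[[i]], "error")) failed[i] <- conditionMessage(runs[[i]])
  }
  ok <- !vapply(runs, inherits, logical(1), "error")
  pts <- t(vapply(runs[ok], function(r) normalize_point(r$best_point, bounds),
                  numeric(bounds$dim)))
  structure(list(method = method,
                 fits = vapply(runs[ok], `[[`, numeric(1), "best_fit"),
                 points = pts,
                 points_phys = t(vapply(runs[ok], `[[`,
                                        numeric(bounds$dim), "best_point")),
                 time_proxy = vapply(runs[ok], function(r)
                   as.numeric(r$n_evaluations), numeric(1)),
                 runs = runs, failed = failed[!ok],
                 n_runs = sum(ok), subject_id = subject_id,
                 master_seed = as.integer(master_seed)),
            class = "run_set")
}

#' @export
print.run_set <- function(x, ...) {
  cat(sprintf("<run_set:%s> %d runs, best fit %.4f, mean evaluations %.0f\n",
              x$method, x$n_runs, max(x$fits), mean(x$time_proxy)))
  invisible(x)
}

# clamp a normalized point into the unit box
clamp01 <- function(x) pmin(pmax(x, 0), 1)
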