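#' Desk-scale optimizer benchmark on a synthetic cohort
#'
#' End-to-end study: generates a cohort of synthetic subjects with known
#' ground-truth parameters, runs the grid-search baseline and replicated
#' executions of the selected optimizers against each subject's
#' ground-truth FC, and evaluates the methods with success-probability
#' curves, the five-component multiplicative cost function, per-subject
#' recommendations and a winner tally.
#'
#' Each subject gets an individual connectome, natural frequencies drawn
#' uniformly inside the resting-state band, and a ground-truth FC simulated
#' at subject-specific true parameters `(C*, tau*)` with the noise intensity
#' fixed at `sigma_fixed`. The goal function runs in fixed-seed mode with
#' the subject's own seed, so the fit surface is deterministic and equals 1
#' exactly at the truth.
#'
#' @param n_subjects Number of subjects (8 by default).
#' @param n_regions Regions per connectome (20 by default).
#' @param density SC density of the synthetic connectomes.
#' @param grid_shape Length-2 vector: nodes along the coupling and delay
#'   axes of the 2Dim baseline grid (16 x 12 by default, spanning the
#'   default 2Dim grid ranges).
#' @param n_replicates Optimizer executions per subject and method.
#' @param methods Optimizer methods to benchmark.
#' @param sim A [sim_settings()] list; the default shortens the simulation
#'   to 80 s with a 22 s transient so a full benchmark runs on a desk
#'   machine.
#' @param truth_c_range,truth_tau_range Ranges of the per-subject true
#'   coupling and delay.
#' @param sigma_fixed Noise intensity of the 2Dim scenario (0.3).
#' @param threshold_fraction Success threshold as a fraction of the
#'   grid-search fit (0.95).
#' @param n_resamples Resamples of the success-probability estimator.
#' @param level Success-probability level whose run count enters the time
#'   component (0.8).
#' @param master_seed Master seed; everything else derives from it.
#' @param verbose Print per-subject progress.
#' @return Object of class `benchmark_study`: per-subject table
#'   (`subjects`), run sets, grid results, success curves and runs-to-level
#'   per method, the cost breakdowns, the normalized `psi` matrix,
#'   recommendations, `winner`, and the audit of goal evaluations.
#' @export
run_benchmark_study <- function(n_subjects = 8L, n_regions = 20L,
                                density = 0.35, grid_shape = c(16L, 12L),
                                n_replicates = 5L,
                                methods = c("nma", "pso", "cmaes", "bo"),
                                sim = sim_settings(duration = 80,
                                                   transient = 22),
                                truth_c_range = c(0.3, 0.7),
                                truth_tau_range = c(5, 40),
                                sigma_fixed = 0.3,
                                threshold_fraction = 0.95,
                                n_resamples = 500L, level = 0.8,
                                master_seed = 1L, verbose = FALSE) {
  stopifnot(n_subjects >= 1, n_replicates >= 2)
  cfg <- cohort_config(n_subjects, n_regions = n_regions, density = density,
                       master_seed = master_seed)
  bounds <- box_bounds(2)
  grid <- make_grid(2,
                    c_axis = seq(0, 0.945, length.out = grid_shape[1]),
                    tau_axis = seq(0, 94, length.out = grid_shape[2]))
  audit <- new_eval_audit()
  subjects <- data.frame(subject = seq_len(n_subjects), truth_c = NA_real_,
                         truth_tau = NA_real_, grid_best = NA_real_)
  runsets <- list()
  grids <- list()
  breakdowns <- list()
  for (s in seq_len(n_subjects)) {
    conn <- generate_connectome(cfg, child_seed(master_seed, 100 + s))
    freqs <- with_seed(child_seed(master_seed, 200 + s),
                       runif(n_regions, 0.02, 0.08))
    truth <- with_seed(child_seed(master_seed, 300 + s), c(
      runif(1, truth_c_range[1], truth_c_range[2]),
      runif(1, truth_tau_range[1], truth_tau_range[2])))
    subject_seed <- child_seed(master_seed, 400 + s)
    params <- model_params(truth[1], truth[2], sigma_fixed, freqs,
                           dt = sim$dt, tr = sim$tr, duration = sim$duration,
                           transient = sim$transient)
    empfc <- make_ground_truth_subject(conn, params, subject_seed)
    goal <- make_goal(conn, empfc, freqs, sim = sim,
                      seed_policy = seed_policy("fixed", subject_seed),
                      sigma_fixed = sigma_fixed, bounds = bounds,
                      audit = audit)
    gres <- run_grid_search(goal, grid)
    subjects$truth_c[s] <- truth[1]
    subjects$truth_tau[s] <- truth[2]
    subjects$grid_best[s] <- gres$best_fit
    grids[[s]] <- gres
    for (m in methods) {
      runsets[[paste(s, m, sep = ":")]] <-
        run_replicates(m, goal, bounds, n_runs = n_replicates,
                       master_seed = child_seed(master_seed, 1000 * s +
                                                  match(m, methods)),
                       subject_id = s)
    }
    if (verbose)
      message(sprintf("subject %d/%d: truth (%.3f, %.2f), grid best %.3f",
                      s, n_subjects, truth[1], truth[2], gres$best_fit))
  }
  # success curves and runs-to-level per method
  curves <- list()
  runs_needed <- list()
  for (m in methods) {
    fits <- lapply(seq_len(n_subjects), function(s)
      runsets[[paste(s, m, sep = ":")]]$fits)
    curves[[m]] <- success_curve(fits, subjects$grid_best,
                                 threshold_fraction = threshold_fraction,
                                 n_resamples = n_resamples,
                                 seed = child_seed(master_seed,
                                                   5000 + match(m, methods)))
    runs_needed[[m]] <- runs_for_level(curves[[m]], level)
  }
  # cost breakdowns: time = runs-to-level x mean per-run evaluations
  for (s in seq_len(n_subjects)) {
    gt <- grid_top_points(grids[[s]], bounds)
    for (m in methods) {
      rs <- runsets[[paste(s, m, sep = ":")]]
      t80 <- runs_needed[[m]]$runs * mean(rs$time_proxy)
      breakdowns[[paste(s, m, sep = ":")]] <- cost_components(rs, gt, t80)
    }
  }
  agg <- aggregate_costs(breakdowns)
  time_mat <- matrix(NA_real_, n_subjects, length(methods),
                     dimnames = list(as.character(seq_len(n_subjects)),
                                     sort(methods)))
  for (b in breakdowns)
    time_mat[as.character(b$subject_id), b$method] <- b$comp_time
  rec <- recommend_methods(agg$psi, time_mat)
  structure(list(subjects = subjects, runsets = runsets, grids = grids,
                 curves = curves, runs_needed = runs_needed,
                 breakdowns = breakdowns, psi = agg$psi,
                 normalized = agg$normalized,
                 recommendations = rec, winner = rec$winner,
                 methods = methods, bounds = bounds, grid = grid, sim = sim,
                 n_evaluations = audit$count,
                 master_seed = as.integer(master_seed)),
            class = "benchmark_study")
}

#' @export
print.benchmark_study <- function(x, ...) {
  cat(sprintf("<benchmark_study> %d subjects x {%s}, %d goal evaluations\n",
              nrow(x$subjects), paste(x$methods, collapse = ", "),
              round(x$n_evaluations)))
  cat(sprintf("  winner: %s (recommendations: %s)\n", x$winner,
              paste(sprintf("%s=%d", names(x$recommendations$tally),
                            as.integer(x$recommendations$tally)),
                    collapse = ", ")))
  invisible(x)
}
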