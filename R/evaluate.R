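#' Closed-form success probability
#'
#' Probability that at least one of `r` goodness-of-fit values drawn without
#' replacement from `r_max` available runs passes the threshold, when
#' exactly `n_pass` of them pass: `1 - choose(r_max - n_pass, r) /
#' choose(r_max, r)` (hypergeometric). Serves as the exact oracle for the
#' resampling estimator.
#'
#' @param n_pass Number of passing fits among the `r_max` runs.
#' @param r_max Total number of runs.
#' @param r Number of runs drawn.
#' @return Probability in `[0, 1]`.
#' @export
success_closed_form <- function(n_pass, r_max, r) {
  stopifnot(r >= 1, r <= r_max, n_pass >= 0, n_pass <= r_max)
  1 - choose(r_max - n_pass, r) / choose(r_max, r)
}

# resampled per-subject success rate for one r
resample_success <- function(fits, threshold, r, n_resamples) {
  mean(vapply(seq_len(n_resamples), function(i)
    any(sample(fits, r) >= threshold), logical(1)))
}

#' Success-probability curve over the number of runs
#'
#' For each subject, `r` goodness-of-fit values are drawn without
#' replacement from the available runs `n_resamples` times; a draw succeeds
#' when its best value reaches `threshold_fraction` of that subject's
#' grid-search fit. The curve reports, for r from 1 to `r_max`, the mean
#' over subjects of the per-subject resampled success rates, with the
#' standard error across subjects.
#'
#' @param fits_by_subject List of per-subject fit vectors (one element per
#'   subject; all of length >= `r_max`).
#' @param grid_best Vector of per-subject grid-search best fits (positive).
#' @param r_max Largest number of runs considered; defaults to the shortest
#'   fit vector.
#' @param threshold_fraction Fraction of the grid fit counted as success
#'   (0.95).
#' @param n_resamples Resamples per subject and `r` (500).
#' @param seed Integer seed for the resampling.
#' @return Object of class `success_curve`: data frame `curve` with columns
#'   `r`, `probability`, `se`, plus the settings.
#' @export
success_curve <- function(fits_by_subject, grid_best, r_max = NULL,
                          threshold_fraction = 0.95, n_resamples = 500L,
                          seed = 1L) {
  if (!is.list(fits_by_subject)) fits_by_subject <- list(fits_by_subject)
  n_sub <- length(fits_by_subject)
  stopifnot(length(grid_best) == n_sub, all(grid_best > 0))
  lens <- vapply(fits_by_subject, length, integer(1))
  if (is.null(r_max)) r_max <- min(lens)
  if (r_max > min(lens)) stop("r exceeds the number of available runs")
  probs <- matrix(NA_real_, n_sub, r_max)
  with_seed(seed, {
    for (s in seq_len(n_sub)) {
      thr <- threshold_fraction * grid_best[s]
      fits <- fits_by_subject[[s]]
      for (r in seq_len(r_max)) {
        n_p <- sum(fits >= thr)
        probs[s, r] <- if (n_p == 0) 0 else if (n_p == length(fits)) 1 else
          resample_success(fits, thr, r, n_resamples)
      }
    }
  })
  p <- colMeans(probs)
  se <- if (n_sub > 1) apply(probs, 2, sd) / sqrt(n_sub)
        else sqrt(pmax(p * (1 - p), 0) / n_resamples)
  structure(list(curve = data.frame(r = seq_len(r_max), probability = p,
                                    se = se),
                 r_max = as.integer(r_max),
                 threshold_fraction = threshold_fraction,
                 n_resamples = as.integer(n_resamples),
                 n_subjects = n_sub, seed = as.integer(seed)),
            class = "success_curve")
}

#' Runs needed to reach a success-probability level
#'
#' Smallest number of runs whose success probability reaches `level`; when
#' the level is never reached within `r_max` runs, `r_max` is returned with
#' `reached = FALSE` (the convention used when budgeting computation time
#' for a method that never attains the level).
#'
#' @param curve A [success_curve()] (or a plain numeric probability vector).
#' @param level Probability level in (0, 1), e.g. 0.5 or 0.8.
#' @return List with `runs` and logical `reached`.
#' @export
runs_for_level <- function(curve, level) {
  stopifnot(level > 0, level < 1)
  p <- if (inherits(curve, "success_curve")) curve$curve$probability
       else as.numeric(curve)
  if (length(p) == 0) stop("empty success curve")
  hit <- which(p >= level)
  if (length(hit) == 0) list(runs = length(p), reached = FALSE)
  else list(runs = hit[1], reached = TRUE)
}

#' Unnormalized cost-function components for one subject and method
#'
#' The five multiplicative components: `1 - max(Fit)`; the population
#' standard deviation of the fits (`1/R` convention); the computation time
#' needed for the runs-to-80%-success (`time_for_80`, in goal evaluations by
#' default); the mean pairwise Euclidean distance between the optimizer
#' solutions in the normalized box (divisor `choose(R, 2)`, the 105 pairs of
#' the 15-run protocol); and the mean over solutions of the distance to the
#' nearest of the five grid-search points. The last term follows the
#' printed product form (minimum over grid points); `dist_rule = "mean"`
#' switches to the mean over grid points.
#'
#' @param runset A [run_replicates()] result (needs >= 2 runs).
#' @param gridtop Matrix of up to five grid points in normalized
#'   coordinates, e.g. from [grid_top_points()].
#' @param time_for_80 Cumulated computation time (or evaluation-count proxy)
#'   for the runs needed to reach 80% success probability.
#' @param dist_rule `"min"` (default) or `"mean"` for the grid-distance term.
#' @return Object of class `cost_breakdown` with `comp_fit`, `comp_sd`,
#'   `comp_time`, `comp_spread`, `comp_dist`, `r_max`.
#' @export
cost_components <- function(runset, gridtop, time_for_80,
                            dist_rule = c("min", "mean")) {
  dist_rule <- match.arg(dist_rule)
  fits <- runset$fits
  pts <- as.matrix(runset$points)
  r <- length(fits)
  if (r < 2) stop("solution spread undefined with fewer than 2 runs")
  if (any(pts < -1e-9) || any(pts > 1 + 1e-9))
    stop("runset points must be in normalized [0,1]^Dim coordinates")
  gridtop <- as.matrix(gridtop)
  comp_fit <- 1 - max(fits)
  comp_sd <- sqrt(mean((fits - mean(fits))^2))
  pd <- dist(pts)
  comp_spread <- sum(pd) / choose(r, 2)
  dmat <- vapply(seq_len(nrow(gridtop)), function(k)
    sqrt(rowSums(sweep(pts, 2, gridtop[k, ])^2)), numeric(r))
  dmat <- matrix(dmat, nrow = r)
  per_run <- if (dist_rule == "min") apply(dmat, 1, min)
             else rowMeans(dmat)
  comp_dist <- mean(per_run)
  structure(list(comp_fit = comp_fit, comp_sd = comp_sd,
                 comp_time = time_for_80, comp_spread = comp_spread,
                 comp_dist = comp_dist, r_max = r,
                 method = runset$method, subject_id = runset$subject_id),
            class = "cost_breakdown")
}

#' Normalize cost components and form the multiplicative cost
#'
#' Each component is divided by its maximum over all subjects and methods
#' (within one parameter-space dimensionality), mapping it to `[0, 1]`; the
#' final cost is the product of the five normalized components. An all-zero
#' component is left at zero for every cell (with a note).
#'
#' @param components Data frame with columns `subject`, `method`,
#'   `comp_fit`, `comp_sd`, `comp_time`, `comp_spread`, `comp_dist` (one row
#'   per subject x method), or a list of `cost_breakdown` objects.
#' @return List with `psi` (subjects x methods matrix), `normalized` (data
#'   frame of normalized components), `maxima`, `notes`.
#' @export
aggregate_costs <- function(components) {
  if (is.list(components) && !is.data.frame(components)) {
    components <- do.call(rbind, lapply(components, function(b)
      data.frame(subject = b$subject_id, method = b$method,
                 comp_fit = b$comp_fit, comp_sd = b$comp_sd,
                 comp_time = b$comp_time, comp_spread = b$comp_spread,
                 comp_dist = b$comp_dist)))
  }
  comp_cols <- c("comp_fit", "comp_sd", "comp_time", "comp_spread",
                 "comp_dist")
  stopifnot(all(c("subject", "method", comp_cols) %in% names(components)))
  notes <- character()
  maxima <- vapply(comp_cols, function(cc) max(components[[cc]]), numeric(1))
  norm <- components
  for (cc in comp_cols) {
    if (maxima[[cc]] == 0) {
      norm[[cc]] <- 0
      notes <- c(notes, sprintf("component %s is zero everywhere", cc))
    } else {
      norm[[cc]] <- components[[cc]] / maxima[[cc]]
    }
  }
  norm$psi <- norm$comp_fit * norm$comp_sd * norm$comp_time *
    norm$comp_spread * norm$comp_dist
  subjects <- unique(norm$subject)
  methods <- sort(unique(norm$method))
  psi <- matrix(NA_real_, length(subjects), length(methods),
                dimnames = list(as.character(subjects), methods))
  for (i in seq_len(nrow(norm)))
    psi[as.character(norm$subject[i]), norm$method[i]] <- norm$psi[i]
  list(psi = psi, normalized = norm, maxima = maxima, notes = notes)
}

#' Per-subject recommendations and the winning method
#'
#' The recommended method for a subject is the one with the smallest cost;
#' ties are broken by the lower time component, then lexicographically by
#' method name (logged). The winner is the method gathering the most
#' recommendations across the cohort.
#'
#' @param psi Subjects x methods cost matrix (as from [aggregate_costs()]).
#' @param comp_time Optional subjects x methods matrix of time components
#'   used for tie-breaking.
#' @return List with `recommendation` (character per subject), `tally`
#'   (named counts summing to the number of subjects), `winner`, `ties`
#'   (logical per subject), `notes`.
#' @export
recommend_methods <- function(psi, comp_time = NULL) {
  psi <- as.matrix(psi)
  if (any(is.na(psi))) stop("psi has missing cells")
  methods <- colnames(psi)
  if (is.null(methods)) methods <- paste0("m", seq_len(ncol(psi)))
  notes <- character()
  rec <- character(nrow(psi))
  ties <- logical(nrow(psi))
  for (s in seq_len(nrow(psi))) {
    cand <- which(psi[s, ] == min(psi[s, ]))
    ties[s] <- length(cand) > 1
    if (ties[s] && !is.null(comp_time)) {
      tt <- comp_time[s, cand]
      cand <- cand[tt == min(tt)]
    }
    if (length(cand) > 1) {
      cand <- cand[order(methods[cand])][1]
      notes <- c(notes, sprintf("subject %s: tie broken lexicographically",
                                rownames(psi)[s] %||% s))
    }
    rec[s] <- methods[cand[1]]
  }
  tally <- table(factor(rec, levels = methods))
  list(recommendation = rec, tally = tally,
       winner = methods[which.max(tally)], ties = ties, notes = notes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extrapolated grid-search cost
#'
#' The back-of-the-envelope scaling of a dense grid search: if one sweep of
#' `p` points along one dimension takes `t_per_sweep` seconds, a
#' `p^dim`-point grid costs `t * p^(dim-1)` per subject, and
#' `s * t * p^(dim-1)` for a cohort, returned in hours.
#'
#' @param t_per_sweep Seconds for a one-dimensional sweep of `p` points.
#' @param p Points per dimension.
#' @param dim Number of free parameters.
#' @param s_subjects Cohort size.
#' @return Hours of computation.
#' @export
estimate_grid_cost <- function(t_per_sweep, p, dim, s_subjects = 1) {
  stopifnot(t_per_sweep > 0, p > 0, dim >= 1, s_subjects > 0)
  s_subjects * t_per_sweep * p^(dim - 1) / 3600
}
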