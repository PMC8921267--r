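#' Structural connectome container
#'
#' Holds a streamline-count matrix (`sc`) and a mean path-length matrix
#' (`pl`). Both must be symmetric with zero diagonal, `sc` nonnegative and
#' `pl` strictly positive wherever `sc > 0`; `pl` is proportional to the
#' signal-transmission delay between regions.
#'
#' @param sc N x N nonnegative symmetric matrix of streamline counts.
#' @param pl N x N symmetric matrix of mean streamline path lengths.
#' @param region_ids Optional character vector of region labels.
#' @return An object of class `connectome` with fields `sc`, `pl`,
#'   `n_regions`, `region_ids`.
#' @export
connectome <- function(sc, pl, region_ids = NULL) {
  sc <- as.matrix(sc); pl <- as.matrix(pl)
  n <- nrow(sc)
  if (n < 2 || ncol(sc) != n) stop("sc must be square with N >= 2")
  if (!all(dim(pl) == c(n, n))) stop("pl must have the same shape as sc")
  if (any(!is.finite(sc)) || any(!is.finite(pl)))
    stop("connectome matrices must be finite")
  if (max(abs(sc - t(sc))) > 1e-8 * max(1, max(abs(sc))))
    stop("sc must be symmetric")
  if (max(abs(pl - t(pl))) > 1e-8 * max(1, max(abs(pl))))
    stop("pl must be symmetric")
  if (any(diag(sc) != 0) || any(diag(pl) != 0))
    stop("sc and pl must have zero diagonals")
  if (any(sc < 0)) stop("sc must be nonnegative")
  if (any(pl[sc > 0] <= 0)) stop("pl must be positive wherever sc > 0")
  if (is.null(region_ids)) region_ids <- paste0("R", seq_len(n))
  structure(list(sc = sc, pl = pl, n_regions = n,
                 region_ids = as.character(region_ids)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  dens <- mean(x$sc[upper.tri(x$sc)] > 0)
  cat(sprintf("<connectome> %d regions, SC density %.2f, PL range [%.1f, %.1f]\n",
              x$n_regions, dens, min(x$pl[x$sc > 0]), max(x$pl)))
  invisible(x)
}

#' Configuration of a synthetic cohort
#'
#' Defines the statistical structure of the generated subjects. Defaults
#' emulate the multi-session resting-state acquisition the fitting pipeline
#' assumes: four sessions of 1200 volumes at a repetition time of 0.72 s.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions Number of brain regions N (parcels); 100 by default.
#' @param density Fraction of nonzero off-diagonal SC pairs, in (0, 1].
#' @param weight_scale Scale (median) of the log-normal SC weights.
#' @param length_range Length-2 vector `(min, max)` of path-length values, in
#'   the same arbitrary units as PL (millimetres for tractography data).
#' @param tr Repetition time in seconds.
#' @param volumes_per_session Volumes (time points) per BOLD session.
#' @param n_sessions Number of BOLD sessions per subject.
#' @param master_seed Master seed from which subject seeds are derived.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, n_regions = 100L, density = 0.35,
                          weight_scale = 1, length_range = c(20, 160),
                          tr = 0.72, volumes_per_session = 1200L,
                          n_sessions = 4L, master_seed = 1L) {
  stopifnot(n_subjects >= 1, n_regions >= 1, density > 0, density <= 1,
            weight_scale > 0, length(length_range) == 2,
            length_range[1] > 0, length_range[1] < length_range[2],
            tr > 0, volumes_per_session >= 1, n_sessions >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 density = density, weight_scale = weight_scale,
                 length_range = as.numeric(length_range), tr = tr,
                 volumes_per_session = as.integer(volumes_per_session),
                 n_sessions = as.integer(n_sessions),
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

#' Generate a synthetic structural connectome
#'
#' Regions are placed uniformly at random in a cube; their Euclidean
#' distances, rescaled affinely into `length_range`, give the path-length
#' matrix PL (symmetric, triangle-like structure by construction). Pair
#' weights are log-normal magnitudes damped by an exponential distance decay
#' `exp(-PL/lambda)` with `lambda` equal to half the span of `length_range`,
#' reproducing the heavy-tailed, distance-dependent statistics of
#' tractography-based SC. The top `round(density * N(N-1)/2)` pairs by weight
#' are kept; all other entries are zero.
#'
#' @param config A [cohort_config()].
#' @param subject_seed Integer seed; the generator is a pure function of
#'   `(config, subject_seed)`.
#' @return A [connectome()].
#' @export
generate_connectome <- function(config, subject_seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_regions
  if (n < 2) stop("n_regions must be at least 2 to build a connectome")
  lr <- config$length_range
  with_seed(subject_seed, {
    coords <- matrix(runif(3 * n), n, 3)
    dmat <- as.matrix(dist(coords))
    ut <- upper.tri(dmat)
    dv <- dmat[ut]
    plv <- lr[1] + (dv - min(dv)) / (max(dv) - min(dv)) * (lr[2] - lr[1])
    lambda <- (lr[2] - lr[1]) / 2
    wv <- rlnorm(length(plv), meanlog = log(config$weight_scale), sdlog = 1) *
      exp(-plv / lambda)
    n_pairs <- n * (n - 1) / 2
    # signif() guards the pair count against binary floating artifacts
    # (e.g. 0.3 * 1225 evaluating just below 367.5)
    n_keep <- as.integer(round(signif(config$density * n_pairs, 12)))
    keep <- rank(-wv, ties.method = "first") <= n_keep
    scv <- ifelse(keep, wv, 0)
    sc <- matrix(0, n, n); pl <- matrix(0, n, n)
    sc[ut] <- scv; pl[ut] <- plv
    sc <- sc + t(sc); pl <- pl + t(pl)
    connectome(sc, pl)
  })
}
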