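#' BOLD session set container
#'
#' A list of T x N matrices (time by region) sharing a repetition time and a
#' region labelling; the unit the empirical-feature extractors
#' ([estimate_natural_frequencies()], [compute_empirical_fc()]) operate on.
#'
#' @param sessions List of T x N numeric matrices.
#' @param tr Repetition time in seconds.
#' @param region_ids Optional character region labels.
#' @return Object of class `bold_session_set`.
#' @export
bold_session_set <- function(sessions, tr, region_ids = NULL) {
  stopifnot(is.list(sessions), length(sessions) >= 1, tr > 0)
  sessions <- lapply(sessions, as.matrix)
  n <- ncol(sessions[[1]])
  for (s in sessions) {
    if (ncol(s) != n) stop("all sessions must share the number of regions")
    if (any(!is.finite(s))) stop("BOLD sessions must not contain missing values")
  }
  if (is.null(region_ids)) region_ids <- paste0("R", seq_len(n))
  structure(list(sessions = sessions, tr = tr,
                 region_ids = as.character(region_ids)),
            class = "bold_session_set")
}

#' Generate synthetic BOLD sessions
#'
#' Each region oscillates sinusoidally at its assigned natural frequency with
#' a random phase, superposed with Gaussian noise; a correlation matrix
#' (`coupling_fc`) may be supplied to induce inter-regional correlation of
#' the noise via its Cholesky factor. Sessions are independent given the
#' seed; the periodogram peak of each region within 0.01-0.1 Hz lies at its
#' assigned frequency up to the spectral resolution.
#'
#' @param config A [cohort_config()].
#' @param frequencies Vector of region frequencies in Hz (below Nyquist).
#' @param coupling_fc Optional [fc_matrix()] (or plain correlation matrix)
#'   used to correlate the noise across regions; `NULL` for independent
#'   noise.
#' @param subject_seed Integer seed.
#' @param noise_amp Standard deviation of the additive noise relative to the
#'   unit-amplitude sinusoids; 0 gives pure sinusoids.
#' @return A [bold_session_set()].
#' @export
generate_bold_sessions <- function(config, frequencies, coupling_fc = NULL,
                                   subject_seed = 1L, noise_amp = 0.5) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_regions
  if (length(frequencies) != n)
    stop("frequencies must have length n_regions")
  nyq <- 0.5 / config$tr
  if (any(frequencies <= 0) || any(frequencies >= nyq))
    stop(sprintf("frequencies must lie in (0, %.4f) Hz (below Nyquist)", nyq))
  cf <- NULL
  if (!is.null(coupling_fc)) {
    v <- if (inherits(coupling_fc, "fc_matrix")) coupling_fc$values
         else as.matrix(coupling_fc)
    if (!all(dim(v) == c(n, n))) stop("coupling_fc must be N x N")
    cf <- chol(v)
  }
  tt <- (seq_len(config$volumes_per_session) - 1) * config$tr
  sessions <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    sessions[[s]] <- with_seed(child_seed(subject_seed, s), {
      phase <- runif(n, 0, 2 * pi)
      sig <- vapply(seq_len(n),
                    function(i) sin(2 * pi * frequencies[i] * tt + phase[i]),
                    numeric(length(tt)))
      if (noise_amp > 0) {
        z <- matrix(rnorm(length(tt) * n), length(tt), n)
        if (!is.null(cf)) z <- z %*% cf
        sig <- sig + noise_amp * z
      }
      sig
    })
  }
  bold_session_set(sessions, tr = config$tr)
}

# Remove a least-squares linear trend from each column.
detrend_linear <- function(x) {
  x <- as.matrix(x)
  t_idx <- seq_len(nrow(x))
  xm <- cbind(1, t_idx)
  x - xm %*% qr.coef(qr(xm), x)
}

# Detrend, then z-score each column; errors on zero-variance columns
# (checked before detrending, where a constant column is exactly constant).
detrend_zscore <- function(x, region_ids = NULL, where = "session") {
  x <- as.matrix(x)
  sds0 <- apply(x, 2, sd)
  x <- detrend_linear(x)
  sds <- apply(x, 2, sd)
  if (any(sds0 == 0) || any(sds == 0)) {
    bad <- which(sds0 == 0 | sds == 0)[1]
    lab <- if (!is.null(region_ids)) region_ids[bad] else as.character(bad)
    stop(sprintf("region %s has constant signal (zero variance) in %s",
                 lab, where))
  }
  scale(x, center = TRUE, scale = sds)
}

#' Estimate natural frequencies from BOLD spectra
#'
#' Per region, returns the frequency of the maximal peak of the raw
#' periodogram (no tapering or averaging) of the linearly detrended, z-scored
#' and session-concatenated signal, restricted to bins inside `band`. The
#' spectral resolution is `1/(T_total * tr)`.
#'
#' @param bold A [bold_session_set()].
#' @param band Length-2 vector `(low, high)` in Hz; default the 0.01-0.1 Hz
#'   range in which resting-state BOLD power concentrates.
#' @return Numeric vector of frequencies (Hz), one per region.
#' @export
estimate_natural_frequencies <- function(bold, band = c(0.01, 0.1)) {
  stopifnot(inherits(bold, "bold_session_set"), length(band) == 2,
            band[1] < band[2], band[1] > 0)
  nyq <- 0.5 / bold$tr
  if (band[2] > nyq) stop("band must lie below the Nyquist frequency")
  x <- do.call(rbind, lapply(seq_along(bold$sessions), function(s)
    detrend_zscore(bold$sessions[[s]], bold$region_ids,
                   sprintf("session %d", s))))
  nt <- nrow(x)
  freqs <- (seq_len(nt) - 1) / (nt * bold$tr)
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (length(in_band) < 1)
    stop("frequency band is empty after discretization; series too short")
  pw <- abs(mvfft(x))^2
  f_hat <- freqs[in_band[apply(pw[in_band, , drop = FALSE], 2, which.max)]]
  names(f_hat) <- bold$region_ids
  f_hat
}

#' Empirical functional connectivity from BOLD sessions
#'
#' Pearson correlation of per-session linearly detrended, z-scored BOLD time
#' series concatenated across sessions (z-scoring before concatenation keeps
#' sessions on a common scale).
#'
#' @param bold A [bold_session_set()].
#' @return An [fc_matrix()].
#' @export
compute_empirical_fc <- function(bold) {
  stopifnot(inherits(bold, "bold_session_set"))
  total_t <- sum(vapply(bold$sessions, nrow, integer(1)))
  if (total_t < 3) stop("need at least 3 time points in total per region")
  x <- do.call(rbind, lapply(seq_along(bold$sessions), function(s)
    detrend_zscore(bold$sessions[[s]], bold$region_ids,
                   sprintf("session %d", s))))
  fc_matrix(cor(x), region_ids = bold$region_ids)
}
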