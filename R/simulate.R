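#' Functional connectivity matrix container
#'
#' N x N symmetric Pearson-correlation matrix with unit diagonal, used for
#' both empirical (`empFC`) and simulated (`simFC`) connectivity.
#'
#' @param values N x N numeric matrix.
#' @param region_ids Optional region labels.
#' @return Object of class `fc_matrix` with fields `values`, `region_ids`.
#' @export
fc_matrix <- function(values, region_ids = NULL) {
  v <- as.matrix(values)
  n <- nrow(v)
  if (ncol(v) != n) stop("FC matrix must be square")
  if (any(!is.finite(v))) stop("FC matrix must be finite")
  if (max(abs(v - t(v))) > 1e-8) stop("FC matrix must be symmetric")
  v <- (v + t(v)) / 2
  if (max(abs(diag(v) - 1)) > 1e-8) stop("FC matrix diagonal must be 1")
  diag(v) <- 1
  if (max(abs(v)) > 1 + 1e-8) stop("FC entries must lie in [-1, 1]")
  v[v > 1] <- 1; v[v < -1] <- -1
  if (is.null(region_ids)) region_ids <- paste0("R", seq_len(n))
  structure(list(values = v, region_ids = as.character(region_ids)),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  ut <- x$values[upper.tri(x$values)]
  cat(sprintf("<fc_matrix> %d regions, off-diagonal range [%.3f, %.3f], mean %.3f\n",
              nrow(x$values), min(ut), max(ut), mean(ut)))
  invisible(x)
}

#' Model parameters for the phase-oscillator simulation
#'
#' @param coupling_c Dimensionless global coupling C >= 0.
#' @param delay_tau Global delay tau in seconds, >= 0.
#' @param noise_sigma Dimensionless noise intensity sigma >= 0.
#' @param frequencies Natural frequencies f_i in Hz (one per region, all > 0).
#' @param dt Integration step in seconds (0.06 by default).
#' @param tr Output sampling period in seconds (0.72 by default); must be an
#'   integer multiple of `dt`.
#' @param duration Total simulated time in seconds.
#' @param transient Initial interval discarded before computing FC, seconds.
#' @return Object of class `model_params`.
#' @export
model_params <- function(coupling_c, delay_tau, noise_sigma, frequencies,
                         dt = 0.06, tr = 0.72, duration = 4000,
                         transient = 500) {
  stopifnot(coupling_c >= 0, delay_tau >= 0, noise_sigma >= 0,
            all(frequencies > 0), dt > 0, tr > 0, duration > transient,
            transient >= 0)
  stride <- tr / dt
  if (abs(stride - round(stride)) > 1e-8)
    stop("tr must be an integer multiple of dt")
  structure(list(coupling_c = coupling_c, delay_tau = delay_tau,
                 noise_sigma = noise_sigma,
                 frequencies = as.numeric(frequencies), dt = dt, tr = tr,
                 duration = duration, transient = transient),
            class = "model_params")
}

#' Simulation length settings
#'
#' Convenience bundle of the integration/sampling settings shared by all goal
#' evaluations of a study. The defaults are the full-scale conditions (3500 s
#' of retained signal after a 500 s transient); desk-scale studies shorten
#' `duration`/`transient`.
#'
#' @inheritParams model_params
#' @return A list with fields `dt`, `tr`, `duration`, `transient`.
#' @export
sim_settings <- function(dt = 0.06, tr = 0.72, duration = 4000,
                         transient = 500) {
  list(dt = dt, tr = tr, duration = duration, transient = transient)
}

#' Build pairwise couplings and delays from a connectome
#'
#' Scales the structural matrices into the model's coupling and delay
#' parameters: `k_ij = SC_ij / <SC> * C / N` and `tau_ij = PL_ij / <PL> *
#' tau`, where `< >` is the mean over all off-diagonal entries (zeros
#' included, diagonal excluded). Continuous delays are discretized to
#' integration steps by nearest-integer rounding, `d_ij = round(tau_ij /
#' dt)`.
#'
#' @param connectome A [connectome()].
#' @param coupling_c Global coupling C >= 0.
#' @param delay_tau Global delay tau in seconds >= 0.
#' @param dt Integration step in seconds.
#' @param max_delay Optional cap (seconds) on the largest admissible pairwise
#'   delay; exceeding it is an error.
#' @return Object of class `coupling_spec` with fields `k` (N x N),
#'   `delay_steps` (N x N integer) and `dt`.
#' @export
build_coupling <- function(connectome, coupling_c, delay_tau, dt = 0.06,
                           max_delay = NULL) {
  stopifnot(inherits(connectome, "connectome"), coupling_c >= 0,
            delay_tau >= 0, dt > 0)
  n <- connectome$n_regions
  off <- !diag(n)
  mean_sc <- mean(connectome$sc[off])
  if (mean_sc == 0) stop("empty connectome: mean off-diagonal SC is zero")
  k <- connectome$sc / mean_sc * (coupling_c / n)
  diag(k) <- 0
  if (delay_tau > 0) {
    mean_pl <- mean(connectome$pl[off])
    if (mean_pl == 0) stop("mean off-diagonal PL is zero but delay_tau > 0")
    tau_ij <- connectome$pl / mean_pl * delay_tau
  } else {
    tau_ij <- matrix(0, n, n)
  }
  if (!is.null(max_delay) && max(tau_ij) > max_delay)
    stop(sprintf("maximal pairwise delay %.2f s exceeds cap %.2f s",
                 max(tau_ij), max_delay))
  d <- matrix(as.integer(round(tau_ij / dt)), n, n)
  d[k == 0] <- 0L
  structure(list(k = k, delay_steps = d, dt = dt), class = "coupling_spec")
}

# Index of the first/last retained downsampled sample: samples sit at
# t = m * tr; the first retained one is the smallest m*tr >= transient.
sample_window <- function(duration, transient, tr) {
  m0 <- as.integer(ceiling(transient / tr - 1e-9))
  m1 <- as.integer(floor(duration / tr + 1e-9))
  if (m1 < m0) stop("no samples retained: duration too short for transient")
  list(m0 = m0, m1 = m1, n_retained = m1 - m0 + 1L)
}

#' Integrate the delay-coupled phase oscillators (stochastic Heun)
#'
#' Solves `dtheta_i/dt = 2*pi*f_i + sum_j k_ij sin(theta_j(t - tau_ij) -
#' theta_i(t)) + sigma*eta_i(t)` with `eta ~ U[-1, 1]` using the
#' predictor-corrector (Heun) scheme at step `dt`. The noise increment
#' `sigma*sqrt(dt)*u` is added once per step and is identical in predictor
#' and corrector. Delay history is a ring buffer of depth `max(d_ij) + 1`
#' pre-filled with the initial phases; initial phases are uniform on
#' `[0, 2*pi)` drawn from `seed` unless `init_phases` is given. Phases are
#' stored unwrapped and downsampled to the repetition time, discarding
#' samples before the transient. The trajectory is bitwise reproducible
#' given the seed.
#'
#' @param spec A [build_coupling()] result.
#' @param params A [model_params()] (its `dt` must equal `spec$dt`).
#' @param seed Integer seed for initial phases and noise.
#' @param init_phases Optional vector of initial phases (radians) overriding
#'   the random initialization.
#' @param max_delay Optional cap (seconds) on the largest pairwise delay;
#'   exceeding it is an error. Unlimited by default: delays longer than the
#'   simulation are well-defined (the delayed input stays at the constant
#'   pre-history) though dynamically degenerate.
#' @return Object of class `phase_trajectory`: `theta` (M x N matrix of
#'   unwrapped phases at the downsampled rate), `tr`, `t0` (time of the
#'   first retained sample).
#' @export
heun_integrate <- function(spec, params, seed, init_phases = NULL,
                           max_delay = NULL) {
  stopifnot(inherits(spec, "coupling_spec"), inherits(params, "model_params"))
  n <- length(params$frequencies)
  if (nrow(spec$k) != n)
    stop("coupling spec and params disagree on the number of regions")
  if (abs(spec$dt - params$dt) > 1e-12)
    stop("spec and params disagree on dt")
  stride <- as.integer(round(params$tr / params$dt))
  if (abs(stride - params$tr / params$dt) > 1e-8)
    stop("tr must be an integer multiple of dt")
  w <- sample_window(params$duration, params$transient, params$tr)
  max_d <- max(spec$delay_steps)
  if (!is.null(max_delay) && max_d * params$dt > max_delay)
    stop(sprintf("maximal pairwise delay %.2f s exceeds cap %.2f s",
                 max_d * params$dt, max_delay))
  theta <- heun_kuramoto_cpp(spec$k, spec$delay_steps,
                             2 * pi * params$frequencies,
                             params$noise_sigma, params$dt, stride,
                             w$m0, w$m1, as.integer(seed), init_phases)
  structure(list(theta = theta, tr = params$tr, t0 = w$m0 * params$tr),
            class = "phase_trajectory")
}

#' Convert a phase trajectory to simulated BOLD
#'
#' The simulated BOLD signal of region i is `sin(theta_i(t))` at the
#' retained, downsampled samples.
#'
#' @param traj A [heun_integrate()] result.
#' @return T x N numeric matrix with values in `[-1, 1]`.
#' @export
phases_to_bold <- function(traj) {
  stopifnot(inherits(traj, "phase_trajectory"))
  sin(traj$theta)
}

#' Pearson functional connectivity of simulated BOLD
#'
#' @param bold T x N matrix of simulated BOLD (T >= 3, no constant columns).
#' @param region_ids Optional region labels.
#' @return An [fc_matrix()].
#' @export
bold_to_fc <- function(bold, region_ids = NULL) {
  bold <- as.matrix(bold)
  if (nrow(bold) < 3) stop("need at least 3 time points to correlate")
  sds <- apply(bold, 2, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    lab <- if (!is.null(region_ids)) region_ids[bad] else as.character(bad)
    stop(sprintf("region %s has constant simulated signal (zero variance)", lab))
  }
  fc_matrix(cor(bold), region_ids = region_ids)
}

#' Simulate functional connectivity at a parameter point
#'
#' Convenience composition: build couplings and delays, integrate, convert
#' phases to BOLD and correlate.
#'
#' @inheritParams heun_integrate
#' @param connectome A [connectome()].
#' @return An [fc_matrix()].
#' @export
simulate_fc <- function(connectome, params, seed, init_phases = NULL) {
  spec <- build_coupling(connectome, params$coupling_c, params$delay_tau,
                         dt = params$dt)
  traj <- heun_integrate(spec, params, seed, init_phases)
  bold_to_fc(phases_to_bold(traj), region_ids = connectome$region_ids)
}

#' Create a ground-truth subject for parameter recovery
#'
#' Runs the simulator at known parameters `(C*, tau*, sigma*)` and returns
#' the resulting simFC as the subject's "empirical" FC. Re-evaluating the
#' goal function at the truth with the same fixed seed then returns exactly
#' 1, which anchors parameter-recovery tests.
#'
#' @param connectome A [connectome()].
#' @param params A [model_params()] holding the true parameters.
#' @param subject_seed Integer seed used for the ground-truth simulation.
#' @return An [fc_matrix()].
#' @export
make_ground_truth_subject <- function(connectome, params, subject_seed) {
  simulate_fc(connectome, params, subject_seed)
}
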