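# shared fixtures: all built in code, nothing stored on disk

with_seed <- kurafit:::with_seed
normalize_point <- kurafit:::normalize_point

# small synthetic connectome
tiny_connectome <- function(n = 6, seed = 42, density = 0.6) {
  generate_connectome(cohort_config(1, n_regions = n, density = density),
                      seed)
}

# short simulation settings for fit tests
desk_sim <- function(duration = 80, transient = 22) {
  sim_settings(duration = duration, transient = transient)
}

# coupling spec assembled by hand (bypasses SC/PL scaling)
raw_coupling <- function(k, d = NULL, dt = 0.06) {
  k <- as.matrix(k)
  if (is.null(d)) d <- matrix(0L, nrow(k), ncol(k))
  structure(list(k = k, delay_steps = matrix(as.integer(d), nrow(k)),
                 dt = dt), class = "coupling_spec")
}

# symmetric unit-diagonal matrix from its upper-triangle entries
# (column-major order)
mat_from_ut <- function(ut, n) {
  m <- diag(n)
  m[upper.tri(m)] <- ut
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# deterministic concave bump on the normalized unit box, maximum at u*
bump_goal <- function(bounds, ustar) {
  audited_goal(function(p) {
    u <- normalize_point(p, bounds)
    exp(-20 * sum((u - ustar)^2))
  })
}

# run_set stub for the evaluation module
fake_runset <- function(fits, points, method = "toy", subject = 1L) {
  structure(list(method = method, fits = fits,
                 points = as.matrix(points), time_proxy = rep(1, length(fits)),
                 n_runs = length(fits), subject_id = subject),
            class = "run_set")
}

# goal whose value rises with the call count and then freezes; used for the
# stall-rule checks (improvements stop after `freeze_after` evaluations)
frozen_goal <- function(freeze_after) {
  count <- 0
  function(point) {
    count <<- count + 1
    min(count, freeze_after)
  }
}
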