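#' Pearson similarity of two FC matrices
#'
#' Pearson correlation of the strictly upper-triangular entries of the two
#' matrices. The constant unit diagonal is excluded: including it would
#' inflate the correlation without carrying information.
#'
#' @param sim,emp [fc_matrix()] objects (or plain symmetric matrices) with
#'   the same region count and ordering.
#' @return Correlation in `[-1, 1]`.
#' @export
fc_similarity <- function(sim, emp) {
  a <- if (inherits(sim, "fc_matrix")) sim$values else as.matrix(sim)
  b <- if (inherits(emp, "fc_matrix")) emp$values else as.matrix(emp)
  if (!all(dim(a) == dim(b)))
    stop(sprintf("FC matrices disagree in size: %d vs %d regions",
                 nrow(a), nrow(b)))
  ut <- upper.tri(a)
  x <- a[ut]; y <- b[ut]
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in an FC upper triangle; similarity undefined")
  cor(x, y)
}

#' Optimization box bounds
#'
#' Default feasible boxes for the free parameters: `(C, tau) in [0, 1] x
#' [0, 100]` in two dimensions, `(C, tau, sigma) in [0, 1] x [0, 100] x
#' [0, 2]` in three.
#'
#' @param dim 2 or 3 (or any positive integer when both bounds are given).
#' @param lower,upper Optional numeric vectors overriding the defaults.
#' @return Object of class `box_bounds` with fields `lower`, `upper`, `dim`.
#' @export
box_bounds <- function(dim = 2, lower = NULL, upper = NULL) {
  if (is.null(lower) || is.null(upper)) {
    if (!dim %in% c(2, 3))
      stop("default bounds exist only for dim 2 or 3; give lower and upper")
    lower <- c(0, 0, 0)[seq_len(dim)]
    upper <- c(1, 100, 2)[seq_len(dim)]
  }
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == length(upper), all(lower < upper))
  structure(list(lower = lower, upper = upper, dim = length(lower)),
            class = "box_bounds")
}

# map physical <-> normalized unit-box coordinates
normalize_point <- function(x, bounds)
  (as.numeric(x) - bounds$lower) / (bounds$upper - bounds$lower)
denormalize_point <- function(u, bounds)
  bounds$lower + as.numeric(u) * (bounds$upper - bounds$lower)

#' Evaluate the model-fitting goal function at one parameter point
#'
#' `F(C, tau[, sigma])` is the Pearson similarity between the FC simulated at
#' the point and the subject's empirical FC. Each evaluation draws its noise
#' seed from the seed policy (fresh child seed by default; a fixed-seed
#' policy makes F deterministic). With a 2-dimensional point the noise
#' intensity is held at `sigma_fixed`.
#'
#' @param connectome A [connectome()].
#' @param empfc The subject's empirical [fc_matrix()].
#' @param point Numeric vector `(C, tau)` or `(C, tau, sigma)`.
#' @param frequencies Natural frequencies f_i in Hz.
#' @param sim A [sim_settings()] list.
#' @param seed_policy A [seed_policy()].
#' @param sigma_fixed Noise intensity used when `point` is 2-dimensional
#'   (0.3 by default).
#' @param bounds A [box_bounds()]; points outside it are an error (callers
#'   must project first).
#' @param audit Optional [new_eval_audit()] counter, incremented once per
#'   evaluation.
#' @return Object of class `goal_evaluation`: `fit`, `point`, `seed`,
#'   `n_sim_seconds`.
#' @export
goal_function <- function(connectome, empfc, point, frequencies,
                          sim = sim_settings(), seed_policy,
                          sigma_fixed = 0.3, bounds = NULL, audit = NULL) {
  point <- as.numeric(point)
  dim <- length(point)
  if (!dim %in% c(2, 3)) stop("point must have length 2 or 3")
  if (is.null(bounds)) bounds <- box_bounds(dim)
  if (any(point < bounds$lower - 1e-12) || any(point > bounds$upper + 1e-12))
    stop("point lies outside the feasible box; project it first")
  point <- pmin(pmax(point, bounds$lower), bounds$upper)
  sigma <- if (dim == 3) point[3] else sigma_fixed
  seed <- seed_policy$next_seed()
  params <- model_params(point[1], point[2], sigma, frequencies,
                         dt = sim$dt, tr = sim$tr, duration = sim$duration,
                         transient = sim$transient)
  simfc <- simulate_fc(connectome, params, seed)
  if (!is.null(audit)) audit$count <- audit$count + 1
  structure(list(fit = fc_similarity(simfc, empfc), point = point,
                 seed = seed, n_sim_seconds = sim$duration),
            class = "goal_evaluation")
}

#' Build a scalar goal closure for optimizers and grid search
#'
#' Wraps [goal_function()] into a `function(point) -> fit` closure carrying a
#' shared audit counter and seed policy, which is the form the grid search
#' and the optimizers consume.
#'
#' @inheritParams goal_function
#' @param audit A [new_eval_audit()] counter (created if not given).
#' @return A function of a parameter point returning the fit, with
#'   attributes `audit`, `seed_policy`, `bounds`, `dim`.
#' @export
make_goal <- function(connectome, empfc, frequencies, sim = sim_settings(),
                      seed_policy, sigma_fixed = 0.3, bounds = NULL,
                      dim = 2, audit = new_eval_audit()) {
  if (is.null(bounds)) bounds <- box_bounds(dim)
  f <- function(point) {
    goal_function(connectome, empfc, point, frequencies, sim = sim,
                  seed_policy = seed_policy, sigma_fixed = sigma_fixed,
                  bounds = bounds, audit = audit)$fit
  }
  attr(f, "audit") <- audit
  attr(f, "seed_policy") <- seed_policy
  attr(f, "bounds") <- bounds
  attr(f, "goal_dim") <- bounds$dim
  f
}

# wrap an arbitrary scalar function as an audited goal (used for dry runs,
# surrogate landscapes and evaluation accounting)
#' Wrap a plain function as an audited goal
#'
#' Attaches a shared evaluation counter to any scalar function of a
#' parameter point. Used for dry-run sweep accounting and for deterministic
#' surrogate landscapes in optimizer tests.
#'
#' @param fun Function taking a numeric point and returning a scalar.
#' @param audit A [new_eval_audit()] counter.
#' @param bounds Optional [box_bounds()] attached for the optimizers.
#' @return An audited goal closure.
#' @export
audited_goal <- function(fun, audit = new_eval_audit(), bounds = NULL) {
  f <- function(point) {
    audit$count <- audit$count + 1
    fun(point)
  }
  attr(f, "audit") <- audit
  attr(f, "bounds") <- bounds
  f
}
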