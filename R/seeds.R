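#' Derive a child seed from a master seed
#'
#' Counter-based scheme used throughout the package: every stochastic
#' operation (subject, session, optimizer replicate, goal evaluation) receives
#' `child_seed(master, index)` for a documented integer index, so a whole
#' analysis is reproducible from one master seed and the index table recorded
#' in its run manifest. The map mixes `(master, index)` through two rounds of
#' a Lehmer step modulo the Mersenne prime 2^31 - 1; all intermediates stay
#' below 2^53 and are exact in doubles.
#'
#' @param master_seed Integer master seed.
#' @param index Nonnegative integer counter (may be a vector).
#' @return Integer seed(s) in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(42, 1:3)
child_seed <- function(master_seed, index) {
  m <- 2147483647
  x <- (abs(as.double(master_seed)) %% m + 1103515245 * (as.double(index) + 1)) %% m
  x <- (x * 48271) %% m
  x <- (x * 48271) %% m
  as.integer(x)
}

#' Seed policy for goal-function evaluations
#'
#' The goal function is stochastic: every simulation draws fresh noise. The
#' default `"fresh"` policy hands each evaluation a new child seed from an
#' internal counter, emulating independently perturbed evaluations. The
#' `"fixed"` policy returns the same seed every time, which makes the goal
#' function deterministic (used for exact tests, ground-truth recovery and
#' bit-exact replays).
#'
#' @param mode `"fresh"` or `"fixed"`.
#' @param seed Integer master (or fixed) seed.
#' @return An object of class `seed_policy` with elements `next_seed()`
#'   (draws the next evaluation seed) and `info()` (snapshot for manifests).
#' @export
seed_policy <- function(mode = c("fresh", "fixed"), seed) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(seed), length(seed) == 1)
  env <- new.env(parent = emptyenv())
  env$counter <- 0L
  pol <- list(
    mode = mode,
    seed = as.integer(seed),
    next_seed = function() {
      if (mode == "fixed") return(as.integer(seed))
      env$counter <- env$counter + 1L
      child_seed(seed, env$counter)
    },
    info = function() list(mode = mode, master_seed = as.integer(seed),
                           drawn = env$counter)
  )
  class(pol) <- "seed_policy"
  pol
}

#' Shared audit counter of goal-function evaluations
#'
#' A mutable counter passed to goal functions so that the total number of
#' model simulations issued by a sweep or optimizer benchmark can be audited
#' exactly (it is also the hardware-independent time proxy of the cost
#' function).
#'
#' @return An environment with a numeric field `count`.
#' @export
new_eval_audit <- function() {
  e <- new.env(parent = emptyenv())
  e$count <- 0
  e
}

# Evaluate `code` under a temporary R RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
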