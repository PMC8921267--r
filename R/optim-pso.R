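#' Particle-swarm maximization on a box
#'
#' Global stochastic search with a swarm of `lambda` particles (60 by
#' default). Velocities follow the constriction-type update `v <- w*v +
#' c1*r1*(pbest - x) + c2*r2*(gbest - x)` with `w = 0.7298`, `c1 = c2 =
#' 1.49618`; positions are clamped to the unit box with the violating
#' velocity component zeroed. Stops after `max_iterations` iterations or
#' when the global best has not strictly improved for `stall_window`
#' consecutive iterations.
#'
#' @inheritParams nelder_mead
#' @param config An [optimizer_config()] with `method = "pso"`.
#' @return An `optimizer_run` (see [run_optimizer()]).
#' @export
particle_swarm <- function(goal, bounds, config = optimizer_config("pso"),
                           seed = 1L) {
  n <- bounds$dim
  lam <- if (is.null(config$lambda)) 60L else as.integer(config$lambda)
  nev <- 0L
  evalp <- function(u) {
    nev <<- nev + 1L
    goal(denormalize_point(u, bounds))
  }
  run <- with_seed(seed, {
    x <- matrix(runif(lam * n), lam, n)
    v <- matrix(0, lam, n)
    f <- apply(x, 1, evalp)
    pbest <- x
    pf <- f
    gi <- which.max(pf)
    gbest <- pbest[gi, ]
    gf <- pf[gi]
    history <- numeric(0)
    stall <- 0L
    reason <- "max_iter"
    it <- 0L
    while (it < config$max_iterations) {
      it <- it + 1L
      r1 <- matrix(runif(lam * n), lam, n)
      r2 <- matrix(runif(lam * n), lam, n)
      v <- config$pso_inertia * v +
        config$pso_c1 * r1 * (pbest - x) +
        config$pso_c2 * r2 * (sweep(-x, 2, gbest, "+"))
      x <- x + v
      out_lo <- x < 0
      out_hi <- x > 1
      v[out_lo | out_hi] <- 0
      x[out_lo] <- 0
      x[out_hi] <- 1
      f <- apply(x, 1, evalp)
      better <- f > pf
      pbest[better, ] <- x[better, , drop = FALSE]
      pf[better] <- f[better]
      gi <- which.max(pf)
      if (pf[gi] > gf) {
        gf <- pf[gi]
        gbest <- pbest[gi, ]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      history <- c(history, gf)
      if (stall >= config$stall_window) {
        reason <- "stall"
        break
      }
    }
    list(gbest = gbest, gf = gf, it = it, history = history, reason = reason)
  })
  optimizer_run("pso", denormalize_point(run$gbest, bounds), run$gf, run$it,
                nev, run$reason, run$history, seed)
}
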