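# --- Gaussian-process surrogate (Matern-5/2 + observation noise) ----------

matern52 <- function(r) (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)

gp_kernel <- function(d, ell, sf2) sf2 * matern52(d / ell)

gp_nll <- function(par, X, y, d, noise) {
  ell <- exp(par[1]); sf2 <- exp(par[2])
  sn2 <- if (noise) exp(par[3]) else 1e-10
  n <- length(y)
  K <- gp_kernel(d, ell, sf2)
  diag(K) <- sf2 + sn2 + 1e-10
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi))
}

# Fit a GP to (X, y): y standardized internally, hyperparameters by marginal
# likelihood (L-BFGS-B); falls back to `prev`'s hyperparameters when the fit
# degenerates.
gp_fit <- function(X, y, noise = TRUE, prev = NULL) {
  X <- as.matrix(X)
  my <- mean(y); sy <- sd(y)
  if (!is.finite(sy) || sy == 0) sy <- 1
  ys <- (y - my) / sy
  d <- as.matrix(dist(X))
  par0 <- if (!is.null(prev)) prev$par else c(log(0.3), log(1), log(1e-2))
  if (!noise) par0 <- par0[1:2]
  lower <- c(log(1e-3), log(1e-4), log(1e-8))[seq_along(par0)]
  upper <- c(log(10), log(1e3), log(1))[seq_along(par0)]
  fit <- tryCatch(
    optim(par0, gp_nll, X = X, y = ys, d = d, noise = noise,
          method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 4, factr = 1e9)),
    error = function(e) NULL)
  fell_back <- FALSE
  if (is.null(fit) || !is.finite(fit$value)) {
    par <- par0
    fell_back <- !is.null(prev)
  } else par <- fit$par
  ell <- exp(par[1]); sf2 <- exp(par[2])
  sn2 <- if (noise) exp(par[3]) else 1e-10
  n <- length(ys)
  K <- gp_kernel(d, ell, sf2)
  diag(K) <- sf2 + sn2 + 1e-10
  L <- tryCatch(chol(K), error = function(e) {
    chol(K + diag(1e-6, n))
  })
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  structure(list(X = X, y = y, my = my, sy = sy, par = par, ell = ell,
                 sf2 = sf2, sn2 = sn2, L = L, alpha = alpha,
                 fell_back = fell_back),
            class = "kurafit_gp")
}

# Posterior mean and sd at new points (rows of Xnew), on the original scale.
gp_predict <- function(gp, Xnew) {
  Xnew <- matrix(as.numeric(Xnew), ncol = ncol(gp$X))
  # cross-distances
  d2 <- outer(rowSums(Xnew^2), rowSums(gp$X^2), "+") - 2 * Xnew %*% t(gp$X)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  ks <- gp_kernel(d, gp$ell, gp$sf2)
  mu <- as.numeric(ks %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(ks))
  var <- pmax(gp$sf2 - colSums(v^2), 1e-12)
  list(mean = gp$my + gp$sy * mu, sd = gp$sy * sqrt(var))
}

# Expected improvement (maximization) at normalized points u
gp_ei <- function(gp, u, incumbent) {
  p <- gp_predict(gp, u)
  z <- (p$mean - incumbent) / p$sd
  (p$mean - incumbent) * pnorm(z) + p$sd * dnorm(z)
}

#' Bayesian optimization with a Gaussian-process surrogate
#'
#' Sequential model-based maximization: a Matern-5/2 Gaussian process with an
#' observation-noise term is fitted to all evaluations (hyperparameters
#' refitted by marginal-likelihood maximization each iteration, falling back
#' to the previous values on a degenerate fit), and the next point is the
#' expected-improvement maximizer found by multi-start local search over the
#' box. The initial design is a Latin hypercube of 5 (2Dim) or 10 (3Dim)
#' points; exactly `max_iterations` acquisition iterations follow (the
#' iteration cap is the stopping rule).
#'
#' @inheritParams nelder_mead
#' @param config An [optimizer_config()] with `method = "bo"`.
#' @return An `optimizer_run` (see [run_optimizer()]).
#' @export
bayesian_opt <- function(goal, bounds, config = optimizer_config("bo"),
                         seed = 1L) {
  n <- bounds$dim
  n0 <- config$bo_initial
  if (is.null(n0)) n0 <- if (n <= 2) 5L else 10L
  nev <- 0L
  evalp <- function(u) {
    nev <<- nev + 1L
    goal(denormalize_point(clamp01(u), bounds))
  }
  run <- with_seed(seed, {
    X <- lhs::randomLHS(n0, n)
    y <- apply(X, 1, evalp)
    history <- numeric(0)
    gp <- NULL
    notes <- character()
    for (it in seq_len(config$max_iterations)) {
      gp <- gp_fit(X, y, noise = TRUE, prev = gp)
      if (gp$fell_back)
        notes <- c(notes, sprintf("iteration %d: kernel refit degenerate, kept previous hyperparameters", it))
      inc <- max(y)
      cand <- matrix(runif(64 * n), 64, n)
      ei <- gp_ei(gp, cand, inc)
      starts <- cand[order(ei, decreasing = TRUE)[1:2], , drop = FALSE]
      starts <- rbind(starts, X[which.max(y), ])
      best_u <- cand[which.max(ei), ]
      best_ei <- max(ei)
      for (s in seq_len(nrow(starts))) {
        op <- tryCatch(
          optim(starts[s, ], function(u) -gp_ei(gp, u, inc),
                method = "L-BFGS-B", lower = rep(0, n), upper = rep(1, n),
                control = list(maxit = 25)),
          error = function(e) NULL)
        if (!is.null(op) && is.finite(op$value) && -op$value > best_ei) {
          best_ei <- -op$value
          best_u <- op$par
        }
      }
      y_new <- evalp(best_u)
      X <- rbind(X, best_u)
      y <- c(y, y_new)
      history <- c(history, max(y))
    }
    list(X = X, y = y, history = history, notes = notes)
  })
  bi <- which.max(run$y)
  optimizer_run("bo", denormalize_point(run$X[bi, ], bounds), run$y[bi],
                config$max_iterations, nev, "max_iter", run$history, seed,
                run$notes)
}
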