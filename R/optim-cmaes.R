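#' CMA-ES maximization on a box
#'
#' Covariance matrix adaptation evolution strategy with the standard update
#' loop: log-rank selection weights over the best `floor(lambda/2)` samples,
#' cumulative step-size adaptation, and a rank-one plus rank-mu covariance
#' update, run in normalized coordinates on the negated goal. The benchmark
#' population is `lambda = 24` (12 parents). The initial mean is uniform in
#' the box and the initial step is 0.3; out-of-box samples are projected
#' onto the box before evaluation and the projected points are used in the
#' updates. Stops after `max_iterations` iterations, on a
#' `stall_window`-iteration stall, and repairs a covariance that loses
#' positive definiteness by eigenvalue flooring (logged in `notes`).
#'
#' @inheritParams nelder_mead
#' @param config An [optimizer_config()] with `method = "cmaes"`.
#' @return An `optimizer_run` (see [run_optimizer()]).
#' @export
cmaes <- function(goal, bounds, config = optimizer_config("cmaes"),
                  seed = 1L) {
  n <- bounds$dim
  lam <- if (is.null(config$lambda)) 24L else as.integer(config$lambda)
  mu <- floor(lam / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)
  c_sig <- (mu_eff + 2) / (n + mu_eff + 5)
  d_sig <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + c_sig
  c_c <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  c_1 <- 2 / ((n + 1.3)^2 + mu_eff)
  c_mu <- min(1 - c_1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  chi_n <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  nev <- 0L
  best_fit <- -Inf
  best_u <- NULL
  notes <- character()
  evalp <- function(u) {
    nev <<- nev + 1L
    fit <- goal(denormalize_point(u, bounds))
    if (fit > best_fit) {
      best_fit <<- fit
      best_u <<- u
    }
    fit
  }

  run <- with_seed(seed, {
    m <- runif(n)
    sig <- config$cmaes_step
    C <- diag(n)
    p_sig <- numeric(n)
    p_c <- numeric(n)
    history <- numeric(0)
    stall <- 0L
    reason <- "max_iter"
    it <- 0L
    prev_best <- -Inf
    while (it < config$max_iterations) {
      it <- it + 1L
      eig <- eigen(C, symmetric = TRUE)
      ev <- eig$values
      if (any(ev <= 0) || max(ev) / max(min(ev), .Machine$double.xmin) > 1e14) {
        floor_v <- max(ev) * 1e-14
        ev <- pmax(ev, floor_v)
        C <- eig$vectors %*% diag(ev, n) %*% t(eig$vectors)
        notes <- c(notes, sprintf("iteration %d: covariance repaired by eigenvalue flooring", it))
      }
      B <- eig$vectors
      D <- sqrt(pmax(ev, .Machine$double.xmin))
      z <- matrix(rnorm(lam * n), n, lam)
      y <- B %*% (D * z)               # C^{1/2} z, columns
      xs <- sweep(sig * y, 1, m, "+")  # candidate points, columns
      xs_proj <- apply(xs, 2, clamp01)
      if (n == 1) xs_proj <- matrix(xs_proj, 1, lam)
      fits <- apply(xs_proj, 2, evalp)
      ord <- order(fits, decreasing = TRUE)
      sel <- xs_proj[, ord[seq_len(mu)], drop = FALSE]
      m_old <- m
      m <- as.numeric(sel %*% w)
      # C^{-1/2} (m - m_old) / sig
      y_w <- (m - m_old) / sig
      c_inv_half <- B %*% ((1 / D) * t(B))
      p_sig <- (1 - c_sig) * p_sig +
        sqrt(c_sig * (2 - c_sig) * mu_eff) * as.numeric(c_inv_half %*% y_w)
      h_sig <- as.numeric(sqrt(sum(p_sig^2)) /
        sqrt(1 - (1 - c_sig)^(2 * it)) / chi_n < 1.4 + 2 / (n + 1))
      p_c <- (1 - c_c) * p_c +
        h_sig * sqrt(c_c * (2 - c_c) * mu_eff) * y_w
      ys <- sweep(sel, 1, m_old, "-") / sig
      rank_mu <- matrix(0, n, n)
      for (i in seq_len(mu)) rank_mu <- rank_mu + w[i] * tcrossprod(ys[, i])
      C <- (1 - c_1 - c_mu) * C +
        c_1 * (tcrossprod(p_c) + (1 - h_sig) * c_c * (2 - c_c) * C) +
        c_mu * rank_mu
      sig <- sig * exp((c_sig / d_sig) * (sqrt(sum(p_sig^2)) / chi_n - 1))
      if (best_fit > prev_best) {
        prev_best <- best_fit
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      history <- c(history, best_fit)
      if (stall >= config$stall_window) {
        reason <- "stall"
        break
      }
    }
    list(it = it, history = history, reason = reason, mean = m)
  })
  r <- optimizer_run("cmaes", denormalize_point(best_u, bounds), best_fit,
                     run$it, nev, run$reason, run$history, seed, notes)
  r$final_mean <- denormalize_point(clamp01(run$mean), bounds)
  r
}
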