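#' Nelder-Mead simplex maximization on a box
#'
#' Downhill-simplex search with the Lagarias coefficients (reflection 1,
#' expansion 2, contraction 0.5, shrink 0.5), run in the normalized unit box
#' on the negated goal. The initial simplex is a random interior point plus
#' one axis perturbation per dimension; every candidate is projected onto
#' the box before evaluation. Terminates when the longest simplex edge falls
#' below `nma_edge_tol` or after `max_iterations` iterations.
#'
#' @param goal Goal closure (physical coordinates in, fit out).
#' @param bounds A [box_bounds()].
#' @param config An [optimizer_config()] with `method = "nma"`.
#' @param seed Integer seed for the initial simplex.
#' @return An `optimizer_run` (see [run_optimizer()]).
#' @export
nelder_mead <- function(goal, bounds, config = optimizer_config("nma"),
                        seed = 1L) {
  n <- bounds$dim
  nev <- 0L
  best_fit <- -Inf
  best_u <- NULL
  fmin <- function(u) {
    u <- clamp01(u)
    fit <- goal(denormalize_point(u, bounds))
    nev <<- nev + 1L
    if (fit > best_fit) {
      best_fit <<- fit
      best_u <<- u
    }
    -fit
  }
  step <- config$nma_step
  verts <- with_seed(seed, {
    x0 <- runif(n, 0.05, 0.95)
    v <- rbind(x0, t(vapply(seq_len(n), function(i) {
      p <- x0
      p[i] <- p[i] + step
      p
    }, numeric(n))))
    v
  })
  verts <- t(apply(verts, 1, clamp01))
  fv <- apply(verts, 1, fmin)
  history <- numeric(0)
  reason <- "max_iter"
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    ord <- order(fv)
    verts <- verts[ord, , drop = FALSE]
    fv <- fv[ord]
    cent <- colMeans(verts[-(n + 1), , drop = FALSE])
    worst <- verts[n + 1, ]
    xr <- clamp01(cent + (cent - worst))
    fr <- fmin(xr)
    if (fr < fv[1]) {
      xe <- clamp01(cent + 2 * (cent - worst))
      fe <- fmin(xe)
      if (fe < fr) {
        verts[n + 1, ] <- xe; fv[n + 1] <- fe
      } else {
        verts[n + 1, ] <- xr; fv[n + 1] <- fr
      }
    } else if (fr < fv[n]) {
      verts[n + 1, ] <- xr; fv[n + 1] <- fr
    } else if (fr < fv[n + 1]) {
      xc <- clamp01(cent + 0.5 * (xr - cent))
      fc <- fmin(xc)
      if (fc <= fr) {
        verts[n + 1, ] <- xc; fv[n + 1] <- fc
      } else {
        for (i in 2:(n + 1)) {
          verts[i, ] <- clamp01(verts[1, ] + 0.5 * (verts[i, ] - verts[1, ]))
          fv[i] <- fmin(verts[i, ])
        }
      }
    } else {
      xc <- clamp01(cent - 0.5 * (cent - worst))
      fc <- fmin(xc)
      if (fc < fv[n + 1]) {
        verts[n + 1, ] <- xc; fv[n + 1] <- fc
      } else {
        for (i in 2:(n + 1)) {
          verts[i, ] <- clamp01(verts[1, ] + 0.5 * (verts[i, ] - verts[1, ]))
          fv[i] <- fmin(verts[i, ])
        }
      }
    }
    history <- c(history, best_fit)
    edges <- as.matrix(dist(verts))
    if (max(edges) < config$nma_edge_tol) {
      reason <- "simplex_tol"
      break
    }
  }
  optimizer_run("nma", denormalize_point(best_u, bounds), best_fit, it, nev,
                reason, history, seed)
}
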