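#' Parameter grid specification
#'
#' Defaults reproduce the study grids: in two dimensions 64 equidistant
#' coupling values on `[0, 0.945]` crossed with 48 equidistant delays on
#' `[0, 94]` (3072 nodes, noise fixed at 0.3); in three dimensions 48
#' equidistant couplings on `[0, 0.94]`, 22 delays on `[0, 48]` spaced
#' quadratically (`tau_m = 48 * (m/21)^2`, denser near zero) and 81
#' equidistant noise intensities on `[0, 2]` (85536 nodes).
#'
#' @param dim 2 or 3.
#' @param c_axis,tau_axis,sigma_axis Optional strictly increasing override
#'   axes. For `dim = 2`, `sigma_axis` must be a single fixed value.
#' @return Object of class `grid_spec` with the axes, `dim` and the fixed
#'   `sigma` when `dim = 2`.
#' @export
make_grid <- function(dim = 2, c_axis = NULL, tau_axis = NULL,
                      sigma_axis = NULL) {
  if (!dim %in% c(2, 3)) stop("dim must be 2 or 3")
  if (dim == 2) {
    if (is.null(c_axis)) c_axis <- seq(0, 0.945, length.out = 64)
    if (is.null(tau_axis)) tau_axis <- seq(0, 94, length.out = 48)
    if (is.null(sigma_axis)) sigma_axis <- 0.3
    if (length(sigma_axis) != 1)
      stop("in 2Dim the noise intensity is a single fixed value")
  } else {
    if (is.null(c_axis)) c_axis <- seq(0, 0.94, length.out = 48)
    if (is.null(tau_axis)) tau_axis <- 48 * ((0:21) / 21)^2
    if (is.null(sigma_axis)) sigma_axis <- seq(0, 2, length.out = 81)
  }
  for (ax in list(c_axis, tau_axis, if (dim == 3) sigma_axis else NULL)) {
    if (!is.null(ax) && length(ax) > 1 && any(diff(ax) <= 0))
      stop("grid axes must be strictly increasing")
  }
  structure(list(c_axis = as.numeric(c_axis),
                 tau_axis = as.numeric(tau_axis),
                 sigma_axis = as.numeric(sigma_axis), dim = dim),
            class = "grid_spec")
}

#' Number of nodes of a grid
#' @param grid A [make_grid()] specification.
#' @return Integer node count.
#' @export
grid_size <- function(grid) {
  n <- length(grid$c_axis) * length(grid$tau_axis)
  if (grid$dim == 3) n <- n * length(grid$sigma_axis)
  as.integer(n)
}

# all grid nodes as a matrix, C varying fastest
grid_nodes <- function(grid) {
  if (grid$dim == 2) {
    g <- expand.grid(C = grid$c_axis, tau = grid$tau_axis,
                     KEEP.OUT.ATTRS = FALSE)
  } else {
    g <- expand.grid(C = grid$c_axis, tau = grid$tau_axis,
                     sigma = grid$sigma_axis, KEEP.OUT.ATTRS = FALSE)
  }
  as.matrix(g)
}

#' Exhaustive grid search of the goal function
#'
#' Evaluates the goal at every node exactly once and extracts the best node
#' and the five nodes with the highest fit (the grid-search reference points
#' used by the cost function). Per-node results can be checkpointed to a
#' file and the search resumed, skipping completed nodes.
#'
#' @param goal A goal closure from [make_goal()] (or any function of a
#'   parameter point returning a scalar fit).
#' @param grid A [make_grid()] specification.
#' @param checkpoint Optional path of a tab-separated checkpoint file; one
#'   record per completed node, appended as the search proceeds.
#' @param verbose Print progress every 500 nodes.
#' @return Object of class `grid_result`: `grid`, `nodes` (matrix), `fits`,
#'   `best_point`, `best_fit`, `top_points` (up to 5 rows, descending fit),
#'   `top_fits`, `n_evaluations`, `seed_info`.
#' @export
run_grid_search <- function(goal, grid, checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  nodes <- grid_nodes(grid)
  n <- nrow(nodes)
  fits <- rep(NA_real_, n)
  done <- rep(FALSE, n)
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    ck <- read.table(checkpoint, header = FALSE,
                     col.names = c("idx", "fit"))
    keep <- ck$idx >= 1 & ck$idx <= n
    fits[ck$idx[keep]] <- ck$fit[keep]
    done[ck$idx[keep]] <- TRUE
  }
  con <- if (!is.null(checkpoint)) file(checkpoint, open = "a") else NULL
  on.exit(if (!is.null(con)) close(con))
  for (i in seq_len(n)) {
    if (done[i]) next
    fits[i] <- goal(nodes[i, ])
    if (!is.null(con)) {
      cat(sprintf("%d\t%.17g\n", i, fits[i]), file = con)
      flush(con)
    }
    if (verbose && i %% 500 == 0)
      message(sprintf("grid search: %d / %d nodes", i, n))
  }
  ord <- order(fits, decreasing = TRUE)
  top <- ord[seq_len(min(5, n))]
  pol <- attr(goal, "seed_policy")
  structure(list(grid = grid, nodes = nodes, fits = fits,
                 best_point = nodes[ord[1], ], best_fit = fits[ord[1]],
                 top_points = nodes[top, , drop = FALSE],
                 top_fits = fits[top], n_evaluations = n,
                 seed_info = if (!is.null(pol)) pol$info() else NULL),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d nodes, best fit %.4f at (%s)\n",
              x$n_evaluations, x$best_fit,
              paste(signif(x$best_point, 4), collapse = ", ")))
  invisible(x)
}

#' Top grid points in normalized coordinates
#'
#' Maps the up-to-five best grid nodes into the normalized unit box of the
#' optimizer bounds, the coordinate system in which the cost-function
#' distances are measured.
#'
#' @param grid_result A [run_grid_search()] result.
#' @param bounds A [box_bounds()].
#' @return Matrix (up to 5 x Dim) of normalized points, descending fit.
#' @export
grid_top_points <- function(grid_result, bounds = NULL) {
  if (is.null(bounds)) bounds <- box_bounds(grid_result$grid$dim)
  tp <- grid_result$top_points
  t(apply(tp, 1, normalize_point, bounds = bounds))
}
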