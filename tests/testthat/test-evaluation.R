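# success probability, cost function, recommendations, grid-cost scaling

test_that("closed-form success probability matches hypergeometric cases", {
  expect_equal(success_closed_form(1, 15, 3), 1 - 364 / 455)
  expect_equal(success_closed_form(1, 15, 3), 0.2)
  expect_equal(success_closed_form(0, 15, 5), 0)
  expect_equal(success_closed_form(15, 15, 1), 1)
  # single draw with 8 of 15 passing exceeds 50%
  expect_equal(success_closed_form(8, 15, 1), 8 / 15)
  # monotone in the number of draws for every m
  for (m in 0:15) {
    p <- vapply(1:15, function(r) success_closed_form(m, 15, r), numeric(1))
    expect_true(all(diff(p) >= -1e-12))
  }
})

test_that("resampled success curves agree with the closed form", {
  # per-comparison z-scores: ~3-sigma excursions are expected at this count,
  # so bound the exceedance rate rather than every single draw
  n_bad3 <- 0; n_tot <- 0
  for (i in 1:20) {
    fits <- with_seed(1000 + i, runif(15))
    thr <- with_seed(2000 + i, runif(1, 0.2, 0.9))
    m <- sum(fits >= 0.95 * thr)
    curve <- success_curve(list(fits), thr, n_resamples = 500,
                           seed = 3000 + i)
    for (r in c(1, 3, 7, 15)) {
      p_exact <- success_closed_form(m, 15, r)
      se <- sqrt(p_exact * (1 - p_exact) / 500)
      d <- abs(curve$curve$probability[r] - p_exact)
      n_tot <- n_tot + 1
      n_bad3 <- n_bad3 + (d > max(3 * se, 1e-12))
      expect_lte(d, max(5 * se, 1e-12))
    }
  }
  expect_lte(n_bad3 / n_tot, 0.02)
  expect_error(success_curve(list(runif(5)), 0.5, r_max = 9), "exceeds")
})

test_that("runs_for_level applies the not-reached convention", {
  expect_equal(runs_for_level(c(0.6, 0.9), 0.8), list(runs = 2, reached = TRUE))
  flat <- runs_for_level(rep(0.4, 24), 0.8)
  expect_equal(flat$runs, 24)
  expect_false(flat$reached)
  p <- vapply(1:15, function(r) success_closed_form(8, 15, r), numeric(1))
  expect_equal(runs_for_level(p, 0.5)$runs, 1)
  expect_error(runs_for_level(numeric(0), 0.5), "empty")
})

test_that("cost components reproduce the hand-computed toy decomposition", {
  rs <- fake_runset(c(0.2, 0.3, 0.4), matrix(c(0.1, 0.2, 0.4), 3, 1))
  cb <- cost_components(rs, matrix(0.2, 1, 1), time_for_80 = 10)
  expect_equal(cb$comp_fit, 0.6)
  expect_equal(cb$comp_sd, sqrt(mean((c(0.2, 0.3, 0.4) - 0.3)^2)))
  expect_equal(cb$comp_sd, 0.081650, tolerance = 1e-5)
  expect_equal(cb$comp_spread, (0.1 + 0.3 + 0.2) / 3)
  expect_equal(cb$comp_dist, (0.1 + 0 + 0.2) / 3)
  prod5 <- cb$comp_fit * cb$comp_sd * cb$comp_time * cb$comp_spread * cb$comp_dist
  expect_equal(prod5, 0.6 * sqrt(1 / 150) * 10 * 0.2 * 0.1)
  # prose variant: mean instead of min over grid points
  g2 <- matrix(c(0.0, 0.2), 2, 1)
  cb_min <- cost_components(rs, g2, 10)
  cb_mean <- cost_components(rs, g2, 10, dist_rule = "mean")
  expect_equal(cb_min$comp_dist, mean(c(0.1, 0.0, 0.2)))
  expect_equal(cb_mean$comp_dist, mean(c(mean(c(0.1, 0.1)), mean(c(0.2, 0.0)),
                                         mean(c(0.4, 0.2)))))
  expect_error(cost_components(fake_runset(0.5, matrix(0.1)), g2, 1),
               "fewer than 2")
})

test_that("15-run protocol divides the spread by the 105 solution pairs", {
  fits <- with_seed(5, runif(15))
  pts <- with_seed(6, matrix(runif(30), 15, 2))
  cb <- cost_components(fake_runset(fits, pts), matrix(0.5, 5, 2), 1)
  pd <- as.matrix(dist(pts))
  expect_equal(cb$comp_spread, sum(pd[upper.tri(pd)]) / 105)
})

test_that("degenerate run sets zero out the cost product", {
  rs <- fake_runset(c(1, 1, 1), matrix(0.2, 3, 1))
  cb <- cost_components(rs, matrix(0.2, 1, 1), time_for_80 = 5)
  expect_equal(cb$comp_fit, 0)
  expect_equal(cb$comp_sd, 0)
  expect_equal(cb$comp_spread, 0)
  expect_equal(cb$comp_dist, 0)
})

test_that("cost normalization is per-component and scale invariant", {
  comps <- data.frame(
    subject = rep(1:2, each = 2), method = rep(c("a", "b"), 2),
    comp_fit = c(0.2, 0.4, 0.1, 0.3), comp_sd = c(0.02, 0.08, 0.04, 0.06),
    comp_time = c(10, 40, 20, 30), comp_spread = c(0.1, 0.5, 0.2, 0.4),
    comp_dist = c(0.3, 0.1, 0.2, 0.4))
  agg <- aggregate_costs(comps)
  # hand-check one cell: subject 1, method a
  psi_11 <- (0.2 / 0.4) * (0.02 / 0.08) * (10 / 40) * (0.1 / 0.5) * (0.3 / 0.4)
  expect_equal(agg$psi["1", "a"], psi_11)
  expect_true(all(agg$normalized[paste0("comp_", c("fit", "sd", "time",
                                                   "spread", "dist"))] <= 1))
  # doubling every time component leaves psi unchanged
  comps2 <- comps; comps2$comp_time <- comps2$comp_time * 2
  expect_equal(aggregate_costs(comps2)$psi, agg$psi)
  # all-zero component collapses to zero with a note
  comps3 <- comps; comps3$comp_sd <- 0
  agg3 <- aggregate_costs(comps3)
  expect_true(all(agg3$psi == 0))
  expect_match(agg3$notes, "comp_sd")
})

test_that("recommendations partition the cohort and break ties as documented", {
  psi <- matrix(c(0.2, 0.1, 0.3, 0.1,
                  0.5, 0.4, 0.2, 0.3), 2, 4, byrow = TRUE,
                dimnames = list(1:2, c("a", "b", "c", "d")))
  tm <- matrix(1, 2, 4, dimnames = dimnames(psi))
  rec <- recommend_methods(psi, tm)
  expect_equal(rec$recommendation, c("b", "c"))  # tie b/d -> lexicographic b
  expect_true(rec$ties[1])
  expect_equal(sum(rec$tally), 2)
  # time breaks the tie before the name does
  tm2 <- tm; tm2[1, "d"] <- 0.5
  expect_equal(recommend_methods(psi, tm2)$recommendation[1], "d")
  # dominant method collects every subject
  psi_dom <- matrix(c(0.1, 0.2, 0.4, 0.5), 2, 2,
                    dimnames = list(1:2, c("a", "b")))
  rec_dom <- recommend_methods(psi_dom)
  expect_equal(rec_dom$winner, "a")
  expect_equal(as.integer(rec_dom$tally), c(2L, 0L))
  # random matrices: tallies always sum to the number of subjects
  for (i in 1:10) {
    p <- matrix(runif(12), 3, 4, dimnames = list(1:3, letters[1:4]))
    expect_equal(sum(recommend_methods(p)$tally), 3)
  }
  expect_error(recommend_methods(matrix(c(1, NA), 1, 2)), "missing")
})

test_that("grid-cost extrapolation follows s * t * p^(dim-1)", {
  expect_equal(estimate_grid_cost(100, 48, 3, 1), 64)
  expect_equal(estimate_grid_cost(100, 48, 3, 100), 6400)
  # one dimension: p drops out
  expect_equal(estimate_grid_cost(7200, 48, 1, 1),
               estimate_grid_cost(7200, 999, 1, 1))
  expect_equal(estimate_grid_cost(7200, 48, 1, 1), 2)
})
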