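# synthetic connectomes, BOLD sessions and the empirical-feature extractors

test_that("connectome generation is deterministic and respects the density", {
  cfg <- cohort_config(1, n_regions = 50, density = 0.3)
  a <- generate_connectome(cfg, 7)
  b <- generate_connectome(cfg, 7)
  expect_identical(a$sc, b$sc)
  expect_identical(a$pl, b$pl)
  # 0.3 of C(50,2) = 1225 pairs -> 368 nonzero pairs
  expect_equal(sum(a$sc[upper.tri(a$sc)] > 0), 368)
  expect_equal(sum(upper.tri(a$sc)), 1225)
  # full density: every off-diagonal pair nonzero
  full <- generate_connectome(cohort_config(1, n_regions = 3, density = 1), 1)
  expect_equal(sum(full$sc[upper.tri(full$sc)] > 0), 3)
  # different seed -> different connectome
  expect_false(identical(generate_connectome(cfg, 8)$sc, a$sc))
})

test_that("generated connectomes are valid: symmetric, zero-diagonal, PL in range", {
  cfg <- cohort_config(1, n_regions = 30, density = 0.4,
                       length_range = c(10, 120))
  cn <- generate_connectome(cfg, 3)
  expect_identical(cn$sc, t(cn$sc))
  expect_identical(cn$pl, t(cn$pl))
  expect_true(all(diag(cn$sc) == 0) && all(diag(cn$pl) == 0))
  expect_true(all(cn$sc >= 0))
  expect_true(all(cn$pl[cn$sc > 0] >= 10 - 1e-9))
  expect_true(all(cn$pl[cn$sc > 0] <= 120 + 1e-9))
  expect_error(generate_connectome(cohort_config(1, n_regions = 1), 1),
               "at least 2")
  expect_error(cohort_config(1, density = 0), "density")
})

test_that("BOLD sessions carry the planted spectral peaks", {
  cfg <- cohort_config(1, n_regions = 3, volumes_per_session = 1200,
                       n_sessions = 1)
  f <- c(0.03, 0.05, 0.08)
  # noise-free: periodogram argmax at the planted frequency +- one bin
  bold <- generate_bold_sessions(cfg, f, subject_seed = 1, noise_amp = 0)
  est <- estimate_natural_frequencies(bold)
  expect_true(all(abs(est - f) <= 1 / (1200 * 0.72) + 1e-12))
  # determinism
  bold2 <- generate_bold_sessions(cfg, f, subject_seed = 1, noise_amp = 0)
  expect_identical(bold$sessions, bold2$sessions)
  # noisy signals still recover the peaks
  bold3 <- generate_bold_sessions(cfg, f, subject_seed = 2, noise_amp = 0.5)
  est3 <- estimate_natural_frequencies(bold3)
  expect_true(all(abs(est3 - f) <= 2 / (1200 * 0.72)))
  expect_error(generate_bold_sessions(cfg, c(0.03, 0.05, 0.8), 1), "Nyquist")
})

test_that("identity coupling yields decorrelated sessions within the sampling bound", {
  cfg <- cohort_config(1, n_regions = 10, volumes_per_session = 400,
                       n_sessions = 2)
  f <- seq(0.02, 0.09, length.out = 10)
  bold <- generate_bold_sessions(cfg, f, coupling_fc = diag(10),
                                 subject_seed = 9, noise_amp = 0.5)
  fc <- compute_empirical_fc(bold)
  off <- fc$values[upper.tri(fc$values)]
  expect_lt(mean(abs(off)), 3 / sqrt(800))
})

test_that("natural-frequency estimation restricts to the band and picks the strongest peak", {
  tt <- (0:1199) * 0.72
  # out-of-band 0.2 Hz peak is ignored in favour of in-band 0.03 Hz
  x1 <- sin(2 * pi * 0.2 * tt) + 0.2 * sin(2 * pi * 0.03 * tt)
  # two in-band peaks: the stronger (0.08 Hz) wins
  x2 <- sin(2 * pi * 0.04 * tt) + 2 * sin(2 * pi * 0.08 * tt)
  bold <- bold_session_set(list(cbind(x1, x2)), tr = 0.72)
  est <- estimate_natural_frequencies(bold)
  bin <- 1 / (1200 * 0.72)
  expect_lt(abs(est[1] - 0.03), bin + 1e-12)
  expect_lt(abs(est[2] - 0.08), bin + 1e-12)
  expect_error(estimate_natural_frequencies(bold, band = c(0.3, 0.8)),
               "Nyquist")
})

test_that("empirical FC matches hand-checkable cases", {
  tt <- (0:199) * 0.72
  s <- sin(2 * pi * 0.05 * tt)
  noise <- with_seed(4, matrix(rnorm(200 * 2, sd = 0.3), 200, 2))
  base <- s + noise[, 1]
  # duplicated region -> correlation 1; negated region -> -1
  bold <- bold_session_set(list(cbind(base, base, -base, s + noise[, 2])),
                           tr = 0.72)
  fc <- compute_empirical_fc(bold)
  expect_equal(fc$values[1, 2], 1)
  expect_equal(fc$values[1, 3], -1)
  # linear trend is removed exactly: trend + sine correlates 1 with the sine
  bold2 <- bold_session_set(list(cbind(0.01 * seq_along(tt) + s, s)),
                            tr = 0.72)
  fc2 <- compute_empirical_fc(bold2)
  expect_equal(fc2$values[1, 2], 1, tolerance = 1e-10)
  # constant region is flagged by name
  bold3 <- bold_session_set(list(cbind(A = s, B = rep(2, 200))), tr = 0.72,
                            region_ids = c("A", "B"))
  expect_error(compute_empirical_fc(bold3), "region B")
})

test_that("empirical FC of random session sets is a valid correlation matrix", {
  for (i in 1:100) {
    n <- sample(3:6, 1)
    bold <- bold_session_set(
      list(matrix(rnorm(30 * n), 30, n), matrix(rnorm(25 * n), 25, n)),
      tr = 0.72)
    fc <- compute_empirical_fc(bold)
    expect_identical(fc$values, t(fc$values))
    expect_equal(diag(fc$values), rep(1, n))
    expect_true(all(abs(fc$values) <= 1))
  }
})

test_that("ground-truth subjects close the parameter-recovery loop exactly", {
  conn <- tiny_connectome(n = 10, seed = 21, density = 0.5)
  f <- with_seed(22, runif(10, 0.02, 0.08))
  params <- model_params(0.5, 12, 0.3, f, duration = 60, transient = 15)
  emp <- make_ground_truth_subject(conn, params, 77)
  expect_s3_class(emp, "fc_matrix")
  # determinism
  expect_identical(emp$values,
                   make_ground_truth_subject(conn, params, 77)$values)
  # goal at the truth with the same fixed seed is exactly 1
  ev <- goal_function(conn, emp, c(0.5, 12), f,
                      sim = sim_settings(duration = 60, transient = 15),
                      seed_policy = seed_policy("fixed", 77))
  expect_equal(ev$fit, 1, tolerance = 1e-12)
})

test_that("decoupled noise-free subjects have weak off-diagonal FC", {
  conn <- tiny_connectome(n = 8, seed = 31, density = 0.6)
  f <- seq(0.02, 0.09, length.out = 8)
  short <- make_ground_truth_subject(
    conn, model_params(0, 1, 0, f, duration = 150, transient = 20), 5)
  long <- make_ground_truth_subject(
    conn, model_params(0, 1, 0, f, duration = 1000, transient = 20), 5)
  m_short <- mean(abs(short$values[upper.tri(short$values)]))
  m_long <- mean(abs(long$values[upper.tri(long$values)]))
  # incommensurate sinusoids decorrelate as the series grows
  expect_lt(m_long, m_short)
  expect_lt(m_long, 0.2)
})
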