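test_that("snr_db definition, sign alignment and cap", {
  set.seed(50)
  s <- rnorm(5000)
  expect_equal(snr_db(s, s), 300)
  expect_equal(snr_db(-s, s), 300)   # sign-aligned
  n <- rnorm(5000)
  noisy <- s + n * sd(s) * 0.1 / sd(n)   # noise variance = 1% of signal
  expect_equal(snr_db(noisy, s), 20, tolerance = 0.1)
  expect_equal(snr_db(noisy, s), snr_db(-noisy, s), tolerance = 1e-12)
  # strictly decreasing in noise level
  lv <- sapply(c(0.05, 0.1, 0.2, 0.4), function(a) snr_db(s + a * n, s))
  expect_true(all(diff(lv) < 0))
  expect_error(snr_db(s, rep(1, 5000)), "zero-variance")
})

test_that("match_components recovers permutation and sign, leaves noise unmatched", {
  set.seed(51)
  S <- gen_sources(list(source_spec("uniform", 10000, 60),
                        source_spec("laplace", 10000, 61),
                        source_spec("spikes", 10000, 62)))
  E <- S[c(3, 1, 2), ] * c(-1, 1, -1)
  m <- match_components(E, S)
  expect_identical(m$matches$truth[order(m$matches$estimate)], c(3L, 1L, 2L))
  expect_true(all(abs(m$matches$correlation) > 0.9999))
  # an extra noise row stays unmatched
  E2 <- rbind(E, rnorm(10000))
  m2 <- match_components(E2, S)
  expect_identical(m2$unmatched, 4L)
  # unrelated sets: all |corr| small
  R <- matrix(rnorm(2 * 10000), 2)
  m3 <- match_components(R, S)
  expect_true(all(abs(m3$matches$correlation) < 0.2))
})

test_that("classify_run labels and flags behave as specified", {
  fx <- small_four_source(17, n = 2000)
  mk <- function(status, corr_src, restarts = 0, dtr = c(0.1, 0.2)) {
    y <- corr_src
    structure(list(weight = c(1, 0, 0, 0), source = y, status = status,
                   iterations = 10L, restarts = restarts, mu_trace = c(0, 0),
                   delta_trace = dtr, closeness_trace = c(0, 0),
                   theta_trace = c(0, 0), used_inits = list(),
                   closeness_final = -0.9, xi = -0.5, measure = "corr",
                   eta_final = 0.1), class = "icar_extraction")
  }
  good <- mk("converged", fx$sources[1, ] + 0.01 * rnorm(2000))
  cl <- classify_run(good, fx, 1)
  expect_identical(cl$label, "accurate")
  expect_false(cl$negative_denominator)
  # scripted delta trace with a negative entry flags the run
  flagged <- mk("converged", fx$sources[1, ], dtr = c(0.2, -0.1, 0.3))
  expect_true(classify_run(flagged, fx, 1)$negative_denominator)
  # terminated far from the desired source: misconverged
  bad <- mk("nonconvergent", fx$sources[2, ])
  expect_identical(classify_run(bad, fx, 1)$label, "misconverged")
  # restart-exhausted stabilized run: nonconvergent, not misconverged
  ne <- mk("nonconvergent", rnorm(2000), restarts = 10)
  expect_identical(classify_run(ne, fx, 1)$label, "nonconvergent")
  expect_identical(classify_run(mk("diverged", rnorm(2000)), fx, 1)$label,
                   "diverged")
})

test_that("misconvergence benchmark is reproducible and handles zero trials", {
  fx <- small_four_source(18, n = 1500)
  b0 <- misconvergence_benchmark(fx, "new", n_trials = 0)
  expect_true(all(b0$counts$accurate == 0))
  expect_true(all(b0$counts$n_trials == 0))
  b1 <- misconvergence_benchmark(fx, c("new", "lin_fast"), n_trials = 5,
                                 desired_ics = c(1, 4), master_seed = 7)
  b2 <- misconvergence_benchmark(fx, c("new", "lin_fast"), n_trials = 5,
                                 desired_ics = c(1, 4), master_seed = 7)
  drop_rt <- function(d) d[, setdiff(names(d), "mean_runtime_s")]
  expect_identical(drop_rt(b1$counts), drop_rt(b2$counts))
  # label counts partition the trials
  with(b1$counts, expect_true(all(
    accurate + misconverged + nonconvergent + diverged == n_trials)))
})

test_that("basin indicator: fixed points, boundary ties and monotone basin size", {
  set.seed(52)
  S <- gen_sources(list(source_spec("uniform", 4000, 70),
                        source_spec("laplace", 4000, 71),
                        source_spec("spikes", 4000, 72)))
  fx <- mixture_fixture(S, gen_mixing(3, 3, FALSE, 73))
  wh <- whitened(fx)
  Z <- wh$signals$data
  # exact demixing direction of each source is predicted as itself
  for (i in 1:3) {
    wi <- drop(Z %*% S[i, ]) / ncol(Z); wi <- wi / sqrt(sum(wi^2))
    expect_identical(basin_indicator(fx, Z, wi), i)
  }
  # Monte-Carlo basin fractions are ordered like the kurtosis magnitudes
  counts <- c(0, 0, 0)
  for (t in 1:300) {
    w <- rnorm(3); w <- w / sqrt(sum(w^2))
    p <- basin_indicator(fx, Z, w)
    if (is.numeric(p)) counts[p] <- counts[p] + 1
  }
  expect_true(counts[1] < counts[2] && counts[2] < counts[3])
})
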