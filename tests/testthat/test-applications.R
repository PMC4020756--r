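test_that("reference deflation identities", {
  set.seed(40)
  s1 <- as.numeric(reference_signal(rnorm(4000)))
  s2 <- as.numeric(reference_signal(runif(4000)))
  s2 <- as.numeric(reference_signal(s2 - mean(s1 * s2) * s1))  # exactly decorrelated
  # uncorrelated y leaves r unchanged
  r <- reference_signal(s2)
  r2 <- deflate_reference(r, s1)
  expect_lt(max(abs(as.numeric(r2) - as.numeric(r))), 1e-10)
  # r = (s1 + s2)/sqrt(2), deflate by s1 -> s2
  rm <- reference_signal((s1 + s2) / sqrt(2))
  rd <- deflate_reference(rm, s1)
  expect_gt(abs(cor(as.numeric(rd), s2)), 0.999)
  expect_lt(abs(mean(as.numeric(rd) * s1)), 1e-10)
  # idempotent after the first application
  rdd <- deflate_reference(rd, s1)
  expect_lt(max(abs(as.numeric(rdd) - as.numeric(rd))), 1e-10)
  expect_error(deflate_reference(reference_signal(s1), s1), "fully explained")
})

test_that("reorthogonalization against prior components", {
  set.seed(41)
  p1 <- as.numeric(reference_signal(rnorm(3000)))
  q <- as.numeric(reference_signal(runif(3000)))
  q <- as.numeric(reference_signal(q - mean(q * p1) * p1))
  expect_lt(max(abs(reorthogonalize_ic(q, list()) - q)), 1e-12)
  expect_lt(max(abs(reorthogonalize_ic(q, list(p1)) - q)), 1e-10)
  y <- 0.9 * p1 + sqrt(1 - 0.81) * q
  out <- reorthogonalize_ic(y, list(p1))
  expect_gt(abs(cor(out, q)), 0.9999)
  expect_error(reorthogonalize_ic(p1, list(p1)), "span")
})

test_that("constraint center recovers the best-correlated direction", {
  fx <- small_four_source(13, n = 3000)
  wh <- whitened(fx)
  r <- reference_signal(fx$sources[3, ])
  w <- constraint_center(wh$signals, r)
  y <- drop(crossprod(w, wh$signals$data))
  expect_gte(abs(cor(y, fx$sources[3, ])), 0.999)
  # matches a projected-gradient oracle maximizing E{y r} on the sphere
  Z <- wh$signals$data
  w2 <- rnorm(4); w2 <- w2 / sqrt(sum(w2^2))
  Zr <- drop(Z %*% as.numeric(r)) / ncol(Z)
  for (i in 1:5000) {
    g <- Zr - sum(Zr * w2) * w2
    w2 <- w2 + 0.1 * g
    w2 <- w2 / sqrt(sum(w2^2))
  }
  ang <- acos(min(1, abs(sum(w * w2))))
  expect_lt(ang, 1e-3)
  expect_error(constraint_center(wh$signals, reference_signal(rnorm(3000))),
               NA)  # weakly correlated but not zero: no error expected
})

test_that("threshold widening converges exactly when the target becomes feasible", {
  fx <- small_four_source(14, n = 3000)
  wh <- whitened(fx)
  set.seed(42)
  r <- make_reference(fx$sources[1, ], 0.8, seed = 80)
  eps_target <- -abs(mean(as.numeric(r) * fx$sources[1, ]))
  cfg <- icar_config(xi = -0.5, init = "center", max_restarts = 3)
  res <- adaptive_threshold_extract(wh$signals, r, cfg,
                                    xi_start = -0.95, xi_step = 0.1, xi_stop = -0.55)
  expect_true(res$status != "nonconvergent")
  expect_gte(abs(cor(res$source, fx$sources[1, ])), 0.95)
  # oracle: direct extraction at each threshold in the schedule
  set.seed(42)
  oracle_xi <- NA
  for (xi in seq(-0.95, -0.55, by = 0.1)) {
    cfg$xi <- xi
    o <- extract_one(wh$signals, r, cfg)
    if (o$status != "nonconvergent") { oracle_xi <- xi; break }
  }
  expect_equal(res$xi_used, oracle_xi)
  expect_gte(res$xi_used, eps_target)   # infeasible thresholds were skipped

  # schedule entirely tighter than any closeness: nonconvergent
  res2 <- adaptive_threshold_extract(wh$signals, r,
                                     icar_config(xi = -0.5, init = "center",
                                                 max_restarts = 2, max_iter = 300),
                                     xi_start = -0.99, xi_step = 0.005, xi_stop = -0.97)
  expect_identical(res2$status, "nonconvergent")
  expect_true(is.na(res2$xi_used))
})

test_that("recover_all separates a clean square mixture completely", {
  fx <- small_four_source(15, n = 3000)
  set.seed(43)
  rec <- recover_all(signal_matrix(fx$observations))
  expect_gte(length(rec$results), 4)
  m <- match_components(rec$sources, fx$sources)
  expect_identical(sort(m$matches$truth), 1:4)
  expect_true(all(abs(m$matches$correlation) >= 0.95))
  # no duplicate extraction
  if (nrow(rec$sources) > 1) {
    cc <- abs(cor(t(rec$sources)))
    expect_lt(max(cc[upper.tri(cc)]), 0.999)
  }
  # spike and laplace rows flagged super-Gaussian, none as noise
  expect_false(any(rec$noise_flags))
})

test_that("recover_all is invariant to channel permutation (up to order and sign)", {
  fx <- small_four_source(16, n = 2500)
  set.seed(44)
  rec1 <- recover_all(signal_matrix(fx$observations))
  set.seed(44)
  rec2 <- recover_all(signal_matrix(fx$observations[c(3, 1, 4, 2), ]))
  m1 <- match_components(rec1$sources, fx$sources)$matches
  m2 <- match_components(rec2$sources, fx$sources)$matches
  expect_identical(sort(m1$truth), sort(m2$truth))
  expect_equal(sort(abs(m1$correlation)), sort(abs(m2$correlation)), tolerance = 0.02)
})

test_that("recover_all returns nothing for pure Gaussian input", {
  set.seed(45)
  g <- matrix(rnorm(4 * 2500), 4)
  rec <- recover_all(signal_matrix(g), icar_config(xi = -0.05, init = "center",
                                                   max_restarts = 4))
  expect_identical(length(rec$results), 0L)
  expect_identical(rec$stop_reason, "nonconvergence_reached")
})

test_that("recover_all finds the four physiological sources of the ECG-like fixture", {
  fx <- ecg_like_fixture(seed = 3, n_samples = 4000)
  # maternal spike trains are strongly super-Gaussian
  expect_gt(excess_kurtosis(fx$sources[1, ]), 3)
  expect_gt(excess_kurtosis(fx$sources[2, ]), 3)
  # channel 1 is the fetal-dominated lead
  ch_corr <- abs(cor(t(fx$observations), fx$sources[fx$fetal, ]))
  expect_identical(which.max(ch_corr), 1L)
  set.seed(46)
  rec <- recover_all(signal_matrix(fx$observations))
  expect_identical(length(rec$results), 4L)
  m <- match_components(rec$sources, fx$sources)
  expect_identical(sort(m$matches$truth), 1:4)
  expect_true(all(abs(m$matches$correlation) >= 0.9))
})
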