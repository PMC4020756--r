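test_that("extract_one recovers a clearly referenced source with high fidelity", {
  fx <- small_four_source(6, n = 3000)
  wh <- whitened(fx)
  set.seed(30)
  r <- reference_signal(fx$sources[2, ])
  res <- extract_one(wh$signals, r, icar_config(xi = -0.5, init = "center"))
  expect_true(res$status %in% c("converged", "converged_after_restart"))
  expect_gte(abs(cor(res$source, fx$sources[2, ])), 0.99)
  expect_lte(res$closeness_final, -0.5 + 1e-6)
  expect_equal(sum(res$weight^2), 1, tolerance = 1e-10)
  expect_lt(abs(mean(res$source^2) - 1), 1e-6)
})

test_that("extraction traces satisfy the structural invariants", {
  fx <- small_four_source(7, n = 2000)
  wh <- whitened(fx)
  set.seed(31)
  for (d in c(1, 4)) {
    r <- make_reference(fx$sources[d, ], 0.9, seed = 50 + d)
    res <- extract_one(wh$signals, r, icar_config(xi = -0.5))
    expect_true(all(res$mu_trace >= 0))
    if (res$status != "nonconvergent")
      expect_lte(res$closeness_final, -0.5 + 1e-6)
    expect_equal(sum(res$weight^2), 1, tolerance = 1e-10)
  }
})

test_that("pure Gaussian input never yields a converged component", {
  set.seed(32)
  g <- matrix(rnorm(5 * 3000), 5)
  wh <- whiten_signals(center_signals(signal_matrix(g)))
  r <- reference_signal(rnorm(3000))
  res <- extract_one(wh$signals, r, icar_config(xi = -0.05, max_restarts = 5))
  expect_identical(res$status, "nonconvergent")
})

test_that("detection disabled reproduces the legacy fast variant bit-for-bit", {
  fx <- small_four_source(8, n = 2000)
  wh <- whitened(fx)
  r <- make_reference(fx$sources[3, ], 0.9, seed = 60)
  cfg <- icar_config(xi = -0.5, stabilized = FALSE, lr_halving = FALSE)
  set.seed(33)
  a <- extract_one(wh$signals, r, cfg, detect = FALSE)
  set.seed(33)
  b <- extract_one_legacy(wh$signals, r, icar_config(xi = -0.5), variant = "lin_fast")
  expect_identical(a$weight, b$weight)
  expect_identical(a$mu_trace, b$mu_trace)
  expect_identical(a$delta_trace, b$delta_trace)
})

test_that("counterexample: stabilized extractor recovers the only feasible source", {
  cx <- counterexample_fixture(9, n_samples = 3000)
  expect_equal(excess_kurtosis(cx$fixture$sources[1, ]), -1.291, tolerance = 0.1)
  expect_equal(excess_kurtosis(cx$fixture$sources[2, ]), -1.4982, tolerance = 0.1)
  expect_equal(cx$closeness[1], -0.8907, tolerance = 0.03)
  expect_equal(cx$closeness[2], -0.4166, tolerance = 0.03)
  # only source 1 is feasible at xi = -0.6
  expect_lte(cx$closeness[1], -0.6)
  expect_gt(cx$closeness[2], -0.6)
  wh <- whitened(cx$fixture)
  set.seed(34)
  for (i in 1:10) {
    res <- extract_one(wh$signals, cx$reference, cx$config)
    expect_true(res$status %in% c("converged", "converged_after_restart"))
    expect_gte(abs(cor(res$source, cx$fixture$sources[1, ])), 0.95)
  }
})

test_that("legacy variants exhibit the documented fault modes", {
  cx <- counterexample_fixture(10, n_samples = 3000)
  wh <- whitened(cx$fixture)
  set.seed(35)
  statuses <- character(0); mis <- 0
  for (i in 1:40) {
    res <- extract_one_legacy(wh$signals, cx$reference, cx$config, variant = "lin_fast")
    statuses <- c(statuses, res$status)
    if (abs(cor(res$source, cx$fixture$sources[1, ])) < 0.95) mis <- mis + 1
  }
  expect_gte(mis, 1)   # misconvergence occurs on the counterexample

  # mixed sub/super fixture: the legacy rule hits negative-curvature events
  fx <- small_four_source(11, n = 2000)
  whf <- whitened(fx)
  set.seed(36)
  any_neg <- FALSE; lu_ok <- TRUE
  for (i in 1:10) {
    r <- make_reference(fx$sources[1 + i %% 4, ], 0.9, seed = 70 + i)
    res <- extract_one_legacy(whf$signals, r, icar_config(xi = -0.5), variant = "lin_fast")
    if (any(res$delta_trace < 0)) any_neg <- TRUE
    lu <- extract_one_legacy(whf$signals, r, icar_config(xi = -0.5), variant = "lu_original")
    if (!lu$status %in% c("converged", "nonconvergent", "diverged")) lu_ok <- FALSE
  }
  expect_true(any_neg)
  expect_true(lu_ok)
})

test_that("extraction with the G1 contrast also works", {
  fx <- small_four_source(12, n = 3000)
  wh <- whitened(fx)
  set.seed(37)
  r <- reference_signal(fx$sources[4, ])
  res <- extract_one(wh$signals, r, icar_config(xi = -0.5),
                     spec = contrast_spec("G1_logcosh"))
  expect_true(res$status %in% c("converged", "converged_after_restart"))
  expect_gte(abs(cor(res$source, fx$sources[4, ])), 0.95)
})
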