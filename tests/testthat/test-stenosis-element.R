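# Train tiny regressors once for element-level tests.
element_bundle <- function() {
  memo_fixture("bundle", function() {
    fx <- medium_table()
    acol <- grep("^alpha_", names(fx$table), value = TRUE)
    X <- as.matrix(fx$table[acol])
    kvm <- gpr_fit(X, fx$table$kv,
                   kernel_config("Matern", nu = 2.5, c_scale = 10,
                                 noise_var = 1e-2),
                   feature_transform(2, TRUE), seed = 1, target_name = "kv")
    ktm <- gpr_fit(X, fx$table$kt,
                   kernel_config("Matern", nu = 2.5, c_scale = 10,
                                 noise_var = 1e-2),
                   feature_transform(2, TRUE), seed = 1, target_name = "kt")
    list(bundle = stenosis_bundle(fx$sm, kvm, ktm), fx = fx, X = X)
  })
}

test_that("predicted pressure drop composes the h-terms with the GP means", {
  eb <- element_bundle()
  consts <- fluid_constants()
  a <- eb$X[3, ]
  q <- 3.333e-6
  pr <- predict_dp(eb$bundle, a, q)
  ht <- h_terms(q, consts)
  expect_equal(pr$dp, pr$kv * ht$h1q + pr$kt * ht$h2q2, tolerance = 1e-12)
  expect_equal(pr$dp_sigma,
               sqrt((ht$h1q * pr$kv_sigma)^2 + (ht$h2q2 * pr$kt_sigma)^2),
               tolerance = 1e-12)
  expect_identical(predict_dp(eb$bundle, a, 0)$dp, 0)
  # strictly increasing in flow for positive coefficients
  qs <- seq(1e-7, 5e-6, length.out = 9)
  dps <- vapply(qs, function(qq) predict_dp(eb$bundle, a, qq)$dp, numeric(1))
  expect_true(all(diff(dps) > 0))
})

test_that("the comparator model reduces exactly in its degenerate limits", {
  consts <- fluid_constants()
  q <- 3.333e-6
  # no stenosis: the quadratic term vanishes identically
  g0 <- heinen_geometry(a_s = 1.5e-3, kv = 3, kt = 9)
  expect_equal(heinen_dp(g0, q, consts),
               3 * h_terms(q, consts)$h1q, tolerance = 1e-12)
  # Kv = 1, Kt = 0 reduces to the viscous h1 term
  g1 <- heinen_geometry(kv = 1, kt = 0, a_s = 0.75e-3)
  expect_equal(heinen_dp(g1, q, consts), 58.68, tolerance = 1e-3)
  # Kv = 0, Kt = 1 at half-radius: Borda-Carnot factor (4-1)^2 = 9
  g2 <- heinen_geometry(kv = 0, kt = 1, a_s = 0.75e-3)
  expect_equal(heinen_dp(g2, q, consts), 9 * 117.84, tolerance = 1e-1)
  # comparator equals the oracle's straight-tube drop at a_s = a0, Kv = kv*
  straight <- raw_profile(rep(consts$a0, 20))
  ko <- oracle_coefficients(straight, consts)
  expect_equal(heinen_dp(heinen_geometry(kv = ko$kv_star, kt = 1), q, consts),
               ko$kv_star * h_terms(q, consts)$h1q, tolerance = 1e-9)
})

test_that("under-relaxation converges geometrically with the exact ratio", {
  st <- waveform_state(alpha_relax = 0.3, q_smoothed = 0)
  seq_vals <- numeric(6)
  for (i in 1:6) {
    st <- smooth_flow(st, 1)
    seq_vals[i] <- st$q_smoothed
  }
  expect_equal(seq_vals[1:3], c(0.7, 0.91, 0.973), tolerance = 1e-12)
  # distance to the fixed point contracts by exactly the smoothing factor
  expect_equal(diff(log(1 - seq_vals)), rep(log(0.3), 5), tolerance = 1e-9)

  # reversed flow contributes by magnitude
  st2 <- smooth_flow(waveform_state(0.3, 1), -1)
  expect_identical(st2$q_smoothed, 1)
  # no smoothing at alpha = 0
  expect_identical(smooth_flow(waveform_state(0, 5), -2.5)$q_smoothed, 2.5)
})

test_that("resistance matches the algebraic identity with the drop law", {
  consts <- fluid_constants()
  expect_equal(resistance(1, 0, 1e-6, consts), 1.761e7, tolerance = 1e-3)
  expect_identical(resistance(2, 5, 0, consts), 2 * resistance(1, 5, 0, consts))
  q <- 2.5e-6
  ht <- h_terms(q, consts)
  expect_equal(resistance(4, 60, q, consts) * q,
               4 * ht$h1q + 60 * ht$h2q2, tolerance = 1e-12)
})

test_that("FFR is the affine complement of the normalized drop", {
  expect_identical(ffr_from_dp(mmhg_to_pa(20), mmhg_to_pa(100)), 0.8)
  expect_identical(ffr_from_dp(0), 1)
  expect_equal(ffr_from_dp(mmhg_to_pa(60)), 0.4, tolerance = 1e-12)
  # affine identity in the drop
  dp <- mmhg_to_pa(17)
  for (c in c(0.5, 2, 3.7)) {
    expect_equal(ffr_from_dp(c * dp),
                 1 - c * (1 - ffr_from_dp(dp)), tolerance = 1e-12)
  }
  expect_error(ffr_from_dp(10, 0), "positive")
})

test_that("waveform driving reaches the steady algebraic limit", {
  consts <- fluid_constants()
  q <- 3e-6
  res <- run_waveform(kv = 10, kt = 50, q_series = rep(q, 200))
  steady_dp <- 10 * h_terms(q, consts)$h1q + 50 * h_terms(q, consts)$h2q2
  expect_equal(res$table$dp_pa[200], steady_dp, tolerance = 1e-10)
  expect_equal(res$ffr, ffr_from_dp(steady_dp), tolerance = 1e-10)

  # zero flow: no drop, FFR exactly one
  res0 <- run_waveform(10, 50, rep(0, 50))
  expect_true(all(res0$table$dp_pa == 0))
  expect_identical(res0$ffr, 1)

  # doubling the waveform more than doubles the drop (quadratic term)
  wave <- coronary_waveform(n_steps = 100, n_cycles = 2)
  r1 <- run_waveform(10, 50, wave$q_m3s)
  r2 <- run_waveform(10, 50, 2 * wave$q_m3s)
  expect_gt(mean(abs(r2$table$dp_pa)), 2 * mean(abs(r1$table$dp_pa)))

  # reversed flow gives a reversed (negative) drop
  rneg <- run_waveform(10, 50, c(rep(2e-6, 5), -2e-6))
  expect_lt(rneg$table$dp_pa[6], 0)
})
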