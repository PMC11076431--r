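test_that("SPGR signal matches its closed form and limits", {
  # frozen direct evaluation of m0 sin(a) (1-E)/(1-E cos a)
  expect_equal(spgr_signal(1000, 1000, 5.03, 10), 43.2742410845,
               tolerance = 1e-10)
  # alpha -> 0: signal vanishes (S ~ m0 sin(a) here since E is close to 1)
  expect_lt(spgr_signal(1000, 1000, 5.03, 1e-5), 1e-3)
  # tr >> t1: full relaxation, S = m0 sin(a)
  expect_equal(spgr_signal(1000, 10, 1e5, 30), 1000 * sin(30 * pi / 180),
               tolerance = 1e-12)
  expect_error(spgr_signal(1000, -5, 5, 10), "t1")
  expect_error(spgr_signal(1000, 1000, 5, 95), "alpha")
})

test_that("two-point VFA inverts noiseless SPGR signals exactly", {
  s <- spgr_signal(500, 820, 5.03, c(2, 10))
  fit <- fit_t1_vfa(s[1], s[2], 2, 10, 5.03)
  expect_equal(fit$t10, 820, tolerance = 1e-9)
  expect_equal(fit$m0, 500, tolerance = 1e-9)
})

test_that("degenerate VFA signal pairs raise a non-physical error", {
  # a high-flip signal far below the model prediction forces E >= 1
  expect_error(fit_t1_vfa(100, 10, 2, 10, 5.03), "non-physical")
  expect_error(fit_t1_vfa(100, 120, 5, 5, 5.03), "distinct")
})

test_that("VFA recovery under Rician noise at SNR 50 is within 2% in the median", {
  t1_true <- 1000; m0 <- 1000; tr <- 5.03
  s_true <- spgr_signal(m0, t1_true, tr, c(2, 10))
  sigma <- max(s_true) / 50
  set.seed(7)
  n <- 10000
  s1 <- rician_draw(rep(s_true[1], n), sigma)
  s2 <- rician_draw(rep(s_true[2], n), sigma)
  fit <- suppressWarnings(fit_t1_vfa(s1, s2, 2, 10, tr))
  expect_lt(abs(median(fit$t10, na.rm = TRUE) - t1_true) / t1_true, 0.02)
})

test_that("signal at baseline maps to zero concentration", {
  acq <- acquisition_params()
  s_pre <- spgr_signal(1000, 1200, acq$tr_dce, acq$flip_dce)
  cs <- signal_to_concentration(rep(s_pre, acq$n_post), s_pre, 1200, acq)
  expect_equal(cs$values, rep(0, acq$n_post))
  expect_equal(cs$n_clipped, 0L)
})

test_that("signal-to-concentration inverts the forward relaxation model", {
  acq <- acquisition_params()
  t10 <- 1100; m0 <- 800
  conc <- c(seq(0.05, 1.2, length.out = 20), seq(1.2, 0.6, length.out = 9))
  r1t <- 1000 / t10 + acq$r1 * conc
  sig <- spgr_signal(m0, 1000 / r1t, acq$tr_dce, acq$flip_dce)
  s_pre <- spgr_signal(m0, t10, acq$tr_dce, acq$flip_dce)
  cs <- signal_to_concentration(sig, s_pre, t10, acq)
  expect_equal(cs$values, conc, tolerance = 1e-6)
})

test_that("relaxation-rate bookkeeping: C = 1 mM at r1 = 5 adds 5 s^-1", {
  # R1(t) = 1/1.0 s + 5 * 1 = 6 s^-1 for t10 = 1000 ms: invert and check
  acq <- acquisition_params(r1 = 5)
  t1_t <- 1000 / 6          # ms
  sig <- spgr_signal(1000, t1_t, acq$tr_dce, acq$flip_dce)
  s_pre <- spgr_signal(1000, 1000, acq$tr_dce, acq$flip_dce)
  cs <- signal_to_concentration(rep(sig, acq$n_post), s_pre, 1000, acq)
  expect_equal(cs$values, rep(1, acq$n_post), tolerance = 1e-9)
})

test_that("signals outside the physical branch are flagged as missing", {
  acq <- acquisition_params()
  s_pre <- spgr_signal(1000, 1200, acq$tr_dce, acq$flip_dce)
  sig <- rep(s_pre, acq$n_post)
  sig[5] <- 1000 * sin(acq$flip_dce * pi / 180) * 1.5  # above m0 sin(a)
  cs <- signal_to_concentration(sig, s_pre, 1200, acq)
  expect_true(is.na(cs$values[5]))
  expect_true(all(!is.na(cs$values[-5])))
})

test_that("concentration increases monotonically with signal above baseline", {
  acq <- acquisition_params()
  s_pre <- spgr_signal(1000, 1200, acq$tr_dce, acq$flip_dce)
  sig <- seq(s_pre, s_pre * 2.5, length.out = acq$n_post)
  cs <- signal_to_concentration(sig, s_pre, 1200, acq)
  ok <- !is.na(cs$values)
  expect_true(all(diff(cs$values[ok]) > 0))
})
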