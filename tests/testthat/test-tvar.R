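# Sliding-window VAR, PDC, TPDC, and the time-reversal screen.

test_that("theta-power channel selection picks the rhythmic channel and breaks ties", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  set.seed(9)
  sig <- rbind(rnorm(length(t)),
               rnorm(length(t)) + 2 * sin(2 * pi * 6 * t),
               rnorm(length(t)))
  ch <- data.frame(id = c("a1", "a2", "a3"), area = "RFA", layer = "L5")
  ps <- multitaper_power(recording(sig, fs, ch), segment_s = 0.5)
  expect_identical(select_channel_by_theta(ps, "RFA", "L5"), "a2")

  one <- multitaper_power(recording(sig[2, , drop = FALSE], fs,
                                    ch[2, , drop = FALSE]), segment_s = 0.5)
  expect_identical(select_channel_by_theta(one, "RFA", "L5"), "a2")

  tie <- recording(rbind(sig[2, ], sig[2, ]), fs,
                   data.frame(id = c("b1", "b2"), area = "CFA", layer = "L6"))
  pst <- multitaper_power(tie, segment_s = 0.5)
  expect_identical(select_channel_by_theta(pst, "CFA", "L6"), "b1")
  expect_error(select_channel_by_theta(ps, "PMC", "L5"), "no channels")
})

test_that("sliding-window VAR recovers constant coefficients and flags noise", {
  A <- array(0, c(2, 2, 2))
  A[1, , ] <- rbind(c(0.4, 0.0), c(0.35, 0.3))
  A[2, , ] <- rbind(c(-0.2, 0.0), c(0.1, -0.15))
  x <- generate_var_process(A, diag(2), 4e4, seed = 5)
  m <- fit_tvar(x, order = 2, window_s = 10, step_s = 5, fs = 200)
  expect_true(all(abs(coef(m) - A) < 0.05))

  # white noise: coefficients are statistical zeroes
  w <- matrix(rnorm(2 * 2e4), 2)
  mw <- fit_tvar(w, order = 1, window_s = 20, step_s = 10, fs = 200)
  se <- 1 / sqrt(20 * 200)
  expect_true(all(abs(coef(mw)) < 3.5 * se))

  # a coupling switched on mid-recording moves the coefficient track
  A1 <- array(0, c(1, 2, 2)); A1[1, , ] <- rbind(c(0.3, 0), c(0, 0.3))
  A2 <- A1; A2[1, 2, 1] <- 0.5
  x1 <- generate_var_process(A1, diag(2), 1e4, seed = 6)
  x2 <- generate_var_process(A2, diag(2), 1e4, seed = 7)
  ms <- fit_tvar(cbind(x1, x2), order = 1, window_s = 5, step_s = 2.5, fs = 200)
  W <- dim(ms$A)[1]
  first <- mean(ms$A[seq_len(W %/% 2 - 1), 1, 2, 1])
  second <- mean(ms$A[(W %/% 2 + 2):W, 1, 2, 1])
  expect_gt(second - first, 0.3)

  expect_error(fit_tvar(matrix(rnorm(20), 2), order = 1, window_s = 1,
                        step_s = 1, fs = 200), "window")
})

test_that("model order selection by AIC finds a known order", {
  A <- array(0, c(3, 1, 1)); A[, 1, 1] <- c(0.5, -0.3, 0.2)
  x <- generate_var_process(A, matrix(1), 2e4, seed = 8)
  expect_identical(select_var_order(x, p_max = 8), 3L)
})

test_that("PDC respects its exact structural identities", {
  f <- seq(0.5, 99.5, 0.5)
  # diagonal coefficients: no cross-influence at any frequency
  Ad <- array(0, c(2, 3, 3))
  Ad[1, , ] <- diag(c(0.4, 0.3, 0.2)); Ad[2, , ] <- diag(c(-0.1, 0.1, 0.05))
  pd <- pdc_from_coefficients(Ad, f, 200)
  off <- pd; for (i in 1:3) off[, i, i] <- 0
  expect_true(all(off == 0))

  # unidirectional VAR(1): silent reverse direction, active forward one
  A <- array(0, c(1, 2, 2)); A[1, , ] <- rbind(c(0.5, 0), c(0.4, 0.3))
  p <- pdc_from_coefficients(A, f, 200)
  expect_true(all(p[, 1, 2] == 0))        # nothing flows 2 -> 1
  expect_true(all(p[, 2, 1] > 0))         # 1 -> 2 present at every f

  # column normalization exact for arbitrary coefficients
  set.seed(10)
  Ar <- array(rnorm(2 * 3 * 3, 0, 0.2), c(2, 3, 3))
  pr <- pdc_from_coefficients(Ar, f, 200)
  colsum <- apply(pr^2, c(1, 3), sum)
  expect_true(all(abs(colsum - 1) < 1e-12))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("stationary TPDC equals the static band PDC of the truth", {
  A <- array(0, c(1, 2, 2)); A[1, , ] <- rbind(c(0.5, 0), c(0.4, 0.3))
  x <- generate_var_process(A, diag(2), 200 * 120, seed = 11)
  # 10-s windows: PDC is a nonlinear function of the coefficients, so the
  # per-window estimation noise leaves a small positive bias on null
  # influences that shrinks with window length, not with window count
  m <- fit_tvar(x, order = 1, window_s = 10, step_s = 2.5, fs = 200)
  res <- tpdc(m, band_preset("mouse"), fmax_hz = 99)
  f <- res$freq
  truth <- pdc_from_coefficients(A, f, 200)
  expect_lt(max(abs(res$pdc_freq - truth)), 0.03)
  expect_error(tpdc(m, band_table("x", 150, 180, convention = "exact")),
               "no bins")
})

test_that("time reversal flags true lagged coupling and stays quiet on noise", {
  rec <- coupled_lfp(seed = 41, fs = 200, dur = 60)
  trt <- time_reversal_test(rec, order = 6, n_surr = 19, seed = 42,
                            fmax_hz = 99)
  beta <- trt[trt$band == "beta", ]
  expect_true(beta$significant)
  expect_identical(beta$direction, "ch1->ch2")
  expect_gt(beta$delta, 0)
  expect_lt(beta$rev_delta, 0)

  # independent white channels: mostly quiet
  set.seed(43)
  w <- matrix(rnorm(2 * 200 * 60), 2)
  trtw <- time_reversal_test(w, fs = 200, order = 4, n_surr = 19, seed = 44,
                             fmax_hz = 99)
  expect_lte(mean(trtw$significant), 2 / 7)
})
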