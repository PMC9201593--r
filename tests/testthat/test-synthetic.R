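# Ground-truth generators: determinism, analytic moments, stability rules.

test_that("VAR generator matches Yule-Walker closed form and rejects unstable systems", {
  # degenerate VAR: white noise with unit variance
  A0 <- array(0, c(1, 2, 2))
  w <- generate_var_process(A0, diag(2), 1e5, seed = 1)
  expect_equal(dim(w), c(2, 1e5))
  expect_true(all(abs(apply(w, 1, stats::var) - 1) < 0.05))

  # bivariate VAR(1): frozen independent Yule-Walker solution of
  # G0 = A G0 A' + Q for A=[[.5,0],[.4,.3]], Q=I:
  #   Var(x1)=4/3, Var(x2)=1.416074, Cov(x2_t, x1_{t-1})=0.627451
  A <- array(0, c(1, 2, 2)); A[1, , ] <- rbind(c(0.5, 0), c(0.4, 0.3))
  n <- 2e4
  x <- generate_var_process(A, diag(2), n, seed = 7)
  lag1_21 <- mean(x[2, -1] * x[1, -n])
  se <- 3 / sqrt(n)   # generous Monte-Carlo scale for a correlation-type moment
  expect_lt(abs(mean(x[1, ]^2) - 4 / 3), 4 * se)
  expect_lt(abs(lag1_21 - 0.627451), 4 * se)
  g <- var_autocovariance(A, diag(2), max_lag = 1)
  expect_equal(g[1, 1, 1], 4 / 3, tolerance = 1e-10)
  expect_equal(g[2, 2, 1], 0.6274510, tolerance = 1e-6)

  # determinism and stability diagnostics
  expect_identical(generate_var_process(A, diag(2), 500, seed = 3),
                   generate_var_process(A, diag(2), 500, seed = 3))
  Abad <- array(0, c(1, 2, 2)); Abad[1, , ] <- diag(2) * 1.05
  expect_error(generate_var_process(Abad, diag(2), 100, seed = 1),
               "spectral radius")
})

test_that("band-coupled LFP has the imposed 1/f slope and beta-band coupling", {
  rec <- generate_band_coupled_lfp(sim_config(1000, 60, 1, seed = 3))
  ps <- multitaper_power(rec, segment_s = 1, freq_step_hz = 0.25, fmax_hz = 100)
  sel <- ps$freq >= 1 & ps$freq <= 80
  slope <- unname(stats::coef(stats::lm(log(ps$power[1, sel]) ~
                                          log(ps$freq[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.15)

  rec2 <- coupled_lfp(seed = 11, fs = 1000, dur = 60)
  cp <- coherence(rec2, c("ch1", "ch2"), fmax_hz = 100)
  bm <- coherence_band_means <- local({
    bt <- band_preset("mouse")
    vapply(seq_len(nrow(bt)), function(b) {
      s <- cp$freq >= bt$low[b] & cp$freq < bt$upper[b]
      mean(cp$coherence[s])
    }, numeric(1)) |> stats::setNames(bt$name)
  })
  expect_gt(bm["beta"], bm["medium_gamma"])
  expect_identical(names(which.max(bm)), "beta")

  # zero-gain coupling leaves the pair indistinguishable from independent
  rec0 <- coupled_lfp(seed = 12, fs = 1000, dur = 60, gain = 0)
  cp0 <- flag_significant(surrogate_null(rec0, c("ch1", "ch2"), n_perm = 100,
                                         seed = 5, fmax_hz = 100),
                          bands = band_preset("mouse"))
  expect_false(cp0$band_significant["beta"])

  # coupling band above Nyquist rejected
  expect_error(sim_config(100, 10, 2, couplings = list(
    coupling_spec("ch1", "ch2", c(60, 80), 5, 1))), "Nyquist")

  expect_identical(coupled_lfp(5)$signal, coupled_lfp(5)$signal)
})

test_that("instantaneous mixing is zero-lag, rank-checked, and metadata-preserving", {
  rec <- independent_lfp(21, fs = 200, dur = 20)
  same <- apply_instantaneous_mixing(rec, diag(2))
  expect_identical(same$signal, rec$signal)
  expect_error(apply_instantaneous_mixing(rec, matrix(1, 2, 2)), "singular")
  expect_error(apply_instantaneous_mixing(rec, diag(3)), "2 x 2")
  M <- rbind(c(1, 0.5), c(0.5, 1))
  mixed <- apply_instantaneous_mixing(rec, M)
  expect_identical(mixed$channels, rec$channels)
  expect_equal(mixed$signal, M %*% rec$signal, ignore_attr = TRUE)
  # mixing induces strong low-frequency coherence (volume conduction look)
  cp <- coherence(mixed, c("ch1", "ch2"), fmax_hz = 90)
  expect_gt(mean(cp$coherence[cp$freq <= 10]), 0.5)
})

test_that("spiking-trace generator embeds templates at stated times with ground truth", {
  fs <- 20000
  # zero templates: detector false alarms are rare across seeds
  clean <- vapply(1:20, function(s) {
    tr <- generate_spiking_trace(fs, 1, list(), list(), noise_sd = 1, seed = s)
    length(detect_spikes(tr$trace, fs)$times_s) == 0L
  }, logical(1))
  expect_gte(mean(clean), 0.95)

  # 100 spikes at 8 sigma: recovered within +/-0.2 ms
  set.seed(42)
  st <- gen_unit_times(100, 20)
  tr <- generate_spiking_trace(fs, 20, list(st), list(spike_template(fs, 1.5, 8)),
                               noise_sd = 1, seed = 9)
  ev <- detect_spikes(tr$trace, fs)
  hits <- vapply(tr$ground_truth$time_s, function(t)
    any(abs(ev$times_s - t) < 2e-4), logical(1))
  expect_gte(mean(hits), 0.95)

  expect_identical(
    generate_spiking_trace(fs, 1, list(0.5), list(spike_template(fs)), seed = 4)$trace,
    generate_spiking_trace(fs, 1, list(0.5), list(spike_template(fs)), seed = 4)$trace)

  expect_error(generate_spiking_trace(fs, 1, list(0.5),
                                      list(numeric(round(0.004 * fs))), seed = 1),
               "3.5-ms")
  expect_error(generate_spiking_trace(fs, 1, list(c(0.5, 0.5004)),
                                      list(spike_template(fs)), seed = 1),
               "1 ms")
})

test_that("mediation generator reproduces path-tracing moments", {
  # all paths zero: near-zero correlations
  d0 <- generate_mediation_dataset(2000, list(), seed = 1)
  cm <- stats::cor(d0)
  # 4/sqrt(n): a 3-sigma bound on each of 6 correlations has a ~2%
  # family-wise false-alarm rate; one extra sigma keeps the check exact
  # in spirit (all correlations are statistical zeroes) without flaking
  expect_true(all(abs(cm[upper.tri(cm)]) < 4 / sqrt(2000)))

  # a=0.7, b=0.6, no direct path: standardized input-output covariance = a b
  d <- generate_mediation_dataset(1e4, list(a1 = 0.7, b1 = 0.6), seed = 2)
  expect_lt(abs(stats::cov(d$input, d$output) - 0.42), 0.03)
  expect_lt(abs(stats::var(d$output) - 1), 0.05)

  expect_identical(generate_mediation_dataset(100, mediation_truth(), seed = 3),
                   generate_mediation_dataset(100, mediation_truth(), seed = 3))
  expect_error(generate_mediation_dataset(5, list()), ">= 10")
  expect_error(generate_mediation_dataset(100, list(a1 = Inf)), "finite")
})

test_that("imposed coupling band is the argmax coherence band across seeds", {
  hits <- vapply(1:20, function(s) {
    rec <- coupled_lfp(seed = 300 + s, fs = 500, dur = 30)
    cp <- coherence(rec, c("ch1", "ch2"), fmax_hz = 100)
    bt <- band_preset("mouse")
    bm <- vapply(seq_len(nrow(bt)), function(b) {
      selb <- cp$freq >= bt$low[b] & cp$freq < bt$upper[b]
      mean(cp$coherence[selb])
    }, numeric(1))
    bt$name[which.max(bm)] == "beta"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
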