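# Spike detection, features, SPC clustering, quality screen.

test_that("detector thresholds, artifact rule, and degenerate traces", {
  fs <- 20000
  expect_length(detect_spikes(rep(0, fs) + rnorm(fs, 0, 1e-12), fs)$times_s, 0)
  expect_error(detect_spikes(rnorm(10), fs), "waveform window")

  # single 40-sigma deflection: excluded by the artifact rule
  set.seed(5)
  tr <- rnorm(fs)
  sig <- motorconn:::robust_sigma(tr)
  tmpl <- spike_template(fs, 1.5, 40 * sig)
  i0 <- fs %/% 2
  tr[i0:(i0 + length(tmpl) - 1)] <- tr[i0:(i0 + length(tmpl) - 1)] + tmpl
  ev <- detect_spikes(tr, fs)
  expect_length(ev$times_s, 0)
  expect_identical(ev$n_artifacts, 1L)

  # retained events never exceed the artifact bound (hard guarantee)
  fx <- spike_fixture(31, dur = 10)
  rec <- butterworth_filter(recording(matrix(fx$trace, 1), fs),
                            "bandpass", c(300, 3000), order = 2)
  ev2 <- detect_spikes(rec$signal[1, ], fs)
  expect_true(all(abs(ev2$amplitude) <= 30 * ev2$sigma))

  # robust sigma is hardly inflated by spikes; raw SD is
  expect_lt(motorconn:::robust_sigma(rec$signal[1, ]) /
              stats::sd(rec$signal[1, ]), 1)
})

test_that("waveform window spans -0.5/+3 ms with the trough at the offset", {
  fs <- 20000
  fx <- spike_fixture(32, dur = 5)
  rec <- butterworth_filter(recording(matrix(fx$trace, 1), fs),
                            "bandpass", c(300, 3000), order = 2)
  ev <- detect_spikes(rec$signal[1, ], fs)
  expect_identical(ncol(ev$waveforms), as.integer(round(0.0035 * fs)))
  troughs <- apply(ev$waveforms, 1, which.min)
  pre <- round(0.0005 * fs)
  expect_gt(mean(abs(troughs - (pre + 1)) <= 1), 0.9)
})

test_that("KS-ranked wavelet features expose template structure", {
  fs <- 20000
  set.seed(6)
  # two distinct templates + noise: top-ranked coefficient is bimodal
  pad <- function(w, len = 64) c(w, rep(0, len - length(w)))
  w1 <- pad(spike_template(fs, 1.0, 8)); w2 <- pad(spike_template(fs, 2.2, 8))
  n <- 150
  wf <- rbind(t(replicate(n, w1 + rnorm(length(w1), 0, 0.5))),
              t(replicate(n, w2 + rnorm(length(w2), 0, 0.5))))
  fe <- extract_features(wf, 10)
  top <- fe[, 1]
  lab <- rep(1:2, each = n)
  between <- abs(mean(top[lab == 1]) - mean(top[lab == 2]))
  within <- mean(c(stats::sd(top[lab == 1]), stats::sd(top[lab == 2])))
  expect_gt(between / within, 3)   # clearly bimodal

  # i.i.d. Gaussian "waveforms": selected KS statistics remain null-scale
  g <- matrix(rnorm(200 * 64), 200)
  feg <- extract_features(g, 10)
  expect_lt(max(attr(feg, "ks")), 0.12)

  # constant coefficient: zero deviation, never outranks informative ones
  wc <- cbind(wf[, 1:40], 5)
  fec <- extract_features(wc, 10)
  expect_false((ncol(wc) %in% attr(fec, "selected")))
  expect_error(extract_features(wf[1:10, ], 10), ">= 20 events")
})

test_that("SPC separates well-separated clouds and respects min_cluster", {
  set.seed(7)
  n <- 250
  cl1 <- matrix(rnorm(n * 3), n)
  cl2 <- sweep(matrix(rnorm(n * 3), n), 2, c(10, 0, 0), `+`)
  feats <- rbind(cl1, cl2)
  res <- spc_cluster(feats, seed = 8)
  expect_identical(res$n_clusters, 2L)
  lab <- rep(1:2, each = n)
  expect_gte(assignment_accuracy(lab, res$assignments), 0.95)

  single <- spc_cluster(cl1, seed = 9)
  expect_identical(single$n_clusters, 1L)

  few <- spc_cluster(matrix(rnorm(20), 10), min_cluster = 20, seed = 10)
  expect_true(all(few$assignments == 0L))
  expect_identical(few$n_clusters, 0L)

  # conservation: assigned + unassigned = all events
  expect_identical(sum(res$assignments > 0) + sum(res$assignments == 0),
                   as.integer(2 * n))
})

test_that("quality screen keeps clean units and drops merged/unstable ones", {
  dur <- 600
  set.seed(11)
  mk_unit <- function(times, amps, id = 1L) {
    structure(list(list(id = id, times_s = times, amplitude = amps,
                        mean_waveform = -amps[1] * spike_template(20000),
                        n = length(times),
                        firing_rate_hz = length(times) / dur)),
              class = "unit_clusters", duration_s = dur, n_unassigned = 0L)
  }
  # Poisson train at 5 Hz with enforced refractory: kept
  t_ok <- gen_unit_times(5 * dur, dur, min_gap = 0.0015)
  ok <- quality_filter(mk_unit(t_ok, rnorm(length(t_ok), -60, 3)))
  expect_length(ok, 1L)

  # two merged units: 10% ISI violations and bimodal amplitudes: dropped
  t1 <- gen_unit_times(2000, dur, min_gap = 0.0015)
  t_bad <- sort(c(t1, t1[seq(1, length(t1), 10)] + 0.0004))
  a_bad <- c(rnorm(length(t_bad) %/% 2, -40, 2),
             rnorm(length(t_bad) - length(t_bad) %/% 2, -80, 2))
  bad <- quality_filter(mk_unit(t_bad, a_bad))
  expect_length(bad, 0L)
  expect_false(attr(bad, "quality")$keep)

  # drift: amplitude changes > 30% between halves
  t_dr <- gen_unit_times(1000, dur, min_gap = 0.0015)
  a_dr <- ifelse(t_dr < dur / 2, -40, -80) + rnorm(length(t_dr))
  expect_length(quality_filter(mk_unit(t_dr, a_dr)), 0L)

  expect_length(quality_filter(structure(list(), class = "unit_clusters",
                                         duration_s = dur, n_unassigned = 0L)),
                0L)
})

test_that("firing rate is count over duration", {
  expect_identical(firing_rate(100, 10), 10)
  expect_identical(firing_rate(0, 10), 0)
  expect_equal(firing_rate(436, 600), 0.72667, tolerance = 1e-5)
  expect_error(firing_rate(10, 0), "> 0")
})

test_that("end-to-end sorting recovers the planted units", {
  fx <- spike_fixture(71, dur = 30)
  res <- sort_spikes(fx$trace, fx$fs, seed = 72)
  expect_length(res$units, 3L)
  lab <- match_events(res$events$times_s, fx$truth)
  expect_gte(assignment_accuracy(lab, res$clustering$assignments), 0.9)
  expect_true(all(abs(res$events$amplitude) <= 30 * res$events$sigma))
})
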