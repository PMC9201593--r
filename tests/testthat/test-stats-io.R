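# Group statistics, file round trips, pipeline orchestration.

test_that("Bonferroni-corrected Welch tests behave across bands", {
  set.seed(31)
  # identical groups: capped adjusted p of 1
  d_same <- data.frame(value = rep(rnorm(10), 2),
                       group = rep(c("CFA", "RFA"), each = 10),
                       band = "beta")
  out <- pairwise_band_tests(d_same, m = 7)
  expect_identical(out$p_adjusted, 1)

  # adjusted p is min(1, raw * m) and never below raw
  d2 <- data.frame(value = c(rnorm(20), rnorm(20, 0.9)),
                   group = rep(c("a", "b"), each = 20), band = "beta")
  o2 <- pairwise_band_tests(d2, m = 7)
  expect_equal(o2$p_adjusted, pmin(1, o2$p_raw * 7))
  expect_gte(o2$p_adjusted, o2$p_raw)

  # power at the human cohort size: unit effect detected despite m = 7.
  # closed-form oracle: noncentral-t power at the Bonferroni level
  ncp <- 1 * sqrt(34 * 34 / 68)
  crit <- stats::qt(1 - (0.05 / 7) / 2, df = 66)
  analytic <- 1 - stats::pt(crit, df = 66, ncp = ncp)
  expect_gt(analytic, 0.9)
  hits <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    d <- data.frame(value = c(rnorm(34), rnorm(34, 1)),
                    group = rep(c("g1", "g2"), each = 34), band = "beta")
    pairwise_band_tests(d, m = 7)$p_adjusted < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - analytic),
            3 * sqrt(analytic * (1 - analytic) / 200))

  expect_error(pairwise_band_tests(
    data.frame(value = c(1, 1, 1, 1), group = c("a", "a", "b", "b"),
               band = "x")), "degenerate")
  expect_error(pairwise_band_tests(
    data.frame(value = rnorm(3), group = c("a", "b", "c"), band = "x")),
    "2 levels")
})

test_that("recording round trips are bit-exact for TSV and HDF5", {
  rec <- coupled_lfp(91, fs = 200, dur = 2)
  tmp <- withr::local_tempdir()

  tsv <- file.path(tmp, "rec.tsv")
  write_recording(rec, tsv)
  back <- read_recording(tsv)
  expect_identical(back$signal, rec$signal)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$channels, rec$channels)
  expect_true(file.exists(file.path(tmp, "rec.truth.json")))
  gt <- attr(back, "ground_truth")
  expect_identical(unname(unlist(gt$couplings["lag_samples"])), 10L)

  h5 <- file.path(tmp, "rec.h5")
  write_recording(rec, h5)
  bh <- read_recording(h5)
  expect_identical(unname(bh$signal), unname(rec$signal))
  expect_identical(bh$fs, rec$fs)
  expect_identical(bh$channels$area, rec$channels$area)

  # schema errors name the missing piece
  file.remove(file.path(tmp, "rec.meta.json"))
  expect_error(read_recording(tsv), "metadata")
  expect_error(read_recording(file.path(tmp, "nope.xyz")), "extension")
})

test_that("pipeline runs are deterministic and stage dependencies enforced", {
  cfg <- list(
    stages = c("preprocess", "power", "coherence", "tpdc"),
    simulate = list(n_subjects = 2, fs_hz = 1000, duration_s = 20),
    coherence = list(n_perm = 25),
    tpdc = list(order = 5, n_surr = 9))
  tmp <- withr::local_tempdir()
  m1 <- run_pipeline(cfg, file.path(tmp, "a"), seed = 5)
  m2 <- run_pipeline(cfg, file.path(tmp, "b"), seed = 5)
  expect_identical(unname(unlist(m1$files)), unname(unlist(m2$files)))
  expect_true(file.exists(file.path(tmp, "a", "manifest.json")))
  m3 <- run_pipeline(cfg, file.path(tmp, "c"), seed = 6)
  expect_false(identical(unname(unlist(m1$files)), unname(unlist(m3$files))))

  cfg_bad <- cfg
  cfg_bad$stages <- c("power", "coherence", "tpdc", "sem")
  expect_error(run_pipeline(cfg_bad, file.path(tmp, "d"), seed = 5),
               "missing SU input")
})

test_that("sem stage runs from an external feature table", {
  tmp <- withr::local_tempdir()
  d <- generate_mediation_dataset(300, mediation_truth(), seed = 61)
  tsv <- file.path(tmp, "features.tsv")
  write_table_tsv(d, tsv)
  m <- run_pipeline(list(stages = "sem", sem = list(data = tsv),
                         simulate = list(n_subjects = 1, fs_hz = 200,
                                         duration_s = 5)),
                    file.path(tmp, "out"), seed = 3)
  expect_true("sem_fit.json" %in% names(m$files))
  fit <- jsonlite::read_json(file.path(tmp, "out", "sem_fit.json"),
                             simplifyVector = TRUE)
  expect_lt(fit$rmsea, 0.2)
  expect_identical(fit$n, 300L)
})
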