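# Path-model construction and ML fitting.

test_that("mediation specs have the right paths and reject bad graphs", {
  one <- build_mediation_spec("x", "m", "y")
  expect_identical(nrow(one$paths), 3L)
  two <- build_mediation_spec("tpdc", c("coherence", "power"), "su")
  expect_identical(nrow(two$paths), 5L)
  expect_setequal(two$variables, c("tpdc", "coherence", "power", "su"))
  expect_error(build_mediation_spec("x", "x", "y"), "distinct")

  dsl <- parse_path_dsl("tpdc -> coh; tpdc -> pow; coh -> su; pow -> su; tpdc -> su")
  expect_identical(nrow(dsl$paths), 5L)
  expect_error(parse_path_dsl("a -> b; b -> a"), "acyclic")
  expect_error(parse_path_dsl("a => b"), "parse")
})

test_that("ML fit recovers standardized paths and matches the OLS oracle", {
  spec <- build_mediation_spec("input", c("mediator1", "mediator2"), "output")
  d <- generate_mediation_dataset(1e4, mediation_truth(), seed = 21)
  fit <- fit_ml(spec, d)
  s <- coef(fit)
  expect_lt(abs(s["input->mediator1"] - 0.7), 0.02)
  expect_true(all(abs(s - mediation_truth_vec()) < 0.03))
  expect_true(all(fit$paths$p_value[abs(mediation_truth_vec()) > 0] < 1e-6))

  # equation-wise OLS is the ML estimator for this recursive model:
  # an independent oracle for the raw coefficients
  ols <- stats::coef(stats::lm(output ~ mediator1 + mediator2 + input, d))
  raw <- coef(fit, standardized = FALSE)
  expect_lt(abs(raw["mediator1->output"] - ols["mediator1"]), 1e-3)
  expect_lt(abs(raw["input->output"] - ols["input"]), 1e-3)

  # independent columns: every standardized path is a statistical zero
  d0 <- generate_mediation_dataset(2000, list(), seed = 22)
  f0 <- fit_ml(spec, d0)
  expect_true(all(abs(coef(f0)) < 3 / sqrt(2000)))

  # saturated single-mediator model: exact fit
  d1 <- generate_mediation_dataset(500, list(a1 = 0.5, b1 = 0.4), seed = 23)
  f1 <- fit_ml(build_mediation_spec("input", "mediator1", "output"),
               d1[c("input", "mediator1", "output")])
  expect_identical(f1$df, 0)
  expect_lt(f1$chi2, 1e-4)
  expect_identical(f1$rmsea, 0)
})

test_that("rmsea follows its closed form", {
  expect_identical(rmsea(10, 10, 500), 0)
  expect_identical(rmsea(5, 10, 500), 0)      # clipped at zero
  expect_equal(rmsea(20, 10, 101), 0.1)
  expect_identical(rmsea(123, 0, 500), 0)     # saturated convention
  expect_error(rmsea(1, -1, 10), "df")
  expect_error(rmsea(1, 1, 1), "n")
})

test_that("AIC prefers the generating model among nested candidates", {
  spec2 <- build_mediation_spec("input", c("mediator1", "mediator2"), "output")
  spec2_nodirect <- path_model_spec(
    spec2$paths[!(spec2$paths$from == "input" & spec2$paths$to == "output"), ])
  truth_nodirect <- list(a1 = 0.7, a2 = 0.6, b1 = 0.5, b2 = 0.4, c = 0)
  n_rep <- 200   # the per-replicate win probability P(chi2_1 < 2) ~ 0.843
  wins <- diffs <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    d <- generate_mediation_dataset(500, truth_nodirect, seed = 400 + i)
    a_small <- aic(fit_ml(spec2_nodirect, d))
    a_big <- aic(fit_ml(spec2, d))
    wins[i] <- a_small < a_big
    diffs[i] <- a_big - a_small
  }
  expect_gte(mean(wins), 0.8)
  expect_gt(mean(diffs), 0)   # a zero-true extra path raises AIC on average

  d <- generate_mediation_dataset(500, mediation_truth(), seed = 431)
  expect_identical(aic(fit_ml(spec2, d)), aic(fit_ml(spec2, d)))
})

test_that("standardized coefficients are invariant under positive rescaling", {
  spec <- build_mediation_spec("input", c("mediator1", "mediator2"), "output")
  d <- generate_mediation_dataset(500, mediation_truth(), seed = 24)
  base <- coef(fit_ml(spec, d))
  d2 <- d
  d2$mediator1 <- d2$mediator1 * 1000
  d2$output <- d2$output * 0.003
  expect_lt(max(abs(coef(fit_ml(spec, d2)) - base)), 1e-6)
  expect_lt(ics_criterion(spec, d, n_draws = 3, seed = 25), 1e-6)
})

test_that("free mediator covariance extends the model to a saturated fit", {
  spec <- build_mediation_spec("input", c("mediator1", "mediator2"), "output")
  d <- generate_mediation_dataset(1000, mediation_truth(), seed = 26)
  f_free <- fit_ml(spec, d, free_mediator_cov = TRUE)
  expect_identical(f_free$df, 0)
  expect_lt(f_free$chi2, 1e-3)
})

test_that("fit errors are informative", {
  spec <- build_mediation_spec("input", c("mediator1", "mediator2"), "output")
  d <- generate_mediation_dataset(100, mediation_truth(), seed = 27)
  expect_error(fit_ml(spec, d[, 1:3]), "lacks column")
  d_sing <- d; d_sing$output <- d_sing$input
  expect_error(fit_ml(spec, d_sing), "singular")
})
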