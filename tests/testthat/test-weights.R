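# Stabilized weight assembly, truncation and diagnostics.

cell_fit <- function(mechanism, role, cells, p) {
  structure(list(spec = mechanism_spec(mechanism, role),
                 type = "cells",
                 cells = data.frame(cell = cells, p = p),
                 diagnostics = list(clip = 1e-6)),
            class = "propensity_fit")
}

two_quarter_pq <- function() {
  structure(data.frame(participant = c(1L, 1L), quarter = 0:1,
                       arm = "HI", at_risk = TRUE, event = FALSE,
                       censor_cause = "none"),
            class = c("person_quarter", "data.frame"),
            horizon = 2L, cohort_size = 1L,
            baseline_covariates = character(),
            quarterly_covariates = character())
}

test_that("weights follow the cumulative numerator/denominator recurrence", {
  pq <- two_quarter_pq()
  num <- list(regimen = cell_fit("uncensored_regimen", "numerator",
                                 1:2, c(0.8, 0.9)))
  den <- list(regimen = cell_fit("uncensored_regimen", "denominator",
                                 1:2, c(0.5, 0.6)))
  wt <- compute_stabilized_weights(pq, num, den)
  expect_equal(wt$sw, c(0.8 / 0.5, (0.8 / 0.5) * (0.9 / 0.6)),
               tolerance = 1e-12)
  expect_equal(wt$sw[2], 2.4, tolerance = 1e-12)
  expect_equal(wt$num_prob, c(0.8, 0.72), tolerance = 1e-12)
  expect_equal(wt$den_prob, c(0.5, 0.30), tolerance = 1e-12)
})

test_that("identical numerator and denominator fits give unit weights", {
  pq <- scenario_pq("confounded", 2000, 41)
  fits <- list(
    treatment = fit_mechanism(pq, mechanism_spec("treatment_at_index",
                                                 "denominator",
                                                 "risk_score")),
    regimen = fit_mechanism(pq, mechanism_spec("uncensored_regimen",
                                               "denominator",
                                               "biomarker")))
  wt <- compute_stabilized_weights(pq, fits, fits)
  expect_lt(max(abs(wt$sw - 1)), 1e-12)
})

test_that("truncation caps weights, is idempotent, and validates input", {
  pq <- two_quarter_pq()
  num <- list(regimen = cell_fit("uncensored_regimen", "numerator",
                                 1:2, c(0.9999, 0.9999)))
  den <- list(regimen = cell_fit("uncensored_regimen", "denominator",
                                 1:2, c(0.2, 0.05)))
  # sw = (0.9999/0.2, 0.9999^2/0.01) ~ (5, 100): only the second row
  # exceeds the default bound
  wt <- compute_stabilized_weights(pq, num, den)
  expect_gt(wt$sw[2], 20)
  expect_equal(wt$sw_trunc[2], 20)
  expect_equal(attr(wt, "n_truncated"), 1L)
  wt5 <- truncate_weights(wt, 3)
  expect_equal(wt5$sw_trunc, pmin(wt$sw, 3))
  expect_identical(truncate_weights(wt5, 3)$sw_trunc, wt5$sw_trunc)
  expect_equal(truncate_weights(wt, 25)$sw_trunc[1], wt$sw[1])
  expect_error(truncate_weights(wt, 0), "positive")
  bad <- wt
  bad$sw[1] <- -1
  expect_error(truncate_weights(bad, 20), "invariant")
})

test_that("diagnostics agree with an independent brute-force pass", {
  pq <- scenario_pq("confounded", 2000, 41)
  cfg <- default_config()
  res <- ipw_analysis(pq, cfg)
  wt <- structure(data.frame(participant = pq$participant,
                             quarter = pq$quarter, num_prob = NA,
                             den_prob = NA, sw = res$sw,
                             sw_trunc = pmin(res$sw, 20),
                             at_risk = pq$at_risk),
                  class = c("weight_table", "data.frame"),
                  truncation_bound = 20)
  d <- weight_diagnostics(wt)
  for (q in c(0, 4, 9)) {
    sw <- res$sw[pq$at_risk & pq$quarter == q]
    expect_equal(d$mean[d$quarter == q], mean(sw))
    expect_equal(d$max[d$quarter == q], max(sw))
    expect_equal(d$p99[d$quarter == q],
                 unname(quantile(sw, 0.99, type = 7)))
  }
  expect_error(weight_diagnostics(wt[0, ]), "empty")
})

test_that("stabilized weights concentrate near one without confounding", {
  pq <- scenario_pq("null_confounding", 20000, 5)
  res <- ipw_analysis(pq, default_config())
  frac_out <- mean(res$sw[pq$at_risk] < 0.8 | res$sw[pq$at_risk] > 1.25)
  expect_lt(frac_out, 0.05)
})
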