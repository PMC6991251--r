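# Marginal structural models: closed-form saturated hazards, the
# proportional model, survival/risk algebra.

one_stratum_pq <- function(n, events, w = NULL) {
  pq <- structure(data.frame(participant = seq_len(n), quarter = 0L,
                             arm = "HI", at_risk = TRUE,
                             event = seq_len(n) <= events,
                             censor_cause = "none"),
                  class = c("person_quarter", "data.frame"),
                  horizon = 1L, cohort_size = n,
                  baseline_covariates = character(),
                  quarterly_covariates = character())
  wt <- structure(data.frame(participant = seq_len(n), quarter = 0L,
                             num_prob = 1, den_prob = 1,
                             sw = if (is.null(w)) rep(1, n) else w,
                             sw_trunc = if (is.null(w)) rep(1, n) else w,
                             at_risk = TRUE),
                  class = c("weight_table", "data.frame"),
                  truncation_bound = 20)
  list(pq = pq, wt = wt)
}

test_that("saturated hazards are weighted event fractions", {
  f <- one_stratum_pq(10, 1)
  # the single-arm fixture leaves the other arm's stratum empty
  expect_warning(s <- fit_saturated_msm(f$pq, f$wt), "empty")
  expect_equal(s$hazard["q1", "HI"], 0.1)
  # event row weight 2 among nine unit-weight non-events
  f2 <- one_stratum_pq(10, 1, w = c(2, rep(1, 9)))
  expect_warning(s2 <- fit_saturated_msm(f2$pq, f2$wt), "empty")
  expect_equal(s2$hazard["q1", "HI"], 2 / 11)
})

test_that("saturated closed form equals the iterative weighted logistic MLE", {
  pq <- scenario_pq("confounded", 2000, 41)
  res <- ipw_analysis(pq, default_config())
  sw <- pmin(res$sw, 20)
  keep <- pq$at_risk
  cellf <- factor(paste(pq$arm, pq$quarter)[keep])
  g <- suppressWarnings(glm(pq$event[keep] ~ 0 + cellf, weights = sw[keep],
                            family = quasibinomial()))
  h_glm <- plogis(coef(g))
  names(h_glm) <- sub("^cellf", "", names(h_glm))
  for (q in 0:9) {
    expect_equal(unname(res$hazard[q + 1, "HI"]),
                 unname(h_glm[paste("HI", q)]), tolerance = 1e-8)
    expect_equal(unname(res$hazard[q + 1, "AI"]),
                 unname(h_glm[paste("AI", q)]), tolerance = 1e-8)
  }
})

test_that("unit-weight survival equals the discrete Kaplan-Meier estimator", {
  pq <- scenario_pq("null_confounding", 2000, 23)
  surf <- fit_saturated_msm(pq)
  sr <- survival_and_risks(surf)
  for (arm in c("HI", "AI")) {
    km <- km_reference(pq, arm)
    expect_lt(max(abs(sr$survival[-1, arm] - km)), 1e-10)
  }
})

test_that("proportional MSM with unit weights equals the pooled logistic glm", {
  pq <- scenario_pq("null_confounding", 2000, 23)
  fit <- fit_proportional_msm(pq)
  keep <- pq$at_risk
  g <- glm(pq$event[keep] ~ factor(pq$quarter[keep]) +
             I(pq$arm[keep] == "AI"), family = binomial())
  expect_equal(fit$beta, unname(coef(g)[11]), tolerance = 1e-7)
  sg <- sqrt(diag(vcov(g)))[11]
  expect_equal(fit$se, unname(sg), tolerance = 1e-4)
})

test_that("survival and risk algebra follows the product-limit identities", {
  hz <- matrix(0, 10, 2, dimnames = list(paste0("q", 1:10),
                                         c("HI", "AI")))
  surf <- structure(list(hazard = hz, model_form = "saturated",
                         horizon = 10L), class = "hazard_surface")
  sr <- survival_and_risks(surf)
  expect_true(all(sr$survival == 1))

  hz2 <- hz
  hz2[1:2, "HI"] <- 0.1
  surf2 <- structure(list(hazard = hz2, model_form = "saturated",
                          horizon = 10L), class = "hazard_surface")
  sr2 <- survival_and_risks(surf2)
  expect_equal(unname(sr2$survival["q2", "HI"]), 0.81)
  expect_equal(risk_difference(sr2, 2), 0 - (1 - 0.81))
  expect_equal(risk_difference(sr2, 10), -(1 - 0.81))

  # identical curves -> zero risk difference; sign convention: AI above HI
  # means a positive difference
  hz3 <- hz
  hz3[, "AI"] <- 0.05
  sr3 <- survival_and_risks(structure(list(hazard = hz3,
                                           model_form = "saturated",
                                           horizon = 10L),
                                      class = "hazard_surface"))
  expect_gt(risk_difference(sr3, 4), 0)
  expect_equal(risk_difference(sr3, 4), 1 - 0.95^4)
  expect_error(risk_difference(sr3, 11), "beyond")

  surf_na <- structure(list(hazard = rbind(hz[1:9, ],
                                           q10 = c(NA, 0)),
                            model_form = "saturated", horizon = 10L),
                       class = "hazard_surface")
  expect_error(survival_and_risks(surf_na), "undefined hazard")
})

test_that("event-weighted quarterly odds ratios align with the single HR", {
  pq <- scenario_pq("proportional_effect", 20000, 3)
  res <- ipw_analysis(pq, default_config())
  h <- res$hazard
  or_q <- (h[, "AI"] / (1 - h[, "AI"])) / (h[, "HI"] / (1 - h[, "HI"]))
  surf <- fit_saturated_msm(pq) # crude events for weighting the average
  wts <- rowSums(surf$events_w)
  or_bar <- sum(or_q * wts) / sum(wts)
  expect_lt(abs(or_bar - res$hazard_ratio) / res$hazard_ratio, 0.10)
})

test_that("adjusted and crude risks coincide without confounding", {
  pq <- scenario_pq("null_confounding", 20000, 5)
  adj <- ipw_analysis(pq, default_config())
  crude <- ipw_analysis(pq, pipeline_config(unadjusted = TRUE))
  expect_lt(max(abs(adj$rd - crude$rd)), 0.01)
  # and the area statistic is the sum of the quarterly risk differences
  expect_equal(adj$area_T, sum(adj$risk[, "AI"] - adj$risk[, "HI"]),
               tolerance = 1e-12)
})
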