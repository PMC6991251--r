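# Propensity mechanisms: pooled logistic fits, predictions and the
# discrete Super Learner.

make_pq <- function(df, horizon = 10L, baseline = character(),
                    quarterly = character()) {
  structure(df, class = c("person_quarter", "data.frame"),
            horizon = horizon, cohort_size = length(unique(df$participant)),
            baseline_covariates = baseline, quarterly_covariates = quarterly)
}

test_that("an intercept-only treatment fit returns the sample fraction", {
  pq <- make_pq(data.frame(participant = 1:100, quarter = 0L,
                           arm = rep(c("AI", "HI"), c(60, 40)),
                           at_risk = TRUE, event = FALSE,
                           censor_cause = "none"))
  fit <- fit_mechanism(pq, mechanism_spec("treatment_at_index",
                                          "denominator"))
  p <- predict_probability(fit, pq)
  expect_equal(p[1:60], rep(0.6, 60), tolerance = 1e-8)
  expect_equal(p[61:100], rep(0.4, 40), tolerance = 1e-8)
})

test_that("predictions are the inverse-logit of the linear predictor", {
  pq <- scenario_pq("confounded", 5000, 17)
  spec <- mechanism_spec("uncensored_regimen", "denominator",
                         c("risk_score", "biomarker"))
  fit <- fit_mechanism(pq, spec)
  rows <- c(3L, 50L, 1000L, 20000L, nrow(pq))
  co <- fit$coefficients
  for (i in rows) {
    eta <- co[["(Intercept)"]] +
      (if (pq$quarter[i] > 0)
         co[[paste0("factor(quarter)", pq$quarter[i])]] else 0) +
      co[["armAI"]] * (pq$arm[i] == "AI") +
      co[["risk_score"]] * pq$risk_score[i] +
      co[["biomarker"]] * pq$biomarker[i]
    y_i <- !(pq$censor_cause[i] %in% c("gap", "switch", "no_fill"))
    expect_equal(predict_probability(fit, pq)[i],
                 if (y_i) plogis(eta) else 1 - plogis(eta),
                 tolerance = 1e-10)
  }
})

test_that("null-confounding covariate coefficients are statistically null", {
  pq <- scenario_pq("null_confounding", 20000, 5)
  for (mech in c("treatment_at_index", "uncensored_regimen",
                 "uncensored_disenrollment")) {
    fit <- fit_mechanism(pq, mechanism_spec(
      mech, "denominator", c("risk_score", "age_c", "biomarker")))
    z <- fit$coefficients / fit$se
    covs <- c("risk_score", "age_c", "biomarker")
    expect_true(all(abs(z[covs]) < 3.5),
                info = paste(mech, paste(round(z[covs], 2), collapse = " ")))
  }
})

test_that("fitted probabilities track the marginal rates without confounding", {
  pq <- scenario_pq("null_confounding", 20000, 5)
  mr <- ipwmsm:::.mechanism_rows(pq, "uncensored_regimen")
  fit <- fit_mechanism(pq, mechanism_spec("uncensored_regimen",
                                          "denominator",
                                          c("risk_score", "biomarker")))
  p1 <- ipwmsm:::.predict_p1(fit, pq, mr$rows)
  # the model is stratified on quarter, so compare within quarters
  for (q in 0:9) {
    inq <- pq$quarter[mr$rows] == q
    expect_lt(max(abs(p1[inq] - mean(mr$y[inq]))), 0.02)
  }
})

test_that("degenerate responses and missing covariates raise errors", {
  pq <- make_pq(data.frame(participant = 1:50, quarter = 0L,
                           arm = "HI", at_risk = TRUE, event = FALSE,
                           censor_cause = "none"))
  expect_error(fit_mechanism(pq, mechanism_spec("treatment_at_index",
                                                "denominator")),
               "degenerate")
  pq2 <- scenario_pq("null_confounding", 2000, 9)
  expect_error(fit_mechanism(pq2, mechanism_spec("uncensored_regimen",
                                                 "denominator", "nope")),
               "nope")
  fit <- fit_mechanism(pq2, mechanism_spec("uncensored_regimen",
                                           "denominator", "risk_score"))
  pq3 <- pq2
  pq3$risk_score <- NULL
  expect_error(predict_probability(fit, pq3), "risk_score")
})

test_that("numerator specifications reject time-varying covariates", {
  pq <- scenario_pq("null_confounding", 2000, 9)
  expect_error(fit_mechanism(pq, mechanism_spec("uncensored_regimen",
                                                "numerator", "biomarker")),
               "time-varying")
})

test_that("the discrete Super Learner selects the CV-loss minimizer", {
  pq <- scenario_pq("confounded", 5000, 17)
  # single candidate -> that candidate
  one <- super_learner_select(pq, "treatment_at_index",
                              list(c("risk_score")), folds = 5, seed = 3)
  expect_equal(one$report$selected, 1L)
  # selected loss is minimal by construction
  two <- super_learner_select(pq, "treatment_at_index",
                              list(c("noise1", "noise2"), c("risk_score")),
                              folds = 5, seed = 3)
  expect_equal(two$report$selected, which.min(two$report$cv_loss))
  expect_equal(two$report$selected, 2L)
  # determinism
  rep2 <- super_learner_select(pq, "treatment_at_index",
                               list(c("noise1", "noise2"), c("risk_score")),
                               folds = 5, seed = 3)
  expect_identical(two$report$cv_loss, rep2$report$cv_loss)
})

test_that("the true confounder set beats pure noise across seeds", {
  wins <- 0L
  for (s in 1:20) {
    raw <- generate_cohort(preset_scenario("confounded", 20000,
                                           seed = 100 + s))
    pq <- build_person_quarters(raw, build_config())
    sl <- super_learner_select(pq, "treatment_at_index",
                               list(true = c("risk_score"),
                                    noise = c("noise1", "noise2")),
                               folds = 10, seed = s)
    wins <- wins + (sl$report$selected == 1L)
  }
  expect_gte(wins, 18L)
})
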