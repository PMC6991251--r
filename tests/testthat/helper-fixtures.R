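# Shared fixtures and small builders for the test suite. Heavier simulated
# cohorts are memoised so several test files can reuse the same build.

default_config <- function(unadjusted = FALSE) {
  pipeline_config(treatment_covariates = c("risk_score", "age_c"),
                  censoring_covariates = c("risk_score", "age_c", "biomarker"),
                  unadjusted = unadjusted)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

scenario_pq <- function(name, n = 20000, seed = 1) {
  cached(paste("pq", name, n, seed, sep = "_"), {
    raw <- generate_cohort(preset_scenario(name, n_participants = n,
                                           seed = seed))
    build_person_quarters(raw, build_config())
  })
}

# hand-made raw study data; every participant gets a day-0 human fill
# unless dispensings are supplied
tiny_raw <- function(dispensings,
                     enrollment = NULL,
                     events = NULL,
                     deaths = NULL,
                     baseline = NULL) {
  ids <- unique(dispensings$participant)
  if (is.null(enrollment))
    enrollment <- data.frame(participant = ids, start_day = 0L,
                             end_day = 990L)
  if (is.null(events))
    events <- data.frame(participant = integer(), outcome = character(),
                         day = integer())
  if (is.null(deaths))
    deaths <- data.frame(participant = integer(), day = integer())
  if (is.null(baseline))
    baseline <- data.frame(participant = ids)
  list(dispensings = dispensings, enrollment = enrollment, events = events,
       deaths = deaths, baseline_covariates = baseline,
       quarterly_covariates = data.frame(participant = integer(),
                                         quarter = integer()))
}

fills <- function(participant, day, insulin_class = "human") {
  data.frame(participant = participant, day = day,
             insulin_class = insulin_class)
}

# discrete-time Kaplan-Meier reference via the survival package: events at
# the end of their terminal quarter (time t+1), informative censoring just
# before the next quarter's events (time t+0.5), administrative-end rows
# censored after the final quarter's events (time t+1)
km_reference <- function(pq, arm, horizon = attr(pq, "horizon")) {
  term <- pq[c(diff(pq$participant) != 0, TRUE), ]
  term <- term[term$arm == arm, ]
  time <- ifelse(term$event | term$at_risk,
                 term$quarter + 1, term$quarter + 0.5)
  fit <- survival::survfit(survival::Surv(time, term$event) ~ 1)
  summary(fit, times = seq_len(horizon), extend = TRUE)$surv
}
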