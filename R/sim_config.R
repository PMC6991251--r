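#' Configure the synthetic longitudinal cohort generator
#'
#' Defines the full data-generating mechanism for a two-regimen new-user
#' cohort followed on a 90-day (quarterly) grid: baseline covariates, a
#' logistic treatment-choice model at the index date, quarterly refill /
#' switch behaviour, disenrollment, an autoregressive time-varying
#' covariate, and discrete-time outcome (and optionally death) hazards.
#' All per-quarter probabilities are inverse-logit transforms of linear
#' predictors over the configured covariates, so they always lie in (0, 1).
#'
#' Coefficient vectors are named numeric vectors; recognised names are
#' `"intercept"`, `"arm_ai"` (indicator of the comparator regimen) and the
#' names of baseline or time-varying covariates.
#'
#' @param n_participants cohort size (>= 1).
#' @param seed integer seed; identical `(config, seed)` pairs produce
#'   byte-identical cohorts.
#' @param baseline_covariate_spec named list; each element is
#'   `list(dist = "normal", mean =, sd =)` or `list(dist = "bernoulli", p =)`.
#' @param treatment_model coefficients for the log-odds of initiating the
#'   comparator (AI) regimen at the index date, over baseline covariates.
#' @param refill_model list with elements `ontime` (log-odds of refilling on
#'   time at each quarterly due date; a failed refill starts a supply gap),
#'   `switch` (log-odds, given an on-time refill, of switching therapy
#'   class), and `resume_prob` (probability that a participant who stopped
#'   refilling resumes three quarters later, which the supply rule then
#'   classifies as a gap rather than a permanent discontinuation).
#' @param disenrollment_model per-quarter log-odds of losing insurance
#'   enrollment (coverage ends at the last day of that quarter).
#' @param outcome_model per-quarter log-odds of the outcome event as a
#'   function of regimen (`arm_ai`), baseline and time-varying covariates.
#' @param death_model per-quarter log-odds of death as a competing
#'   censoring process; only used when `death_is_outcome` is `FALSE`.
#' @param covariate_update_model list describing one autoregressive
#'   time-varying covariate: `name`, `init_coef`, `init_sd`, `ar`,
#'   `drift_coef`, `sd`, and optional `arm_ai` effect.
#' @param horizon_quarters number of 90-day quarters simulated (default 10).
#' @param outcome_name label for the outcome event.
#' @param death_is_outcome if `TRUE` the outcome *is* death and
#'   `death_model` must be `NULL`.
#' @param day0_human_with_ai_prob probability that a comparator-regimen
#'   initiator also fills the reference class on day 0 (the comparator
#'   regimen definition allows concomitant reference-class use).
#'
#' @return An object of class `sim_config`.
#' @seealso [preset_scenario()], [generate_cohort()],
#'   [true_counterfactual_risks()]
#' @export
sim_config <- function(n_participants,
                       seed = 1L,
                       baseline_covariate_spec = list(),
                       treatment_model = c(intercept = 0),
                       refill_model = list(ontime = c(intercept = qlogis(0.92)),
                                           switch = c(intercept = qlogis(0.015)),
                                           resume_prob = 0.7),
                       disenrollment_model = c(intercept = qlogis(0.02)),
                       outcome_model = c(intercept = qlogis(0.02)),
                       death_model = NULL,
                       covariate_update_model = NULL,
                       horizon_quarters = 10L,
                       outcome_name = "death",
                       death_is_outcome = TRUE,
                       day0_human_with_ai_prob = 0.2) {
  cfg <- structure(
    list(n_participants = as.integer(n_participants),
         seed = as.integer(seed),
         baseline_covariate_spec = baseline_covariate_spec,
         treatment_model = treatment_model,
         refill_model = refill_model,
         disenrollment_model = disenrollment_model,
         outcome_model = outcome_model,
         death_model = death_model,
         covariate_update_model = covariate_update_model,
         horizon_quarters = as.integer(horizon_quarters),
         outcome_name = outcome_name,
         death_is_outcome = isTRUE(death_is_outcome),
         day0_human_with_ai_prob = day0_human_with_ai_prob),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_participants) || cfg$n_participants < 1)
    stop("configuration error in field 'n_participants': must be >= 1",
         call. = FALSE)
  if (cfg$horizon_quarters < 1)
    stop("configuration error in field 'horizon_quarters': must be >= 1",
         call. = FALSE)
  for (nm in names(cfg$baseline_covariate_spec)) {
    sp <- cfg$baseline_covariate_spec[[nm]]
    if (identical(sp$dist, "normal")) {
      if (!is.numeric(sp$sd) || sp$sd <= 0 || !is.finite(sp$mean))
        stop("configuration error in field 'baseline_covariate_spec$", nm,
             "': normal distribution needs finite mean and sd > 0",
             call. = FALSE)
    } else if (identical(sp$dist, "bernoulli")) {
      if (!is.numeric(sp$p) || sp$p < 0 || sp$p > 1)
        stop("configuration error in field 'baseline_covariate_spec$", nm,
             "': bernoulli probability must lie in [0, 1]", call. = FALSE)
    } else {
      stop("configuration error in field 'baseline_covariate_spec$", nm,
           "': unknown distribution family '", sp$dist, "'", call. = FALSE)
    }
  }
  for (fld in c("treatment_model", "disenrollment_model", "outcome_model")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || is.null(names(v)) || any(!is.finite(v)))
      stop("configuration error in field '", fld,
           "': must be a finite named numeric vector", call. = FALSE)
  }
  rp <- cfg$refill_model$resume_prob
  if (!is.numeric(rp) || rp < 0 || rp > 1)
    stop("configuration error in field 'refill_model$resume_prob': ",
         "must lie in [0, 1]", call. = FALSE)
  if (cfg$death_is_outcome && !is.null(cfg$death_model))
    stop("configuration error in field 'death_model': must be NULL when ",
         "death_is_outcome is TRUE", call. = FALSE)
  p0 <- cfg$day0_human_with_ai_prob
  if (!is.numeric(p0) || p0 < 0 || p0 > 1)
    stop("configuration error in field 'day0_human_with_ai_prob': ",
         "must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

# Shared scaffolding for the preset scenarios. Parameter scale rationale
# (fixed at design time; see the methods vignette):
#  * ~15% comparator (AI) initiation,
#  * per-quarter stop-refilling odds ~8% so that roughly 57% of the cohort
#    interrupts therapy within 10 quarters,
#  * 70% of stoppers eventually resume (supply gap) vs 30% never refill,
#  * ~1.5% per-quarter class switching,
#  * ~2% per-quarter disenrollment and ~2% per-quarter event hazard.
.preset_base <- function(n_participants, seed) {
  list(
    n_participants = n_participants,
    seed = seed,
    baseline_covariate_spec = list(
      risk_score = list(dist = "normal", mean = 0, sd = 1),
      age_c = list(dist = "normal", mean = 0, sd = 1),
      noise1 = list(dist = "normal", mean = 0, sd = 1),
      noise2 = list(dist = "normal", mean = 0, sd = 1)),
    covariate_update_model = list(
      name = "biomarker",
      init_coef = c(intercept = 0, risk_score = 0.4), init_sd = 1,
      drift_coef = c(intercept = 0, risk_score = 0.2), ar = 0.7, sd = 0.6,
      arm_ai = 0))
}

#' Preset data-generating scenarios
#'
#' Fully specified [sim_config()] objects used throughout the test battery:
#'
#' * `"null_confounding"`: treatment, censoring and outcome are mutually
#'   independent (all covariate coefficients zero, no regimen effect).
#' * `"confounded"`: a baseline risk score raises both comparator-regimen
#'   initiation and the outcome hazard, and the time-varying biomarker
#'   drives both censoring (refill gaps, disenrollment) and the outcome —
#'   baseline confounding plus informative censoring, with a null regimen
#'   effect so any crude arm difference is pure bias.
#' * `"informative_censoring"`: no baseline confounding of treatment, but
#'   biomarker-driven censoring and outcome as in `"confounded"`.
#' * `"proportional_effect"`: a constant regimen log-odds effect of
#'   `log(1.5)` on the outcome in every quarter, no covariate effects on
#'   the outcome (so the marginal discrete-time odds ratio is exactly 1.5),
#'   with covariate-driven treatment choice and censoring to exercise the
#'   weighting machinery.
#'
#' @param name one of `"null_confounding"`, `"confounded"`,
#'   `"informative_censoring"`, `"proportional_effect"`.
#' @param n_participants cohort size (default 20000, the package's standard
#'   property-test size).
#' @param seed integer seed.
#' @return A `sim_config`.
#' @export
preset_scenario <- function(name, n_participants = 20000L, seed = 1L) {
  valid <- c("null_confounding", "confounded", "informative_censoring",
             "proportional_effect")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "), call. = FALSE)
  base <- .preset_base(n_participants, seed)
  args <- switch(
    name,
    null_confounding = list(
      treatment_model = c(intercept = qlogis(0.15)),
      refill_model = list(ontime = c(intercept = qlogis(0.92)),
                          switch = c(intercept = qlogis(0.015)),
                          resume_prob = 0.7),
      disenrollment_model = c(intercept = qlogis(0.02)),
      outcome_model = c(intercept = qlogis(0.02), arm_ai = 0)),
    confounded = list(
      treatment_model = c(intercept = -1.75, risk_score = 0.8),
      refill_model = list(
        ontime = c(intercept = qlogis(0.92), biomarker = -0.4),
        switch = c(intercept = qlogis(0.015)),
        resume_prob = 0.7),
      disenrollment_model = c(intercept = qlogis(0.02), biomarker = 0.3),
      outcome_model = c(intercept = qlogis(0.02), arm_ai = 0,
                        risk_score = 0.35, biomarker = 0.35)),
    informative_censoring = list(
      treatment_model = c(intercept = -1.75),
      refill_model = list(
        ontime = c(intercept = qlogis(0.92), biomarker = -0.4),
        switch = c(intercept = qlogis(0.015)),
        resume_prob = 0.7),
      disenrollment_model = c(intercept = qlogis(0.02), biomarker = 0.3),
      outcome_model = c(intercept = qlogis(0.02), arm_ai = 0,
                        risk_score = 0.35, biomarker = 0.35)),
    proportional_effect = list(
      treatment_model = c(intercept = -1.75, risk_score = 0.8),
      refill_model = list(
        ontime = c(intercept = qlogis(0.92), biomarker = -0.4),
        switch = c(intercept = qlogis(0.015)),
        resume_prob = 0.7),
      disenrollment_model = c(intercept = qlogis(0.02), biomarker = 0.3),
      outcome_model = c(intercept = qlogis(0.02), arm_ai = log(1.5))))
  do.call(sim_config, c(base, args))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_participants, "participants,",
      x$horizon_quarters, "quarters, seed", x$seed, "\n")
  cat("  outcome:", x$outcome_name,
      if (x$death_is_outcome) "(fatal)" else "(nonfatal, death censors)", "\n")
  cat("  baseline covariates:",
      paste(names(x$baseline_covariate_spec), collapse = ", "), "\n")
  if (!is.null(x$covariate_update_model))
    cat("  time-varying covariate:", x$covariate_update_model$name, "\n")
  invisible(x)
}
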