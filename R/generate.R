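#' Simulate a raw longitudinal study cohort
#'
#' Generates the six raw tables the cohort builder consumes: dispensing
#' records, enrollment spans, outcome events, deaths, baseline covariates
#' and quarterly time-varying covariates. Time is measured in days from
#' each participant's index date (day 0, the first dispensing); refill
#' behaviour, disenrollment, death and the outcome are simulated quarter by
#' quarter from the configured logistic models, and an event or death stops
#' all subsequent simulation for that participant.
#'
#' Within a quarter the simulation order is: refill decisions (stopping
#' the current fill, or switching class at the next fill), then
#' disenrollment, then death, then the (nonfatal) outcome — death is
#' always drawn before the nonfatal outcome, and a participant cannot
#' have both in one quarter. Once a censoring process fires, outcome
#' capture stops from the terminal quarter of follow-up onward (events
#' occurring after therapy interruption or coverage loss are not
#' observed), which is what per-protocol censoring assumes.
#' Disenrollment ends coverage on the last day of the quarter in which
#' it occurs.
#'
#' @param config a [sim_config()].
#' @return An object of class `raw_study_data`: a list with elements
#'   `dispensings` (participant, day, insulin_class), `enrollment`
#'   (participant, start_day, end_day), `events` (participant, outcome,
#'   day), `deaths` (participant, day), `baseline_covariates` and
#'   `quarterly_covariates` (participant, quarter, one column per
#'   time-varying covariate).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  H <- config$horizon_quarters

  V <- .draw_baseline(config, n)
  L <- .draw_tv_paths(config, n, V, arm_ai = NULL) # filled in below if needed

  # treatment at index
  p_ai <- plogis(.linpred(config$treatment_model, V, field = "treatment_model"))
  ai <- runif(n) < p_ai

  # regenerate the time-varying path if the update model has a regimen term
  cum <- config$covariate_update_model
  if (!is.null(cum) && !is.null(cum$arm_ai) && cum$arm_ai != 0)
    L <- .draw_tv_paths(config, n, V, arm_ai = as.numeric(ai))

  fatal <- config$death_is_outcome
  fill_day <- vector("list", 2L * H + 4L)
  fill_class <- vector("list", 2L * H + 4L)
  fill_pid <- vector("list", 2L * H + 4L)
  nf <- 0L
  add_fills <- function(pid, day, cls) {
    nf <<- nf + 1L
    fill_pid[[nf]] <<- pid
    fill_day[[nf]] <<- day
    fill_class[[nf]] <<- cls
  }

  arm_class <- ifelse(ai, "analogue", "human")
  add_fills(seq_len(n), rep.int(0L, n), arm_class)
  conc <- ai & (runif(n) < config$day0_human_with_ai_prob)
  if (any(conc)) add_fills(which(conc), rep.int(0L, sum(conc)),
                           rep.int("human", sum(conc)))

  alive <- rep.int(TRUE, n)
  filling <- rep.int(TRUE, n)
  # first quarter from which outcome capture is suppressed by a censoring
  # process (the terminal quarter of analytic follow-up)
  cens_q <- rep.int(NA_integer_, n)
  disen_q <- rep.int(NA_integer_, n)
  death_day <- rep.int(NA_integer_, n)
  event_day <- rep.int(NA_integer_, n)

  rfm <- config$refill_model
  for (t in 0:(H - 1L)) {
    Ldat <- if (is.null(cum)) V else cbind(V, setNames(
      data.frame(L[, t + 1L]), cum$name))

    # refill decisions: stopping applies to the fill due at the start of
    # this quarter (the previous fill's supply still spans it, so the
    # supply lapse ends follow-up at the end of this quarter); switching
    # applies to the next due fill
    if (t >= 1L) {
      due <- alive & filling
      p_on <- plogis(.linpred(rfm$ontime, Ldat, arm_ai = as.numeric(ai),
                              field = "refill_model$ontime"))
      stop_now <- due & (runif(n) >= p_on)
      resume <- stop_now & (runif(n) < rfm$resume_prob)
      if (any(stop_now)) {
        filling[stop_now] <- FALSE
        cens_q[stop_now] <- pmin(cens_q[stop_now], t, na.rm = TRUE)
        if (any(resume))
          add_fills(which(resume), rep.int(90L * (t + 3L), sum(resume)),
                    arm_class[resume])
      }
      fillers <- due & !stop_now
      if (any(fillers))
        add_fills(which(fillers), rep.int(90L * t, sum(fillers)),
                  arm_class[fillers])
    } else {
      fillers <- alive & filling
    }
    p_sw <- plogis(.linpred(rfm$switch, Ldat, arm_ai = as.numeric(ai),
                            field = "refill_model$switch"))
    switch_now <- fillers & (runif(n) < p_sw)
    if (any(switch_now)) {
      other <- ifelse(ai[switch_now], "human", "analogue")
      add_fills(which(switch_now), rep.int(90L * (t + 1L), sum(switch_now)),
                other)
      filling[switch_now] <- FALSE
      # a reference-arm switch violates the regimen at the switch fill
      # itself (end of this quarter); a comparator-arm switch lets the
      # analogue supply run out one quarter later
      cq <- ifelse(ai[switch_now], t + 1L, t)
      cens_q[switch_now] <- pmin(cens_q[switch_now], cq, na.rm = TRUE)
    }

    p_dis <- plogis(.linpred(config$disenrollment_model, Ldat,
                             field = "disenrollment_model"))
    dis <- alive & is.na(disen_q) & (runif(n) < p_dis)
    if (any(dis)) {
      disen_q[dis] <- t
      filling[dis] <- FALSE
      cens_q[dis] <- pmin(cens_q[dis], t, na.rm = TRUE)
    }

    eligible <- alive & (is.na(cens_q) | t < cens_q)
    if (fatal) {
      pe <- plogis(.linpred(config$outcome_model, Ldat,
                            arm_ai = as.numeric(ai), field = "outcome_model"))
      died <- eligible & (runif(n) < pe)
      death_day[died] <- 90L * t + sample.int(89L, n, replace = TRUE)[died] - 1L
      alive[died] <- FALSE
    } else {
      pd <- plogis(.linpred(config$death_model, Ldat, arm_ai = as.numeric(ai),
                            field = "death_model"))
      died <- eligible & (runif(n) < pd)
      death_day[died] <- 90L * t + sample.int(89L, n, replace = TRUE)[died] - 1L
      alive[died] <- FALSE
      pe <- plogis(.linpred(config$outcome_model, Ldat,
                            arm_ai = as.numeric(ai), field = "outcome_model"))
      ev <- eligible & !died & (runif(n) < pe)
      event_day[ev] <- 90L * t + sample.int(89L, n, replace = TRUE)[ev] - 1L
      alive[ev] <- FALSE
    }
  }

  dispensings <- data.frame(
    participant = unlist(fill_pid[seq_len(nf)]),
    day = unlist(fill_day[seq_len(nf)]),
    insulin_class = unlist(fill_class[seq_len(nf)]))
  dispensings <- dispensings[order(dispensings$participant, dispensings$day,
                                   dispensings$insulin_class), ]
  rownames(dispensings) <- NULL

  enrollment <- data.frame(
    participant = seq_len(n),
    start_day = 0L,
    end_day = ifelse(is.na(disen_q), 90L * H + 90L, 90L * disen_q + 89L))

  events <- if (fatal) {
    data.frame(participant = integer(), outcome = character(),
               day = integer())
  } else {
    idx <- which(!is.na(event_day))
    data.frame(participant = idx,
               outcome = rep.int(config$outcome_name, length(idx)),
               day = event_day[idx])
  }
  deaths <- {
    idx <- which(!is.na(death_day))
    data.frame(participant = idx, day = death_day[idx])
  }

  baseline_covariates <- cbind(data.frame(participant = seq_len(n)), V)
  if (is.null(cum)) {
    quarterly_covariates <- data.frame(participant = integer(),
                                       quarter = integer())
  } else {
    quarterly_covariates <- data.frame(
      participant = rep(seq_len(n), times = H),
      quarter = rep(0:(H - 1L), each = n),
      as.vector(L))
    names(quarterly_covariates)[3L] <- cum$name
    quarterly_covariates <- quarterly_covariates[
      order(quarterly_covariates$participant, quarterly_covariates$quarter), ]
    rownames(quarterly_covariates) <- NULL
  }

  structure(list(dispensings = dispensings,
                 enrollment = enrollment,
                 events = events,
                 deaths = deaths,
                 baseline_covariates = baseline_covariates,
                 quarterly_covariates = quarterly_covariates,
                 config = config),
            class = "raw_study_data")
}

#' @noRd
.draw_baseline <- function(config, n) {
  out <- data.frame(row.names = seq_len(n))
  for (nm in names(config$baseline_covariate_spec)) {
    sp <- config$baseline_covariate_spec[[nm]]
    out[[nm]] <- switch(sp$dist,
                        normal = rnorm(n, sp$mean, sp$sd),
                        bernoulli = as.numeric(runif(n) < sp$p))
  }
  out
}

# Autoregressive time-varying covariate paths, an n x H matrix.
#' @noRd
.draw_tv_paths <- function(config, n, V, arm_ai = NULL) {
  cum <- config$covariate_update_model
  if (is.null(cum)) return(NULL)
  H <- config$horizon_quarters
  L <- matrix(0, n, H)
  arm_term <- if (is.null(arm_ai) || is.null(cum$arm_ai)) 0
              else cum$arm_ai * arm_ai
  L[, 1L] <- .linpred(cum$init_coef, V, field = "covariate_update_model") +
    rnorm(n, 0, cum$init_sd)
  if (H > 1L) for (t in 2:H) {
    L[, t] <- .linpred(cum$drift_coef, V, field = "covariate_update_model") +
      cum$ar * L[, t - 1L] + arm_term + rnorm(n, 0, cum$sd)
  }
  L
}

#' Monte-Carlo counterfactual risk oracle
#'
#' Computes the ground-truth counterfactual cumulative risks under a forced
#' regimen: participants are simulated from `config` with treatment set to
#' `regimen` for everyone and all censoring processes (refill gaps,
#' switching, disenrollment, and death when the outcome is nonfatal)
#' disabled. Rather than drawing individual event indicators, the
#' per-participant conditional cumulative risk is accumulated from the
#' per-quarter hazards and averaged (a Rao-Blackwellized Monte-Carlo
#' estimate — identical in expectation to drawing events, with smaller
#' Monte-Carlo error).
#'
#' @param config a [sim_config()].
#' @param regimen `"HI"` or `"AI"`.
#' @param mc_reps number of simulated participants (>= 1000).
#' @param seed integer seed (defaults to `config$seed`).
#' @return An object of class `sim_truth` with elements `config`,
#'   `regimen`, `risk` (cumulative risk at the end of quarters 1..horizon),
#'   `mc_se` (Monte-Carlo standard errors) and `mc_reps`.
#' @export
true_counterfactual_risks <- function(config, regimen, mc_reps = 50000L,
                                      seed = config$seed) {
  validate_sim_config(config)
  stopifnot(regimen %in% .ARMS)
  if (mc_reps < 1000L)
    stop("mc_reps must be >= 1000 for a stable oracle", call. = FALSE)
  set.seed(seed)
  n <- as.integer(mc_reps)
  H <- config$horizon_quarters
  V <- .draw_baseline(config, n)
  arm_ai <- rep.int(as.numeric(regimen == "AI"), n)
  L <- .draw_tv_paths(config, n, V, arm_ai = arm_ai)
  cum_risk <- rep.int(0, n)
  risk <- numeric(H)
  se <- numeric(H)
  for (t in 0:(H - 1L)) {
    Ldat <- if (is.null(L)) V else cbind(V, setNames(
      data.frame(L[, t + 1L]), config$covariate_update_model$name))
    pe <- plogis(.linpred(config$outcome_model, Ldat, arm_ai = arm_ai,
                          field = "outcome_model"))
    cum_risk <- cum_risk + (1 - cum_risk) * pe
    risk[t + 1L] <- mean(cum_risk)
    se[t + 1L] <- sd(cum_risk) / sqrt(n)
  }
  structure(list(config = config, regimen = regimen,
                 risk = setNames(risk, paste0("q", 1:H)),
                 mc_se = setNames(se, paste0("q", 1:H)),
                 mc_reps = n),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> forced regimen", x$regimen, "-", x$mc_reps,
      "Monte-Carlo participants\n")
  print(round(rbind(risk = x$risk, mc_se = x$mc_se), 5))
  invisible(x)
}
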