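#' Configure the person-quarter dataset builder
#'
#' @param supply_days assumed maximum duration of one dispensing, 180
#'   (primary) or 365 (sensitivity).
#' @param horizon_quarters number of 90-day quarters of follow-up retained.
#' @param admin_end_day administrative end of follow-up, in days from the
#'   index date (outcome-specific in designs with lagged registries).
#' @param outcome_name which event in the raw `events` table is the
#'   outcome.
#' @param death_is_outcome if `TRUE`, deaths are the outcome events;
#'   otherwise death is a right-censoring cause.
#' @return An object of class `build_config`.
#' @export
build_config <- function(supply_days = 180L, horizon_quarters = 10L,
                         admin_end_day = NULL, outcome_name = "death",
                         death_is_outcome = TRUE) {
  if (!supply_days %in% c(180L, 365L))
    stop("supply_days must be 180 or 365", call. = FALSE)
  if (horizon_quarters < 1L)
    stop("horizon_quarters must be >= 1", call. = FALSE)
  if (is.null(admin_end_day)) admin_end_day <- 90L * horizon_quarters
  structure(list(supply_days = as.integer(supply_days),
                 quarter_days = 90L,
                 horizon_quarters = as.integer(horizon_quarters),
                 admin_end_day = as.integer(admin_end_day),
                 outcome_name = outcome_name,
                 death_is_outcome = isTRUE(death_is_outcome)),
            class = "build_config")
}

#' Assign the regimen arm from index-date dispensings
#'
#' A participant belongs to the comparator arm (`"AI"`) if any day-0 fill
#' is analogue insulin — with or without concomitant human insulin — and to
#' the reference arm (`"HI"`) if all day-0 fills are human insulin.
#'
#' @param dispensings dispensing table (`participant`, `day`,
#'   `insulin_class`).
#' @param participant the participant id.
#' @return `"HI"` or `"AI"`.
#' @export
assign_arm <- function(dispensings, participant) {
  d0 <- dispensings[dispensings$participant == participant &
                      dispensings$day == 0, , drop = FALSE]
  cls <- d0$insulin_class
  if (any(cls == "analogue")) return("AI")
  if (any(cls == "human")) return("HI")
  stop("participant ", participant, " has no human or analogue dispensing ",
       "on day 0; new-user design requires an index fill", call. = FALSE)
}

#' Exposure intervals implied by the supply rule
#'
#' Each fill opens a half-open exposure interval `[day, end)` that closes
#' at the earlier of `supply_days` after dispensing or the next fill (no
#' stockpiling: a new fill is assumed to replace any remaining supply).
#'
#' @inheritParams assign_arm
#' @param supply_days 180 or 365.
#' @return A data.frame with columns `start_day`, `end_day`,
#'   `insulin_class`, one row per fill, sorted by `start_day`.
#' @export
exposure_timeline <- function(dispensings, participant, supply_days = 180L) {
  d <- dispensings[dispensings$participant == participant, , drop = FALSE]
  if (nrow(d) == 0L) stop("no dispensings for participant ", participant,
                          call. = FALSE)
  if (any(d$day < 0)) stop("negative dispensing day", call. = FALSE)
  d <- d[order(d$day), ]
  nxt <- c(d$day[-1L], Inf)
  data.frame(start_day = d$day,
             end_day = pmin(d$day + supply_days, nxt),
             insulin_class = d$insulin_class,
             row.names = NULL)
}

# Vectorized end-of-follow-up computation for every participant at once.
# Returns one row per participant: arm, end day and cause of the analytic
# end of follow-up, the terminal quarter, and whether the terminal row is
# an event. All the single-participant helpers delegate here so there is a
# single implementation of the censoring rules.
#' @noRd
.resolve_followup <- function(dispensings, enrollment, events, deaths,
                              config) {
  participant <- day <- insulin_class <- arm <- NULL # data.table NSE
  supply <- config$supply_days
  cap <- min(config$admin_end_day, 90L * config$horizon_quarters)

  ds <- data.table::as.data.table(dispensings)
  if (any(ds$day < 0)) stop("negative dispensing day", call. = FALSE)
  data.table::setkey(ds, participant, day)

  # arm from day-0 fills
  d0 <- ds[day == 0L]
  if (nrow(d0) == 0L || !all(unique(ds$participant) %in% d0$participant))
    stop("every participant needs a dispensing on day 0 (index date)",
         call. = FALSE)
  armdt <- d0[, .(arm = if (any(insulin_class == "analogue")) "AI"
                        else if (any(insulin_class == "human")) "HI"
                        else NA_character_),
              by = participant]
  if (anyNA(armdt$arm))
    stop("participant(s) with only 'other'-class day-0 fills: ",
         paste(head(armdt$participant[is.na(armdt$arm)]), collapse = ", "),
         call. = FALSE)

  ds <- armdt[ds, on = "participant"]

  # first supply lapse of the regimen-defining class
  def <- ds[(arm == "HI" & insulin_class == "human") |
              (arm == "AI" & insulin_class == "analogue")]
  lap <- def[, {
    nxt <- c(day[-1L], Inf)
    i <- which(nxt > day + supply)[1L]
    .(lapse_day = day[i] + supply)
  }, by = participant]

  # fills after the lapse (any class / analogue only), and continuing
  # reference-class supply at the lapse, to classify the interruption
  info <- ds[lap, on = "participant"][, .(
    any_after = any(day > lapse_day[1L]),
    analogue_after = any(day > lapse_day[1L] & insulin_class == "analogue"),
    human_spans = any(insulin_class %in% c("human", "other") &
                        day + supply > lapse_day[1L])),
    by = participant]
  lap <- info[lap, on = "participant"]
  lap[, cause_sup := data.table::fifelse(
    arm_lu(participant, armdt) == "AI",
    data.table::fifelse(analogue_after, "gap",
                        data.table::fifelse(human_spans, "switch", "no_fill")),
    data.table::fifelse(any_after, "gap", "no_fill"))]

  # regimen-violating fills: analogue or other for HI; other for AI
  vio <- .min_day_by(ds[(arm == "HI" & insulin_class %in%
                           c("analogue", "other")) |
                          (arm == "AI" & insulin_class == "other")],
                     "vio_day")

  # enrollment: coverage gap > 90 days, dated at the last covered day
  en <- data.table::as.data.table(enrollment)
  data.table::setorder(en, participant, start_day)
  if (nrow(en[, if (.N > 1L && any(start_day[-1L] < end_day[-.N]))
                  .(bad = TRUE), by = participant]) > 0L)
    stop("overlapping enrollment spans", call. = FALSE)
  dis <- en[, {
    nxt_start <- c(start_day[-1L], Inf)
    i <- which(nxt_start - end_day > 90)[1L]
    .(dis_day = end_day[i])
  }, by = participant]

  ev <- data.table::as.data.table(events)
  preg <- .min_day_by(ev[ev$outcome == "pregnancy"], "preg_day")
  if (config$death_is_outcome) {
    out_ev <- .min_day_by(data.table::as.data.table(deaths), "event_day")
    dth <- out_ev[0L]
  } else {
    out_ev <- .min_day_by(ev[ev$outcome == config$outcome_name], "event_day")
    dth <- .min_day_by(data.table::as.data.table(deaths), "event_day")
  }
  if (nrow(out_ev) && any(out_ev$event_day < 0))
    stop("negative event day", call. = FALSE)

  res <- armdt
  res <- lap[res, on = "participant"]
  res <- vio[res, on = "participant"]
  res <- dis[res, on = "participant"]
  res <- preg[res, on = "participant"]
  if (nrow(dth)) {
    data.table::setnames(dth, "event_day", "death_day")
    res <- dth[res, on = "participant"]
  } else res[, death_day := NA_integer_]
  res <- out_ev[res, on = "participant"]

  # earliest censoring candidate; ties broken by the fixed precedence
  # order death > disenrollment > switch > gap/no_fill > pregnancy >
  # admin_end (the event is resolved afterwards and beats everything)
  cand_day <- cbind(death = res$death_day,
                    disenrollment = res$dis_day,
                    switch = res$vio_day,
                    interruption = res$lapse_day,
                    pregnancy = res$preg_day,
                    admin_end = rep.int(cap, nrow(res)))
  cand_day[is.na(cand_day)] <- Inf
  pick <- max.col(-cand_day, ties.method = "first")
  end_day <- cand_day[cbind(seq_len(nrow(res)), pick)]
  cause <- colnames(cand_day)[pick]
  cause[cause == "interruption"] <- res$cause_sup[cause == "interruption"]

  term_q <- pmax(0, (end_day - 1) %/% 90)
  ed <- res$event_day
  ev_q <- ed %/% 90
  is_event <- !is.na(ed) & ed <= end_day & ev_q <= term_q
  term_q[is_event] <- ev_q[is_event]
  cause[is_event] <- "none"
  end_day[is_event] <- ed[is_event]

  data.table::data.table(
    participant = res$participant, arm = res$arm,
    end_day = end_day, cause = cause,
    terminal_quarter = as.integer(term_q), is_event = is_event)
}

#' @noRd
arm_lu <- function(pid, armdt) armdt$arm[match(pid, armdt$participant)]

# earliest day per participant, safe on empty tables
#' @noRd
.min_day_by <- function(dt, colname) {
  participant <- day <- NULL
  out <- if (nrow(dt)) dt[, .(d = min(day)), by = participant]
         else data.table::data.table(participant = integer(), d = integer())
  data.table::setnames(out, "d", colname)
  out
}

#' Analytic end of follow-up for one participant
#'
#' Returns the earliest of: a supply lapse of the regimen-defining class
#' (cause `"gap"` if any insulin fill follows the lapse, `"no_fill"`
#' otherwise; for the comparator arm a lapse with the reference class still
#' supplied is a `"switch"`), a regimen-violating fill (`"switch"`), an
#' enrollment coverage gap of more than 90 days (`"disenrollment"`, dated
#' at the last covered day), pregnancy start, death (when death is not the
#' outcome) and the administrative end of follow-up.
#'
#' @param timeline exposure timeline as returned by [exposure_timeline()]
#'   (accepted for interface completeness; the schedule is recomputed from
#'   the dispensing records, the single code path for the censoring rules).
#' @param arm `"HI"` or `"AI"` (checked against the day-0 fills).
#' @param dispensings,enrollment,deaths raw tables for this participant.
#' @param pregnancy_events data.frame of pregnancy starts (`participant`,
#'   `day`), possibly empty.
#' @param config a [build_config()].
#' @return A list with `end_day` and `cause`.
#' @export
censoring_schedule <- function(timeline, arm, dispensings, enrollment,
                               deaths = NULL, pregnancy_events = NULL,
                               config = build_config()) {
  if (is.null(deaths)) deaths <- data.frame(participant = integer(),
                                            day = integer())
  ev <- data.frame(participant = integer(), outcome = character(),
                   day = integer())
  if (!is.null(pregnancy_events) && nrow(pregnancy_events))
    ev <- data.frame(participant = pregnancy_events$participant,
                     outcome = "pregnancy", day = pregnancy_events$day)
  # resolve with death always censoring and no outcome events, so the
  # returned end is the censoring schedule itself
  cfg <- config
  cfg$death_is_outcome <- FALSE
  res <- .resolve_followup(dispensings, enrollment, ev, deaths, cfg)
  if (nrow(res) != 1L)
    stop("censoring_schedule expects the tables of a single participant",
         call. = FALSE)
  if (!identical(res$arm, arm))
    stop("declared arm ", arm, " does not match day-0 fills (", res$arm, ")",
         call. = FALSE)
  list(end_day = res$end_day, cause = res$cause)
}

#' Build the person-quarter analytic dataset
#'
#' Discretizes each participant's follow-up into 90-day quarters (quarter
#' `t` spans days `[90t, 90(t+1))`, 0-based), assigns the regimen arm at
#' the index date, applies the supply-rule censoring schedule, and returns
#' one row per participant-quarter with the event indicator, censoring
#' cause on the terminal row, and merged baseline and quarterly covariates.
#'
#' An event dated on or before the censoring day (and within the censored
#' follow-up) takes precedence over censoring. Terminal censoring rows are
#' flagged `at_risk = FALSE` and are excluded from hazard estimation —
#' except administrative-end rows falling exactly on a quarter boundary,
#' whose final quarter was fully observed.
#'
#' @param raw a `raw_study_data` list (see [generate_cohort()]) or any list
#'   with the same six tables.
#' @param config a [build_config()].
#' @return A `data.frame` of class `person_quarter` with columns
#'   `participant`, `quarter`, `arm`, `at_risk`, `event`, `censor_cause`
#'   plus covariate columns, and attributes `horizon`, `cohort_size`,
#'   `baseline_covariates`, `quarterly_covariates`.
#' @export
build_person_quarters <- function(raw, config = build_config()) {
  participant <- NULL
  res <- .resolve_followup(raw$dispensings, raw$enrollment, raw$events,
                           raw$deaths, config)
  data.table::setorder(res, participant)
  nq <- res$terminal_quarter + 1L
  pq <- data.table::data.table(
    participant = rep(res$participant, nq),
    quarter = sequence(nq) - 1L,
    arm = rep(res$arm, nq))
  last <- cumsum(nq)
  pq[, `:=`(event = FALSE, censor_cause = "none")]
  pq$event[last] <- res$is_event
  pq$censor_cause[last] <- ifelse(res$is_event, "none", res$cause)
  pq[, at_risk := censor_cause == "none" |
       (censor_cause == "admin_end" & rep(res$end_day %% 90, nq) == 0)]

  bl <- data.table::as.data.table(raw$baseline_covariates)
  bl_names <- setdiff(names(bl), "participant")
  if (length(bl_names)) pq <- bl[pq, on = "participant"]
  qc <- data.table::as.data.table(raw$quarterly_covariates)
  qc_names <- setdiff(names(qc), c("participant", "quarter"))
  if (length(qc_names)) pq <- qc[pq, on = c("participant", "quarter")]
  data.table::setorder(pq, participant, quarter)
  data.table::setcolorder(pq, c("participant", "quarter", "arm", "at_risk",
                                "event", "censor_cause"))
  out <- as.data.frame(pq)
  structure(out,
            class = c("person_quarter", "data.frame"),
            horizon = config$horizon_quarters,
            cohort_size = nrow(res),
            outcome_name = config$outcome_name,
            death_is_outcome = config$death_is_outcome,
            baseline_covariates = bl_names,
            quarterly_covariates = qc_names)
}
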