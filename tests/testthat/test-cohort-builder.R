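# Arm assignment, supply-rule exposure, censoring schedule and the
# person-quarter expansion.

test_that("arm assignment follows the day-0 fill classes", {
  d <- fills(c(1, 2, 2, 3), c(0, 0, 0, 0),
             c("human", "analogue", "human", "analogue"))
  expect_identical(assign_arm(d, 1), "HI")
  expect_identical(assign_arm(d, 2), "AI") # analogue with human -> AI
  expect_identical(assign_arm(d, 3), "AI")
  expect_error(assign_arm(fills(4, 10), 4), "day 0")
})

test_that("exposure intervals close at the next fill or supply end", {
  d <- fills(1, c(0L, 100L))
  tl <- exposure_timeline(d, 1, supply_days = 180)
  expect_equal(tl$start_day, c(0, 100))
  expect_equal(tl$end_day, c(100, 280))
  tl1 <- exposure_timeline(fills(1, 0L), 1, supply_days = 180)
  expect_equal(tl1$end_day, 180)
  tl2 <- exposure_timeline(fills(1, 0L), 1, supply_days = 365)
  expect_equal(tl2$end_day, 365)
  expect_error(exposure_timeline(fills(1, -5L), 1), "negative")
})

test_that("censoring schedule picks the earliest cause", {
  cfg <- build_config()
  # single fill, never refilled, alive and enrolled -> supply lapse with
  # no later fill
  d <- fills(1, 0L)
  cs <- censoring_schedule(exposure_timeline(d, 1), "HI", d,
                           data.frame(participant = 1, start_day = 0,
                                      end_day = 990),
                           config = cfg)
  expect_equal(cs$end_day, 180)
  expect_identical(cs$cause, "no_fill")

  # an analogue fill violates the reference regimen at its dispensing day
  d2 <- fills(1, c(0L, 60L), c("human", "analogue"))
  cs2 <- censoring_schedule(exposure_timeline(d2, 1), "HI", d2,
                            data.frame(participant = 1, start_day = 0,
                                       end_day = 990),
                            config = cfg)
  expect_equal(cs2$end_day, 60)
  expect_identical(cs2$cause, "switch")

  # enrollment ends at day 45 with no re-enrollment
  d3 <- fills(1, c(0L, 90L, 180L, 270L))
  cs3 <- censoring_schedule(exposure_timeline(d3, 1), "HI", d3,
                            data.frame(participant = 1, start_day = 0,
                                       end_day = 45),
                            config = cfg)
  expect_equal(cs3$end_day, 45)
  expect_identical(cs3$cause, "disenrollment")

  # a later fill after the lapse turns discontinuation into a gap
  d4 <- fills(1, c(0L, 400L))
  cs4 <- censoring_schedule(exposure_timeline(d4, 1), "HI", d4,
                            data.frame(participant = 1, start_day = 0,
                                       end_day = 990),
                            config = cfg)
  expect_equal(cs4$end_day, 180)
  expect_identical(cs4$cause, "gap")

  # comparator arm: analogue lapse while human continues is a switch
  d5 <- fills(1, c(0L, 90L, 180L, 270L),
              c("analogue", "human", "human", "human"))
  cs5 <- censoring_schedule(exposure_timeline(d5, 1), "AI", d5,
                            data.frame(participant = 1, start_day = 0,
                                       end_day = 990),
                            config = cfg)
  expect_equal(cs5$end_day, 180)
  expect_identical(cs5$cause, "switch")
})

test_that("person-quarter expansion honours event/censoring precedence", {
  cfg <- build_config()
  quarterly_fills <- fills(1, seq(0L, 810L, by = 90L))

  # event at day 95 -> rows t = 0 (no event) and t = 1 (event)
  raw <- tiny_raw(quarterly_fills, deaths = data.frame(participant = 1,
                                                       day = 95))
  pq <- build_person_quarters(raw, cfg)
  expect_equal(pq$quarter, 0:1)
  expect_equal(pq$event, c(FALSE, TRUE))
  expect_true(all(pq$at_risk))

  # disenrollment at day 50 -> a single censoring row at t = 0
  raw2 <- tiny_raw(quarterly_fills,
                   enrollment = data.frame(participant = 1, start_day = 0,
                                           end_day = 50))
  pq2 <- build_person_quarters(raw2, cfg)
  expect_equal(nrow(pq2), 1L)
  expect_identical(pq2$censor_cause, "disenrollment")
  expect_false(pq2$event)
  expect_false(pq2$at_risk)

  # event (day 100) beats the supply-gap censoring day (180)
  raw3 <- tiny_raw(fills(1, 0L), deaths = data.frame(participant = 1,
                                                     day = 100))
  pq3 <- build_person_quarters(raw3, cfg)
  expect_equal(pq3$quarter, 0:1)
  expect_true(pq3$event[2])

  # uncensored, event-free follow-up ends administratively at the horizon
  raw4 <- tiny_raw(quarterly_fills)
  pq4 <- build_person_quarters(raw4, cfg)
  expect_equal(nrow(pq4), 10L)
  expect_identical(pq4$censor_cause[10], "admin_end")
  expect_true(pq4$at_risk[10]) # boundary administrative end: full quarter

  expect_error(
    build_person_quarters(
      tiny_raw(quarterly_fills,
               enrollment = data.frame(participant = c(1, 1),
                                       start_day = c(0, 100),
                                       end_day = c(200, 990))), cfg),
    "overlapping")
})

test_that("every participant has exactly one terminal status", {
  pq <- scenario_pq("confounded", 5000, 17)
  s <- summarize_follow_up(pq)
  expect_equal(sum(s$counts), s$cohort_size)
  expect_equal(sum(s$interruption_detail), s$counts[["interruption"]])
  term <- pq[c(diff(pq$participant) != 0, TRUE), ]
  expect_equal(nrow(term), attr(pq, "cohort_size"))
  # rows are contiguous quarters from 0 and the arm is constant
  dt <- data.table::as.data.table(as.data.frame(pq))
  chk <- dt[, .(contig = identical(quarter, 0:(.N - 1L)),
                one_arm = data.table::uniqueN(arm) == 1L),
            by = participant]
  expect_true(all(chk$contig))
  expect_true(all(chk$one_arm))
  # no rows after an event
  ev_rows <- which(pq$event)
  expect_true(all(ev_rows %in% c(which(c(diff(pq$participant) != 0, TRUE)))))
})

test_that("enlarging the supply window never shortens follow-up", {
  raw <- generate_cohort(preset_scenario("confounded", 500, seed = 19))
  n180 <- table(factor(build_person_quarters(raw, build_config(180))$participant,
                       levels = 1:500))
  n365 <- table(factor(build_person_quarters(raw, build_config(365))$participant,
                       levels = 1:500))
  expect_true(all(as.integer(n365) >= as.integer(n180)))
})

test_that("disabling refill gaps removes gap and no-fill censoring", {
  cfg <- preset_scenario("null_confounding", 2000, seed = 23)
  cfg$refill_model$ontime <- c(intercept = 20)
  cfg$refill_model$switch <- c(intercept = -20)
  pq <- build_person_quarters(generate_cohort(cfg), build_config())
  expect_false(any(pq$censor_cause %in% c("gap", "no_fill", "switch")))
})

test_that("follow-up accounting percentages use one-decimal rounding", {
  # ten participants: 4 administrative, 3 gaps, 2 events, 1 death-censored
  expect_equal(followup_percentages(c(4, 3, 2, 1), 10),
               c(40.0, 30.0, 20.0, 10.0))
  expect_equal(followup_percentages(5464, 127600), 4.3)
  expect_equal(followup_percentages(73654, 127600), 57.7)
})
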