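#' Cohort percentages at one-decimal precision
#'
#' The reporting convention for follow-up accounting tables:
#' `round(100 * count / cohort_size, 1)`.
#'
#' @param counts integer vector of participant counts.
#' @param cohort_size total number of participants.
#' @return Numeric vector of percentages rounded to one decimal.
#' @export
followup_percentages <- function(counts, cohort_size) {
  round(100 * counts / cohort_size, 1)
}

#' Summarize reasons for end of analytic follow-up
#'
#' Tabulates each participant exactly once by terminal status (outcome
#' event or censoring cause), with percentages of the cohort to one
#' decimal, interruption-of-therapy subtotals (gap / switch / no fill),
#' and at-risk person-quarters by arm.
#'
#' @param pq a `person_quarter` table from [build_person_quarters()].
#' @param cohort_size cohort denominator; defaults to the number of
#'   participants in `pq`.
#' @return An object of class `followup_summary`.
#' @export
summarize_follow_up <- function(pq, cohort_size = NULL) {
  term <- pq[c(diff(pq$participant) != 0, TRUE), ]
  if (is.null(cohort_size)) cohort_size <- nrow(term)
  status <- ifelse(term$event, "event", term$censor_cause)
  interruption <- sum(status %in% .INTERRUPTION_CAUSES)
  counts <- c(admin_end = sum(status == "admin_end"),
              disenrollment = sum(status == "disenrollment"),
              pregnancy = sum(status == "pregnancy"),
              death_censoring = sum(status == "death"),
              event = sum(status == "event"),
              interruption = interruption)
  detail <- c(gap = sum(status == "gap"),
              switch = sum(status == "switch"),
              no_fill = sum(status == "no_fill"))
  pqs <- tapply(pq$at_risk, pq$arm, sum)
  structure(list(cohort_size = cohort_size,
                 counts = counts,
                 percentages = followup_percentages(counts, cohort_size),
                 interruption_detail = detail,
                 person_quarters = pqs),
            class = "followup_summary")
}

#' @export
print.followup_summary <- function(x, ...) {
  cat("End of analytic follow-up (cohort of", x$cohort_size,
      "participants)\n")
  lbl <- c(admin_end = "Administrative end of follow-up",
           disenrollment = "End of enrollment",
           pregnancy = "Start of pregnancy",
           death_censoring = "Death as a right-censoring event",
           event = "Outcome",
           interruption = "Interruption of initial therapy")
  for (nm in names(x$counts))
    cat(sprintf("  %-34s %8d (%.1f%%)\n", lbl[[nm]], x$counts[[nm]],
                x$percentages[[nm]]))
  cat(sprintf("    gap %d / switch %d / no fill %d\n",
              x$interruption_detail[["gap"]],
              x$interruption_detail[["switch"]],
              x$interruption_detail[["no_fill"]]))
  cat("  At-risk person-quarters:",
      paste(names(x$person_quarters), unclass(x$person_quarters),
            collapse = ", ", sep = " "), "\n")
  invisible(x)
}
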