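#' Specify one propensity-score mechanism
#'
#' The weighting machinery factorizes the observed-data likelihood into a
#' baseline treatment mechanism and per-quarter uncensored-status
#' mechanisms, one per censoring cause, modelled sequentially (regimen
#' interruption, then disenrollment, then death), each conditional on
#' remaining uncensored by the prior causes.
#'
#' Denominator models are pooled logistic regressions over person-quarters
#' with quarter indicator terms, the regimen arm, and the requested
#' covariates (time-varying covariates allowed). Numerator models may use
#' only the arm, time, and baseline covariates; with an empty covariate set
#' the numerator is saturated in (arm, quarter) and fit in closed form as
#' weighted cell means — the maximum-likelihood solution of the saturated
#' logistic model.
#'
#' @param mechanism one of `"treatment_at_index"`, `"uncensored_regimen"`,
#'   `"uncensored_disenrollment"`, `"uncensored_death"`.
#' @param role `"denominator"` or `"numerator"`.
#' @param covariates character vector of covariate column names.
#' @return An object of class `mechanism_spec`.
#' @export
mechanism_spec <- function(mechanism = c("treatment_at_index",
                                         "uncensored_regimen",
                                         "uncensored_disenrollment",
                                         "uncensored_death"),
                           role = c("denominator", "numerator"),
                           covariates = character()) {
  structure(list(mechanism = match.arg(mechanism),
                 role = match.arg(role),
                 covariates = covariates),
            class = "mechanism_spec")
}

# risk-set rows and 0/1 response for each mechanism, under the sequential
# cause-specific factorization
#' @noRd
.mechanism_rows <- function(pq, mechanism) {
  cc <- pq$censor_cause
  switch(mechanism,
         treatment_at_index = list(
           rows = which(pq$quarter == 0L),
           y = as.numeric(pq$arm == "AI")[pq$quarter == 0L]),
         uncensored_regimen = list(
           rows = seq_len(nrow(pq)),
           y = as.numeric(!(cc %in% .INTERRUPTION_CAUSES))),
         uncensored_disenrollment = {
           rows <- which(!(cc %in% .INTERRUPTION_CAUSES))
           list(rows = rows,
                y = as.numeric(cc[rows] != "disenrollment"))
         },
         uncensored_death = {
           rows <- which(!(cc %in% c(.INTERRUPTION_CAUSES, "disenrollment")))
           list(rows = rows, y = as.numeric(cc[rows] != "death"))
         },
         stop("unknown mechanism '", mechanism, "'", call. = FALSE))
}

#' @noRd
.mechanism_design <- function(pq, spec, rows) {
  miss <- setdiff(spec$covariates, names(pq))
  if (length(miss))
    stop("covariate column(s) missing from the person-quarter table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (spec$role == "numerator") {
    bl <- attr(pq, "baseline_covariates")
    tv <- intersect(spec$covariates, attr(pq, "quarterly_covariates"))
    if (length(tv))
      stop("numerator covariate set may not include time-varying ",
           "covariates: ", paste(tv, collapse = ", "), call. = FALSE)
  }
  d <- pq[rows, , drop = FALSE]
  horizon <- attr(pq, "horizon")
  if (spec$mechanism == "treatment_at_index") {
    fm <- if (length(spec$covariates))
      stats::reformulate(spec$covariates) else ~1
  } else {
    terms <- c("factor(quarter)", "arm", spec$covariates)
    fm <- stats::reformulate(terms)
    d$quarter <- factor(d$quarter, levels = 0:(horizon - 1L))
    d$arm <- factor(d$arm, levels = .ARMS)
  }
  model.matrix(fm, data = d)
}

#' Fit one propensity-score mechanism
#'
#' Maximum-likelihood logistic fit of the mechanism response (comparator
#' arm at the index date, or remaining uncensored by one cause through the
#' quarter) on the design implied by the [mechanism_spec()]. Numerator
#' specifications with an empty covariate set are fit in closed form as
#' weighted (arm, quarter) cell means.
#'
#' @param pq a `person_quarter` table.
#' @param spec a [mechanism_spec()].
#' @param weights optional nonnegative case weights, one per row of `pq`
#'   (used by the participant-resampling bootstrap).
#' @return An object of class `propensity_fit` with the coefficients and
#'   fit diagnostics (log-likelihood, iterations, convergence flag, and
#'   the probability clipping bound used by [predict_probability()]).
#' @export
fit_mechanism <- function(pq, spec, weights = NULL) {
  mr <- .mechanism_rows(pq, spec$mechanism)
  w <- if (is.null(weights)) NULL else weights[mr$rows]
  saturated_num <- spec$role == "numerator" && !length(spec$covariates)
  if (saturated_num) {
    if (spec$mechanism == "treatment_at_index") {
      p1 <- if (is.null(w)) mean(mr$y) else sum(w * mr$y) / sum(w)
      cells <- data.frame(cell = 1L, p = p1)
    } else {
      horizon <- attr(pq, "horizon")
      cell <- .cell_index(pq, horizon)[mr$rows]
      ws <- if (is.null(w)) rep.int(1, length(mr$y)) else w
      num <- rowsum(ws * mr$y, cell)
      den <- rowsum(ws, cell)
      cells <- data.frame(cell = as.integer(rownames(num)),
                          p = drop(num / den))
    }
    fit <- list(spec = spec, type = "cells", cells = cells,
                diagnostics = list(loglik = NA_real_, iterations = 0L,
                                   converged = TRUE, clip = .PROB_CLIP))
    return(structure(fit, class = "propensity_fit"))
  }
  X <- .mechanism_design(pq, spec, mr$rows)
  lf <- .logit_fit(X, mr$y, w = w, vcov = TRUE)
  if (!lf$converged)
    stop("logistic fit for mechanism '", spec$mechanism,
         "' did not converge after ", lf$iterations, " iterations",
         call. = FALSE)
  if (max(abs(lf$coefficients)) > 15)
    stop("apparent separation in mechanism '", spec$mechanism,
         "' (|coefficient| > 15); reduce the covariate adjustment set",
         call. = FALSE)
  structure(list(spec = spec, type = "logit",
                 coefficients = lf$coefficients,
                 se = sqrt(diag(lf$vcov)),
                 diagnostics = list(loglik = lf$loglik,
                                    iterations = lf$iterations,
                                    converged = lf$converged,
                                    clip = .PROB_CLIP)),
            class = "propensity_fit")
}

#' @noRd
.cell_index <- function(pq, horizon) {
  as.integer(pq$quarter) + horizon * as.integer(pq$arm == "AI") + 1L
}

# probability that the mechanism response equals 1, for every row of
# newdata (clipped)
#' @noRd
.predict_p1 <- function(fit, pq, rows = seq_len(nrow(pq))) {
  if (fit$type == "cells") {
    if (fit$spec$mechanism == "treatment_at_index")
      return(.clip_prob(rep.int(fit$cells$p, length(rows))))
    cell <- .cell_index(pq, attr(pq, "horizon"))[rows]
    p <- fit$cells$p[match(cell, fit$cells$cell)]
    return(.clip_prob(p))
  }
  X <- .mechanism_design(pq, fit$spec, rows)
  keep <- intersect(colnames(X), names(fit$coefficients))
  if (!setequal(colnames(X), names(fit$coefficients)))
    X <- X[, names(fit$coefficients), drop = FALSE]
  .clip_prob(plogis(drop(X %*% fit$coefficients)))
}

#' Predicted probability of the observed status
#'
#' Inverse-logit of the fitted linear predictor, returned as the
#' probability of each row's *observed* status: for the treatment
#' mechanism, `P(A = observed arm)`; for censoring mechanisms, the
#' probability of the observed uncensored/censored status. Probabilities
#' are clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param fit a [fit_mechanism()] result.
#' @param pq a `person_quarter` table containing every covariate in the
#'   fit's specification.
#' @return Numeric vector, one probability per mechanism risk-set row of
#'   `pq` (rows outside the mechanism's risk set get `NA`).
#' @export
predict_probability <- function(fit, pq) {
  mr <- .mechanism_rows(pq, fit$spec$mechanism)
  p1 <- .predict_p1(fit, pq, mr$rows)
  out <- rep.int(NA_real_, nrow(pq))
  out[mr$rows] <- ifelse(mr$y == 1, p1, 1 - p1)
  out
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit>", x$spec$mechanism, "/", x$spec$role, "\n")
  if (x$type == "cells") {
    cat("  saturated (arm x quarter) cell-mean fit,",
        nrow(x$cells), "cells\n")
  } else {
    cat("  pooled logistic,", length(x$coefficients), "coefficients,",
        x$diagnostics$iterations, "iterations\n")
  }
  invisible(x)
}

#' Discrete Super Learner over candidate adjustment sets
#'
#' V-fold cross-validated selection among candidate logistic covariate
#' adjustment sets for one propensity-score mechanism. Folds partition
#' *participants* (all of a participant's person-quarters stay in one
#' fold). The loss is the mean negative Bernoulli log-likelihood of the
#' held-out observed statuses; the candidate minimizing the
#' cross-validated loss (ties broken by candidate order) is refit on the
#' full data.
#'
#' @param pq a `person_quarter` table.
#' @param mechanism the mechanism name (see [mechanism_spec()]).
#' @param candidate_sets list of covariate-name character vectors (or of
#'   `mechanism_spec` objects) defining the candidates.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer seed for the fold assignment; the same
#'   `(table, seed, folds)` always yields the same report.
#' @return A list with the refit winning `fit` and a `report` of class
#'   `sl_report` (per-candidate losses, selection, folds, seed).
#' @export
super_learner_select <- function(pq, mechanism, candidate_sets,
                                 folds = 10L, seed = 1L) {
  if (length(candidate_sets) < 1L) stop("need at least one candidate",
                                        call. = FALSE)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  specs <- lapply(candidate_sets, function(cs) {
    if (inherits(cs, "mechanism_spec")) cs
    else mechanism_spec(mechanism, "denominator", covariates = cs)
  })
  ids <- unique(pq$participant)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(ids)))
  row_fold <- fold_of[match(pq$participant, ids)]
  mr <- .mechanism_rows(pq, mechanism)
  losses <- rep.int(NA_real_, length(specs))
  for (k in seq_along(specs)) {
    tot <- 0
    nobs <- 0L
    ok <- TRUE
    for (v in seq_len(folds)) {
      test_rows <- mr$rows[row_fold[mr$rows] == v]
      w <- as.numeric(row_fold != v)
      fit <- tryCatch(fit_mechanism(pq, specs[[k]], weights = w),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        warning("candidate ", k, " dropped: fold ", v, " failed (",
                conditionMessage(fit), ")", call. = FALSE)
        ok <- FALSE
        break
      }
      p1 <- .predict_p1(fit, pq, test_rows)
      y <- mr$y[match(test_rows, mr$rows)]
      tot <- tot - sum(y * log(p1) + (1 - y) * log1p(-p1))
      nobs <- nobs + length(y)
    }
    if (ok) losses[k] <- tot / nobs
  }
  if (all(is.na(losses)))
    stop("all Super Learner candidates failed", call. = FALSE)
  sel <- which.min(losses)
  fit <- fit_mechanism(pq, specs[[sel]])
  report <- structure(list(mechanism = mechanism,
                           candidates = lapply(specs, `[[`, "covariates"),
                           cv_loss = losses, selected = sel,
                           folds = folds, seed = seed),
                      class = "sl_report")
  list(fit = fit, report = report)
}

#' @export
print.sl_report <- function(x, ...) {
  cat("<sl_report> discrete Super Learner,", x$mechanism, "-",
      length(x$candidates), "candidates,", x$folds, "folds\n")
  for (k in seq_along(x$candidates)) {
    cat(sprintf("  %s[%d] loss %.6f  {%s}\n",
                if (k == x$selected) "*" else " ", k, x$cv_loss[k],
                paste(x$candidates[[k]], collapse = ", ")))
  }
  invisible(x)
}
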