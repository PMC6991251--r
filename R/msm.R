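#' Saturated marginal structural model for discrete-time hazards
#'
#' One hazard parameter per (quarter, regimen) cell. At the maximum
#' likelihood the weighted saturated logistic model has the closed-form
#' solution
#' `h(t, a) = sum(w * Y) / sum(w)` over the at-risk rows of stratum
#' `(t, a)` — identical (to numerical precision) to iteratively fitting
#' the saturated weighted logistic regression, which the test suite
#' asserts against [stats::glm()].
#'
#' @param pq a `person_quarter` table.
#' @param weights a `weight_table` aligned row-for-row with `pq`, or
#'   `NULL` for unit weights (the crude analysis).
#' @return An object of class `hazard_surface`: hazard matrix
#'   (`horizon` rows, columns `HI`/`AI`), weighted event and at-risk
#'   totals, and `model_form = "saturated"`. Strata with no at-risk weight
#'   are `NA` and flagged with a warning.
#' @export
fit_saturated_msm <- function(pq, weights = NULL) {
  w <- .aligned_weights(pq, weights)
  horizon <- attr(pq, "horizon")
  keep <- pq$at_risk
  cell <- .cell_index(pq, horizon)[keep]
  wk <- w[keep]
  yk <- as.numeric(pq$event[keep])
  lev <- seq_len(2L * horizon)
  ev <- den <- numeric(2L * horizon)
  agg_e <- rowsum(wk * yk, cell)
  agg_d <- rowsum(wk, cell)
  ev[as.integer(rownames(agg_e))] <- agg_e
  den[as.integer(rownames(agg_d))] <- agg_d
  h <- ifelse(den > 0, ev / den, NA_real_)
  hz <- matrix(h, nrow = horizon, ncol = 2L,
               dimnames = list(paste0("q", seq_len(horizon)), .ARMS))
  if (anyNA(hz))
    warning("empty (quarter, regimen) strata: ",
            paste(which(is.na(hz)), collapse = ", "), call. = FALSE)
  structure(list(hazard = hz,
                 events_w = matrix(ev, horizon, 2L,
                                   dimnames = dimnames(hz)),
                 atrisk_w = matrix(den, horizon, 2L,
                                   dimnames = dimnames(hz)),
                 model_form = "saturated", horizon = horizon),
            class = "hazard_surface")
}

#' @noRd
.aligned_weights <- function(pq, weights) {
  if (is.null(weights)) return(rep.int(1, nrow(pq)))
  if (nrow(weights) != nrow(pq) ||
      !identical(weights$participant, pq$participant))
    stop("weight table is not aligned with the person-quarter table",
         call. = FALSE)
  weights$sw_trunc
}

#' Proportional-hazards marginal structural model
#'
#' Weighted pooled logistic regression of the event on quarter indicators
#' plus a single regimen term. The exponentiated regimen coefficient is a
#' discrete-time odds ratio that approximates the hazard ratio when
#' quarterly hazards are small, and is reported as the hazard ratio. The
#' standard error is the model-based (inverse Fisher information) one;
#' [bootstrap_cis()] provides resampling intervals.
#'
#' @inheritParams fit_saturated_msm
#' @return A list with the regimen coefficient `beta` and its `se`, the
#'   `hazard_ratio`, a Wald 95% CI, the model-implied `hazard_surface`
#'   (`model_form = "proportional"`), and fit diagnostics.
#' @export
fit_proportional_msm <- function(pq, weights = NULL) {
  w <- .aligned_weights(pq, weights)
  horizon <- attr(pq, "horizon")
  keep <- pq$at_risk
  q <- factor(pq$quarter[keep], levels = 0:(horizon - 1L))
  ai <- as.numeric(pq$arm[keep] == "AI")
  X <- cbind(model.matrix(~q), arm_ai = ai)
  lf <- .logit_fit(X, as.numeric(pq$event[keep]), w = w[keep], vcov = TRUE)
  if (!lf$converged)
    stop("proportional MSM did not converge after ", lf$iterations,
         " iterations", call. = FALSE)
  beta <- lf$coefficients[["arm_ai"]]
  se <- sqrt(lf$vcov["arm_ai", "arm_ai"])
  co <- lf$coefficients
  base <- co[1L] + c(0, co[2:horizon])
  hz <- cbind(HI = plogis(base), AI = plogis(base + beta))
  rownames(hz) <- paste0("q", seq_len(horizon))
  surface <- structure(list(hazard = hz, model_form = "proportional",
                            horizon = horizon),
                       class = "hazard_surface")
  list(surface = surface, beta = beta, se = se,
       hazard_ratio = exp(beta),
       wald_ci = exp(beta + c(-1, 1) * 1.96 * se),
       diagnostics = list(loglik = lf$loglik, iterations = lf$iterations,
                          converged = lf$converged))
}

#' Survival curves and cumulative risks from a hazard surface
#'
#' `S_a(t) = prod_{k <= t} (1 - h(k, a))`, `Risk_a(t) = 1 - S_a(t)`, with
#' `S_a(0) = 1`. `t` counts completed quarters of follow-up (so `t = 4` is
#' 1 year and `t = 8` is 2 years on the 90-day grid).
#'
#' @param surface a `hazard_surface`.
#' @return A list with matrices `survival` (rows `q0..qH`) and `risk`
#'   (rows `q1..qH`), columns `HI`/`AI`.
#' @export
survival_and_risks <- function(surface) {
  hz <- surface$hazard
  if (anyNA(hz)) {
    bad <- which(is.na(hz), arr.ind = TRUE)
    stop("undefined hazard stratum (quarter ", bad[1L, 1L], ", ",
         colnames(hz)[bad[1L, 2L]], ")", call. = FALSE)
  }
  S <- apply(1 - hz, 2L, cumprod)
  surv <- rbind(q0 = c(HI = 1, AI = 1), S)
  rownames(surv) <- paste0("q", 0:surface$horizon)
  list(survival = surv, risk = 1 - S)
}

#' Counterfactual risk difference at a quarter
#'
#' `Risk_AI(t) - Risk_HI(t)`; the reference regimen is continuous HI
#' exposure, so a positive difference means higher risk under the
#' comparator regimen.
#'
#' @param risks result of [survival_and_risks()].
#' @param t quarter (number of completed 90-day quarters; 4 = 1 year,
#'   8 = 2 years).
#' @return The risk difference.
#' @export
risk_difference <- function(risks, t) {
  H <- nrow(risks$risk)
  if (!(t %in% seq_len(H)))
    stop("quarter t = ", t, " is beyond the ", H, "-quarter horizon",
         call. = FALSE)
  unname(risks$risk[t, "AI"] - risks$risk[t, "HI"])
}

#' @export
print.hazard_surface <- function(x, ...) {
  cat("<hazard_surface>", x$model_form, "MSM,", x$horizon, "quarters\n")
  print(round(x$hazard, 5))
  invisible(x)
}
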