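#' Configure the weighting-and-MSM analysis pipeline
#'
#' @param treatment_covariates baseline covariates for the treatment
#'   denominator model.
#' @param censoring_covariates covariates (baseline and/or time-varying)
#'   for the censoring denominator models.
#' @param death_ipcw include a death-censoring weight mechanism when the
#'   outcome is nonfatal (default `TRUE`).
#' @param ps_method `"glm"` (fixed adjustment sets) or `"superlearner"`
#'   (discrete Super Learner selection among `candidates`, run once per
#'   mechanism before weighting; bootstrap replicates condition on the
#'   selected sets).
#' @param candidates list of covariate-name vectors, the Super Learner
#'   library of candidate adjustment sets (required for
#'   `ps_method = "superlearner"`).
#' @param folds,sl_seed cross-validation folds and fold seed for the
#'   Super Learner.
#' @param truncation_bound upper weight truncation bound (default 20).
#' @param unadjusted if `TRUE` all weights are 1 (the crude analysis).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(treatment_covariates = character(),
                            censoring_covariates = character(),
                            death_ipcw = TRUE,
                            ps_method = c("glm", "superlearner"),
                            candidates = NULL,
                            folds = 10L, sl_seed = 1L,
                            truncation_bound = 20,
                            unadjusted = FALSE) {
  ps_method <- match.arg(ps_method)
  if (ps_method == "superlearner" && is.null(candidates))
    stop("ps_method = 'superlearner' needs a list of candidate ",
         "adjustment sets", call. = FALSE)
  structure(list(treatment_covariates = treatment_covariates,
                 censoring_covariates = censoring_covariates,
                 death_ipcw = isTRUE(death_ipcw),
                 ps_method = ps_method, candidates = candidates,
                 folds = as.integer(folds), sl_seed = as.integer(sl_seed),
                 truncation_bound = truncation_bound,
                 unadjusted = isTRUE(unadjusted)),
            class = "pipeline_config")
}

# If requested, run the discrete Super Learner once per mechanism and fix
# the selected covariate sets in the config.
#' @noRd
.resolve_ps <- function(pq, config) {
  if (config$ps_method != "superlearner") return(config)
  reports <- list()
  sl_t <- super_learner_select(pq, "treatment_at_index", config$candidates,
                               folds = config$folds, seed = config$sl_seed)
  config$treatment_covariates <- sl_t$report$candidates[[sl_t$report$selected]]
  reports$treatment <- sl_t$report
  mechs <- c("uncensored_regimen", "uncensored_disenrollment",
             if (.death_mechanism_active(pq, config)) "uncensored_death")
  cens_sets <- vapply(mechs, function(m) {
    sl <- super_learner_select(pq, m, config$candidates,
                               folds = config$folds, seed = config$sl_seed)
    reports[[m]] <<- sl$report
    sl$report$selected
  }, integer(1))
  # one censoring covariate set per mechanism
  config$censoring_covariates <- lapply(
    cens_sets, function(k) config$candidates[[k]])
  names(config$censoring_covariates) <- mechs
  config$sl_reports <- reports
  config
}

#' @noRd
.death_mechanism_active <- function(pq, config) {
  !isTRUE(attr(pq, "death_is_outcome")) && config$death_ipcw
}

#' @noRd
.censoring_set <- function(config, mech) {
  cs <- config$censoring_covariates
  if (is.list(cs)) cs[[mech]] else cs
}

# Precompute everything the weighting + MSM pipeline needs so that a
# bootstrap replicate only has to change participant multiplicities:
# design matrices, responses, risk-set row indices, cell indices and
# warm-start coefficients from the full-data fits.
#' @noRd
.pipeline_prepare <- function(pq, config) {
  H <- attr(pq, "horizon")
  ids <- unique(pq$participant)
  n <- length(ids)
  pid <- match(pq$participant, ids)
  first <- c(TRUE, diff(pid) != 0)
  t0 <- which(pq$quarter == 0L)

  mechs <- c("uncensored_regimen", "uncensored_disenrollment",
             if (.death_mechanism_active(pq, config)) "uncensored_death")
  mech_list <- list()
  prep <- list(pq = pq, config = config, H = H, n = n, pid = pid,
               first = first, t0 = t0,
               Y = as.numeric(pq$event), at_risk = pq$at_risk,
               cell = .cell_index(pq, H),
               arm_ai = as.numeric(pq$arm == "AI"))
  if (!config$unadjusted) {
    yA <- prep$arm_ai[t0]
    Xt <- .mechanism_design(
      pq, mechanism_spec("treatment_at_index", "denominator",
                         config$treatment_covariates), t0)
    fit_t <- .logit_fit(Xt, yA, loglik = FALSE)
    for (m in mechs) {
      mr <- .mechanism_rows(pq, m)
      cs <- .censoring_set(config, m)
      miss <- setdiff(cs, names(pq))
      if (length(miss))
        stop("covariate column(s) missing from the person-quarter table: ",
             paste(miss, collapse = ", "), call. = FALSE)
      # blocked design: one intercept per quarter, dense part arm + covs
      Z <- cbind(arm_ai = prep$arm_ai,
                 if (length(cs))
                   as.matrix(as.data.frame(pq)[, cs, drop = FALSE]))
      qidx <- as.integer(pq$quarter) + 1L
      bf <- .blocked_fit_fast(qidx[mr$rows], H, Z[mr$rows, , drop = FALSE],
                              mr$y, rep.int(1, length(mr$rows)),
                              tol = 1e-9)
      mech_list[[m]] <- list(rows = mr$rows, y = mr$y,
                             Z = Z[mr$rows, , drop = FALSE],
                             qidx = qidx[mr$rows], start = bf)
    }
    prep$yA <- yA
    prep$Xt <- Xt
    prep$start_t <- fit_t$coefficients
  }
  prep$mechanisms <- mech_list
  # proportional-MSM design over at-risk rows (blocked: quarter
  # intercepts + single regimen term)
  keep <- which(pq$at_risk)
  prep$prop_rows <- keep
  prep$prop_qidx <- as.integer(pq$quarter[keep]) + 1L
  prep$prop_Z <- matrix(prep$arm_ai[keep], dimnames = list(NULL, "arm_ai"))
  prep$start_prop <- .blocked_fit_fast(prep$prop_qidx, H, prep$prop_Z,
                                       prep$Y[keep],
                                       rep.int(1, length(keep)),
                                       tol = 1e-9)
  prep
}

# One full pipeline evaluation under participant multiplicities `mult`
# (NULL = the observed data). Returns hazards, risks, the proportional-MSM
# regimen coefficient, headline risk differences and the area statistic.
#' @noRd
.pipeline_run <- function(prep, mult = NULL, want_beta = TRUE,
                          detail = FALSE) {
  H <- prep$H
  cfg <- prep$config
  m_part <- if (is.null(mult)) rep.int(1, prep$n) else mult
  m_row <- m_part[prep$pid]

  log_floor <- log(.PROB_CLIP)
  if (cfg$unadjusted) {
    sw <- rep.int(1, length(m_row))
  } else {
    # treatment component
    m0 <- m_part
    p_num <- sum(m0 * prep$yA) / sum(m0)
    ft <- .logit_fit(prep$Xt, prep$yA, w = m0, start = prep$start_t,
                     loglik = FALSE)
    pd <- .clip_prob(plogis(drop(prep$Xt %*% ft$coefficients)))
    trt_ratio <- ifelse(prep$yA == 1, .clip_prob(p_num) / pd,
                        .clip_prob(1 - p_num) / (1 - pd))
    log_r <- rep.int(0, length(m_row))
    for (m in names(prep$mechanisms)) {
      mm <- prep$mechanisms[[m]]
      wts <- m_row[mm$rows]
      lf <- .blocked_fit_fast(mm$qidx, H, mm$Z, mm$y, wts,
                              start = mm$start, tol = 1e-6,
                              want_logp = TRUE)
      log_pden <- pmax(lf$logp, log_floor)
      # saturated (arm, quarter) numerator as weighted cell means
      cells <- prep$cell[mm$rows]
      agg <- rowsum(cbind(wts * mm$y, wts), cells)
      pmap <- rep.int(NA_real_, 2L * H)
      pmap[as.integer(rownames(agg))] <- agg[, 1L] / pmax(agg[, 2L], 1e-300)
      log_pnum <- pmax(log(pmap[cells]), log_floor)
      log_r[mm$rows] <- log_r[mm$rows] + log_pnum - log_pden
    }
    cum <- .grouped_cumsum(log_r, prep$first)
    sw <- trt_ratio[cumsum(prep$first)] * exp(cum)
    sw <- pmin(sw, cfg$truncation_bound)
  }

  w_eff <- sw * m_row
  keep <- prep$at_risk
  ev <- den <- numeric(2L * H)
  agg_e <- rowsum((w_eff * prep$Y)[keep], prep$cell[keep])
  agg_d <- rowsum(w_eff[keep], prep$cell[keep])
  ev[as.integer(rownames(agg_e))] <- agg_e
  den[as.integer(rownames(agg_d))] <- agg_d
  if (any(den <= 0)) {
    return(list(ok = FALSE))
  }
  hz <- matrix(ev / den, nrow = H, ncol = 2L,
               dimnames = list(paste0("q", seq_len(H)), .ARMS))
  S <- apply(1 - hz, 2L, cumprod)
  risk <- 1 - S
  rd <- risk[, "AI"] - risk[, "HI"]
  out <- list(ok = TRUE, hazard = hz, risk = risk,
              rd = rd, area_T = sum(rd),
              rd_1y = if (H >= 4L) rd[4L] else NA_real_,
              rd_2y = if (H >= 8L) rd[8L] else NA_real_)
  if (want_beta) {
    lf <- .blocked_fit_fast(prep$prop_qidx, H, prep$prop_Z,
                            prep$Y[prep$prop_rows],
                            w_eff[prep$prop_rows],
                            start = prep$start_prop,
                            tol = if (is.null(mult)) 1e-9 else 1e-6)
    out$beta <- lf$bz[[1L]]
    out$hr <- exp(out$beta)
    if (is.null(mult)) out$se <- sqrt(lf$vcov_bz[1L, 1L])
  }
  if (detail) out$sw <- sw
  out
}

#' @noRd
.bootstrap_replicates <- function(prep, B, seed, want_beta = TRUE) {
  set.seed(seed)
  stats <- matrix(NA_real_, nrow = B, ncol = 4L,
                  dimnames = list(NULL, c("area_T", "hr", "rd_1y", "rd_2y")))
  dropped <- 0L
  for (b in seq_len(B)) {
    mult <- tabulate(sample.int(prep$n, prep$n, replace = TRUE), prep$n)
    r <- .pipeline_run(prep, mult, want_beta = want_beta)
    if (!r$ok) {
      dropped <- dropped + 1L
      next
    }
    stats[b, ] <- c(r$area_T, if (want_beta) r$hr else NA_real_,
                    r$rd_1y, r$rd_2y)
  }
  if (dropped > 0.2 * B)
    stop(dropped, " of ", B, " bootstrap replicates had empty hazard ",
         "strata; the cohort is too small for the saturated MSM",
         call. = FALSE)
  if (dropped > 0L)
    warning(dropped, " bootstrap replicate(s) dropped (empty strata)",
            call. = FALSE)
  list(stats = stats[!is.na(stats[, 1L]), , drop = FALSE],
       dropped = dropped)
}

#' Run the full per-protocol weighting and MSM analysis
#'
#' Convenience wrapper: resolves the propensity method (running the
#' discrete Super Learner if requested), fits all mechanisms, assembles
#' stabilized truncated weights, fits both MSMs, and (optionally)
#' computes participant-level bootstrap percentile confidence intervals
#' for the hazard ratio and the risk differences at 1 and 2 years, plus
#' the area-between-curves test.
#'
#' @param pq a `person_quarter` table from [build_person_quarters()].
#' @param config a [pipeline_config()].
#' @param B bootstrap replicates (0 = point estimates only).
#' @param seed seed for the bootstrap resampling.
#' @return An object of class `msm_result`.
#' @export
ipw_analysis <- function(pq, config = pipeline_config(), B = 0L, seed = 1L) {
  config <- .resolve_ps(pq, config)
  prep <- .pipeline_prepare(pq, config)
  full <- .pipeline_run(prep, NULL, detail = TRUE)
  if (!full$ok)
    stop("empty (quarter, regimen) stratum in the observed data; ",
         "cannot form the saturated MSM", call. = FALSE)
  res <- list(hazard = full$hazard, risk = full$risk, rd = full$rd,
              survival = rbind(q0 = c(HI = 1, AI = 1), 1 - full$risk),
              hazard_ratio = full$hr, beta = full$beta, se = full$se,
              wald_ci = exp(full$beta + c(-1, 1) * 1.96 * full$se),
              rd_1y = full$rd_1y, rd_2y = full$rd_2y,
              area_T = full$area_T,
              sw = full$sw,
              config = config, B = B, seed = seed,
              sl_reports = config$sl_reports)
  if (B > 0L) {
    br <- .bootstrap_replicates(prep, B, seed)
    st <- br$stats
    ci <- function(x) unname(quantile(x, c(0.025, 0.975), type = 7))
    res$ci_hr <- ci(st[, "hr"])
    res$ci_rd_1y <- ci(st[, "rd_1y"])
    res$ci_rd_2y <- ci(st[, "rd_2y"])
    se_T <- sd(st[, "area_T"])
    res$area_se <- se_T
    res$area_p <- 2 * pnorm(-abs(full$area_T) / se_T)
    res$bootstrap_dropped <- br$dropped
  }
  structure(res, class = "msm_result")
}

#' @export
print.msm_result <- function(x, ...) {
  cat("<msm_result> per-protocol IPW-MSM analysis",
      if (x$config$unadjusted) "(unadjusted)" else "", "\n")
  fmt_ci <- function(ci) if (is.null(ci)) "" else
    sprintf(" (%.3f to %.3f)", ci[1], ci[2])
  cat(sprintf("  Hazard ratio (AI vs HI): %.3f%s\n", x$hazard_ratio,
              fmt_ci(x$ci_hr)))
  cat(sprintf("  Risk difference at 1 y:  %+.4f%s\n", x$rd_1y,
              fmt_ci(x$ci_rd_1y)))
  cat(sprintf("  Risk difference at 2 y:  %+.4f%s\n", x$rd_2y,
              fmt_ci(x$ci_rd_2y)))
  cat(sprintf("  Area between curves T = %+.4f", x$area_T))
  if (!is.null(x$area_p)) cat(sprintf(", two-tailed p = %.3f (bootstrap SE %.4f, B = %d)",
                                      x$area_p, x$area_se, x$B))
  cat("\n")
  invisible(x)
}

#' @export
plot.msm_result <- function(x, ...) {
  surv <- x$survival
  tq <- 0:(nrow(surv) - 1L)
  plot(tq, surv[, "HI"], type = "s", ylim = range(surv) - c(0.02, 0),
       xlab = "Quarters of follow-up", ylab = "Survival",
       main = "Counterfactual survival by regimen", ...)
  graphics::lines(tq, surv[, "AI"], type = "s", lty = 2, col = 2)
  graphics::legend("bottomleft", legend = c("HI (reference)", "AI"),
                   lty = c(1, 2), col = c(1, 2), bty = "n")
  invisible(x)
}
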