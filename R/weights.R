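#' Assemble stabilized inverse-probability weights
#'
#' For each person-quarter, the stabilized weight is the treatment
#' numerator/denominator ratio at the index date times the cumulative
#' product, over quarters `k <= t` and over the active censoring
#' mechanisms, of the numerator and denominator probabilities of remaining
#' uncensored:
#' `sw(t) = sw(t-1) * prod_m [ P_num,m(uncensored at t) / P_den,m(uncensored at t) ]`.
#' Weights are then truncated from above at `truncation_bound`.
#'
#' @param pq a `person_quarter` table, ordered by (participant, quarter).
#' @param numerator_fits named list of [fit_mechanism()] results (names
#'   from `"treatment"`, `"regimen"`, `"disenrollment"`, `"death"`).
#' @param denominator_fits named list matching `numerator_fits`.
#' @param truncation_bound upper truncation bound (default 20).
#' @return A data.frame of class `weight_table` keyed by
#'   (`participant`, `quarter`) with the cumulative numerator and
#'   denominator probability products, the stabilized weight `sw`, its
#'   truncated version `sw_trunc`, and the `at_risk` flag. Attributes
#'   record the truncation bound, the number of truncated rows and the
#'   count of denominator probabilities at the clipping floor (possible
#'   positivity violations, also raised as a warning).
#' @export
compute_stabilized_weights <- function(pq, numerator_fits, denominator_fits,
                                       truncation_bound = 20) {
  if (!setequal(names(numerator_fits), names(denominator_fits)))
    stop("numerator and denominator fits must cover the same mechanisms",
         call. = FALSE)
  nrows <- nrow(pq)
  log_num <- rep.int(0, nrows)
  log_den <- rep.int(0, nrows)
  floor_hits <- 0L
  for (nm in names(numerator_fits)) {
    if (nm == "treatment") next
    mech <- numerator_fits[[nm]]$spec$mechanism
    if (!identical(mech, denominator_fits[[nm]]$spec$mechanism))
      stop("numerator and denominator fits for '", nm,
           "' model different mechanisms", call. = FALSE)
    rows <- .mechanism_rows(pq, mech)$rows
    pn <- .predict_p1(numerator_fits[[nm]], pq, rows)
    pd <- .predict_p1(denominator_fits[[nm]], pq, rows)
    floor_hits <- floor_hits + sum(pd <= .PROB_CLIP)
    log_num[rows] <- log_num[rows] + log(pn)
    log_den[rows] <- log_den[rows] + log(pd)
  }
  # cumulative products within participant (rows are quarter-ordered)
  first <- c(TRUE, diff(pq$participant) != 0)
  cum_num <- .grouped_cumsum(log_num, first)
  cum_den <- .grouped_cumsum(log_den, first)

  if (!is.null(numerator_fits$treatment)) {
    t0 <- which(pq$quarter == 0L)
    mr <- .mechanism_rows(pq, "treatment_at_index")
    pn1 <- .predict_p1(numerator_fits$treatment, pq, t0)
    pd1 <- .predict_p1(denominator_fits$treatment, pq, t0)
    obs_num <- ifelse(mr$y == 1, pn1, 1 - pn1)
    obs_den <- ifelse(mr$y == 1, pd1, 1 - pd1)
    floor_hits <- floor_hits + sum(obs_den <= .PROB_CLIP)
    idx <- cumsum(first)  # participant order index
    cum_num <- cum_num + log(obs_num)[idx]
    cum_den <- cum_den + log(obs_den)[idx]
  }
  if (floor_hits > 0L)
    warning(floor_hits, " denominator probabilities at the clipping floor ",
            "(possible positivity violation)", call. = FALSE)
  sw <- exp(cum_num - cum_den)
  out <- data.frame(participant = pq$participant, quarter = pq$quarter,
                    num_prob = exp(cum_num), den_prob = exp(cum_den),
                    sw = sw, sw_trunc = pmin(sw, truncation_bound),
                    at_risk = pq$at_risk)
  structure(out, class = c("weight_table", "data.frame"),
            truncation_bound = truncation_bound,
            n_truncated = sum(sw > truncation_bound),
            clip_floor_hits = floor_hits)
}

# cumulative sums restarting wherever `first` is TRUE
#' @noRd
.grouped_cumsum <- function(x, first) {
  cs <- cumsum(x)
  offset <- cs[first] - x[first]
  cs - offset[cumsum(first)]
}

#' Truncate stabilized weights
#'
#' Replaces each weight by `min(weight, bound)`; idempotent, and records
#' the number of truncated rows.
#'
#' @param weights a `weight_table` from [compute_stabilized_weights()].
#' @param bound positive truncation bound.
#' @return The `weight_table` with updated `sw_trunc` and attributes.
#' @export
truncate_weights <- function(weights, bound = 20) {
  if (!is.numeric(bound) || length(bound) != 1L || bound <= 0)
    stop("truncation bound must be a positive number", call. = FALSE)
  if (any(weights$sw <= 0))
    stop("invariant violation: nonpositive stabilized weight", call. = FALSE)
  weights$sw_trunc <- pmin(weights$sw, bound)
  attr(weights, "truncation_bound") <- bound
  attr(weights, "n_truncated") <- sum(weights$sw > bound)
  weights
}

#' Per-quarter weight diagnostics
#'
#' Mean, maximum, 99th percentile and truncated-row count of the
#' stabilized weights among at-risk rows, by quarter.
#'
#' @param weights a `weight_table`.
#' @return A data.frame with one row per quarter.
#' @export
weight_diagnostics <- function(weights) {
  if (nrow(weights) == 0L) stop("empty weight table", call. = FALSE)
  w <- weights[weights$at_risk, , drop = FALSE]
  bound <- attr(weights, "truncation_bound")
  qs <- sort(unique(w$quarter))
  do.call(rbind, lapply(qs, function(q) {
    sw <- w$sw[w$quarter == q]
    data.frame(quarter = q, n = length(sw), mean = mean(sw), max = max(sw),
               p99 = unname(quantile(sw, 0.99, type = 7)),
               n_truncated = sum(sw > bound))
  }))
}
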