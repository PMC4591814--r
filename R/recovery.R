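# Inference back from lanes to model parameters, and between-enzyme
# comparison.
#
# In the single-hit regime (at most one processive encounter per
# molecule) the insertion probability computed from a lane is an
# unbiased estimator of the generative continuation probability s_i at
# that position; with multiple encounters it is biased upward (failed
# molecules get further chances), which is surfaced as a warning when
# the lanes show a time trend.

#' Estimate an extension profile from lanes
#'
#' Per-position continuation estimates: `s_hat[i]` is the mean over
#' lanes of the insertion probability at Ni. Positions where the mean
#' cumulative signal fraction `cum(i-1)/total` falls below `floor` are
#' flagged as unreliable and carry no confidence interval; elsewhere a
#' t-based interval across lanes is attached (requires >= 2 lanes with
#' the statistic defined).
#'
#' The N0 band pools molecules the polymerase never engaged with
#' molecules that engaged but failed the first insertion, so `s_hat[1]`
#' is confounded by the engagement rate: it is flagged as
#' non-identifiable unless either the lanes are single-hit-conditioned
#' (`single_hit = TRUE`) or the expected engagement count is supplied
#' (`lambda_t`), in which case it is corrected by inverting
#' `insertion(N1) = 1 - exp(-lambda_t * s_1)`.
#'
#' @param lanes List of `tls_lane` on one substrate.
#' @param substrate The `tls_substrate` the lanes were run on.
#' @param floor Minimum mean cumulative signal fraction below which a
#'   position is flagged; default 0.01.
#' @param conf Confidence level for the per-position intervals.
#' @param lambda_t Expected engagements per molecule over the
#'   incubation, if known; used only to de-confound position N1.
#' @param single_hit Set `TRUE` when every molecule is known to have
#'   seen exactly one engagement (conditioned data); N1 then needs no
#'   correction.
#' @return An object of class `tls_profile_estimate`: a list with a
#'   data.frame `estimates` (columns `N`, `s_hat`, `ci_low`, `ci_high`,
#'   `n_lanes`, `flagged`, `flag_reason`), `positions_flagged`, and
#'   `method` metadata (single-hit assumption, `lambda_t` if known).
#' @export
estimate_profile <- function(lanes, substrate, floor = 0.01, conf = 0.95,
                             lambda_t = NULL, single_hit = FALSE) {
  stopifnot(inherits(substrate, "tls_substrate"))
  if (length(lanes) < 1L) stop("at least one lane required", call. = FALSE)
  K <- substrate$K
  if (any(vapply(lanes, lane_K, 1L) != K))
    stop("lane length does not match substrate K", call. = FALSE)
  ins <- vapply(lanes, function(l) {
    vapply(seq_len(K), function(N) insertion_probability(l, N), 1)
  }, numeric(K))
  ins <- matrix(ins, nrow = K)
  cumfrac <- vapply(lanes, function(l) {
    tot <- cumulative_at_least(l, 0L)
    vapply(seq_len(K), function(N) cumulative_at_least(l, N - 1L) / tot, 1)
  }, numeric(K))
  cumfrac <- matrix(cumfrac, nrow = K)
  mean_cumfrac <- rowMeans(cumfrac)
  flagged <- mean_cumfrac < floor
  flag_reason <- ifelse(flagged, "low signal", "")

  n1_correct <- FALSE
  if (!single_hit) {
    if (is.null(lambda_t)) {
      flagged[1L] <- TRUE
      flag_reason[1L] <- paste0(
        if (nzchar(flag_reason[1L])) paste0(flag_reason[1L], "; ") else "",
        "engagement-confounded (unknown lambda_t)")
    } else {
      n1_correct <- TRUE
    }
  }
  if (n1_correct) {
    # invert P(ever extended) = 1 - exp(-lambda_t * s_1), per lane
    ins[1L, ] <- pmin(1, pmax(0, -log1p(-pmin(ins[1L, ], 1 - 1e-15)) /
                                   lambda_t))
  }

  est <- data.frame(N = seq_len(K), s_hat = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, n_lanes = 0L, flagged = flagged,
                    flag_reason = flag_reason, stringsAsFactors = FALSE)
  alpha <- 1 - conf
  for (i in seq_len(K)) {
    x <- ins[i, !is.na(ins[i, ])]
    est$n_lanes[i] <- length(x)
    if (length(x) == 0L) next
    est$s_hat[i] <- mean(x)
    if (!flagged[i] && length(x) >= 2L && stats::sd(x) > 0) {
      hw <- stats::qt(1 - alpha / 2, df = length(x) - 1L) *
        stats::sd(x) / sqrt(length(x))
      est$ci_low[i] <- max(0, est$s_hat[i] - hw)
      est$ci_high[i] <- min(1, est$s_hat[i] + hw)
    } else if (!flagged[i] && length(x) >= 2L) {
      est$ci_low[i] <- est$ci_high[i] <- est$s_hat[i]
    }
  }
  if (any(flagged)) {
    est$ci_low[flagged] <- NA_real_
    est$ci_high[flagged] <- NA_real_
  }
  warn_multi_hit(lanes, est)
  structure(list(estimates = est,
                 positions_flagged = est$N[flagged],
                 method = list(assumption = if (single_hit) "single-hit (conditioned)"
                               else "single-hit",
                               lambda_t = lambda_t,
                               floor = floor, conf = conf,
                               n_lanes = length(lanes))),
            class = "tls_profile_estimate")
}

# Multi-hit diagnostics: with re-engagement, longer incubations push
# measured insertion probabilities up, so a strong positive time trend
# signals bias relative to the single-encounter parameters.
warn_multi_hit <- function(lanes, est) {
  times <- vapply(lanes, `[[`, 1, "time_min")
  if (length(unique(times)) < 2L) return(invisible(NULL))
  for (i in est$N[!est$flagged]) {
    y <- vapply(lanes, function(l) insertion_probability(l, i), 1)
    ok <- !is.na(y)
    if (sum(ok) < 3L || stats::sd(y[ok]) == 0) next
    fit <- stats::lm(y[ok] ~ times[ok])
    tv <- summary(fit)$coefficients
    if (nrow(tv) == 2L && !is.na(tv[2L, 3L]) && tv[2L, 3L] > 2) {
      warning("insertion probability at N", i, " increases with incubation ",
              "time (> 2 SD): single-hit estimates may be biased upward",
              call. = FALSE)
      return(invisible(NULL))
    }
  }
  invisible(NULL)
}

#' @export
print.tls_profile_estimate <- function(x, ...) {
  cat(sprintf("<profile estimate> %d positions from %d lanes (single-hit)\n",
              nrow(x$estimates), x$method$n_lanes))
  print(x$estimates, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Bootstrap confidence interval for bypass efficiency
#'
#' Percentile bootstrap over lanes: in each of `B` resamples, lanes are
#' drawn with replacement independently within the damaged and
#' undamaged arms, the bypass probability at `lesion_N` is averaged
#' within each arm, and the efficiency (percent) recorded. Degenerate
#' resamples (zero or undefined undamaged bypass) are redrawn and
#' counted; more than 10 percent degenerate is an error.
#'
#' With the handful of lanes a gel experiment yields, raw percentile
#' endpoints are systematically too narrow (the bootstrap spread of a
#' mean uses divisor n and normal-range quantiles where a t range is
#' needed), so by default the percentile levels are expanded for small
#' samples: `alpha'/2 = pnorm(-sqrt(n/(n-1)) * qt(1 - alpha/2, n - 1))`
#' with `n` the smaller arm size. Set `expand = FALSE` for the raw
#' percentile interval.
#'
#' @param damaged_lanes,undamaged_lanes Lists of `tls_lane` (>= 2 per
#'   arm).
#' @param lesion_N Evaluation (lesion) position.
#' @param B Number of bootstrap resamples (>= 100); default 2000.
#' @param seed PRNG seed (required).
#' @param level Confidence level; default 0.95.
#' @param expand Apply the small-sample expansion of the percentile
#'   levels (default `TRUE`).
#' @return List with `ci_low`, `ci_high` (percent), `estimate_pct`
#'   (efficiency from the full data), `B`, `level`, `n_redrawn`.
#' @export
bootstrap_efficiency_ci <- function(damaged_lanes, undamaged_lanes, lesion_N,
                                    B = 2000, seed, level = 0.95,
                                    expand = TRUE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (length(damaged_lanes) < 2L || length(undamaged_lanes) < 2L)
    stop("at least 2 lanes per arm required", call. = FALSE)
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  byp_d <- vapply(damaged_lanes, bypass_probability, 1, N = lesion_N)
  byp_u <- vapply(undamaged_lanes, bypass_probability, 1, N = lesion_N)
  if (mean(byp_u, na.rm = TRUE) <= 0 || all(is.na(byp_u)))
    stop("undamaged arm has no bypass signal at N", lesion_N, call. = FALSE)
  est <- bypass_efficiency(mean(byp_d, na.rm = TRUE),
                           mean(byp_u, na.rm = TRUE))
  nd <- length(byp_d); nu <- length(byp_u)
  set.seed(seed)
  effs <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      md <- mean(byp_d[sample.int(nd, nd, replace = TRUE)])
      mu <- mean(byp_u[sample.int(nu, nu, replace = TRUE)])
      if (!is.na(mu) && mu > 0 && !is.na(md)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 0.1 * B)
        stop("more than 10% of bootstrap resamples degenerate", call. = FALSE)
    }
    effs[b] <- 100 * md / mu
  }
  alpha <- 1 - level
  lo <- alpha / 2
  if (expand) {
    n_eff <- min(nd, nu)
    lo <- stats::pnorm(-sqrt(n_eff / (n_eff - 1)) *
                         stats::qt(1 - alpha / 2, df = n_eff - 1L))
  }
  ci <- stats::quantile(effs, c(lo, 1 - lo), names = FALSE)
  list(ci_low = ci[1L], ci_high = ci[2L], estimate_pct = est,
       B = B, level = level, n_redrawn = n_redrawn)
}

#' Fold change between two bypass efficiencies
#'
#' Ratio of a reference efficiency to a variant efficiency (e.g. wild
#' type over a point mutant), with the nearest-integer fold alongside.
#'
#' @param reference,variant `tls_summary` objects carrying
#'   `efficiency_pct`, or bare efficiencies in percent.
#' @return List with `ratio` and `fold` (nearest integer).
#' @examples
#' fold_change(18.0, 3.8)$fold  # 5
#' @export
fold_change <- function(reference, variant) {
  eff <- function(x, what) {
    if (inherits(x, "tls_summary")) {
      if (is.null(x$efficiency_pct))
        stop(what, " summary carries no efficiency", call. = FALSE)
      x$efficiency_pct
    } else as.numeric(x)
  }
  r <- eff(reference, "reference"); v <- eff(variant, "variant")
  if (is.na(r) || r <= 0) stop("reference efficiency must be > 0", call. = FALSE)
  if (is.na(v) || v <= 0)
    stop("infinite fold: variant efficiency is 0", call. = FALSE)
  ratio <- r / v
  list(ratio = ratio, fold = as.integer(floor(ratio + 0.5)))
}
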