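# Core assay statistics computed from gel-lane band intensities.
#
# All statistics are ratios of cumulative band intensities ("bands
# >= N"), so the absolute densitometry scale cancels.  Definitions, for
# a lane with band intensity I(N) at product length index N:
#   termination(N) = I(N)            / sum_{m >= N}   I(m)
#   insertion(N)   = sum_{m >= N}    I(m) / sum_{m >= N-1} I(m)
#   extension(N)   = sum_{m >= N+1}  I(m) / sum_{m >= N}   I(m)
#   bypass(N)      = sum_{m >= N+1}  I(m) / sum_{m >= N-1} I(m)
# whence bypass(N) = insertion(N) * extension(N) and
# termination(N) + extension(N) = 1 wherever defined.  A statistic is
# undefined (NA) when its denominator is zero.

#' Construct a gel lane
#'
#' @param lane_id Unique lane identifier.
#' @param enzyme Enzyme name.
#' @param substrate_name Name of the substrate the lane was run on.
#' @param time_min Incubation time in minutes.
#' @param replicate Replicate (experiment) index.
#' @param intensities Named numeric vector of band intensities, one
#'   entry per product-length index `N` from `"0"` (unextended primer)
#'   to `"K"` (full length); all entries must be present and
#'   non-negative.
#' @return An object of class `tls_lane`.
#' @export
lane <- function(lane_id, enzyme, substrate_name, time_min, replicate,
                 intensities) {
  intensities <- unlist(intensities)
  K <- length(intensities) - 1L
  if (K < 1L) stop("intensities must cover N0..NK with K >= 1", call. = FALSE)
  if (is.null(names(intensities))) names(intensities) <- as.character(0:K)
  if (!identical(names(intensities), as.character(0:K)))
    stop("intensities must be named by consecutive N indices 0..K",
         call. = FALSE)
  if (anyNA(intensities) || any(intensities < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (!is.numeric(time_min) || time_min <= 0)
    stop("time_min must be positive", call. = FALSE)
  structure(list(lane_id = as.character(lane_id), enzyme = as.character(enzyme),
                 substrate_name = as.character(substrate_name),
                 time_min = as.numeric(time_min),
                 replicate = as.integer(replicate),
                 intensities = stats::setNames(as.numeric(intensities),
                                               names(intensities))),
            class = "tls_lane")
}

#' @export
print.tls_lane <- function(x, ...) {
  K <- length(x$intensities) - 1L
  cat(sprintf("<lane %s> %s on %s, %g min, rep %d; N0..N%d, total %.4g\n",
              x$lane_id, x$enzyme, x$substrate_name, x$time_min, x$replicate,
              K, sum(x$intensities)))
  invisible(x)
}

lane_K <- function(lane) length(lane$intensities) - 1L

#' Cumulative band intensity at or beyond a position
#'
#' `cumulative_at_least(lane, N)` is the summed intensity of all bands
#' of length index `>= N`; at `N = 0` it equals the total lane
#' intensity. This is the primitive all assay statistics share.
#'
#' @param lane A `tls_lane`.
#' @param N Position index in `0..K`.
#' @return Non-negative intensity.
#' @export
cumulative_at_least <- function(lane, N) {
  K <- lane_K(lane)
  if (length(N) != 1L || N < 0L || N > K)
    stop("N must lie in 0..", K, call. = FALSE)
  sum(lane$intensities[(N + 1L):(K + 1L)])
}

#' Termination probability at a position
#'
#' Fraction of molecules that reached at least `N` whose synthesis
#' stopped exactly there: band intensity at `N` over total intensity of
#' bands `>= N`. `NA` when no molecule reached `N`.
#'
#' @inheritParams cumulative_at_least
#' @return Fraction in `[0,1]`, or `NA_real_` when undefined.
#' @export
termination_probability <- function(lane, N) {
  denom <- cumulative_at_least(lane, N)
  if (denom == 0) return(NA_real_)
  unname(lane$intensities[N + 1L] / denom)
}

#' Insertion probability at a position
#'
#' Fraction of molecules that reached `N - 1` which incorporated a
#' nucleotide at `N`: intensity of bands `>= N` over bands `>= N - 1`.
#' At the lesion position this is the probability of insertion opposite
#' the lesion.
#'
#' @param lane A `tls_lane`.
#' @param N Position index in `1..K`.
#' @return Fraction in `[0,1]`, or `NA_real_` when undefined.
#' @export
insertion_probability <- function(lane, N) {
  K <- lane_K(lane)
  if (N < 1L || N > K) stop("N must lie in 1..", K, call. = FALSE)
  denom <- cumulative_at_least(lane, N - 1L)
  if (denom == 0) return(NA_real_)
  cumulative_at_least(lane, N) / denom
}

#' Extension probability at a position
#'
#' Fraction of molecules at `N` that were extended further: intensity
#' of bands `>= N + 1` over bands `>= N`. Identically equal to
#' `insertion_probability(lane, N + 1)` and to
#' `1 - termination_probability(lane, N)`.
#'
#' @param lane A `tls_lane`.
#' @param N Position index in `0..K-1`.
#' @return Fraction in `[0,1]`, or `NA_real_` when undefined.
#' @export
extension_probability <- function(lane, N) {
  K <- lane_K(lane)
  if (N < 0L || N > K - 1L) stop("N must lie in 0..", K - 1L, call. = FALSE)
  denom <- cumulative_at_least(lane, N)
  if (denom == 0) return(NA_real_)
  cumulative_at_least(lane, N + 1L) / denom
}

#' Bypass probability at a position
#'
#' Probability of both inserting opposite position `N` and extending
#' past it: intensity of bands `>= N + 1` over bands `>= N - 1`. Equal
#' to `insertion_probability(N) * extension_probability(N)` wherever
#' all three are defined.
#'
#' @param lane A `tls_lane`.
#' @param N Position index in `1..K-1`.
#' @return Fraction in `[0,1]`, or `NA_real_` when undefined.
#' @export
bypass_probability <- function(lane, N) {
  K <- lane_K(lane)
  if (N < 1L || N > K - 1L) stop("N must lie in 1..", K - 1L, call. = FALSE)
  denom <- cumulative_at_least(lane, N - 1L)
  if (denom == 0) return(NA_real_)
  cumulative_at_least(lane, N + 1L) / denom
}

#' Bypass efficiency of a damaged template
#'
#' Ratio of the bypass probability on the damaged template to that on
#' the matched undamaged control, expressed in percent.
#'
#' @param damaged_bypass,undamaged_bypass Bypass probabilities
#'   (fractions).
#' @return Percent (`100 * damaged / undamaged`).
#' @examples
#' bypass_efficiency(0.122, 0.678)  # ~18.0
#' @export
bypass_efficiency <- function(damaged_bypass, undamaged_bypass) {
  if (is.na(undamaged_bypass) || undamaged_bypass <= 0)
    stop("undefined efficiency: undamaged bypass probability must be > 0",
         call. = FALSE)
  100 * damaged_bypass / undamaged_bypass
}

#' Percent of product extended beyond the primer
#'
#' `100 * (1 - I(N0)/total)`: the fraction of label that moved off the
#' unextended primer band, as reported under single-dNTP selectivity
#' lanes.
#'
#' @param lane A `tls_lane` with positive total intensity.
#' @return Percent in `[0, 100]`.
#' @export
percent_extension <- function(lane) {
  total <- cumulative_at_least(lane, 0L)
  if (total == 0) stop("zero-total lane", call. = FALSE)
  100 * (1 - unname(lane$intensities[1L]) / total)
}

#' Per-position statistics table for one lane
#'
#' Long-format table of termination, insertion, extension and bypass
#' probabilities at every position where each is defined, with a
#' defined flag and reason for undefined entries (zero denominator).
#'
#' @param lane A `tls_lane`.
#' @return `data.frame` with columns `lane_id`, `N`, `statistic`,
#'   `value`, `defined`, `reason`.
#' @export
position_stats <- function(lane) {
  K <- lane_K(lane)
  rows <- list()
  add <- function(N, statistic, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      lane_id = lane$lane_id, N = N, statistic = statistic,
      value = value, defined = !is.na(value),
      reason = if (is.na(value)) "zero denominator" else "",
      stringsAsFactors = FALSE)
  }
  for (N in 0:K) add(N, "termination", termination_probability(lane, N))
  for (N in 1:K) add(N, "insertion", insertion_probability(lane, N))
  for (N in 0:(K - 1L)) add(N, "extension", extension_probability(lane, N))
  for (N in 1:(K - 1L)) add(N, "bypass", bypass_probability(lane, N))
  do.call(rbind, rows)
}

#' Aggregate lanes into a bypass summary
#'
#' Computes insertion, extension and bypass probabilities at one
#' evaluation position (by default the lesion position) for each lane,
#' then their mean and standard deviation across lanes. Lanes where a
#' statistic is undefined are excluded from that statistic with a
#' message. With `method = "by_experiment"` the time-course lanes
#' within each replicate are averaged first and the mean/SD taken
#' across replicates; the default pools all lanes.
#'
#' @param lanes List of `tls_lane` sharing one enzyme and substrate.
#' @param eval_N Evaluation position (e.g. the lesion position).
#' @param method `"pooled"` (default) or `"by_experiment"`.
#' @return An object of class `tls_summary` with fields `enzyme`,
#'   `substrate_name`, `eval_N`, `n_lanes`, `n_excluded`,
#'   `insertion_mean`, `insertion_sd`, `extension_mean`, `extension_sd`,
#'   `bypass_mean`, `bypass_sd` (SDs are sample SDs; a single
#'   quantifiable lane yields SD 0 with a warning) and `efficiency_pct`,
#'   `efficiency_sd_pct` (NULL until paired with an undamaged summary).
#' @export
aggregate_lanes <- function(lanes, eval_N,
                            method = c("pooled", "by_experiment")) {
  method <- match.arg(method)
  if (length(lanes) < 1L) stop("at least one lane required", call. = FALSE)
  enz <- unique(vapply(lanes, `[[`, "", "enzyme"))
  sub <- unique(vapply(lanes, `[[`, "", "substrate_name"))
  if (length(enz) != 1L || length(sub) != 1L)
    stop("lanes must share one enzyme and one substrate", call. = FALSE)
  per <- data.frame(
    replicate = vapply(lanes, `[[`, 1L, "replicate"),
    insertion = vapply(lanes, insertion_probability, 1, N = eval_N),
    extension = vapply(lanes, extension_probability, 1, N = eval_N),
    bypass    = vapply(lanes, bypass_probability, 1, N = eval_N))
  ok <- stats::complete.cases(per)
  n_excluded <- sum(!ok)
  if (!any(ok)) stop("aggregation error: no quantifiable lanes", call. = FALSE)
  if (n_excluded > 0L)
    message(n_excluded, " lane(s) excluded (undefined statistics at N",
            eval_N, ")")
  per <- per[ok, , drop = FALSE]
  if (method == "by_experiment") {
    per <- stats::aggregate(per[c("insertion", "extension", "bypass")],
                            by = per["replicate"], FUN = mean)
  }
  mean_sd <- function(x) {
    if (length(x) == 1L) {
      warning("single quantifiable unit: SD reported as 0")
      c(mean(x), 0)
    } else c(mean(x), stats::sd(x))
  }
  ins <- mean_sd(per$insertion); ext <- mean_sd(per$extension)
  byp <- mean_sd(per$bypass)
  structure(list(enzyme = enz, substrate_name = sub, eval_N = eval_N,
                 n_lanes = sum(ok), n_excluded = n_excluded,
                 method = method,
                 insertion_mean = ins[1L], insertion_sd = ins[2L],
                 extension_mean = ext[1L], extension_sd = ext[2L],
                 bypass_mean = byp[1L], bypass_sd = byp[2L],
                 efficiency_pct = NULL, efficiency_sd_pct = NULL),
            class = "tls_summary")
}

#' @export
print.tls_summary <- function(x, ...) {
  cat(sprintf("<bypass summary> %s on %s at N%d (%d lanes)\n",
              x$enzyme, x$substrate_name, x$eval_N, x$n_lanes))
  cat(sprintf("  insertion %s  extension %s  bypass %s\n",
              pct_pm(x$insertion_mean, x$insertion_sd),
              pct_pm(x$extension_mean, x$extension_sd),
              pct_pm(x$bypass_mean, x$bypass_sd)))
  if (!is.null(x$efficiency_pct))
    cat(sprintf("  bypass efficiency %.1f%% +/- %.1f\n",
                x$efficiency_pct, x$efficiency_sd_pct))
  invisible(x)
}

pct_pm <- function(m, s) {
  sprintf("%.1f +/- %.1f", round_half_up(100 * m, 1), round_half_up(100 * s, 1))
}

#' Report-style rounding (half away from zero)
#'
#' Percent values in output tables are rounded half away from zero
#' (so 17.95 prints as 18.0), matching the convention of published
#' summary tables; all internal arithmetic stays on full-precision
#' fractions.
#'
#' @param x Numeric vector.
#' @param digits Decimal places; default 1.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Attach bypass efficiency to a damaged-substrate summary
#'
#' Pairs a damaged-substrate summary with its undamaged control (same
#' enzyme, substrate differing only in the lesion) and computes the
#' bypass efficiency as the ratio of the replicate-mean bypass
#' probabilities, in percent, with a first-order propagated SD:
#' `eff * sqrt((sd_d/mean_d)^2 + (sd_u/mean_u)^2)`.
#'
#' @param damaged,undamaged `tls_summary` objects for the same enzyme.
#' @return `damaged`, with `efficiency_pct` and `efficiency_sd_pct`
#'   filled in.
#' @export
efficiency_from_summaries <- function(damaged, undamaged) {
  stopifnot(inherits(damaged, "tls_summary"), inherits(undamaged, "tls_summary"))
  if (damaged$enzyme != undamaged$enzyme)
    stop("summaries must come from the same enzyme", call. = FALSE)
  if (undamaged$bypass_mean <= 0)
    stop("undefined efficiency: undamaged bypass mean is 0", call. = FALSE)
  eff <- bypass_efficiency(damaged$bypass_mean, undamaged$bypass_mean)
  rel_d <- if (damaged$bypass_mean > 0) damaged$bypass_sd / damaged$bypass_mean else 0
  rel_u <- undamaged$bypass_sd / undamaged$bypass_mean
  damaged$efficiency_pct <- eff
  damaged$efficiency_sd_pct <- eff * sqrt(rel_d^2 + rel_u^2)
  damaged$control_substrate <- undamaged$substrate_name
  damaged
}
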