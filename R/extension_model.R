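# Generative model of processive primer extension.
#
# A polymerase engagement starting from terminus Nj attempts insertions
# at N(j+1), N(j+2), ... ; each attempt at Ni succeeds (incorporation,
# enzyme stays engaged) with probability s_i and otherwise the enzyme
# dissociates, leaving the product at its current length. Termination
# is dissociation: a later engagement resumes from the current terminus
# with the same per-position probabilities (no memory). The number of
# engagements per molecule over an incubation of t minutes is
# Poisson(lambda * t).

DNTPS <- c("dATP", "dCTP", "dGTP", "dTTP")

#' Per-position extension profile of an enzyme on a substrate
#'
#' Holds the generative continuation probabilities: `e_correct[i]` is
#' the probability that an engaged enzyme attempting insertion at Ni
#' with the correct dNTP available incorporates and remains engaged;
#' `e_mis[i]` is used instead when the correct dNTP is absent from the
#' reaction (misinsertion); `displacement_factor` multiplies the
#' continuation probability at positions requiring strand displacement
#' of a downstream oligo.
#'
#' @param label Profile name (e.g. `"WT-like"`).
#' @param e_correct Numeric vector in `[0,1]`, length K of the target
#'   substrate.
#' @param e_mis Numeric vector in `[0,1]`, same length; default 0.01.
#' @param displacement_factor Scalar in `[0,1]`; default 1 (no penalty).
#' @return An object of class `tls_profile`.
#' @export
extension_profile <- function(label, e_correct,
                              e_mis = rep(0.01, length(e_correct)),
                              displacement_factor = 1) {
  e_correct <- as.numeric(e_correct)
  e_mis <- as.numeric(e_mis)
  if (length(e_mis) != length(e_correct))
    stop("e_mis must have the same length as e_correct", call. = FALSE)
  check_prob(e_correct, "e_correct")
  check_prob(e_mis, "e_mis")
  check_prob(displacement_factor, "displacement_factor")
  if (length(displacement_factor) != 1L)
    stop("displacement_factor must be a scalar", call. = FALSE)
  structure(list(label = as.character(label), e_correct = e_correct,
                 e_mis = e_mis, displacement_factor = displacement_factor),
            class = "tls_profile")
}

check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    stop(what, " must lie in [0,1]", call. = FALSE)
  invisible(x)
}

#' Reaction conditions for a simulated lane set
#'
#' @param dNTPs Subset of `c("dATP","dCTP","dGTP","dTTP")` present in
#'   the reaction; default all four.
#' @param times Incubation durations in minutes; default `c(2, 4, 6)`.
#' @param engagement_rate Expected polymerase engagements per molecule
#'   per minute (lambda); default 0.05, keeping lambda*t in 0.1-0.3 so
#'   most extended molecules saw a single processive encounter.
#' @param molecules Primer molecules per lane; default `1e5`.
#' @param noise_sigma_mult Log-normal sigma of multiplicative band
#'   noise; default 0.05.
#' @param background Additive mean background intensity per band;
#'   default 0.
#' @param replicates Lanes per time point (independent experiments);
#'   default 2.
#' @param seed PRNG seed (required: every simulated lane set is
#'   reproducible).
#' @param single_hit If `TRUE`, condition every molecule on exactly one
#'   engagement instead of drawing Poisson counts; the statistics then
#'   estimate the per-encounter probabilities without multi-hit bias.
#' @return An object of class `tls_conditions`.
#' @export
reaction_conditions <- function(dNTPs = DNTPS, times = c(2, 4, 6),
                                engagement_rate = 0.05, molecules = 1e5,
                                noise_sigma_mult = 0.05, background = 0,
                                replicates = 2, seed, single_hit = FALSE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!all(dNTPs %in% DNTPS)) stop("unknown dNTP", call. = FALSE)
  if (length(times) == 0L || any(times <= 0)) stop("times must be positive",
                                                   call. = FALSE)
  if (molecules < 1) stop("molecules must be >= 1", call. = FALSE)
  if (noise_sigma_mult < 0 || background < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  if (engagement_rate < 0) stop("engagement_rate must be >= 0", call. = FALSE)
  structure(list(dNTPs = unique(dNTPs), times = as.numeric(times),
                 engagement_rate = engagement_rate,
                 molecules = as.integer(molecules),
                 noise_sigma_mult = noise_sigma_mult, background = background,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 single_hit = isTRUE(single_hit)),
            class = "tls_conditions")
}

#' Effective continuation vector for an assay variant
#'
#' Composes profile and substrate into the per-position continuation
#' probabilities actually in force for a reaction: `e_correct[i]` when
#' the correct dNTP for Ni is present, `e_mis[i]` otherwise, and
#' multiplied by `displacement_factor` at positions at or beyond a
#' nick.
#'
#' @param profile A `tls_profile` of length K.
#' @param substrate A `tls_substrate` with `K` extendable positions.
#' @param dNTPs dNTPs present in the reaction.
#' @return Numeric vector `s` of length K.
#' @export
effective_continuation <- function(profile, substrate, dNTPs = DNTPS) {
  stopifnot(inherits(profile, "tls_profile"),
            inherits(substrate, "tls_substrate"))
  if (length(profile$e_correct) != substrate$K)
    stop("configuration error: profile length ", length(profile$e_correct),
         " does not match substrate K = ", substrate$K, call. = FALSE)
  pm <- position_map(substrate)
  have <- pm$correct_dNTP %in% dNTPs
  s <- ifelse(have, profile$e_correct, profile$e_mis)
  s[pm$at_nick] <- s[pm$at_nick] * profile$displacement_factor
  s
}

# Single-engagement transition matrix over termini 0..K: from terminus
# j the enzyme reaches terminus m (> j) by succeeding at j+1..m and
# failing at m+1 (or reaching K).
transition_matrix <- function(s) {
  K <- length(s)
  Tm <- matrix(0, K + 1L, K + 1L)
  Tm[K + 1L, K + 1L] <- 1
  for (j in 0:(K - 1L)) {
    Tm[j + 1L, j + 1L] <- 1 - s[j + 1L]
    cp <- 1
    for (m in (j + 1L):K) {
      cp <- cp * s[m]
      if (m < K) Tm[j + 1L, m + 1L] <- cp * (1 - s[m + 1L])
      else Tm[j + 1L, K + 1L] <- cp
    }
  }
  Tm
}

#' Analytic product-length distribution
#'
#' Exact distribution of product termini N0..NK after a Poisson number
#' of processive engagements (or after exactly `engagements`
#' engagements when that argument is given), computed by dynamic
#' programming over the single-engagement transition kernel with the
#' Poisson mixture truncated when the remaining tail mass drops below
#' `tol`.
#'
#' @param s Continuation vector in `[0,1]` (length K).
#' @param lambda_t Expected number of engagements (lambda * t, >= 0).
#' @param engagements Optional non-negative integer: condition on this
#'   exact number of engagements instead of mixing over Poisson counts.
#' @param tol Poisson tail-mass truncation tolerance.
#' @return Named probability vector over termini `"0".."K"`, summing to
#'   1 within `tol`.
#' @export
expected_length_distribution <- function(s, lambda_t = NULL,
                                         engagements = NULL, tol = 1e-12) {
  check_prob(s, "s")
  K <- length(s)
  Tm <- transition_matrix(s)
  v <- c(1, numeric(K))
  if (!is.null(engagements)) {
    stopifnot(engagements >= 0, engagements == round(engagements))
    m <- 0L
    while (m < engagements) {
      v <- as.numeric(v %*% Tm)
      m <- m + 1L
    }
    out <- v
  } else {
    if (is.null(lambda_t) || lambda_t < 0)
      stop("lambda_t must be a non-negative number", call. = FALSE)
    out <- stats::dpois(0, lambda_t) * v
    m <- 0L
    while (stats::ppois(m, lambda_t, lower.tail = FALSE) > tol) {
      m <- m + 1L
      v <- as.numeric(v %*% Tm)
      out <- out + stats::dpois(m, lambda_t) * v
    }
  }
  names(out) <- as.character(0:K)
  out
}

#' Simulate gel lanes for one enzyme on one substrate
#'
#' For each time point and replicate, draws a Poisson engagement count
#' per molecule (all molecules start at N0), advances molecules through
#' the single-engagement kernel that many times, tallies terminus
#' counts into band intensities at unit amplitude per molecule, and
#' applies densitometry noise: each band is multiplied by an
#' independent log-normal factor (`meanlog = 0`,
#' `sdlog = noise_sigma_mult`) and incremented by
#' `|Normal(background, background/3)|`, then clamped at zero.
#' Reproducible given `conditions$seed`.
#'
#' @param profile A `tls_profile`.
#' @param substrate A `tls_substrate`.
#' @param conditions A `tls_conditions`.
#' @param enzyme Enzyme name recorded on the lanes; defaults to the
#'   profile label.
#' @return List of `tls_lane` objects
#'   (`length(times) * replicates` of them).
#' @export
simulate_lanes <- function(profile, substrate, conditions,
                           enzyme = profile$label) {
  stopifnot(inherits(conditions, "tls_conditions"))
  s <- effective_continuation(profile, substrate, conditions$dNTPs)
  K <- length(s)
  Tm <- transition_matrix(s)
  n <- conditions$molecules
  set.seed(conditions$seed)
  lanes <- list()
  for (t in conditions$times) {
    for (r in seq_len(conditions$replicates)) {
      counts <- simulate_termini(Tm, n, conditions$engagement_rate * t,
                                 conditions$single_hit)
      intens <- as.numeric(counts)
      if (conditions$noise_sigma_mult > 0)
        intens <- intens * stats::rlnorm(K + 1L, 0, conditions$noise_sigma_mult)
      if (conditions$background > 0)
        intens <- intens + abs(stats::rnorm(K + 1L, conditions$background,
                                            conditions$background / 3))
      intens <- pmax(intens, 0)
      names(intens) <- as.character(0:K)
      lanes[[length(lanes) + 1L]] <- lane(
        lane_id = sprintf("%s_%s_t%g_r%d", enzyme, substrate$name, t, r),
        enzyme = enzyme, substrate_name = substrate$name,
        time_min = t, replicate = r, intensities = intens)
    }
  }
  lanes
}

# Propagate molecule counts through the engagement kernel.  Molecules
# are grouped by their Poisson engagement count; each group's terminus
# counts are advanced one multinomial step per engagement.
simulate_termini <- function(Tm, n, lambda_t, single_hit = FALSE) {
  K1 <- nrow(Tm)
  total <- numeric(K1)
  if (single_hit) {
    groups <- c(`1` = n)
  } else {
    M <- stats::rpois(n, lambda_t)
    groups <- table(M)
  }
  for (g in names(groups)) {
    m <- as.integer(g)
    u <- numeric(K1)
    u[1L] <- as.numeric(groups[[g]])
    step <- 0L
    while (step < m) {
      nxt <- numeric(K1)
      for (j in which(u > 0)) {
        nxt <- nxt + as.numeric(stats::rmultinom(1L, u[j], Tm[j, ]))
      }
      u <- nxt
      step <- step + 1L
    }
    total <- total + u
  }
  total
}

#' Noiseless lane from the analytic length distribution
#'
#' Convenience constructor used as an oracle: builds a `tls_lane` whose
#' band intensities are exactly the analytic terminus probabilities
#' (times an arbitrary total), so that the assay statistics computed
#' from it can be compared with the generative parameters in closed
#' form.
#'
#' @param substrate A `tls_substrate`.
#' @param s Continuation vector (length `substrate$K`).
#' @param lambda_t,engagements Passed to
#'   [expected_length_distribution()].
#' @param total Total lane intensity; default 1.
#' @param enzyme,time_min,replicate,lane_id Lane metadata.
#' @return A `tls_lane`.
#' @export
analytic_lane <- function(substrate, s, lambda_t = NULL, engagements = NULL,
                          total = 1, enzyme = "analytic", time_min = 1,
                          replicate = 1L,
                          lane_id = paste0("analytic_", substrate$name)) {
  p <- expected_length_distribution(s, lambda_t = lambda_t,
                                    engagements = engagements)
  lane(lane_id = lane_id, enzyme = enzyme, substrate_name = substrate$name,
       time_min = time_min, replicate = replicate, intensities = p * total)
}
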