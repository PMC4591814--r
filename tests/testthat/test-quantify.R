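test_that("cumulative_at_least sums bands at or beyond N and is monotone", {
  l <- make_lane(c(50, 25, 25))
  expect_equal(cumulative_at_least(l, 1), 50)
  expect_equal(cumulative_at_least(l, 0), 100)
  expect_error(cumulative_at_least(l, 3), "0\\.\\.2")

  set.seed(5)
  for (i in 1:20) {
    r <- random_lane()
    v <- vapply(0:8, function(N) cumulative_at_least(r, N), 1)
    expect_true(all(diff(v) <= 0))
  }
})

test_that("per-position probabilities match their definitions", {
  l <- make_lane(c(50, 25, 25))
  expect_equal(termination_probability(l, 0), 0.5)
  expect_equal(termination_probability(l, 2), 1.0)
  expect_equal(extension_probability(l, 1), 0.5)

  l2 <- make_lane(c(25, 25, 50))
  expect_equal(insertion_probability(l2, 1), 0.75)
  expect_equal(insertion_probability(l2, 2), 50 / 75)
  expect_equal(bypass_probability(l2, 1), 0.5)
  expect_equal(bypass_probability(l2, 1),
               insertion_probability(l2, 1) * extension_probability(l2, 1))

  full <- make_lane(c(0, 0, 100))
  expect_equal(bypass_probability(full, 1), 1.0)

  # zero denominators are NA, not errors
  dead <- make_lane(c(100, 0, 0))
  expect_true(is.na(extension_probability(dead, 1)))
  expect_true(is.na(insertion_probability(dead, 2)))
})

test_that("algebraic identities hold to 1e-12 on random lanes", {
  set.seed(9)
  for (i in 1:200) {
    l <- random_lane(K = sample(3:12, 1))
    K <- length(l$intensities) - 1L
    for (N in 1:(K - 1L)) {
      ins <- insertion_probability(l, N)
      ext <- extension_probability(l, N)
      trm <- termination_probability(l, N)
      byp <- bypass_probability(l, N)
      expect_equal(trm + ext, 1, tolerance = 1e-12)
      expect_equal(byp, ins * ext, tolerance = 1e-12)
      expect_equal(ext, insertion_probability(l, N + 1L), tolerance = 1e-12)
      expect_true(all(c(ins, ext, trm, byp) >= 0 & c(ins, ext, trm, byp) <= 1))
    }
  }
})

test_that("statistics are invariant to the densitometry scale", {
  set.seed(13)
  l <- random_lane(K = 6)
  for (c_ in c(1e-4, 3.7, 1e5)) {
    ls <- make_lane(l$intensities * c_)
    for (N in 1:5) {
      expect_equal(bypass_probability(ls, N), bypass_probability(l, N),
                   tolerance = 1e-12)
      expect_equal(termination_probability(ls, N),
                   termination_probability(l, N), tolerance = 1e-12)
    }
  }
})

test_that("single-hit analytic lanes return the generating probabilities", {
  set.seed(17)
  sub <- fixture_substrates[["14/Tg"]]
  for (i in 1:20) {
    s <- random_s(sub$K)
    al <- analytic_lane(sub, s, engagements = 1)
    for (N in seq_len(sub$K)) {
      if (cumulative_at_least(al, N - 1L) > 0)
        expect_equal(insertion_probability(al, N), s[N], tolerance = 1e-12)
    }
  }
})

test_that("multi-hit lanes inflate insertion probabilities", {
  sub <- fixture_substrates[["14/Tg"]]
  s <- effective_continuation(example_profiles()[["WT-like"]]$damaged, sub)
  single <- analytic_lane(sub, s, engagements = 1)
  # lambda*t = 1, conditioned on at least one engagement (molecules the
  # polymerase never touched say nothing about per-encounter probabilities)
  p1 <- expected_length_distribution(s, lambda_t = 1)
  p0 <- stats::dpois(0, 1)
  p_cond <- (p1 - p0 * c(1, numeric(sub$K))) / (1 - p0)
  multi <- lane("mh", "WT", sub$name, 1, 1L, intensities = p_cond)
  for (N in seq_len(sub$K)) {
    expect_gte(insertion_probability(multi, N),
               insertion_probability(single, N) - 1e-12)
  }
})

test_that("bypass efficiency reproduces the characterized ratios", {
  expect_equal(round_half_up(bypass_efficiency(0.122, 0.678), 1), 18.0)
  expect_equal(round_half_up(bypass_efficiency(0.024, 0.636), 1), 3.8)
  expect_equal(round_half_up(bypass_efficiency(0.045, 0.446), 1), 10.1)
  expect_equal(bypass_efficiency(0.3, 0.3), 100)
  expect_error(bypass_efficiency(0.1, 0), "undefined")
})

test_that("percent_extension measures label moved off the primer band", {
  expect_equal(percent_extension(make_lane(c(40, 60))), 60)
  expect_equal(percent_extension(make_lane(c(100, 0))), 0)
  expect_error(percent_extension(make_lane(c(0, 0))), "zero-total")

  # no permissible insertion: e_mis = 0 with only dTTP on 16/G
  sub <- fixture_substrates[["16/G"]]
  prof <- extension_profile("strict", rep(0.9, 14), e_mis = rep(0, 14))
  co <- reaction_conditions(dNTPs = "dTTP", times = 2, replicates = 1,
                            molecules = 1e4, noise_sigma_mult = 0,
                            seed = 3)
  l <- simulate_lanes(prof, sub, co)[[1]]
  expect_equal(percent_extension(l), 0)
})

test_that("position_stats flags undefined entries with a reason", {
  df <- position_stats(make_lane(c(80, 20, 0, 0)))
  expect_true(all(c("termination", "insertion", "extension", "bypass") %in%
                  df$statistic))
  und <- df[!df$defined, ]
  expect_true(nrow(und) > 0)
  expect_true(all(und$reason == "zero denominator"))
  expect_true(all(df$value[df$defined] >= 0 & df$value[df$defined] <= 1))
})

test_that("aggregate_lanes averages per-lane statistics", {
  mk <- function(byp, id) {
    # two-band construction with bypass(1) = byp: I = (0, 1-byp, byp)
    make_lane(c(0, 1 - byp, byp), id = id)
  }
  lanes <- list(mk(0.12, "a"), mk(0.13, "b"), mk(0.11, "c"))
  s <- aggregate_lanes(lanes, 1)
  expect_equal(s$bypass_mean, 0.12)
  expect_equal(s$bypass_sd, 0.01)
  expect_equal(s$n_lanes, 3L)

  w <- capture_warnings(s1 <- aggregate_lanes(list(mk(0.2, "a")), 1))
  expect_match(w, "single", all = TRUE)
  expect_equal(s1$bypass_sd, 0)

  # six noiseless single-hit lanes from one profile: SD 0, mean analytic
  sub <- fixture_substrates[["14/Tg"]]
  prof <- example_profiles()[["WT-like"]]$damaged
  p <- expected_length_distribution(effective_continuation(prof, sub),
                                    engagements = 1)
  lanes6 <- lapply(1:6, function(i)
    lane(paste0("n", i), "WT", sub$name, time_min = 2, replicate = i,
         intensities = p))
  s6 <- aggregate_lanes(lanes6, sub$lesion_N)
  expect_equal(s6$bypass_sd, 0)
  expect_equal(s6$insertion_mean, 0.296, tolerance = 1e-12)
  expect_equal(s6$extension_mean, 0.418, tolerance = 1e-12)

  expect_error(aggregate_lanes(list(), 1), "at least one")
})

test_that("efficiency_from_summaries pairs damaged with control", {
  mk_sum <- function(mean, sd, substrate) {
    structure(list(enzyme = "WT", substrate_name = substrate, eval_N = 3,
                   n_lanes = 6L, n_excluded = 0L, method = "pooled",
                   insertion_mean = 0.3, insertion_sd = 0.01,
                   extension_mean = 0.4, extension_sd = 0.01,
                   bypass_mean = mean, bypass_sd = sd,
                   efficiency_pct = NULL, efficiency_sd_pct = NULL),
              class = "tls_summary")
  }
  out <- efficiency_from_summaries(mk_sum(0.122, 0.002, "14/Tg"),
                                   mk_sum(0.678, 0.009, "14/T"))
  expect_equal(round_half_up(out$efficiency_pct, 1), 18.0)

  out15 <- efficiency_from_summaries(mk_sum(0.045, 0.002, "15/Tg"),
                                     mk_sum(0.446, 0.002, "15/T"))
  expect_equal(round_half_up(out15$efficiency_pct, 1), 10.1)

  # identical arms: 100% with closed-form propagated SD
  same <- efficiency_from_summaries(mk_sum(0.2, 0.02, "14/Tg"),
                                    mk_sum(0.2, 0.02, "14/T"))
  expect_equal(same$efficiency_pct, 100)
  expect_equal(same$efficiency_sd_pct, 100 * sqrt(2) * 0.1, tolerance = 1e-12)

  expect_error(efficiency_from_summaries(mk_sum(0.1, 0, "14/Tg"),
                                         mk_sum(0, 0, "14/T")),
               "undefined")
})
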