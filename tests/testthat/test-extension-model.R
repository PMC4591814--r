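wt_profile_14 <- function() example_profiles()[["WT-like"]]$damaged

test_that("effective_continuation composes dNTP availability, lesion and nick", {
  sub <- fixture_substrates[["14/Tg"]]
  prof <- extension_profile("p", rep(0.8, 16), e_mis = rep(0.02, 16))
  expect_equal(effective_continuation(prof, sub), rep(0.8, 16))

  # dTTP only on 16/G: first template base G needs dCTP, so misinsertion
  sub_g <- fixture_substrates[["16/G"]]
  prof_g <- extension_profile("p", rep(0.8, 14), e_mis = rep(0.02, 14))
  s <- effective_continuation(prof_g, sub_g, dNTPs = "dTTP")
  expect_equal(s[1], 0.02)

  # absorbing nick: displacement_factor 0 zeroes everything at/after nick
  nick <- fixture_substrates[["nicked-16/T"]]
  prof_n <- extension_profile("p", rep(0.9, 14), displacement_factor = 0)
  expect_equal(effective_continuation(prof_n, nick), rep(0, 14))

  expect_error(effective_continuation(prof, sub_g), "configuration error")
})

test_that("expected_length_distribution matches hand enumeration", {
  expect_equal(expected_length_distribution(c(0.5, 0.5), lambda_t = 0),
               c("0" = 1, "1" = 0, "2" = 0))
  expect_equal(expected_length_distribution(c(0.5, 0.5), engagements = 1),
               c("0" = 0.5, "1" = 0.25, "2" = 0.25))
  expect_equal(expected_length_distribution(c(0.5), engagements = 2),
               c("0" = 0.25, "1" = 0.75))
  expect_error(expected_length_distribution(c(1.2)), "\\[0,1\\]")
})

test_that("analytic distribution is a probability vector for random inputs", {
  set.seed(21)
  for (i in 1:50) {
    K <- sample(2:16, 1)
    s <- random_s(K)
    lt <- stats::runif(1, 0, 5)
    p <- expected_length_distribution(s, lambda_t = lt)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("more permissive lesion continuation shifts mass past the lesion", {
  sub <- fixture_substrates[["14/Tg"]]
  base <- rep(0.9, 16)
  low <- base; low[3] <- 0.2
  high <- base; high[3] <- 0.6
  p_low <- expected_length_distribution(low, lambda_t = 0.3)
  p_high <- expected_length_distribution(high, lambda_t = 0.3)
  past <- (sub$lesion_N + 1L):16 + 1L
  expect_gt(sum(p_high[past]), sum(p_low[past]))
})

test_that("saturating engagement drives everything to full length", {
  set.seed(2)
  s <- stats::runif(10, 0.5, 0.95)
  expect_gt(expected_length_distribution(s, lambda_t = 50)[["10"]], 0.999)
  # monotone approach for weaker continuation too
  s2 <- random_s(10)
  m5 <- expected_length_distribution(s2, lambda_t = 5)[["10"]]
  m50 <- expected_length_distribution(s2, lambda_t = 50)[["10"]]
  expect_gt(m50, m5)

  # all s = 1: every engaged molecule reaches NK
  p1 <- expected_length_distribution(rep(1, 5), engagements = 1)
  expect_equal(unname(p1[["5"]]), 1)
})

test_that("simulated termini agree with the analytic oracle (single hit)", {
  sub <- fixture_substrates[["14/Tg"]]
  prof <- wt_profile_14()
  co <- reaction_conditions(times = 2, replicates = 1, molecules = 1e5,
                            noise_sigma_mult = 0, background = 0,
                            seed = 101, single_hit = TRUE)
  l <- simulate_lanes(prof, sub, co)[[1]]
  p_hat <- l$intensities / sum(l$intensities)
  p <- expected_length_distribution(effective_continuation(prof, sub),
                                    engagements = 1)
  tol <- 3 * sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(p_hat - p) <= pmax(tol, 1e-6)))
})

test_that("empirical vs analytic total-variation distance stays below 0.01", {
  set.seed(33)
  for (nm in c("14/Tg", "15/T", "16/G")) {
    sub <- fixture_substrates[[nm]]
    s <- stats::runif(sub$K)
    prof <- extension_profile("u", s)
    co <- reaction_conditions(times = 4, replicates = 1, molecules = 1e5,
                              noise_sigma_mult = 0, background = 0,
                              seed = sample.int(1e6, 1))
    l <- simulate_lanes(prof, sub, co)[[1]]
    p_hat <- l$intensities / sum(l$intensities)
    p <- expected_length_distribution(s, lambda_t = co$engagement_rate * 4)
    expect_lt(0.5 * sum(abs(p_hat - p)), 0.01)
  }
})

test_that("simulation is reproducible bit-for-bit given the seed", {
  sub <- fixture_substrates[["14/Tg"]]
  prof <- wt_profile_14()
  co <- reaction_conditions(seed = 7, molecules = 1e4)
  l1 <- simulate_lanes(prof, sub, co)
  l2 <- simulate_lanes(prof, sub, co)
  expect_identical(l1, l2)
  expect_length(l1, length(co$times) * co$replicates)
  expect_equal(vapply(l1, `[[`, 1, "time_min"), rep(c(2, 4, 6), each = 2))
})
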