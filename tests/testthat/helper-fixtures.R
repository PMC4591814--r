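# Shared fixtures: lanes built in code, never stored on disk.

make_lane <- function(intens, id = "l1", enzyme = "WT", substrate = "test",
                      time = 2, rep = 1L) {
  names(intens) <- as.character(seq_along(intens) - 1L)
  lane(lane_id = id, enzyme = enzyme, substrate_name = substrate,
       time_min = time, replicate = rep, intensities = intens)
}

# Random positive lane over K+1 bands.
random_lane <- function(K = 8L, id = "r1") {
  make_lane(stats::runif(K + 1L, 0.01, 10), id = id)
}

# Random continuation vector avoiding the exact 0/1 corners.
random_s <- function(K) stats::runif(K, 0.05, 0.95)

fixture_substrates <- tls_substrates()
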