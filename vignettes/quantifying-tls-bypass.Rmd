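---
title: "Quantifying translesion synthesis from primer-extension gels"
author: "tlsbypass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying translesion synthesis from primer-extension gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlsbypass)
```

## The assay

A translesion synthesis (TLS) primer-extension assay measures how well a
DNA polymerase replicates across a damaged template base. A 5'-labeled
primer is annealed to a longer template; here, 14- to 16-mer primers on
a 30-mer template whose first variable base X is an undamaged T, a G, or
a (5S)-thymine glycol (Tg), an oxidized thymine that blocks most
replicative polymerases. The polymerase extends the primer
position-by-position; the reaction is stopped and products are resolved
on a denaturing gel, giving one band per product length. Band
intensities are read by phosphorimaging.

The package uses an *N-coordinate* throughout: N0 is the unextended
primer (n0 nucleotides), Ni the product extended by i nucleotides, and
NK full length, with K = template length − primer length. On the 14-mer
primer the lesion sits at N3; on the 15-mer at N2; on the 16-mer at N1
(the primer 3' end abuts X). `tls_substrates()` returns these eight
substrates, including a nicked variant in which a downstream 14-mer
anneals flush with the extended 16-mer primer so that synthesis beyond
the nick requires strand displacement.

## The statistics

All statistics are ratios of cumulative band intensities, so the
absolute densitometry scale cancels (`cum(N)` is the summed intensity of
bands at length index ≥ N):

* **termination(N)** = I(N) / cum(N) — of the molecules that reached N,
  the fraction that stopped there;
* **insertion(N)** = cum(N) / cum(N−1) — of the molecules that reached
  N−1, the fraction that incorporated a nucleotide opposite position N;
* **extension(N)** = cum(N+1) / cum(N) — of the molecules at N, the
  fraction extended further;
* **bypass(N)** = cum(N+1) / cum(N−1) — insertion *and* extension, so
  bypass = insertion × extension and termination + extension = 1
  identically;
* **bypass efficiency** = 100 × bypass(damaged) / bypass(undamaged),
  evaluated at the lesion position with the same N used on the matched
  undamaged control;
* **percent extension** = 100 × (1 − I(N0)/total), used for
  single-dNTP nucleotide-selectivity lanes.

A statistic whose denominator is zero is *undefined* and is carried as
a flagged missing value with a reason, never silently as 0.

The evaluation position for summary tables is the lesion position
(N3 for the 14-mer primer, N2 for the 15-mer), which is the only
reading under which "insertion" means incorporation opposite Tg.
Replicate aggregation defaults to pooling all lanes (two experiments ×
three time points = six lanes in the characterized design); an
alternative `by_experiment` switch averages the time-course lanes
within each experiment first. Dispersion is reported as the sample SD
across the pooled units and is labelled as such. Internally everything
is a fraction; percent formatting (one decimal, half away from zero,
`round_half_up()`) happens only in reports.

```{r worked}
# characterized wild-type values: damaged vs undamaged bypass probability
round_half_up(bypass_efficiency(0.122, 0.678), 1)
# a point mutation in the finger domain drops efficiency about 5-fold
fold_change(18.0, 3.8)$fold
```

## The generative model

The synthetic-data stage simulates the physical process the statistics
assume. A polymerase *engagement* starting from terminus Nj attempts
insertion at N(j+1), N(j+2), ...; each attempt at Ni succeeds with a
per-position continuation probability s_i, and the first failure is
dissociation, stranding the product at its current length. Termination
is dissociation: a later engagement resumes from the current terminus
with the same probabilities (no memory). Over an incubation of t
minutes each molecule receives M ~ Poisson(λt) engagements.

The continuation vector is composed by `effective_continuation()` from
an enzyme profile and a substrate: `e_correct[i]` when the correct dNTP
is present in the reaction, `e_mis[i]` when it is absent (single-dNTP
selectivity lanes), and a multiplicative `displacement_factor` at
positions at or beyond a nick (strand displacement).

`expected_length_distribution()` gives the exact terminus distribution
by dynamic programming over the single-engagement kernel, mixing over
Poisson counts until the tail mass falls below 1e−12 (below float
accumulation error; the returned vector sums to 1 within that
tolerance). It serves as the independent oracle for the Monte-Carlo
simulator: in the single-engagement conditional, insertion(Ni) equals
s_i exactly, which is what makes the assay statistics estimators of
per-encounter probabilities.

`simulate_lanes()` draws engagement counts per molecule, advances
terminus counts by multinomial steps, and converts counts to band
intensities at unit amplitude per molecule (absolute scale is
irrelevant to ratio statistics). Densitometry noise is multiplicative
log-normal per band (sdlog `noise_sigma_mult`, default 0.05) plus an
optional additive background `|Normal(background, background/3)|`,
clamped at zero. The noise model is a modelling choice of this
package — published descriptions of such assays give no densitometry
error model — and the defaults are deliberately mild.

Default conditions mirror the characterized bypass experiments:
incubations of 2, 4 and 6 min, two replicate experiments per time
point, all four dNTPs, 1e5 molecules per lane. The engagement rate λ
has no published counterpart (enzyme:DNA ratios do not translate
directly into engagements per molecule), so it is a free synthetic
parameter; the default 0.05 /min keeps λt in 0.1–0.3, the near
single-hit regime such assays are designed for. `single_hit = TRUE`
conditions every molecule on exactly one engagement, which is the
regime in which the statistics are exactly unbiased.

```{r profiles}
# profiles whose lesion-position continuation reproduces the
# characterized wild-type statistics in the single-hit limit
prof <- example_profiles()[["WT-like"]]
subs <- tls_substrates()
co <- reaction_conditions(seed = 42, single_hit = TRUE)
damaged   <- simulate_lanes(prof$damaged,   subs[["14/Tg"]], co)
undamaged <- simulate_lanes(prof$undamaged, subs[["14/T"]],  co)
eff <- efficiency_from_summaries(aggregate_lanes(damaged, 3),
                                 aggregate_lanes(undamaged, 3))
eff
```

## Parameter recovery and its limits

`estimate_profile()` inverts the statistics: the mean insertion
probability across lanes estimates s_i. Two caveats are intrinsic and
are surfaced rather than hidden:

* **Position N1 is confounded by the engagement rate.** The N0 band
  pools molecules the polymerase never engaged with molecules that
  engaged and failed, so insertion(N1) estimates 1 − exp(−λt·s_1), not
  s_1. N1 is therefore flagged `engagement-confounded` unless the lanes
  are single-hit-conditioned or λt is supplied, in which case the
  first-passage relation is inverted per lane. All later positions
  condition on molecules that demonstrably engaged and are unaffected.
* **Multi-hit bias is upward.** Re-engagement gives stalled molecules
  further chances, so measured insertion probabilities exceed the
  per-encounter s_i; at λt = 0.1 the analytic bias is at most ~0.012
  at the positions flanking the lesion and falls with λt. A warning is
  emitted when insertion probabilities trend upward with incubation
  time beyond 2 SD, the observable signature of this bias. No λt
  deconvolution is attempted.

Positions where the mean cumulative signal fraction cum(i−1)/total
drops below 1% are flagged `low signal` and carry no confidence
interval: essentially no molecules reach them, so the ratio is noise.

## Uncertainty for the efficiency ratio

`bootstrap_efficiency_ci()` resamples lanes with replacement within
the damaged and undamaged arms and recomputes the ratio of mean bypass
probabilities. With the handful of lanes a gel experiment yields
(six per arm), raw percentile endpoints are systematically too narrow:
the bootstrap spread of a mean carries divisor n rather than n−1 and
normal-range rather than t-range quantiles, which costs roughly ten
points of coverage at n = 6. The percentile levels are therefore
expanded for small samples (α′/2 = Φ(−√(n/(n−1)) · t₍n−1, α/2₎), with
n the smaller arm size), a standard correction that keeps the
percentile mechanics; simulation at the default conditions puts
empirical coverage of the nominal 95% interval at ~94–96%. Degenerate
resamples (no undamaged bypass signal) are redrawn and counted, and
more than 10% of them is an error. `expand = FALSE` restores the raw
percentile interval.

The propagated SD attached by `efficiency_from_summaries()`
(first-order delta method on the ratio of means) and the bootstrap
interval are two deliberately different uncertainty statements;
published "±" values for such efficiencies rarely state their
derivation, and neither is claimed to reproduce one.

## Numerical and design notes

* Sequences are stored 5'→3'; constructors accept the template in
  3'→5' orientation under an explicit flag because bottom strands are
  conventionally printed that way — this prevents silent
  reverse-complement bugs. Tg is an annotation on a T base and pairs
  as T during annealing validation.
* Band lengths in files are absolute nucleotides (gels are read in
  nt); conversion to N indices happens at load against the substrate
  registry, and bands outside [n0, n0+K] are rejected — products
  beyond full length (e.g. untemplated additions) are treated as data
  errors rather than silently folded in.
* Ratio-of-means (not mean-of-ratios) defines the efficiency, which
  reproduces the published worked ratios; with published *rounded*
  inputs one row (R957A, 15-mer) reconstructs to 3.3% against a
  printed 3.4%, an artifact of feeding one-decimal means back into the
  ratio, which the package documents rather than corrects.
* The simulator's count propagation is exact (multinomial transitions
  through the engagement kernel, molecules grouped by Poisson count),
  so agreement with the analytic oracle is limited only by sampling:
  the test suite checks total-variation distance < 0.01 at 1e5
  molecules and 3-sigma binomial bands per position.
* Problem sizes in the test suite were chosen to make the stochastic
  properties sharp at desk scale: 1e5 molecules per lane, 100
  simulated experiments for bootstrap coverage, 48 lanes for the
  recovery-error estimate (at six lanes, replicate noise at the
  weak-signal position past the lesion is comparable to the 0.012
  multi-hit bias and would test lane count, not the estimator).

## What the synthetic data does and does not show

The generator reproduces the statistical structure the analysis
assumes: processive position-wise extension, lesion-specific
continuation penalties, Poisson re-engagement across time points,
replicate lanes, multiplicative band noise. It does not emulate
image-level densitometry artifacts (band overlap, background gradients,
saturation), nucleotide-level kinetics (kpol/Kd), pH effects, or
untemplated terminal additions. Passing tests therefore validate the
arithmetic and the estimators under the stated model, not the
upstream image quantification of real gels.
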