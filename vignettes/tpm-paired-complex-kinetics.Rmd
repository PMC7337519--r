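---
title: "Models and methods: paired-complex kinetics from tethered particle motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: paired-complex kinetics from tethered particle motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmkin)
```

## The experiment this package models

In a tethered particle motion (TPM) assay a DNA molecule carrying a 12RSS
and a 23RSS anchors a polystyrene bead to a coverslip. The root-mean-squared
displacement (RMSD) of the bead reports the state of the tether: free DNA
gives a large excursion; when the RAG recombinase synapses the two
recombination signal sequences into a looped paired complex (PC) the
effective tether shortens and the RMSD drops; when RAG cleaves the DNA the
bead is released and the trace ends. Each bead therefore yields a time
series with three observable regimes — unlooped, looped, cleaved — from
which three per-sequence summary statistics are computed:

* **looping frequency** — distinct PCs observed divided by beads monitored
  (a tether can loop repeatedly, so the ratio lives in $[0, \infty)$);
* **dwell-time quartiles** — median and first/third quartiles of the pooled
  PC lifetimes, irrespective of how each loop ended;
* **cutting probability** — treating the fate of each fate-resolved PC as a
  Bernoulli trial with success probability $p_\mathrm{cut}$.

## The kinetic null model

Exit from the looped state is modelled as two competing Poisson processes:
unlooping at rate $k_\mathrm{unloop}$ and cleavage at rate $k_\mathrm{cut}$
(both per minute). Each on its own would give an exponential waiting time,

$$P(t \mid k) = k\, e^{-k t},$$

and because the two compete, the observable PC lifetime is exponential with
the total leaving rate

$$k_\mathrm{leave} = k_\mathrm{unloop} + k_\mathrm{cut},$$

while the fate of a loop is cleavage with probability
$k_\mathrm{cut} / (k_\mathrm{unloop} + k_\mathrm{cut})$, independent of the
loop's duration. The single-rate model is deliberately the *null*: the
point of the kinetics module is to fit it honestly and then quantify how
real (or realistically contaminated synthetic) dwell-time distributions
depart from it.

### Posterior for the leaving rate

Observed lifetimes $t_1,\dots,t_n$ enter an exponential likelihood whose
sufficient statistics are $(n, \sum_i t_i)$; the prior on
$k_\mathrm{leave}$ is inverse-Gamma with shape $a$ and scale $b$. The
defaults $a = 2$, $b = 1$ (on a per-minute rate scale) are weakly
informative around 1 min$^{-1}$, the right order of magnitude for PC exit;
they are this package's own choice, and `test-kinetics.R` includes a
sensitivity check showing the posterior mean moves by well under 5% between
materially different priors at realistic sample sizes.

The posterior is one-dimensional, so the sampler can afford to be exact and
fast: `fit_leave_rate()` runs independence Metropolis on
$\theta = \log k$, proposing from a normal centred at the posterior mode
(the positive root of a quadratic in $e^\theta$) with 1.5 times the Laplace
width. In $\theta$ the target's two tails decay as double exponentials, so
the Gaussian proposal dominates them and acceptance rates sit near 0.9;
draws are close to i.i.d. Four chains of 1000 warmup plus 1000 kept draws
are the default; split-chain $\widehat{R} < 1.01$ is enforced (a violation
warns and flags the fit rather than failing silently), and an effective
sample size from a truncated-autocorrelation estimator is reported.

Two further likelihood variants are available by argument, both off by
default:

* **right censoring** — a loop still formed when the observation window
  closes contributes $e^{-k t}$ only (`censored =`);
* **left truncation at the detection threshold** — the state caller cannot
  see loops shorter than `min_dwell`, so observable lifetimes are
  `min_dwell` plus an exponential tail. By memorylessness this is corrected
  exactly by offsetting every dwell by the threshold (`detection_min =`).
  The pipeline applies this correction by default using the state-calling
  `min_dwell`; without it the fitted rate is biased low by roughly 20% at
  the simulation rates used in the acceptance checks.

### Credible bands and the exponentiality check

`ecdf_credible_band()` evaluates, at each time on a grid, the central 95%
interval of the model CDF $1 - e^{-k t}$ over the posterior draws. Because
that CDF is monotone in $k$, the band is computed from the posterior
quantiles of $k$ directly — deterministic given the draws, and monotone in
$t$ by construction.

The published judgement that dwell times are *not* exponential is visual
(an ECDF escaping its credible band). As a formal, calibrated stand-in,
`gof_exponential()` uses a posterior-predictive check: the discrepancy is
the Kolmogorov–Smirnov sup-distance between the empirical CDF and the
exponential CDF at the posterior-median rate, and the p-value is the
fraction of same-size datasets simulated from posterior-drawn rates whose
discrepancy is at least the observed one. Since the observed data also
determined the fitted rate while the replicates did not, the check is
mildly conservative — the acceptance suite measures a type-I error at or
below the nominal 5% and power above 80% against the 50/50 hyperexponential
mixture of rates 0.2 and 5 min$^{-1}$ at $n = 300$.

### What is (not) identifiable

From mixed-fate dwell times alone only $k_\mathrm{leave}$ is identifiable;
the split into $k_\mathrm{unloop}$ and $k_\mathrm{cut}$ enters only through
the fate fractions. `derive_cut_rate()` therefore reports
$k_\mathrm{cut} = p_\mathrm{cut} \cdot k_\mathrm{leave}$ as a derived
quantity, multiplying independent posterior draws of the two factors so
the uncertainty propagates; no attempt is made to fit the two rates
separately.

## The cutting-probability posterior

With $n_\mathrm{loops}$ fate-resolved PCs of which $n_\mathrm{cuts}$ were
cleaved, the Bernoulli likelihood under a uniform Beta(1, 1) prior gives

$$P(p_\mathrm{cut} \mid n_\mathrm{loops}, n_\mathrm{cuts}) \propto
  p_\mathrm{cut}^{\,n_\mathrm{cuts}}
  (1 - p_\mathrm{cut})^{\,n_\mathrm{loops} - n_\mathrm{cuts}},$$

i.e. Beta($n_\mathrm{cuts}+1$, $n_\mathrm{loops}-n_\mathrm{cuts}+1$). The
reported $\mu$ is the mode $n_\mathrm{cuts}/n_\mathrm{loops}$ and $\sigma$
the analytic posterior standard deviation. The uniform prior is inferred
from the published worked example — 70 cleavages among 152 loops with the
most probable value quoted as roughly 0.46, which is exactly the mode under
a flat prior — and `cut_posterior()` also evaluates the density on a grid
of 10$^4$ points (trapezoid-normalised to integrate to one within
$10^{-6}$) so that the closed form is cross-checked numerically rather than
trusted. With zero loops the posterior is the prior and is flagged as such;
the MAP is then reported as undefined rather than a number.

**Which loops count as Bernoulli trials.** A loop still formed when the
window closes has no observed fate, so it cannot be a trial. The package
therefore counts *all* distinct observed loops (censored included) for the
looping frequency, but only fate-resolved loops as trials for
$p_\mathrm{cut}$. Because fate and duration are independent under the
competing-exponential model, restricting trials to resolved loops does not
bias the estimate.

## Looping frequency and its bootstrap

The point estimate is total loops over total beads. Uncertainty comes from
resampling *beads* (each with its loop count) with replacement,
recomputing loops-per-bead for each replicate, and reporting percentile
intervals; the published procedure uses $10^6$ replicates and that is the
default, while tests use $10^4$ for speed. The replicate stream is chunked
so memory stays flat, and a fixed seed makes the replicate set
bit-reproducible. For degenerate per-bead counts (every bead identical)
every replicate equals the constant and the interval has zero width —
asserted in the tests, since it is an easy invariant to break.

## Trajectory processing

* **RMSD.** From x/y positions, a long-window (default 80 s) running mean
  is subtracted per axis as drift correction, then the mean-squared
  displacement is Gaussian-filtered with an 8-s standard deviation — the
  filter scale used in the source experiments — and rooted. Edge frames use
  renormalised truncated windows, so output length equals input length and
  there is no edge attenuation.
* **State calling.** The unlooped/looped boundary defaults to the midpoint
  of the two expected RMSD levels and is fixed *a priori*, never fitted to
  the trace (mirroring threshold lines drawn before looking at data; no
  HMM-style threshold learning is attempted). Frames are classified by
  threshold, then excursions shorter than `min_dwell` (default 30 s, about
  four filter widths — a non-published, configurable choice) are merged
  into the flanking state, shortest first. With a symmetric kernel and
  midpoint threshold, a noiseless step crosses the boundary at the step
  itself, which is why zero-noise round trips in the tests are exact to a
  frame.
* **Cleavage.** A trace that terminates at least `cleavage_gap` (default:
  `min_dwell`) seconds before the nominal end of observation while the
  bead is looped is called cleaved; requiring the gap to persist keeps
  tracking glitches from being read as cuts. Termination while *unlooped*
  is flagged as an anomaly. In real data that signature is sticking or
  detachment; in simulation it is almost always a genuine cleavage whose
  preceding loop was too short to call. The pipeline keeps such a bead's
  pre-termination segments and assigns no fate to the loss, because
  discarding the whole bead would preferentially remove unlooping-fate
  trials (a cut after a short loop announces itself; an unloop after a
  short loop vanishes silently) and measurably biases the cut fraction
  upward.
* **Bead filtering.** A bead is accepted when its protein-free baseline
  RMSD sits nearer the unlooped than the looped level and the baseline
  shows no called looping; every rejection carries a reason
  (`missing_baseline`, `baseline_not_unlooped`, `baseline_looping`). The
  published selection criteria are supplementary-only; these are
  configurable surrogates.

## The synthetic-data generator

`simulate_state_path()` realises the three-state continuous-time Markov
chain exactly as the null model specifies: exponential holding times,
competing fates, cleavage absorbing, looping forbidden during the
protein-free baseline. `render_trajectory()` adds i.i.d. Gaussian
observation noise around two RMSD levels and terminates the trace a short
`release_duration` after a cut. Defaults mirror the source experiment
where it states them — a 10-min baseline, a 60-min observation window,
1-s frames, an 8-s filter — and otherwise are chosen once as realistic:
levels of 250 and 160 nm with 15 nm per-frame noise give a separation of
six noise standard deviations, comparable to what a 2.9-kb tether with a
1.2-kb loop resolves. The levels are *not* calibrated tether-length
values; the published calibration is supplementary and is not reproduced.

Deliberate departures from the null model are available on demand:
`deadend_fraction` makes a fraction of loop entries permanent ("dead-end"
complexes that heavy-tail the dwell distribution), and
`simulate_dwell_sample()` can mix in a second exponential component or
fixed dead-end lifetimes to emulate the empirically observed
non-exponentiality.

What the generator does **not** emulate: drift and low-frequency stages
wander, tracking dropouts, bead–bead interference, diffraction-limited
imaging, HMGB1/RAG concentration effects, or tether-length dependence
(the 1200-bp inter-RSS geometry is fixed). Passing tests therefore show
that the *inference machinery* is correct and calibrated under the stated
model, not that the model captures every artifact of real bead data.

Seeding is hierarchical: one master seed plus bead index and stream label
derive a 31-bit substream seed, so bead $i$ is bit-reproducible regardless
of how many beads are simulated, and the simulation, bootstrap, MCMC and
permutation stages draw from distinct named substreams of the pipeline's
global seed.

## Significance testing between conditions

`permutation_test()` compares a variant dataset against a reference for
any of the three metrics by permuting the pooled units (beads for the
looping frequency, fate-resolved dwells for the median lifetime, per-loop
cut indicators for the cut fraction), with the add-one two-sided p-value
$(1 + \#\{|\Delta_\mathrm{null}| \ge |\Delta_\mathrm{obs}|\})/(1 +
n_\mathrm{perm})$. The published testing procedure is described only at
the level of a 0.05 threshold; this permutation realisation is an explicit
surrogate in the same resampling spirit, validated in the tests against
exhaustive enumeration on tiny inputs and against Fisher's exact test on
the published count tables. P-values are reported per comparison without
multiplicity correction, matching the per-sequence reporting convention; a
Benjamini–Hochberg helper (`adjust_tests()`) is provided for users who
want it.

## Numerical and interface choices

* Rates and dwell times are in minutes, frame timestamps in seconds, with
  explicit converters (`min_to_s()`, `s_to_min()`); RMSD in nm.
* Quartiles interpolate linearly between order statistics (R type 7).
* Short-excursion merging resolves ties deterministically (shortest run
  first, flipped into its left neighbour's state, edge runs into the
  interior), so segmentation is reproducible.
* Degenerate inputs are contracts, not crashes: all rates zero gives a
  single unlooped path; zero loops gives a prior-only posterior with a
  warning; a metric that does not exist for a group (cut fraction with no
  loops) yields an explicitly undefined test result rather than a numeric
  p-value; non-convergent fits warn and carry a flag.
* The pipeline driver (`run_pipeline()`) validates its YAML configuration
  against a closed key set (unknown keys are errors), writes every stage
  table as CSV, and emits a JSON manifest with the config hash, seed,
  per-stage counts and an md5 digest per file; identical configurations
  reproduce byte-identical outputs. The package is driven from R —
  functions, configuration files and this vignette are the interface.

## Problem sizes used in the checks

The test suite exercises the full pipeline at 20 replicates of 50 beads
with hour-long windows for parameter recovery; goodness-of-fit calibration
and power at 100 replicates of 300 dwells each; and bootstrap coverage at
200 simulated experiments of 200 beads with $10^4$ replicates each. These
sizes were chosen so each check has enough resolution to detect the
failure it guards against (coverage to within a few percent, power beyond
80%) while the whole suite stays quick to run routinely.

## Known limitations

* The single-rate model is a null, not a mechanism; when it is rejected
  the package quantifies the departure but does not fit multi-state or
  nick-aware alternatives (those states are not observable in TPM data).
* Absolute RMSD levels are nominal, not calibrated against tether length.
* The bead filter and significance procedure are surrogates for
  supplementary-only protocols and are deliberately configurable.
* Looping frequency saturates near $1/p_\mathrm{cut}$ loops per bead in
  long windows because cleavage absorbs the tether; comparisons of
  looping propensity between conditions are cleanest with matched window
  lengths, as in the package's own condition-comparison checks.
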