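# tpmkin

Kinetic analysis of RAG–RSS paired-complex dynamics from tethered
particle motion (TPM) data, with a fully testable synthetic-data path.

## The problem

In the first steps of V(D)J recombination, the RAG recombinase binds a
12RSS and a 23RSS (recombination signal sequences) and synapses them into
a looped *paired complex* (PC), which it then either releases or cleaves.
TPM assays watch this happen one molecule at a time: a DNA tether anchors
a bead, and the bead's root-mean-squared displacement (RMSD) drops when
the tether loops and the trace ends when the DNA is cut. From such traces
one wants, per RSS sequence or buffer condition:

* the **looping frequency** — distinct PCs per bead monitored,
  with bead-resampling bootstrap confidence intervals;
* the **dwell-time quartiles** of the pooled PC lifetimes;
* the **cutting probability** `p_cut` — each resolved PC is a Bernoulli
  trial; under a uniform prior the posterior is
  Beta(n_cuts + 1, n_loops − n_cuts + 1), reported as the mode
  μ = n_cuts / n_loops with the analytic posterior sd σ;
* the **leaving rate** of the single-rate exponential null model
  P(t | k_leave) = k_leave · exp(−k_leave t), with
  k_leave = k_unloop + k_cut, fitted by MCMC under an inverse-Gamma
  prior — plus 95% credible ECDF bands and a calibrated
  posterior-predictive check that quantifies departure from
  exponentiality (real PC lifetime distributions are not exponential).

The package is aimed at single-molecule biophysicists who want the whole
chain — trajectory simulation, state calling, dwell extraction, summary
metrics, kinetic inference, condition comparison — as tested, seeded,
reproducible R functions rather than one-off scripts.

## What's in the box

| Stage | Functions |
|---|---|
| synthetic data | `sim_config()`, `simulate_state_path()`, `render_trajectory()`, `simulate_dwell_sample()`, `simulate_experiment()` |
| trajectory processing | `compute_rmsd()`, `state_call_config()`, `call_states()`, `extract_dwells()`, `filter_beads()`, `count_loops()` |
| metrics | `rss_dataset()`, `looping_frequency()`, `bootstrap_loop_frequency()`, `cut_posterior()`, `dwell_quartiles()` |
| kinetics | `empirical_cdf()`, `fit_leave_rate()`, `ecdf_credible_band()`, `gof_exponential()`, `compare_conditions()`, `derive_cut_rate()` |
| comparison | `permutation_test()`, `adjust_tests()` |
| interface | `pipeline_config()`, `run_pipeline()`, `validate_tables()`, `write_pipeline_config()` |

The simulator is first-class: it realises the three-state (unlooped /
looped / cleaved) continuous-time Markov model with a protein-free
baseline phase, Gaussian observation noise, optional "dead-end" complexes
and hyperexponential contamination, so every downstream stage is testable
against known ground truth. See the methods vignette
(`vignettes/tpm-paired-complex-kinetics.Rmd`) for the models, priors,
thresholds and their rationale.

## Worked example

The published worked example for the reference sequence — 152 paired
complexes observed, 70 of them cleaved:

```r
library(tpmkin)
post <- cut_posterior(152, 70)
print(post)
#> Cutting probability: MAP 0.4605, sd 0.0400  (n_loops = 152, n_cuts = 70)
```

The MAP is 70/152 ≈ 0.46: a PC on this sequence is roughly a coin flip
away from cleavage. The same object carries the grid-evaluated posterior
density (`post$grid`, `post$density`) for plotting.

An end-to-end synthetic run from the shipped demonstration configuration
(30 beads, magnesium-like rates k_loop = 0.3, k_unloop = 0.25,
k_cut = 0.2 per minute):

```r
cfg <- pipeline_config(system.file("extdata", "demo_config.yaml",
                                   package = "tpmkin"))
manifest <- run_pipeline(cfg, output_dir = "demo_out")
read.csv("demo_out/metrics.csv")[, c("n_beads", "n_loops", "n_cuts",
                                     "loop_freq", "ci_low", "ci_high",
                                     "median", "pcut_map", "pcut_sd")]
#>   n_beads n_loops n_cuts loop_freq   ci_low  ci_high median  pcut_map    pcut_sd
#> 1      30      51     26       1.7 1.333333 2.133333   2.45 0.5098039 0.06802927
read.csv("demo_out/fit_summary.csv")[, c("k_leave_mean", "k_leave_sd",
                                         "ci_low", "ci_high", "rhat")]
#>   k_leave_mean k_leave_sd    ci_low   ci_high     rhat
#> 1    0.4285474 0.05975587 0.3189527 0.5565849 1.001841
read.csv("demo_out/gof.csv")
#>        stat p_value  n low_power
#> 1 0.1276511   0.466 51     FALSE
```

Reading the output: 51 loops over 30 beads give a looping frequency of
1.7 with a bootstrap 95% CI of [1.33, 2.13]; the median PC lifetime is
2.45 min; 26 of 51 resolved loops were cut, so the cutting-probability
MAP is 0.51 ± 0.07, consistent with the generating 4/9 ≈ 0.44; the fitted
leaving rate 0.43 [0.32, 0.56] per min covers the true 0.45; and the
posterior-predictive p-value of 0.47 correctly finds no evidence against
exponentiality — the generator *is* the null model here. The manifest
(`demo_out/manifest.json`) records the seed, config hash, per-stage
counts and an md5 digest per file; re-running the same configuration
reproduces the files byte for byte.

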