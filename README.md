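# pdacmarkov

Markov decision analysis comparing **surgery-first (SF)** and
**neoadjuvant therapy (NAT)** pathways for potentially resectable
pancreatic cancer, as a tested, reusable R pipeline.

In the absence of large randomised head-to-head trials, the comparison
must be synthesised from single-arm phase II/III trials, adjuvant RCTs
and comparative cohorts. `pdacmarkov` provides every stage of that
synthesis for analysts who want to reproduce, stress-test or extend the
decision model:

* **Meta-analytic input synthesis** — pooled proportions via the
  Freeman–Tukey double-arcsine transform under a DerSimonian–Laird
  random-effects model, and pooled median survival via exponential
  hazard averaging, `m_p = (Σ w_i / m_i)⁻¹` (a sample-size-weighted
  harmonic mean of study medians).
* **Decision tree + Markov cohort engine** — a two-strategy chance tree
  over the treatment course actually received, feeding a three-state
  (alive disease-free / alive with disease / dead) monthly Markov model
  with a 60-cycle horizon under constant exponential hazards
  (`λ = ln 2 / median`). Payoffs in life-months (LM) and
  quality-adjusted life-months (QALMs), with utility weights per
  treatment phase and intention-to-treat rollup
  `E[payoff] = Σ_cohorts P(cohort) · payoff(cohort)`.
* **Deterministic sensitivity analysis** — one- and two-way sweeps over
  each variable's reported extremes, with indifference thresholds found
  by bisection on the QALM objective.
* **Probabilistic sensitivity analysis** — seeded 10000-iteration Monte
  Carlo over all transition probabilities, with three sampling
  interpretations (uniform-over-range, moment-matched beta, literal
  fitted distributions), distribution fitting by maximum likelihood for
  14 parametric families (generalized extreme value, generalized
  Pareto, Johnson SB, Burr XII, Pearson 5, log-Pearson 3, Cauchy,
  Pareto 2, plus six standard families) and Anderson–Darling model
  selection.
* **Synthetic literature pools** — generators with known ground truth
  so pooling, rollup and PSA are testable end to end with no downloads.

The baseline transition probabilities, utilities and cohort payoffs are
bundled as a plain-YAML transcription
(`inst/extdata/baseline.yaml`), and the included-trials table as
`inst/extdata/studies.csv`.

## Worked example

```r
library(pdacmarkov)
cfg <- load_config(system.file("extdata", "baseline.yaml",
                               package = "pdacmarkov"))

evaluate_model(cfg)$summary
#> Intention-to-treat expectations:
#>   SF    23.72 life-months   18.51 QALMs
#>   NAT   20.21 life-months   16.17 QALMs
#>   SF - NAT: +3.50 life-months, +2.35 QALMs

find_threshold(cfg, "nat.p_resect", 0.33, 0.86)
#> nat.p_resect: indifference at 0.5158 (SF superior below, NAT above; qalms)
find_threshold(cfg, "sf.p_resect", 0.70, 1.0)
#> sf.p_resect: indifference at 0.7490 (NAT superior below, SF above; qalms)

run_psa(cfg, n_iter = 10000, seed = 1)
#> PSA: 10000 iterations, mode 'range', seed 1
#>   sf_lm     mean  19.81  range  13.67- 28.81  sd  2.71
#>   sf_qalm   mean  15.22  range  10.61- 22.23  sd  2.11
#>   nat_lm    mean  18.27  range  10.86- 30.94  sd  4.58
#>   nat_qalm  mean  14.50  range   7.08- 26.52  sd  4.50
```

Reading: on an intention-to-treat basis surgery-first yields 23.72
expected life-months (18.51 QALMs) against 20.22 (16.26 as published;
16.17 recomputed) for neoadjuvant therapy — but NAT becomes the
superior pathway whenever its resection probability exceeds ~52%
(baseline 41%), or the SF resection probability falls below ~75%
(baseline 94%). Under uncertainty the strategies are closer (SF PSA
mean ≈ 19.8 months), and with a 3.65-month minimum significant
difference the model is indifferent in ~45% of iterations.

A thin command-line wrapper over the same functions is installed as
`exec/pdacmarkov` with subcommands `pool`, `evaluate`, `dsa`, `psa`,
`simulate`, `report` (see `?pdac_cli`).

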