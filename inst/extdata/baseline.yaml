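# Baseline model inputs: transition probabilities with uncertainty, QALM
# utilities, and per-cohort payoffs, as published for the surgery-first vs
# neoadjuvant-therapy comparison in potentially resectable pancreatic cancer.
# CI = 95% confidence interval of the pooled estimate; range = lowest and
# highest values reported across source studies; distribution = parametric
# family fitted to the input data (Anderson-Darling statistic in ad_stat).
nat:
  p_tox3:
    point: 0.35
    ci: [0.28, 0.43]
    range: [0.0, 1.0]
    sd: 0.03799
    distribution:
      family: gev
      params: {k: 0.45856, sigma: 0.01111, mu: 0.00904}
      ad_stat: 0.55904
  p_resect:
    point: 0.41
    ci: [0.33, 0.49]
    range: [0.0, 0.86]
    sd: 0.00848
    distribution:
      family: gev
      params: {k: 0.15727, sigma: 0.00545, mu: 0.00618}
      ad_stat: 0.36129
  p_explore:
    point: 0.10
    ci: [0.07, 0.13]
    range: [0.0, 0.36]
    sd: 0.00349
    distribution:
      family: gpd
      params: {k: 0.06879, sigma: 0.00306, mu: -5.1223e-4}
      ad_stat: 1.3525
  p_r0:
    point: 0.29
    ci: [0.21, 0.36]
    range: [0.0, 0.74]
    sd: 0.0068
    distribution:
      family: johnson_sb
      params: {gamma: 1.7195, delta: 1.0417, lambda: 0.04849, xi: -0.00113}
      ad_stat: 0.35896
  p_poc34:
    point: 0.35
    ci: [0.19, 0.53]
    range: [0.11, 0.64]
    sd: 0.02702
    distribution:
      family: gev
      params: {k: -0.45505, sigma: 0.03128, mu: 0.04101}
      ad_stat: 0.1996
  p_poc5:
    point: 0.02
    ci: [0.01, 0.03]
    range: [0.0, 0.36]
    sd: 0.00097
    distribution:
      family: pareto2
      params: {alpha: 0.34207, beta: 1.3899e-13}
      ad_stat: -13.983
sf:
  p_resect:
    point: 0.94
    ci: [0.90, 0.96]
    range: [0.70, 1.0]
    sd: 0.1219
    distribution:
      family: burr
      params: {k: 0.0595, alpha: 10.327, beta: 0.00112}
      ad_stat: 0.12818
  p_r0:
    point: 0.56
    ci: [0.51, 0.62]
    range: [0.16, 0.86]
    sd: 0.09869
    distribution:
      family: pearson5
      params: {alpha: 0.61636, beta: 7.0460e-4}
      ad_stat: 0.18259
  p_poc34:
    point: 0.22
    ci: [0.13, 0.33]
    range: [0.04, 0.54]
    sd: 0.01297
    distribution:
      family: log_pearson3
      params: {alpha: 66.845, beta: -0.09425, gamma: 2.0838}
      ad_stat: 0.29235
  p_poc5:
    point: 0.07
    ci: [0.02, 0.13]
    range: [0.0, 0.36]
    sd: 0.00948
    distribution:
      family: cauchy
      params: {sigma: 0.00373, mu: 0.00639}
      ad_stat: 0.38658
  p_adjuvant:
    point: 0.61
    ci: [0.57, 0.66]
    range: [0.26, 0.94]
    sd: 0.10088
    distribution:
      family: burr
      params: {k: 0.26048, alpha: 2.145, beta: 9.2071e-4}
      ad_stat: 0.18949
  p_adj_tox3:
    point: 0.43
    ci: [0.25, 0.62]
    range: [0.09, 0.98]
    sd: 0.02753
    distribution:
      family: log_pearson3
      params: {alpha: 1916.0, beta: -0.02672, gamma: 47.081}
      ad_stat: 0.34508
utilities:
  stable_disease: 0.81
  on_chemoradiotherapy: 0.81
  chemo_toxicity: 0.53
  surgical_recovery: 0.59
  surgical_complication: 0.48
  unresectable: 0.65
cohort_payoffs:
  nat_r0:
    label: "NAT, R0 resection"
    life_months: 35.05
    qalms: {baseline: 29.87, POC: 29.76}
  nat_r1:
    label: "NAT, R1 resection"
    life_months: 34.08
    qalms: {baseline: 29.87, POC: 29.76}
  nat_explore:
    label: "NAT, exploratory surgery only"
    life_months: 10.86
    qalms: {baseline: 7.22}
  nat_no_surgery:
    label: "NAT, no surgery"
    life_months: 10.86
    qalms: {baseline: 7.06}
  sf_r0_adj:
    label: "SF, R0 resection, adjuvant therapy received"
    life_months: 30.96
    qalms: {baseline: 24.86, POC: 24.75, AT: 21.82, POC_AT: 21.71}
  sf_r0_no_adj:
    label: "SF, R0 resection, no adjuvant therapy"
    life_months: 24.03
    qalms: {baseline: 20.12, POC: 20.01}
  sf_r1_adj:
    label: "SF, R1 resection, adjuvant therapy received"
    life_months: 25.85
    qalms: {baseline: 20.72, POC: 20.61, AT: 18.20, POC_AT: 18.09}
  sf_r1_no_adj:
    label: "SF, R1 resection, no adjuvant therapy"
    life_months: 21.26
    qalms: {baseline: 17.56, POC: 17.45}
  sf_explore:
    label: "SF, exploratory surgery only"
    life_months: 10.48
    qalms: {baseline: 6.97}
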