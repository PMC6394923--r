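# shared fixtures: the bundled baseline configuration and a scaled copy

baseline_config <- function() {
  load_config(system.file("extdata", "baseline.yaml", package = "pdacmarkov"))
}

# scale every cohort payoff (LM and all QALM variants) by a constant
scale_payoffs <- function(config, c) {
  config$cohort_payoffs <- lapply(config$cohort_payoffs, function(p)
    cohort_payoff(p$label, p$life_months * c, p$qalms * c))
  config
}

# summary row accessor
itt <- function(summary, strategy, what) summary[[what]][summary$strategy == strategy]
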