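# shared helpers for the suite

# lever sets used repeatedly
lv_default <- default_levers()

# a small, fast-converging system for engine-level tests
lv_small <- default_levers(arrival_rate = 5, treatment_capacity = 200,
                           claims_processing_capacity = 8)

scenario_path <- function(name) test_path("scenarios", name)

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / stats::sd(x)^3
}
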