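# Model builders shared across tests.

# N equal independent nodes tuned to a target system-wide spike probability.
equal_model <- function(n, s1, ps, eps) {
  spiking_bursting_model(independent_spike_table(rep(s1^(1 / n), n)), ps, eps)
}

# Random independent-spiking model with admissible dichotomous parameters.
random_model <- function(n) {
  p_vec <- runif(n, 0.1, 0.9)
  eps <- runif(1, 0.02, 0.5)
  ps <- runif(1, 0.2, 0.95) / (1 + eps)
  spiking_bursting_model(independent_spike_table(p_vec), ps, eps)
}
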