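# Small, fast study fixtures used across test files.

quiet_spec <- function(label = "a", amplitude = c(0.4, 0.6, 0.5, 1.2, 1.0, 2.2, 0.8, 3.0),
                       tau = 45, noise_sd = 0, drift = 0) {
  class_spec(label, amplitude = amplitude, tau = tau, noise_sd = noise_sd, drift = drift)
}

tiny_pair <- function(noise_sd = 3e-4) benchmark_specs(noise_sd = noise_sd)

tiny_config <- function(seed = 1, ...) {
  pipeline_config(n_events = 6, duration = 300,
                  ann = train_config(max_epochs = 1500), seed = seed, ...)
}
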