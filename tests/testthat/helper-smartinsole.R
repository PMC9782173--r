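# Shared fixtures: short noiseless bench recordings built in code.

# staircase trace scaled to 4 cycles/level (results identical to the full
# one-minute protocol for the noiseless model: steady state is reached well
# within one 1.5 s cycle)
short_staircase <- function(spec, duration_per_level = 6, sample_rate = 1000) {
  tr <- staircase_protocol(duration_per_level = duration_per_level,
                           sample_rate = sample_rate)
  ct <- simulate_capacitance_trace(tr, spec, noise_sd = 0)
  attr(ct, "protocol") <- attr(tr, "protocol")
  ct
}

# single loading/unloading step at full working pressure, 1 kHz
full_step <- function(spec, sample_rate = 1000) {
  p <- pressure_trace(c(rep(0, sample_rate), rep(spec$p_max, 2 * sample_rate),
                        rep(0, 2 * sample_rate)), sample_rate)
  simulate_capacitance_trace(p, spec, noise_sd = 0)
}
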