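# Small fixture builders shared across test files.

# beat series with constant RR (ms) over `duration_s`
constant_beats <- function(rr_ms = 800, duration_s = 300) {
  n <- floor(duration_s * 1000 / rr_ms)
  rr <- rep(rr_ms, n)
  beat_series(time_s = cumsum(rr) / 1000, rr_ms = rr)
}

# pure-tone tachogram spec at a given frequency/amplitude
tone_spec <- function(freq_hz, amp_ms = 30, duration_s = 135, seed = 1L,
                      noise_sd_ms = 0) {
  if (freq_hz < 0.15)
    rr_gen_spec(duration_s = duration_s, mean_rr_ms = 800,
                lf_amp_ms = amp_ms, lf_freq_hz = freq_hz,
                noise_sd_ms = noise_sd_ms, seed = seed)
  else
    rr_gen_spec(duration_s = duration_s, mean_rr_ms = 800,
                hf_amp_ms = amp_ms, hf_freq_hz = freq_hz,
                noise_sd_ms = noise_sd_ms, seed = seed)
}

tone_window <- function(freq_hz, amp_ms = 30, seed = 1L, fs_hz = 4,
                        noise_sd_ms = 0) {
  b <- generate_rr(tone_spec(freq_hz, amp_ms, seed = seed,
                             noise_sd_ms = noise_sd_ms))
  resample_window(b, 2, fs_hz = fs_hz)
}
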