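# Shared test helpers.

# Minimal hand-built multiplexed stream (bypasses the generator).
make_stream <- function(samples, slots, sample_rate = 500) {
  structure(list(sample_rate = sample_rate, samples = as.numeric(samples),
                 slot = slots, sample_valid = rep(TRUE, length(samples)),
                 components = NULL, truth = NULL, profile = NULL,
                 duration = length(samples) / sample_rate),
            class = "ppg_stream")
}

# Minimal hand-built channel bundle.
make_bundle <- function(red, infrared, reference, fs_channel = 125) {
  structure(list(fs_channel = fs_channel, red = as.numeric(red),
                 infrared = as.numeric(infrared),
                 reference = as.numeric(reference), t0 = 0,
                 sample_rate = fs_channel * 4, ambient_corrected = FALSE),
            class = "channel_bundle")
}

# Independent frequency-response oracle: direct DFT of an impulse response
# (no reuse of the package's polynomial-evaluation path).
dft_of_impulse <- function(h, fs, f) {
  n <- seq_along(h) - 1
  vapply(f, function(fi) sum(h * exp(-2i * pi * fi * n / fs)), complex(1))
}

# Slot-counting oracle: how many samples of a given label an N-sample
# stream contains, by enumerating the LED cycle.
count_slots <- function(n, label) {
  sum(rep(c("RED_ON", "BOTH_OFF", "IR_ON", "BOTH_OFF"),
          length.out = n) == label)
}
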