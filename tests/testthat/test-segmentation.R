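test_that("band energy envelope counts frames and rejects bad input", {
  # N = 44100, frame = 441, hop = 220 -> 199 frames
  p <- envelope_params(frame_s = 0.01, overlap_fraction = 1 - 220 / 441)
  env <- band_energy_envelope(audio_recording(rnorm(44100)), p)
  expect_length(env$values, 199L)
  expect_equal(diff(env$frame_times),
               rep(220 / 44100, 198), tolerance = 1e-12)
  expect_error(band_energy_envelope(audio_recording(rnorm(100))),
               "shorter than one")
  expect_error(band_energy_envelope(audio_recording(rnorm(44100), 1000)),
               "Nyquist")
})

test_that("envelope is zero for silence and band-selective for tones", {
  z <- band_energy_envelope(audio_recording(rep(0, 44100)))
  expect_true(all(z$values == 0))
  t <- (0:88199) / 44100
  in_band <- band_energy_envelope(audio_recording(sin(2 * pi * 500 * t)))
  # independent oracle: one Hamming frame, direct FFT bin sums
  stft_band_oracle <- function(x) {
    frame <- x[221:661] * (0.54 - 0.46 * cos(2 * pi * (0:440) / 440))
    spec <- abs(fft(c(frame, rep(0, 71))))^2 / 512
    freqs <- (0:256) * 44100 / 512
    sum(spec[1:257][freqs >= 80 & freqs <= 1000])
  }
  lo_tone <- sin(2 * pi * 30 * t)
  out_band <- band_energy_envelope(audio_recording(lo_tone))
  expect_equal(out_band$values[2], stft_band_oracle(lo_tone),
               tolerance = 1e-10)
  # a 10 ms Hamming frame has a ~400 Hz main lobe, so a 30 Hz tone still
  # leaks past the 80 Hz edge; the in-band tone dominates it only modestly
  expect_gt(mean(in_band$values) / mean(out_band$values), 2)
  # far above the band no leakage survives
  hi_band <- band_energy_envelope(audio_recording(sin(2 * pi * 5000 * t)))
  expect_gt(mean(in_band$values) / mean(hi_band$values), 100)
})

test_that("robust smoothing preserves structure and suppresses spikes", {
  const <- robust_smooth(rep(5, 200))
  expect_equal(const, rep(5, 200), tolerance = 1e-9)
  # single-sample spike of 100x baseline on a flat envelope
  y <- rep(1, 400)
  y[200] <- 100
  sm <- robust_smooth(y)
  expect_lt(max(sm), 10)
  # mass preservation on a noiseless sinusoidal envelope
  t <- seq(0, 10, by = 0.005)
  env <- 2 + sin(2 * pi * 0.4 * t)
  sm2 <- robust_smooth(env)
  expect_lt(abs(sum(sm2) - sum(env)) / sum(env), 0.05)
  # total variation does not increase
  tv <- function(v) sum(abs(diff(v)))
  noisy <- env + rnorm(length(env), sd = 0.2)
  expect_lte(tv(robust_smooth(noisy)), tv(noisy))
  expect_error(robust_smooth(c(1, 2)), "at least 3")
})

test_that("dtw_distance matches hand-checkable cases", {
  expect_equal(dtw_distance(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(dtw_distance(c(0, 0), c(1, 1)), dtw_enumerate(c(0, 0), c(1, 1)))
  expect_equal(dtw_distance(c(0, 0), c(1, 1)), 2)
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 2, 3)), 0)
  expect_error(dtw_distance(numeric(0), 1), "non-empty")
})

test_that("dtw_distance is symmetric on random sequences", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1))
    b <- rnorm(sample(2:8, 1))
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
  }
})

test_that("pattern normalization is scale invariant with stated edge cases", {
  expect_equal(normalize_pattern(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(normalize_pattern(c(2, 2, 2)), c(0, 0, 0))
  set.seed(8)
  for (i in 1:10) {
    p <- rnorm(20)
    expect_equal(normalize_pattern(3 * p), normalize_pattern(p))
  }
  expect_error(normalize_pattern(numeric(0)), "non-empty")
})

test_that("boundary detection recovers periodic envelope minima", {
  hop <- 0.005
  t <- seq(0, 15, by = hop)                 # 5 periods of 3 s
  env_vals <- (1 - cos(2 * pi * t / 3))^2 + 1e-3
  env <- structure(list(values = env_vals, frame_times = t, hop_s = hop),
                   class = "energy_envelope")
  b <- detect_boundaries(env)
  true_minima <- which(t %in% c(3, 6, 9, 12))
  expect_length(b, 4L)
  expect_true(all(abs(b - true_minima) <= 2))
})

test_that("constant envelopes yield no boundaries", {
  env <- structure(list(values = rep(1, 500),
                        frame_times = seq(0, by = 0.005, length.out = 500),
                        hop_s = 0.005),
                   class = "energy_envelope")
  expect_length(detect_boundaries(env), 0L)
})

test_that("amplitude normalization lets a loud period join the pattern", {
  hop <- 0.005
  t <- seq(0, 15, by = hop)
  env_vals <- (1 - cos(2 * pi * t / 3))^2 + 1e-3
  amp <- rep(1, length(t))
  amp[t >= 6 & t < 9] <- 10                 # one 10x-louder period
  env <- structure(list(values = env_vals * amp, frame_times = t,
                        hop_s = hop),
                   class = "energy_envelope")
  b <- detect_boundaries(env)
  true_minima <- which(t %in% c(3, 6, 9, 12))
  expect_true(all(vapply(true_minima,
                         function(m) any(abs(b - m) <= 3), logical(1))))
})

test_that("duration filter keeps the closed interval and partitions input", {
  sr <- 44100
  spans <- rbind(c(0, 1.0 * sr), c(1.0 * sr, 3.0 * sr), c(3.0 * sr, 9.0 * sr))
  out <- filter_by_duration(spans, sample_rate = sr)
  expect_equal(nrow(out$kept), 1L)
  expect_equal(unname(out$kept[1, 2] - out$kept[1, 1]), 2.0 * sr)
  expect_equal(out$excluded$reason,
               c("duration_too_short", "duration_too_long"))
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(spans))
  # boundary durations are kept (closed interval)
  edge <- filter_by_duration(rbind(c(0, 1.25 * sr), c(0, 5.5 * sr)),
                             sample_rate = sr)
  expect_equal(nrow(edge$kept), 2L)
  empty <- filter_by_duration(matrix(numeric(0), ncol = 2))
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$excluded), 0L)
})

test_that("segment_recording recovers known cycle boundaries", {
  rec <- generate_recording("normal", n_cycles = 5, snr_db = 15, seed = 314)
  seg <- segment_recording(rec$audio)
  expect_equal(nrow(seg$cycles), 5L)
  detected <- seg$cycles$start[-1] / 44100
  truth <- true_boundaries_s(rec)
  m <- match_boundaries(truth, detected, tol_s = 0.25)
  expect_equal(m$n_matched, length(truth))
  expect_true(all(seg$cycles$duration >= 1.25 & seg$cycles$duration <= 5.5))
})

test_that("silence produces an empty result with a diagnostic", {
  seg <- segment_recording(audio_recording(rep(0, 44100 * 3)))
  expect_equal(nrow(seg$cycles), 0L)
  expect_false(is.null(seg$diagnostic))
})

test_that("a short spurious segment is excluded with a duration reason", {
  rec <- generate_recording("normal", n_cycles = 4, snr_db = 20, seed = 47)
  # splice 0.8 s of breath-like sound between cycles 2 and 3
  blip_src <- generate_cycle(cycle_spec("normal", 1.6, seed = 99))$waveform
  blip <- blip_src[seq_len(round(0.4 * 44100))]
  blip <- c(blip, rev(blip)) * 1.2
  cut <- rec$boundaries[3, "start"]
  x <- append(rec$audio$samples, blip, after = cut)
  seg <- segment_recording(audio_recording(x),
                           config = boundary_config(min_separation_s = 0.5))
  expect_gte(nrow(seg$excluded), 1L)
  expect_true(any(seg$excluded$reason == "duration_too_short" &
                    abs(seg$excluded$duration - 0.8) < 0.3))
})

test_that("kept cycles and excluded spans partition the candidate spans", {
  rec <- generate_recording("rhonchi", n_cycles = 6, snr_db = 10, seed = 21)
  seg <- segment_recording(rec$audio)
  spans <- rbind(as.matrix(seg$cycles[, c("start", "end")]),
                 as.matrix(seg$excluded[, c("start", "end")]))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  expect_equal(unname(spans[1, 1]), 0)
  expect_equal(unname(spans[nrow(spans), 2]), length(rec$audio$samples))
  expect_true(all(spans[-1, 1] == spans[-nrow(spans), 2]))
})
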