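#' Specification of one synthetic respiratory cycle
#'
#' Describes the acoustic content of a single inhalation + exhalation cycle.
#' The four sound classes follow the standard clinical picture: normal breath
#' sounds are soft band-limited (100-600 Hz) noise, louder during
#' inspiration; rhonchi add a low-pitched (~150 Hz) amplitude-modulated tonal
#' component concentrated in expiration; fine crackles add many short
#' (~5 ms) high-frequency (400-800 Hz) damped-sinusoid transients clustered
#' in inspiration; coarse crackles add fewer, longer (~15 ms) low-frequency
#' (150-350 Hz) transients.
#'
#' @param sound_class one of `"normal"`, `"rhonchi"`, `"fine_crackle"`,
#'   `"coarse_crackle"`.
#' @param duration cycle duration in seconds; must lie within
#'   `duration_range`.
#' @param inspiration_fraction fraction of the cycle spent inhaling, in
#'   (0, 1). Default 0.4 (expiration is typically longer at rest).
#' @param event_density number of transient events per cycle (crackle
#'   classes); >= 0. Defaults: 20 for fine crackle, 8 for coarse crackle,
#'   0 otherwise.
#' @param snr_db per-cycle SNR bookkeeping slot; noise is added at the
#'   recording level, so this is informational here.
#' @param seed integer seed making the cycle reproducible.
#' @param duration_range admissible duration interval, default the
#'   physiological bounds `c(1.25, 5.5)` seconds.
#' @return an object of class `cycle_spec`.
#' @export
cycle_spec <- function(sound_class, duration,
                       inspiration_fraction = 0.4,
                       event_density = NULL,
                       snr_db = Inf, seed = NULL,
                       duration_range = c(1.25, 5.5)) {
  sound_class <- match.arg(sound_class, lung_sound_classes())
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration)
      || duration <= 0)
    stop("duration must be a positive finite scalar")
  if (duration < duration_range[1] || duration > duration_range[2])
    stop(sprintf("duration %.3f s outside admissible range [%.2f, %.2f] s",
                 duration, duration_range[1], duration_range[2]))
  if (inspiration_fraction <= 0 || inspiration_fraction >= 1)
    stop("inspiration_fraction must be in (0, 1)")
  if (is.null(event_density))
    event_density <- switch(sound_class,
                            fine_crackle = 20, coarse_crackle = 8, 0)
  if (event_density < 0) stop("event_density must be >= 0")
  structure(list(sound_class = sound_class, duration = duration,
                 inspiration_fraction = inspiration_fraction,
                 event_density = event_density, snr_db = snr_db,
                 seed = seed, duration_range = duration_range),
            class = "cycle_spec")
}

#' The four lung-sound classes
#'
#' Normal, rhonchi, fine crackle and coarse crackle; wheeze is deliberately
#' not modelled.
#' @return character vector of class names in canonical order.
#' @export
lung_sound_classes <- function() {
  c("normal", "rhonchi", "fine_crackle", "coarse_crackle")
}

# Breathing amplitude envelope over one cycle: a sin^2 hump per phase, the
# inspiratory hump louder. The two humps overlap slightly (airflow reverses
# without a silent gap mid-cycle) and the cycle ends in a short
# end-expiratory pause, so the deepest notches sit at the cycle edges --
# the structure the segmenter's band-energy envelope picks up.
breath_envelope <- function(n, inspiration_fraction,
                            expiration_gain = 0.55, floor = 0.04,
                            overlap = 0.06, pause = 0.06) {
  t <- seq(0, 1, length.out = n)
  fi <- inspiration_fraction
  env <- rep(floor, n)
  i_hi <- fi + overlap
  insp <- t < i_hi
  env[insp] <- env[insp] + sin(pi * t[insp] / i_hi)^2
  e_lo <- fi - overlap
  e_hi <- 1 - pause
  ex <- t >= e_lo & t < e_hi
  env[ex] <- env[ex] + expiration_gain *
    sin(pi * (t[ex] - e_lo) / (e_hi - e_lo))^2
  env
}

# Gaussian noise band-limited by frequency-domain masking with cosine tapers
# (exact band control; no filter transients). Synthesis runs at a highly
# composite FFT length and is truncated, keeping the transform fast for any
# requested duration.
bandlimited_noise <- function(n_out, sr, f_lo, f_hi, taper_hz = 20) {
  n <- stats::nextn(n_out, c(2L, 3L, 5L))
  x <- rnorm(n)
  X <- fft(x)
  f <- seq(0, sr, length.out = n + 1)[1:n]
  f <- pmin(f, sr - f)  # mirrored frequency of each bin
  w <- rep(0, n)
  inb <- f >= f_lo & f <= f_hi
  w[inb] <- 1
  lo_t <- f >= f_lo - taper_hz & f < f_lo
  w[lo_t] <- 0.5 * (1 + cos(pi * (f_lo - f[lo_t]) / taper_hz))
  hi_t <- f > f_hi & f <= f_hi + taper_hz
  w[hi_t] <- 0.5 * (1 + cos(pi * (f[hi_t] - f_hi) / taper_hz))
  y <- Re(fft(X * w, inverse = TRUE))[seq_len(n_out)] / n
  y / stats::sd(y)
}

# One damped-sinusoid transient of `dur_s` seconds at frequency `freq`.
crackle_kernel <- function(sr, freq, dur_s) {
  n <- max(8L, round(dur_s * sr))
  t <- (seq_len(n) - 1) / sr
  tau <- dur_s / 4  # decay constant: ~4 time constants inside the event
  w <- sin(2 * pi * freq * t) * exp(-t / tau)
  w / max(abs(w))
}

#' Generate one synthetic respiratory cycle
#'
#' Realizes a [cycle_spec()] as a waveform of exactly
#' `round(duration * sample_rate)` samples with peak amplitude <= 1, together
#' with the onsets of any transient events inserted.
#'
#' @param spec a [cycle_spec()].
#' @param sample_rate sampling rate in Hz (default 44100).
#' @return list with `waveform` (numeric vector) and `events` (data.frame
#'   with columns `onset` -- 0-based sample index -- and `kind`).
#' @export
generate_cycle <- function(spec, sample_rate = 44100) {
  if (!inherits(spec, "cycle_spec")) stop("spec must be a cycle_spec")
  with_seed(spec$seed, {
    sr <- sample_rate
    n <- round(spec$duration * sr)
    fi <- spec$inspiration_fraction
    env <- breath_envelope(n, fi)
    base <- bandlimited_noise(n, sr, 100, 600) * env * 0.35
    x <- base
    events <- data.frame(onset = integer(0), kind = character(0),
                         stringsAsFactors = FALSE)
    if (spec$sound_class == "rhonchi") {
      t <- (seq_len(n) - 1) / sr
      f0 <- runif(1, 130, 170)
      am <- 1 + 0.6 * sin(2 * pi * runif(1, 8, 16) * t + runif(1, 0, 2 * pi))
      # tonal snore concentrated in expiration
      exp_env <- env
      ni <- floor(n * fi)
      exp_env[seq_len(ni)] <- exp_env[seq_len(ni)] * 0.25
      x <- x + 0.45 * sin(2 * pi * f0 * t) * am * exp_env
    } else if (spec$sound_class %in% c("fine_crackle", "coarse_crackle")) {
      fine <- spec$sound_class == "fine_crackle"
      k <- round(spec$event_density)
      if (k > 0) {
        dur_s <- if (fine) 0.005 else 0.015
        ni <- floor(n * fi)
        # clustered in inspiration: onsets over the inspiratory phase with a
        # margin so events never straddle the cycle edge
        lead <- max(1L, round(0.05 * n))
        hi <- max(lead + 1L, ni - round(dur_s * sr))
        onsets <- sort(round(runif(k, lead, hi)))
        freqs <- if (fine) runif(k, 400, 800) else runif(k, 150, 350)
        for (i in seq_len(k)) {
          kern <- crackle_kernel(sr, freqs[i], dur_s) * 0.9
          idx <- onsets[i] + seq_along(kern)
          idx <- idx[idx <= n]
          x[idx] <- x[idx] + kern[seq_along(idx)]
        }
        events <- data.frame(onset = onsets,
                             kind = rep(spec$sound_class, k),
                             stringsAsFactors = FALSE)
      }
    }
    peak <- max(abs(x))
    if (peak > 1) x <- x * (0.99 / peak)
    list(waveform = x, events = events)
  })
}

#' Generate a labelled synthetic auscultation recording
#'
#' Concatenates `n_cycles` respiratory cycles of one sound class and adds
#' white Gaussian noise at the requested SNR. Ground-truth cycle boundaries
#' (0-based, half-open sample spans) are exactly the concatenation points.
#'
#' @param sound_class one of [lung_sound_classes()].
#' @param n_cycles number of cycles; the default admissible range is 3-7
#'   (override via `cycle_range`).
#' @param cycle_duration_sampler function of `n` returning `n` durations in
#'   seconds; default uniform on \[1.5, 4.5\] s.
#' @param snr_db recording-level signal-to-noise ratio in dB; `Inf` adds no
#'   noise.
#' @param seed integer seed; drives durations, cycle seeds and noise.
#' @param sample_rate sampling rate in Hz.
#' @param cycle_range admissible `n_cycles` interval, default `c(3, 7)`.
#' @param duration_range admissible cycle-duration interval in seconds.
#' @param clip_durations if `TRUE`, out-of-range sampled durations are
#'   clipped into `duration_range` instead of raising an error.
#' @param keep_components if `TRUE` the clean signal and the noise are stored
#'   alongside the mixture (used to verify realized SNR).
#' @return an object of class `synthetic_recording`: list with `audio`
#'   ([audio_recording()]), `boundaries` (n x 2 integer matrix of half-open
#'   spans), `label`, `events` (data.frame `onset`, `kind`), `snr_db`,
#'   `seed`, and optionally `clean`/`noise`.
#' @export
generate_recording <- function(sound_class, n_cycles = NULL,
                               cycle_duration_sampler = function(n)
                                 runif(n, 1.5, 4.5),
                               snr_db = Inf, seed = NULL,
                               sample_rate = 44100,
                               cycle_range = c(3L, 7L),
                               duration_range = c(1.25, 5.5),
                               clip_durations = FALSE,
                               keep_components = FALSE) {
  sound_class <- match.arg(sound_class, lung_sound_classes())
  with_seed(seed, {
    if (is.null(n_cycles))
      n_cycles <- sample(seq(cycle_range[1], cycle_range[2]), 1L)
    if (n_cycles < cycle_range[1] || n_cycles > cycle_range[2])
      stop(sprintf("n_cycles must lie in [%d, %d]",
                   cycle_range[1], cycle_range[2]))
    durations <- cycle_duration_sampler(n_cycles)
    out_of_range <- durations < duration_range[1] |
      durations > duration_range[2]
    if (any(out_of_range)) {
      if (clip_durations) {
        durations <- pmin(pmax(durations, duration_range[1]),
                          duration_range[2])
      } else {
        stop("sampled cycle duration outside [",
             duration_range[1], ", ", duration_range[2], "] s")
      }
    }
    child <- sample.int(.Machine$integer.max, n_cycles)
    pieces <- vector("list", n_cycles)
    events <- vector("list", n_cycles)
    offset <- 0L
    bounds <- matrix(0L, n_cycles, 2L,
                     dimnames = list(NULL, c("start", "end")))
    for (i in seq_len(n_cycles)) {
      sp <- cycle_spec(sound_class, durations[i], seed = child[i],
                       duration_range = duration_range)
      cyc <- generate_cycle(sp, sample_rate)
      pieces[[i]] <- cyc$waveform
      if (nrow(cyc$events) > 0) {
        cyc$events$onset <- cyc$events$onset + offset
        events[[i]] <- cyc$events
      }
      bounds[i, ] <- c(offset, offset + length(cyc$waveform))
      offset <- offset + length(cyc$waveform)
    }
    clean <- unlist(pieces, use.names = FALSE)
    if (is.finite(snr_db)) {
      p_sig <- mean(clean^2)
      noise <- rnorm(length(clean)) * sqrt(p_sig / 10^(snr_db / 10))
    } else {
      noise <- numeric(length(clean))
    }
    rec <- list(audio = audio_recording(clean + noise, sample_rate),
                boundaries = bounds, label = sound_class,
                events = do.call(rbind, c(events, list(
                  data.frame(onset = integer(0), kind = character(0),
                             stringsAsFactors = FALSE)))),
                snr_db = snr_db, seed = seed)
    if (keep_components) {
      rec$clean <- clean
      rec$noise <- noise
    }
    structure(rec, class = "synthetic_recording")
  })
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording: %s, %d cycles, %.2f s, SNR %s dB>\n",
    x$label, nrow(x$boundaries),
    length(x$audio$samples) / x$audio$sample_rate,
    format(x$snr_db)))
  invisible(x)
}

#' Generate a balanced labelled corpus of synthetic recordings
#'
#' @param n_per_class recordings per sound class (>= 1).
#' @param seed integer seed; fully determines the corpus.
#' @param classes which classes to include (default all four).
#' @param snr_db recording SNR in dB (default 15).
#' @param ... further arguments passed to [generate_recording()].
#' @return an object of class `lung_corpus`: list with `recordings` (list of
#'   [generate_recording()] results) and `labels` (character vector).
#' @export
generate_corpus <- function(n_per_class, seed = 1,
                            classes = lung_sound_classes(),
                            snr_db = 15, ...) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  classes <- match.arg(classes, lung_sound_classes(), several.ok = TRUE)
  labels <- rep(classes, each = n_per_class)
  seeds <- derive_seeds(seed, length(labels))
  recordings <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    recordings[[i]] <- generate_recording(labels[i], snr_db = snr_db,
                                          seed = seeds[i], ...)
  }
  structure(list(recordings = recordings, labels = labels, seed = seed,
                 snr_db = snr_db),
            class = "lung_corpus")
}

#' @export
print.lung_corpus <- function(x, ...) {
  cat(sprintf("<lung_corpus: %d recordings (%s), SNR %s dB, seed %s>\n",
              length(x$recordings),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", "),
              format(x$snr_db), format(x$seed)))
  invisible(x)
}

#' Write a synthetic recording to disk
#'
#' Writes the audio as WAV plus a JSON sidecar holding the label, the
#' ground-truth boundaries, the event onsets and the seed.
#'
#' @param rec a `synthetic_recording`.
#' @param dir output directory (created if missing).
#' @param name base file name (without extension).
#' @param bit_depth passed to [write_wav()].
#' @return paths of the files written, invisibly.
#' @export
write_recording <- function(rec, dir, name, bit_depth = "float32") {
  if (!inherits(rec, "synthetic_recording"))
    stop("rec must be a synthetic_recording")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wav <- file.path(dir, paste0(name, ".wav"))
  json <- file.path(dir, paste0(name, ".json"))
  write_wav(rec$audio, wav, bit_depth = bit_depth)
  meta <- list(label = rec$label,
               boundaries = unname(apply(rec$boundaries, 1, as.list)),
               events = rec$events,
               snr_db = rec$snr_db,
               seed = rec$seed,
               sample_rate = rec$audio$sample_rate)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(wav = wav, json = json))
}
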