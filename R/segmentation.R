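#' Parameters for the band-energy envelope
#'
#' The segmenter frames the audio into 10 ms Hamming-windowed frames,
#' computes a zero-padded FFT per frame and sums the power-spectrum bins
#' whose center frequency falls in the 80-1000 Hz band -- low enough to
#' reject motion artifacts and heart sounds, high enough to avoid
#' high-frequency noise while keeping adventitious-sound energy.
#'
#' @param frame_s frame length in seconds (default 0.010).
#' @param overlap_fraction fractional frame overlap in \[0, 1) (default 0.5).
#' @param nfft FFT length; must be >= the frame length in samples. Default
#'   512 (next power of two above a 441-sample frame at 44.1 kHz).
#' @param band two-element numeric, the energy band in Hz (default
#'   `c(80, 1000)`).
#' @param smoothing_strength multiplier on the default robust-smoothing
#'   penalty (see [robust_smooth()]).
#' @return an object of class `envelope_params`.
#' @export
envelope_params <- function(frame_s = 0.010, overlap_fraction = 0.5,
                            nfft = 512, band = c(80, 1000),
                            smoothing_strength = 1) {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  if (length(band) != 2L || band[1] >= band[2])
    stop("band must be (low, high) with low < high")
  if (frame_s <= 0) stop("frame_s must be positive")
  if (smoothing_strength <= 0) stop("smoothing_strength must be positive")
  structure(list(frame_s = frame_s, overlap_fraction = overlap_fraction,
                 nfft = nfft, band = band,
                 smoothing_strength = smoothing_strength),
            class = "envelope_params")
}

new_energy_envelope <- function(values, frame_times, hop_s) {
  structure(list(values = as.numeric(values),
                 frame_times = as.numeric(frame_times),
                 hop_s = hop_s),
            class = "energy_envelope")
}

#' @export
print.energy_envelope <- function(x, ...) {
  cat(sprintf("<energy_envelope: %d frames, hop %.4f s, span %.2f-%.2f s>\n",
              length(x$values), x$hop_s,
              x$frame_times[1], tail(x$frame_times, 1)))
  invisible(x)
}

#' Band-limited spectral energy envelope
#'
#' @param audio an [audio_recording()] (mono).
#' @param params an [envelope_params()].
#' @return an `energy_envelope`: per-frame band energy (`values`), frame
#'   center times in seconds (`frame_times`) and the hop (`hop_s`).
#' @export
band_energy_envelope <- function(audio, params = envelope_params()) {
  audio <- as_audio(audio)
  sr <- audio$sample_rate
  x <- audio$samples
  frame <- round(params$frame_s * sr)
  hop <- max(1L, round(frame * (1 - params$overlap_fraction)))
  nfft <- params$nfft
  if (length(x) < frame)
    stop("audio shorter than one analysis frame")
  if (nfft < frame) stop("nfft must be >= frame length in samples")
  if (params$band[2] > sr / 2)
    stop("band upper edge exceeds the Nyquist frequency")
  nframes <- (length(x) - frame) %/% hop + 1L
  starts <- (seq_len(nframes) - 1L) * hop  # 0-based
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(frame) - 1) / (frame - 1))
  idx <- outer(seq_len(frame), starts, "+")  # 1-based sample indices
  frames <- matrix(x[idx], nrow = frame) * win
  if (nfft > frame)
    frames <- rbind(frames, matrix(0, nfft - frame, nframes))
  spec <- mvfft(frames)
  nbins <- nfft %/% 2 + 1L
  p <- abs(spec[seq_len(nbins), , drop = FALSE])^2 / nfft
  freqs <- (seq_len(nbins) - 1) * sr / nfft
  inband <- freqs >= params$band[1] & freqs <= params$band[2]
  values <- colSums(p[inband, , drop = FALSE])
  frame_times <- (starts + (frame - 1) / 2) / sr
  new_energy_envelope(values, frame_times, hop / sr)
}

#' Robust Whittaker smoothing of an energy envelope
#'
#' Penalized least squares with a second-difference penalty, iteratively
#' reweighted with bisquare weights on the residuals so that isolated spikes
#' (friction artifacts, clicks) are down-weighted rather than smeared into
#' the respiratory pattern.
#'
#' @param env an `energy_envelope` (or bare numeric vector) with >= 3 frames.
#' @param strength multiplier on the penalty; the default penalty is chosen
#'   so that, at the envelope's hop, fluctuations faster than about 1.5 Hz
#'   are suppressed while respiratory humps (>= 1.25 s) pass through.
#' @param iterations reweighting iterations (default 3).
#' @return object of the same type as `env`, smoothed.
#' @export
robust_smooth <- function(env, strength = 1, iterations = 3) {
  vec_in <- !inherits(env, "energy_envelope")
  y <- if (vec_in) as.numeric(env) else env$values
  n <- length(y)
  if (n < 3L) stop("need at least 3 frames to smooth")
  hop <- if (vec_in) 0.005 else env$hop_s
  # second-order Whittaker penalty acting like a low-pass at ~1.5 Hz
  lambda <- strength * (2 * pi * 1.5 * hop)^-4
  D <- Matrix::bandSparse(n - 2L, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iterations)) {
    A <- Matrix::Diagonal(n, w) + P
    z <- as.numeric(Matrix::solve(A, w * y))
    r <- y - z
    s <- stats::mad(r, center = 0)
    if (s <= .Machine$double.eps) break
    u <- r / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    # keep the system well-posed even if most points were flagged
    w <- pmax(w, 1e-6)
  }
  if (vec_in) z else new_energy_envelope(z, env$frame_times, env$hop_s)
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW with symmetric steps (1,0), (0,1), (1,1)
#' and absolute-difference (1-D Euclidean) local cost. Amplitude
#' normalization is the caller's responsibility (see [normalize_pattern()]).
#'
#' @param a,b non-empty numeric sequences.
#' @return the non-negative total alignment cost; 0 iff a zero-cost
#'   alignment exists.
#' @export
dtw_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("sequences must be non-empty")
  .dtw_cost(a, b)
}

#' Min-max amplitude normalization of a pattern
#'
#' Scales a pattern to \[0, 1\] so DTW comparisons are insensitive to
#' breath-to-breath loudness variation: `normalize_pattern(c * p)` equals
#' `normalize_pattern(p)` for any `c > 0`. A constant pattern maps to all
#' zeros.
#'
#' @param p non-empty numeric vector.
#' @return numeric vector in \[0, 1\].
#' @export
normalize_pattern <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) stop("pattern must be non-empty")
  rng <- range(p)
  if (rng[2] - rng[1] <= 0) return(rep(0, length(p)))
  (p - rng[1]) / (rng[2] - rng[1])
}

#' Boundary-detection configuration
#'
#' @param prominence_frac minimum local-minimum prominence as a fraction of
#'   the envelope range (default 0.05).
#' @param min_separation_s minimum separation between candidate boundaries
#'   in seconds (default 1.25, the shortest plausible cycle).
#' @param theta DTW medoid-similarity threshold: a pattern is spurious when
#'   its distance to the medoid pattern exceeds `theta` times the median
#'   distance (default 3).
#' @param depth_frac candidate minima must lie within this fraction of the
#'   amplitude-scale envelope range above its minimum (default 0.15): cycle
#'   boundaries are near-silent pauses, so their envelope values cluster at
#'   the bottom of the range, while the shallower airflow-reversal dip
#'   inside a cycle stays higher.
#' @param pattern_points patterns are resampled to this many points before
#'   DTW comparison (default 50), making the cost scale-free in length.
#' @return an object of class `boundary_config`.
#' @export
boundary_config <- function(prominence_frac = 0.05, min_separation_s = 1.25,
                            theta = 3, depth_frac = 0.15,
                            pattern_points = 50) {
  structure(list(prominence_frac = prominence_frac,
                 min_separation_s = min_separation_s,
                 theta = theta, depth_frac = depth_frac,
                 pattern_points = pattern_points),
            class = "boundary_config")
}

# Local minima of `x` with at least `min_prom` prominence and `min_dist`
# index separation. Prominence of a minimum = min(rise to the left, rise to
# the right) before a deeper minimum is reached.
local_minima <- function(x, min_prom, min_dist) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(x))) > 0) + 1L
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- x[seq_len(i - 1L)]
    right <- x[seq(i + 1L, n)]
    deeper_l <- which(left < x[i])
    lmax <- if (length(deeper_l)) max(left[seq(max(deeper_l), i - 1L)]) else max(left)
    deeper_r <- which(right < x[i])
    rmax <- if (length(deeper_r)) max(right[seq_len(min(deeper_r))]) else max(right)
    min(lmax, rmax) - x[i]
  }, numeric(1))
  keep <- cand[prom >= min_prom]
  prom <- prom[prom >= min_prom]
  if (length(keep) == 0L) return(integer(0))
  # enforce separation, keeping the more prominent of two close minima
  ord <- order(prom, decreasing = TRUE)
  sel <- logical(length(keep))
  for (k in ord) {
    if (!any(sel & abs(keep - keep[k]) < min_dist)) sel[k] <- TRUE
  }
  sort(keep[sel])
}

resample_pattern <- function(p, n_out) {
  if (length(p) == 1L) return(rep(p, n_out))
  stats::approx(seq_along(p), p, n = n_out)$y
}

#' Detect candidate respiratory-cycle boundaries from a smoothed envelope
#'
#' Detection operates on the amplitude scale (square root of the smoothed
#' band energy, floored at zero), which keeps the depth contrast between the
#' near-silent inter-cycle pause and the shallower mid-cycle airflow
#' reversal. Candidate boundaries are prominent, deep local minima of this
#' envelope. The segments they delimit are min-max normalized and compared by DTW to
#' the medoid segment; a segment whose distance to the medoid exceeds
#' `theta` times the median distance is treated as spurious, and the
#' boundary between it and its closer neighbour is merged away. This encodes
#' the idea that genuine respiratory cycles form a repetitive pattern
#' family, while half-cycles or artifacts do not.
#'
#' @param env a smoothed `energy_envelope`.
#' @param config a [boundary_config()].
#' @return integer vector of boundary frame indices (1-based into
#'   `env$values`), possibly empty.
#' @export
detect_boundaries <- function(env, config = boundary_config()) {
  if (!inherits(env, "energy_envelope"))
    stop("env must be an energy_envelope")
  v <- sqrt(pmax(env$values, 0))  # amplitude scale
  rng <- diff(range(v))
  if (rng <= 0) return(integer(0))
  min_dist <- max(1L, round(config$min_separation_s / env$hop_s))
  mins <- local_minima(v, config$prominence_frac * rng, min_dist)
  mins <- mins[v[mins] <= min(v) + config$depth_frac * rng]
  if (length(mins) < 2L) return(integer(0))
  edges <- c(1L, mins, length(v))
  norm_pat <- function(i0, i1)
    normalize_pattern(resample_pattern(v[i0:i1], config$pattern_points))
  repeat {
    npat <- length(edges) - 1L
    if (npat <= 2L) break
    pats <- lapply(seq_len(npat), function(i)
      norm_pat(edges[i], edges[i + 1L]))
    dmat <- matrix(0, npat, npat)
    for (i in seq_len(npat - 1L)) {
      for (j in seq(i + 1L, npat)) {
        dmat[i, j] <- dmat[j, i] <- dtw_distance(pats[[i]], pats[[j]])
      }
    }
    medoid <- which.min(rowSums(dmat))
    d <- dmat[medoid, ]
    med <- stats::median(d[-medoid])
    if (med <= 0) break
    bad <- which(d > config$theta * med)
    if (length(bad) == 0L) break
    # a spurious segment (e.g. a half cycle split by a surviving shallow
    # minimum) is merged into a neighbour only when the merge genuinely
    # restores the repetitive pattern, i.e. moves the segment closer to the
    # medoid; otherwise the segment is just an atypical but real cycle
    merged_any <- FALSE
    for (worst in bad[order(d[bad], decreasing = TRUE)]) {
      cand_edges <- c(if (worst > 1L) worst,          # merge with left
                      if (worst < npat) worst + 1L)   # merge with right
      cand_edges <- setdiff(cand_edges, c(1L, length(edges)))
      if (length(cand_edges) == 0L) next
      dm <- vapply(cand_edges, function(e)
        dtw_distance(norm_pat(edges[e - 1L], edges[e + 1L]), pats[[medoid]]),
        numeric(1))
      if (min(dm) < d[worst]) {
        edges <- edges[-cand_edges[which.min(dm)]]
        merged_any <- TRUE
        break
      }
    }
    if (!merged_any) break
  }
  interior <- edges[-c(1L, length(edges))]
  as.integer(interior)
}

#' Filter candidate spans by physiological cycle duration
#'
#' Spans with duration inside the closed interval \[`min_s`, `max_s`\]
#' seconds are kept; the rest are excluded as outliers. Input order is
#' preserved and `kept` plus `excluded` partition the input.
#'
#' @param spans n x 2 matrix of half-open \[start, end) sample spans.
#' @param min_s,max_s duration bounds in seconds (defaults 1.25 and 5.5).
#' @param sample_rate sampling rate in Hz.
#' @return list with `kept` (m x 2 matrix) and `excluded` (data.frame with
#'   `start`, `end`, `duration`, `reason`).
#' @export
filter_by_duration <- function(spans, min_s = 1.25, max_s = 5.5,
                               sample_rate = 44100) {
  spans <- matrix(as.numeric(spans), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(spans) == 0L)
    return(list(kept = spans,
                excluded = data.frame(start = numeric(0), end = numeric(0),
                                      duration = numeric(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)))
  dur <- (spans[, 2] - spans[, 1]) / sample_rate
  ok <- dur >= min_s & dur <= max_s
  excluded <- data.frame(start = spans[!ok, 1], end = spans[!ok, 2],
                         duration = dur[!ok],
                         reason = ifelse(dur[!ok] < min_s,
                                         "duration_too_short",
                                         "duration_too_long"),
                         stringsAsFactors = FALSE)
  list(kept = spans[ok, , drop = FALSE], excluded = excluded)
}

# Refine boundary frames against the raw amplitude envelope: heavy
# smoothing biases valley positions toward the quieter expiratory side, and
# the true cycle junction sits at the onset of the next inspiration, i.e.
# the right edge of the near-silent pause. Within +/- window_s of each
# candidate the lightly smoothed (~50 ms) raw envelope minimum is located
# and the boundary is placed where the envelope starts rising again
# (first crossing of min + rise_frac * local range).
refine_minima <- function(raw_env, frames, window_s = 0.5, rise_frac = 0.2) {
  u <- sqrt(pmax(raw_env$values, 0))
  k <- max(3L, 2L * round(0.025 / raw_env$hop_s) + 1L)
  us <- stats::filter(u, rep(1 / k, k), sides = 2)
  us[is.na(us)] <- u[is.na(us)]
  w <- max(1L, round(window_s / raw_env$hop_s))
  refined <- vapply(frames, function(f) {
    lo <- max(1L, f - w); hi <- min(length(us), f + w)
    seg <- us[lo:hi]
    j <- which.min(seg)
    thr <- min(seg) +
      rise_frac * (stats::quantile(seg, 0.95, names = FALSE) - min(seg))
    while (j < length(seg) && seg[j + 1L] <= thr) j <- j + 1L
    lo + j - 1L
  }, numeric(1))
  sort(unique(as.integer(refined)))
}

#' Segment a lung-sound recording into respiratory cycles
#'
#' End-to-end automatic cycle detection: band-energy envelope, robust
#' smoothing, DTW-based boundary detection, mapping of boundary frames to
#' sample indices (frame-center convention) and duration filtering. When no
#' cycles are detected the result is empty with a diagnostic message rather
#' than an error.
#'
#' @param audio an [audio_recording()] (or numeric vector at 44.1 kHz).
#' @param params an [envelope_params()].
#' @param config a [boundary_config()].
#' @param min_duration_s,max_duration_s physiological cycle-duration bounds
#'   (closed interval), defaults 1.25 and 5.5 s.
#' @return an object of class `lung_segmentation`: list with `cycles`
#'   (data.frame `start`, `end`, `duration` -- 0-based half-open sample
#'   spans), `excluded` (data.frame with `reason`), `envelope` (smoothed),
#'   `raw_envelope`, `sample_rate` and `diagnostic`.
#' @export
segment_recording <- function(audio, params = envelope_params(),
                              config = boundary_config(),
                              min_duration_s = 1.25, max_duration_s = 5.5) {
  audio <- as_audio(audio)
  sr <- audio$sample_rate
  raw <- band_energy_envelope(audio, params)
  sm <- robust_smooth(raw, strength = params$smoothing_strength)
  diagnostic <- NULL
  if (diff(range(sm$values)) <= 0) {
    frames <- integer(0)
    diagnostic <- "flat envelope: no respiratory activity detected"
  } else {
    frames <- detect_boundaries(sm, config)
    if (length(frames) == 0L)
      diagnostic <- "no repetitive respiratory pattern found"
  }
  n <- length(audio$samples)
  if (length(frames) > 0L) {
    frames <- refine_minima(raw, frames, window_s = 0.5)
    cuts <- round(sm$frame_times[frames] * sr)
    edges <- c(0, cuts, n)
    spans <- cbind(start = edges[-length(edges)], end = edges[-1])
  } else if (is.null(diagnostic)) {
    spans <- matrix(numeric(0), ncol = 2L)
  } else {
    spans <- matrix(numeric(0), ncol = 2L)
  }
  flt <- filter_by_duration(spans, min_duration_s, max_duration_s, sr)
  cycles <- data.frame(start = flt$kept[, 1], end = flt$kept[, 2])
  cycles$duration <- (cycles$end - cycles$start) / sr
  structure(list(cycles = cycles, excluded = flt$excluded,
                 envelope = sm, raw_envelope = raw,
                 sample_rate = sr, diagnostic = diagnostic),
            class = "lung_segmentation")
}

#' @export
print.lung_segmentation <- function(x, ...) {
  cat(sprintf("<lung_segmentation: %d cycles kept, %d spans excluded>\n",
              nrow(x$cycles), nrow(x$excluded)))
  if (nrow(x$cycles) > 0) {
    cat(sprintf("  durations: %s s\n",
                paste(sprintf("%.2f", x$cycles$duration), collapse = ", ")))
  }
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' @export
plot.lung_segmentation <- function(x, ...) {
  env <- x$envelope
  graphics::plot(env$frame_times, env$values, type = "l",
                 xlab = "time (s)", ylab = "band energy (80-1000 Hz)", ...)
  graphics::lines(x$raw_envelope$frame_times, x$raw_envelope$values,
                  col = "grey70")
  graphics::lines(env$frame_times, env$values)
  if (nrow(x$cycles) > 0)
    graphics::abline(v = c(x$cycles$start, x$cycles$end) / x$sample_rate,
                     col = "firebrick", lty = 2)
  invisible(x)
}

#' Match detected boundaries against ground truth
#'
#' Greedy one-to-one matching of detected interior boundaries to true
#' interior boundaries within a tolerance; used to score the segmenter on
#' synthetic recordings.
#'
#' @param true_bounds,detected_bounds numeric vectors of boundary positions
#'   in seconds (interior boundaries, i.e. between consecutive cycles).
#' @param tol_s matching tolerance in seconds (default 0.25).
#' @return list with `n_true`, `n_detected`, `n_matched`, `recall`,
#'   `precision`.
#' @export
match_boundaries <- function(true_bounds, detected_bounds, tol_s = 0.25) {
  nt <- length(true_bounds); nd <- length(detected_bounds)
  used <- logical(nd)
  matched <- 0L
  for (tb in true_bounds) {
    if (nd == 0L) break
    err <- abs(detected_bounds - tb)
    err[used] <- Inf
    j <- which.min(err)
    if (is.finite(err[j]) && err[j] <= tol_s) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_true = nt, n_detected = nd, n_matched = matched,
       recall = if (nt > 0) matched / nt else NA_real_,
       precision = if (nd > 0) matched / nd else NA_real_)
}

#' Interior ground-truth boundaries of a synthetic recording, in seconds
#' @param rec a `synthetic_recording`.
#' @return numeric vector of cycle-junction times (excludes the recording's
#'   outer edges).
#' @export
true_boundaries_s <- function(rec) {
  b <- rec$boundaries
  if (nrow(b) < 2L) return(numeric(0))
  b[-1, 1] / rec$audio$sample_rate
}

#' Write a segmentation result as JSON (plus optional per-cycle WAVs)
#'
#' @param seg a `lung_segmentation`.
#' @param path output JSON path.
#' @param audio optionally, the segmented [audio_recording()]; when given,
#'   one WAV per kept cycle is written next to `path`.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path, audio = NULL) {
  out <- list(cycles = unname(apply(cbind(seg$cycles$start, seg$cycles$end),
                                    1, as.list)),
              excluded = seg$excluded,
              sample_rate = seg$sample_rate,
              diagnostic = seg$diagnostic)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  if (!is.null(audio)) {
    audio <- as_audio(audio)
    stem <- sub("\\.json$", "", path)
    for (i in seq_len(nrow(seg$cycles))) {
      idx <- seq(seg$cycles$start[i] + 1, seg$cycles$end[i])
      write_wav(audio_recording(audio$samples[idx], audio$sample_rate),
                sprintf("%s_cycle%02d.wav", stem, i))
    }
  }
  invisible(path)
}
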