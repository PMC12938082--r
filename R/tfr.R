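#' Time-frequency image container
#'
#' @param values numeric matrix, frequency-like axis (rows) by time
#'   (columns).
#' @param freq_axis Hz per row (or band/scale center frequencies); must be
#'   monotone.
#' @param time_axis seconds per column (frame centers).
#' @param kind one of `"spectrogram"`, `"mel"`, `"gammatone"`,
#'   `"scalogram"`.
#' @param log_scaled whether `values` are on a dB/log scale.
#' @return an object of class `tf_image`.
#' @export
tf_image <- function(values, freq_axis, time_axis,
                     kind = c("spectrogram", "mel", "gammatone", "scalogram"),
                     log_scaled = FALSE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("tf_image values must be finite")
  if (nrow(values) != length(freq_axis))
    stop("freq_axis length must match the number of rows")
  if (ncol(values) != length(time_axis))
    stop("time_axis length must match the number of columns")
  d <- diff(freq_axis)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0)))
    stop("freq_axis must be monotone")
  structure(list(values = values, freq_axis = as.numeric(freq_axis),
                 time_axis = as.numeric(time_axis), kind = kind,
                 log_scaled = log_scaled),
            class = "tf_image")
}

#' @export
print.tf_image <- function(x, ...) {
  cat(sprintf("<tf_image [%s]: %d x %d, %.1f-%.1f Hz, %.3f-%.3f s%s>\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$freq_axis), max(x$freq_axis),
              x$time_axis[1], tail(x$time_axis, 1),
              if (x$log_scaled) ", dB" else ""))
  invisible(x)
}

#' @export
plot.tf_image <- function(x, clip_range = NULL, ...) {
  v <- x$values
  if (!is.null(clip_range)) v <- pmin(pmax(v, clip_range[1]), clip_range[2])
  graphics::image(x$time_axis, seq_along(x$freq_axis), t(v),
                  xlab = "time (s)", ylab = "band index",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

# Frame a signal into overlapping windowed columns, zero-padded to nfft,
# and return the one-sided power spectrum (1/nfft scaling so that summing
# the implied two-sided spectrum reproduces windowed-frame energy).
stft_power <- function(x, sr, frame, hop, nfft, window) {
  if (length(x) < frame) stop("audio shorter than one analysis frame")
  if (nfft < frame) stop("nfft must be >= frame length")
  nframes <- (length(x) - frame) %/% hop + 1L
  starts <- (seq_len(nframes) - 1L) * hop
  idx <- outer(seq_len(frame), starts, "+")
  frames <- matrix(x[idx], nrow = frame) * window
  if (nfft > frame) frames <- rbind(frames, matrix(0, nfft - frame, nframes))
  spec <- mvfft(frames)
  nbins <- nfft %/% 2 + 1L
  p <- abs(spec[seq_len(nbins), , drop = FALSE])^2 / nfft
  # fold the negative frequencies into the one-sided spectrum
  if (nfft %% 2 == 0) {
    p[2:(nbins - 1L), ] <- 2 * p[2:(nbins - 1L), , drop = FALSE]
  } else {
    p[2:nbins, ] <- 2 * p[2:nbins, , drop = FALSE]
  }
  list(power = p,
       freqs = (seq_len(nbins) - 1) * sr / nfft,
       times = (starts + (frame - 1) / 2) / sr)
}

hamming_win <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
hann_periodic <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' STFT spectrogram
#'
#' Short-time Fourier spectrogram with a 128-sample Hamming frame, 50%
#' overlap and a 1024-point FFT (513 one-sided frequency rows), log-scaled
#' as `10*log10(P + eps)`.
#'
#' @param audio an [audio_recording()] or numeric vector at 44.1 kHz.
#' @param frame frame length in samples (default 128).
#' @param hop hop in samples (default 64, i.e. 50% overlap).
#' @param nfft FFT length (default 1024).
#' @param log_scale return dB values (default `TRUE`); set `FALSE` for raw
#'   one-sided power.
#' @return a [tf_image()] of kind `"spectrogram"`.
#' @export
spectrogram <- function(audio, frame = 128, hop = 64, nfft = 1024,
                        log_scale = TRUE) {
  audio <- as_audio(audio)
  s <- stft_power(audio$samples, audio$sample_rate, frame, hop, nfft,
                  hamming_win(frame))
  v <- if (log_scale) 10 * log10(s$power + .LOG_EPS) else s$power
  tf_image(v, s$freqs, s$times, kind = "spectrogram", log_scaled = log_scale)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular Mel filter bank
#'
#' @param n_mels number of bands (default 128).
#' @param f_lo,f_hi band-edge frequencies in Hz (defaults 62.5 and 15000).
#' @param nfft FFT length the bank applies to.
#' @param sr sampling rate in Hz.
#' @return `n_mels` x `nfft/2+1` weight matrix with an attribute
#'   `"center_freqs"` (Hz).
#' @export
mel_filterbank <- function(n_mels = 128, f_lo = 62.5, f_hi = 15000,
                           nfft = 4096, sr = 44100) {
  if (f_lo >= f_hi) stop("f_lo must be < f_hi")
  if (f_hi > sr / 2) stop("f_hi must not exceed the Nyquist frequency")
  edges <- mel_to_hz(seq(hz_to_mel(f_lo), hz_to_mel(f_hi),
                         length.out = n_mels + 2L))
  nbins <- nfft %/% 2 + 1L
  freqs <- (seq_len(nbins) - 1) * sr / nfft
  H <- matrix(0, n_mels, nbins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; cen <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (freqs - lo) / (cen - lo)
    down <- (hi - freqs) / (hi - cen)
    H[m, ] <- pmax(0, pmin(up, down))
  }
  attr(H, "center_freqs") <- edges[2:(n_mels + 1L)]
  H
}

#' Mel-spectrogram
#'
#' Power spectrum through a 128-band triangular Mel filter bank covering
#' 62.5 Hz - 15 kHz, computed from 2048-sample periodic-Hann frames with a
#' 24-sample hop and a 4096-point FFT.
#'
#' @inheritParams spectrogram
#' @param win window length in samples (default 2048).
#' @param hop hop in samples. The default 24 gives an extremely dense frame
#'   rate; it is configurable for callers who prefer a conventional hop.
#' @param n_mels,f_lo,f_hi Mel bank geometry.
#' @return a [tf_image()] of kind `"mel"` with the band center frequencies
#'   as `freq_axis`.
#' @export
mel_spectrogram <- function(audio, win = 2048, hop = 24, nfft = 4096,
                            n_mels = 128, f_lo = 62.5, f_hi = 15000,
                            log_scale = TRUE) {
  audio <- as_audio(audio)
  s <- stft_power(audio$samples, audio$sample_rate, win, hop, nfft,
                  hann_periodic(win))
  H <- mel_filterbank(n_mels, f_lo, f_hi, nfft, audio$sample_rate)
  m <- H %*% s$power
  v <- if (log_scale) 10 * log10(m + .LOG_EPS) else m
  tf_image(v, attr(H, "center_freqs"), s$times, kind = "mel",
           log_scaled = log_scale)
}

#' Gammatone filter-bank parameters
#'
#' @param n_channels number of gammatone channels (default 64).
#' @param f_min lowest center frequency in Hz (default 50).
#' @param f_max upper frequency limit in Hz; defaults to the Nyquist
#'   frequency at 44.1 kHz.
#' @param twin integration window in seconds (default 0.025).
#' @param thop integration hop in seconds (default 0.010).
#' @param erb_width ERB bandwidth scaling (default 1.0).
#' @return an object of class `gammatone_params`.
#' @export
gammatone_params <- function(n_channels = 64, f_min = 50, f_max = 22050,
                             twin = 0.025, thop = 0.010, erb_width = 1.0) {
  if (n_channels < 2) stop("n_channels must be >= 2")
  if (f_min >= f_max) stop("f_min must be < f_max")
  structure(list(n_channels = n_channels, f_min = f_min, f_max = f_max,
                 twin = twin, thop = thop, erb_width = erb_width),
            class = "gammatone_params")
}

#' ERB-spaced gammatone center frequencies
#'
#' Center frequencies uniform on the Glasberg-Moore ERB-rate scale
#' (`ERB(f) = 24.7 (4.37 f / 1000 + 1)`), stepping down from the upper
#' limit with the lowest channel exactly at `f_min`. Returned in ascending
#' order.
#'
#' @param params a [gammatone_params()] (or `n_channels` when given
#'   positionally with `f_min`/`f_max`).
#' @param f_min,f_max used when `params` is a channel count.
#' @return numeric vector of strictly increasing center frequencies in Hz.
#' @export
erb_center_freqs <- function(params = gammatone_params(), f_min = 50,
                             f_max = 22050) {
  if (is.numeric(params))
    params <- gammatone_params(n_channels = params, f_min = f_min,
                               f_max = f_max)
  # Glasberg-Moore: ERB(f) = 24.7 (4.37 f / 1000 + 1); uniform ERB-rate
  # spacing is uniform spacing in log(f + ear_q * min_bw)
  min_bw <- 24.7; ear_q <- 1000 / (4.37 * min_bw)
  n <- params$n_channels
  cf <- -(ear_q * min_bw) +
    exp(seq_len(n) * (-log(params$f_max + ear_q * min_bw) +
                        log(params$f_min + ear_q * min_bw)) / n) *
    (params$f_max + ear_q * min_bw)
  rev(cf)
}

# 4th-order gammatone filter as a cascade of four biquads (all-pole part
# shared, one zero each), following the classical ERB filter design used by
# auditory-model toolboxes. Returns an n_channels x 20 coefficient matrix
# for the compiled cascade, rows ordered by ascending center frequency.
gammatone_coefs <- function(cfs, sr, erb_width = 1.0) {
  T <- 1 / sr
  min_bw <- 24.7; ear_q <- 1000 / (4.37 * min_bw); order <- 1
  erb <- ((cfs / ear_q)^order + min_bw^order)^(1 / order)
  B <- 1.019 * 2 * pi * erb * erb_width
  arg <- 2 * cfs * pi * T
  vec <- exp(2i * arg)
  k0 <- exp(B * T)
  a1 <- -2 * cos(arg) / k0          # shared denominator: 1 + a1 z^-1 + a2 z^-2
  a2 <- exp(-2 * B * T)
  rt_pos <- sqrt(3 + 2^1.5); rt_neg <- sqrt(3 - 2^1.5)
  z1 <- -(2 * T * cos(arg) / k0 + rt_pos * T * sin(arg) / k0) / 2
  z2 <- -(2 * T * cos(arg) / k0 - rt_pos * T * sin(arg) / k0) / 2
  z3 <- -(2 * T * cos(arg) / k0 + rt_neg * T * sin(arg) / k0) / 2
  z4 <- -(2 * T * cos(arg) / k0 - rt_neg * T * sin(arg) / k0) / 2
  gain <- abs(
    (-2 * vec * T + 2 * exp(-(B * T) + 2i * arg) * T *
       (cos(arg) - rt_neg * sin(arg))) *
      (-2 * vec * T + 2 * exp(-(B * T) + 2i * arg) * T *
         (cos(arg) + rt_neg * sin(arg))) *
      (-2 * vec * T + 2 * exp(-(B * T) + 2i * arg) * T *
         (cos(arg) - rt_pos * sin(arg))) *
      (-2 * vec * T + 2 * exp(-(B * T) + 2i * arg) * T *
         (cos(arg) + rt_pos * sin(arg))) /
      (-2 / exp(2 * B * T) - 2 * vec + 2 * (1 + vec) / exp(B * T))^4)
  n <- length(cfs)
  coefs <- matrix(0, n, 20L)
  zeros <- list(z1, z2, z3, z4)
  for (s in 1:4) {
    b0 <- rep(T, n)
    b1 <- zeros[[s]]
    if (s == 1L) { b0 <- b0 / gain; b1 <- b1 / gain }
    coefs[, (s - 1L) * 5L + 1L] <- b0
    coefs[, (s - 1L) * 5L + 2L] <- b1
    coefs[, (s - 1L) * 5L + 3L] <- 0
    coefs[, (s - 1L) * 5L + 4L] <- a1
    coefs[, (s - 1L) * 5L + 5L] <- a2
  }
  coefs
}

#' Gammatonegram
#'
#' Filters the signal through a 64-channel time-domain gammatone (ERB)
#' filter bank, integrates per-channel magnitude over 25 ms windows with a
#' 10 ms hop, and converts to dB as `20*log10(m + eps)`.
#'
#' @param audio an [audio_recording()] or numeric vector at 44.1 kHz.
#' @param params a [gammatone_params()].
#' @param log_scale return dB values (default `TRUE`).
#' @param clip_range optional two-element dB range applied to the returned
#'   values; intended for display/export only (e.g. `c(-90, -30)`), not for
#'   model inputs.
#' @return a [tf_image()] of kind `"gammatone"` with the channel center
#'   frequencies (ascending) as `freq_axis`.
#' @export
gammatonegram <- function(audio, params = gammatone_params(),
                          log_scale = TRUE, clip_range = NULL) {
  audio <- as_audio(audio)
  sr <- audio$sample_rate
  if (params$f_max > sr / 2 + 1e-9)
    stop("f_max must not exceed the Nyquist frequency")
  cfs <- erb_center_freqs(params)
  coefs <- gammatone_coefs(cfs, sr, params$erb_width)
  win <- round(params$twin * sr)
  hop <- round(params$thop * sr)
  if (length(audio$samples) < win)
    stop("audio shorter than one integration window")
  m <- .gammatone_bank_rms(audio$samples, coefs, as.integer(win),
                           as.integer(hop))
  v <- if (log_scale) 20 * log10(m + .LOG_EPS) else m
  if (!is.null(clip_range)) v <- pmin(pmax(v, clip_range[1]), clip_range[2])
  nframes <- ncol(m)
  times <- ((seq_len(nframes) - 1L) * hop + (win - 1) / 2) / sr
  tf_image(v, cfs, times, kind = "gammatone", log_scaled = log_scale)
}

#' Bump-wavelet scalogram
#'
#' Continuous wavelet transform magnitude using the analytic bump wavelet
#' (frequency-domain support `[(mu - sigma)/s, (mu + sigma)/s]`), on a
#' logarithmic scale grid with `voices` scales per octave spanning
#' pseudo-frequencies `f_range`. Rows are ordered by ascending
#' pseudo-frequency.
#'
#' @param audio an [audio_recording()] or numeric vector.
#' @param voices scales per octave (default 10).
#' @param f_range pseudo-frequency span in Hz; default 20 Hz to Nyquist.
#' @param mu,sigma bump wavelet parameters (defaults 5 and 0.6).
#' @param log_scale return `20*log10(|W| + eps)` (default `FALSE`: raw
#'   magnitude).
#' @return a [tf_image()] of kind `"scalogram"`.
#' @export
scalogram <- function(audio, voices = 10, f_range = NULL, mu = 5,
                      sigma = 0.6, log_scale = FALSE) {
  audio <- as_audio(audio)
  x <- audio$samples
  sr <- audio$sample_rate
  n <- length(x)
  if (is.null(f_range)) f_range <- c(20, sr / 2)
  n_oct <- log2(f_range[2] / f_range[1])
  nsc <- max(2L, ceiling(n_oct * voices) + 1L)
  freqs <- f_range[2] / 2^(seq(0, n_oct, length.out = nsc))  # descending
  scales <- mu * sr / (2 * pi * freqs)                        # per sample
  X <- fft(x)
  omega <- 2 * pi * (seq_len(n) - 1) / n   # rad/sample, [0, 2pi)
  W <- matrix(0, nsc, n)
  for (k in seq_len(nsc)) {
    so <- scales[k] * omega
    arg <- (so - mu) / sigma
    psi <- numeric(n)
    supp <- abs(arg) < 1 & omega <= pi  # analytic: positive frequencies only
    psi[supp] <- exp(1 - 1 / (1 - arg[supp]^2))
    W[k, ] <- Mod(fft(X * psi, inverse = TRUE) / n)
  }
  ord <- order(freqs)  # ascending frequency
  v <- W[ord, , drop = FALSE]
  if (log_scale) v <- 20 * log10(v + .LOG_EPS)
  tf_image(v, freqs[ord], (seq_len(n) - 1) / sr, kind = "scalogram",
           log_scaled = log_scale)
}

# Average rows/columns in contiguous blocks so that no source cell is
# dropped when downscaling (anti-aliasing); the exact target size is then
# reached by bilinear interpolation.
block_average <- function(m, nr, nc) {
  if (nrow(m) >= 2L * nr) {
    f <- nrow(m) %/% nr
    g <- rep(seq_len(ceiling(nrow(m) / f)), each = f)[seq_len(nrow(m))]
    m <- rowsum(m, g) / as.vector(table(g))
  }
  if (ncol(m) >= 2L * nc) {
    f <- ncol(m) %/% nc
    g <- rep(seq_len(ceiling(ncol(m) / f)), each = f)[seq_len(ncol(m))]
    m <- t(rowsum(t(m), g) / as.vector(table(g)))
  }
  m
}

# Bilinear resampling of a matrix to nr x nc.
bilinear_resize <- function(m, nr, nc) {
  m <- block_average(m, nr, nc)
  sr_ <- nrow(m); sc <- ncol(m)
  ri <- if (sr_ == 1L) rep(1, nr) else seq(1, sr_, length.out = nr)
  ci <- if (sc == 1L) rep(1, nc) else seq(1, sc, length.out = nc)
  r0 <- pmin(floor(ri), sr_ - 1L); r0[sr_ == 1L] <- 1L
  c0 <- pmin(floor(ci), sc - 1L); c0[sc == 1L] <- 1L
  if (sr_ == 1L) { r0 <- rep(1L, nr); fr <- rep(0, nr) } else fr <- ri - r0
  if (sc == 1L) { c0 <- rep(1L, nc); fc <- rep(0, nc) } else fc <- ci - c0
  r1 <- pmin(r0 + 1L, sr_); c1 <- pmin(c0 + 1L, sc)
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
  cc <- m[r1, c0, drop = FALSE]; d <- m[r1, c1, drop = FALSE]
  wfr <- matrix(fr, nr, nc); wfc <- matrix(fc, nr, nc, byrow = TRUE)
  a * (1 - wfr) * (1 - wfc) + b * (1 - wfr) * wfc +
    cc * wfr * (1 - wfc) + d * wfr * wfc
}

#' Convert a time-frequency image to a fixed-size model input
#'
#' Min-max normalizes the grid to \[0, 1\], bilinearly resizes it to
#' `size` x `size`, and replicates it into three identical channels
#' (grayscale replication; deterministic and colormap-independent). A
#' constant grid maps to all zeros.
#'
#' @param img a [tf_image()] (or plain finite matrix).
#' @param size output spatial resolution (default 256).
#' @return a `size` x `size` x 3 numeric array with values in \[0, 1\].
#' @export
to_model_input <- function(img, size = 256) {
  m <- if (inherits(img, "tf_image")) img$values else as.matrix(img)
  if (!all(is.finite(m))) stop("model input requires finite values")
  rng <- range(m)
  m <- if (rng[2] - rng[1] <= 0) matrix(0, nrow(m), ncol(m))
  else (m - rng[1]) / (rng[2] - rng[1])
  r <- bilinear_resize(m, size, size)
  array(r, dim = c(size, size, 3L))
}

#' Compute one of the four representations by name
#'
#' @param audio an [audio_recording()] or numeric vector.
#' @param representation `"gammatonegram"` (default), `"spectrogram"`,
#'   `"mel"` or `"scalogram"`.
#' @param ... passed to the underlying representation function.
#' @return a [tf_image()].
#' @export
compute_representation <- function(audio,
                                   representation = c("gammatonegram",
                                                      "spectrogram", "mel",
                                                      "scalogram"), ...) {
  representation <- match.arg(representation)
  switch(representation,
         gammatonegram = gammatonegram(audio, ...),
         spectrogram = spectrogram(audio, ...),
         mel = mel_spectrogram(audio, ...),
         scalogram = scalogram(audio, ...))
}

#' Export a time-frequency image as PNG
#'
#' @param img a [tf_image()].
#' @param path output PNG path.
#' @param size spatial resolution of the export (default 256).
#' @param clip_range optional dB clipping applied before normalization
#'   (e.g. `c(-90, -30)` for gammatonegram display).
#' @return `path`, invisibly.
#' @export
write_tf_png <- function(img, path, size = 256, clip_range = NULL) {
  v <- img$values
  if (!is.null(clip_range)) v <- pmin(pmax(v, clip_range[1]), clip_range[2])
  a <- to_model_input(tf_image(v, img$freq_axis, img$time_axis,
                               kind = img$kind, log_scaled = img$log_scaled),
                      size = size)
  # flip so low frequencies sit at the bottom of the raster
  png::writePNG(a[rev(seq_len(size)), , 1L], path)
  invisible(path)
}
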