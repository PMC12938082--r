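# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Exhaustive DTW: enumerate every monotone alignment path with steps
# (1,0), (0,1), (1,1) and return the minimum total |a_i - b_j| cost.
dtw_enumerate <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, cost) {
    cost <- cost + abs(a[i] - b[j])
    if (cost >= best) return(invisible())
    if (i == n && j == m) {
      best <<- cost
      return(invisible())
    }
    if (i < n) walk(i + 1L, j, cost)
    if (j < m) walk(i, j + 1L, cost)
    if (i < n && j < m) walk(i + 1L, j + 1L, cost)
  }
  walk(1L, 1L, 0)
  best
}

# Count detectable short transients in a waveform by thresholding its
# rectified, lightly smoothed envelope: an event = a maximal run above
# 4x the median absolute level, at least min_gap samples after the last.
count_transients <- function(x, sr, min_gap_s = 0.002) {
  env <- abs(x)
  k <- max(3L, round(0.002 * sr))
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  thr <- 4 * stats::median(env)
  above <- env > thr
  starts <- which(above & !c(FALSE, above[-length(above)]))
  if (length(starts) <= 1L) return(length(starts))
  keep <- c(TRUE, diff(starts) > min_gap_s * sr)
  sum(keep)
}

# Fraction of signal power below split_hz versus in [split_hz, hi_hz],
# computed straight from the periodogram (zero-padded to a composite FFT
# length for speed; padding does not move spectral mass between bands).
bandpower_ratio <- function(x, sr, split_hz = 300, hi_hz = 1000) {
  x <- c(x, rep(0, stats::nextn(length(x)) - length(x)))
  p <- abs(fft(x))^2
  f <- seq(0, sr, length.out = length(x) + 1)[seq_along(x)]
  f <- pmin(f, sr - f)
  low <- sum(p[f < split_hz & f >= 20])
  mid <- sum(p[f >= split_hz & f <= hi_hz])
  low / (low + mid)
}

# Brute-force one-vs-rest metrics from a confusion matrix, loop form.
metrics_bruteforce <- function(cm) {
  K <- nrow(cm)
  total <- sum(cm)
  correct <- 0
  for (i in seq_len(K)) correct <- correct + cm[i, i]
  out <- data.frame(precision = numeric(K), recall = numeric(K),
                    f1 = numeric(K))
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fp <- 0; fn <- 0
    for (i in seq_len(K)) {
      if (i != k) {
        fp <- fp + cm[i, k]
        fn <- fn + cm[k, i]
      }
    }
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    out$precision[k] <- p
    out$recall[k] <- r
    out$f1[k] <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  list(accuracy = correct / total, classwise = out)
}

# Brute-force region/channel-group means for the 9 x 64 sequence reshaping.
sequence_bruteforce <- function(fmap) {
  d <- dim(fmap)
  groups <- function(n, k) {
    sizes <- rep(n %/% k, k)
    if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    Map(seq, starts, ends)
  }
  rg <- groups(d[1], 3L); cg <- groups(d[2], 3L); ch <- groups(d[3], 64L)
  out <- matrix(0, 9L, 64L)
  step <- 1L
  for (i in 1:3) {
    for (j in 1:3) {
      for (c_ in 1:64) {
        acc <- 0; cnt <- 0
        for (r in rg[[i]]) for (cc in cg[[j]]) for (ci in ch[[c_]]) {
          acc <- acc + fmap[r, cc, ci]
          cnt <- cnt + 1
        }
        out[step, c_] <- acc / cnt
      }
      step <- step + 1L
    }
  }
  out
}
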