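#' Backbone specification
#'
#' Describes a convolutional feature extractor: its name, how many of its
#' top layers are trainable (0 = fully frozen) and the shape of the feature
#' map at its final convolutional block.
#'
#' @param name backbone identifier.
#' @param trainable_top_layers number of top layers allowed to train
#'   (default 0, i.e. frozen feature extraction).
#' @param feature_map_shape integer vector `(H, W, C)` of the final
#'   convolutional feature map.
#' @return an object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = "tiny", trainable_top_layers = 0,
                          feature_map_shape = c(8L, 8L, 64L)) {
  if (trainable_top_layers < 0) stop("trainable_top_layers must be >= 0")
  if (any(feature_map_shape[1:2] < 1)) stop("feature map H, W must be >= 1")
  structure(list(name = name,
                 trainable_top_layers = as.integer(trainable_top_layers),
                 feature_map_shape = as.integer(feature_map_shape)),
            class = "backbone_spec")
}

#' Bundled convolutional backbone
#'
#' A small fixed-weight convolutional feature extractor shipped with the
#' package so the whole pipeline runs without downloading pretrained
#' weights. The stem takes the channel mean of the 256 x 256 x 3 input and
#' stacks two views: the image itself and a per-row (frequency-band)
#' standardized copy -- a frozen normalization layer that exposes temporal
#' structure independently of each band's static level. One convolutional
#' layer of sixteen analytically defined 3 x 3 kernels (temporal
#' onset/offset, temporal and spectral center-surround transient detectors,
#' a Laplacian and a smoothing kernel, applied to each view) is followed by
#' ReLU and parallel max- and mean-pooling over 4 (frequency) x 32 (time)
#' blocks, giving a 64 x 8 x 32 feature map: 64 frequency rows, 8 time
#' regions, 16 max-pooled + 16 mean-pooled channels. Max pooling preserves
#' millisecond transients (crackles) that averaging would dilute; mean
#' pooling keeps band levels (rhonchi, breath envelope). The extractor is
#' deterministic and never trained. Pretrained ImageNet backbones can be
#' plugged in behind the same [backbone_spec()] contract but are not
#' bundled.
#'
#' @return an object of class `lung_backbone` with elements `spec`,
#'   `weights` (the fixed kernel tensor) and the pooling geometry.
#' @export
tiny_backbone <- function() {
  k_onset <- matrix(rep(c(-1, 0, 1), each = 3), 3) / 3      # d/dt
  k_trans <- matrix(rep(c(-1, 2, -1), each = 3), 3) / 3     # temporal burst
  k_spec <- t(k_onset)                                      # d/df
  k_lap <- matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3) / 4
  k_avg <- matrix(1 / 9, 3, 3)
  kernels <- list(k_onset, -k_onset, k_trans, -k_trans,
                  k_spec, -k_spec, k_lap, k_avg)
  w <- array(0, c(3, 3, 2, 16))
  for (i in seq_along(kernels)) {
    w[, , 1, i] <- kernels[[i]]       # raw view
    w[, , 2, 8 + i] <- kernels[[i]]   # row-standardized view
  }
  structure(list(spec = backbone_spec("tiny", 0L, c(64L, 8L, 32L)),
                 weights = list(conv1 = w),
                 pool = list(freq = 4L, time = 32L)),
            class = "lung_backbone")
}

#' @export
print.lung_backbone <- function(x, ...) {
  cat(sprintf("<lung_backbone '%s': frozen, feature map %s>\n", x$spec$name,
              paste(x$spec$feature_map_shape, collapse = "x")))
  invisible(x)
}

# Rectangular block pooling of an (H, W, C) array by factors (kr, kc);
# max or mean per block.
pool_blocks <- function(x, kr, kc, what = c("mean", "max")) {
  what <- match.arg(what)
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  nr <- H %/% kr; nc <- W %/% kc
  if (what == "max") {
    out <- array(-Inf, c(nr, nc, C))
    for (di in seq_len(kr)) {
      for (dj in seq_len(kc)) {
        out <- pmax(out, x[seq(di, nr * kr, by = kr),
                           seq(dj, nc * kc, by = kc), , drop = FALSE])
      }
    }
    out
  } else {
    m <- rowsum(matrix(x, H, W * C), rep(seq_len(nr), each = kr))
    a <- aperm(array(m, c(nr, W, C)), c(2, 1, 3))
    m2 <- rowsum(matrix(a, W, nr * C), rep(seq_len(nc), each = kc))
    aperm(array(m2, c(nc, nr, C)), c(2, 1, 3)) / (kr * kc)
  }
}

# 'same' 3x3 convolution via im2col; x is H x W x Cin, w is 3x3xCinxCout.
conv2d_same3 <- function(x, w) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
  cout <- dim(w)[4]
  xp <- array(0, c(H + 2L, W + 2L, cin))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  cols <- matrix(0, H * W, 9L * cin)
  k <- 1L
  for (cc in seq_len(cin)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        cols[, k] <- as.vector(xp[di + seq_len(H), dj + seq_len(W), cc])
        k <- k + 1L
      }
    }
  }
  wm <- matrix(w, nrow = 9L * cin, ncol = cout)
  array(cols %*% wm, dim = c(H, W, cout))
}

#' Extract the backbone's final convolutional feature map
#'
#' Deterministic for a frozen backbone: the same image always yields the
#' same features.
#'
#' @param image a 256 x 256 x 3 array in \[0, 1\] (see [to_model_input()]).
#' @param backbone a [tiny_backbone()].
#' @return an `(H, W, C)` array matching `backbone$spec$feature_map_shape`.
#' @export
extract_feature_map <- function(image, backbone = tiny_backbone()) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L)
    stop("image must be an H x W x 3 array")
  g <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  # second view: per-frequency-row standardization (frozen norm layer)
  mu <- rowMeans(g)
  sd_ <- pmax(apply(g, 1L, stats::sd), 1e-3)
  x <- array(c(g, (g - mu) / sd_), dim = c(dim(g), 2L))
  h <- conv2d_same3(x, backbone$weights$conv1)
  h[h < 0] <- 0
  n_maps <- dim(h)[3]
  fmap <- array(0, backbone$spec$feature_map_shape)
  fmap[, , seq_len(n_maps)] <-
    pool_blocks(h, backbone$pool$freq, backbone$pool$time, "max")
  fmap[, , n_maps + seq_len(n_maps)] <-
    pool_blocks(h, backbone$pool$freq, backbone$pool$time, "mean")
  expected <- backbone$spec$feature_map_shape
  if (!identical(dim(fmap), as.integer(expected)))
    stop("backbone produced feature map ", paste(dim(fmap), collapse = "x"),
         ", expected ", paste(expected, collapse = "x"))
  fmap
}

# Split 1:n into k contiguous near-equal groups, larger groups first
# (7 -> 3,2,2; 8 -> 3,3,2).
contiguous_groups <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(seq, starts, ends)
}

#' Reshape a convolutional feature map into an LSTM input sequence
#'
#' Partitions the spatial grid into 3 x 3 contiguous regions (for a 7 x 7
#' map the row/column group sizes are 3, 2, 2), averages within each
#' region, and reduces the channel dimension to 64 by averaging contiguous
#' channel groups. Regions are traversed row-major, giving a sequence of 9
#' time steps with 64 features each.
#'
#' @param fmap an `(H, W, C)` array with `C >= 64` (or any `C` with
#'   `pad = TRUE`, which repeats channels up to 64 first).
#' @param pad if `TRUE`, maps with fewer than 64 channels are padded by
#'   repeating channels; otherwise such maps are an error.
#' @return a 9 x 64 numeric matrix.
#' @export
sequence_from_feature_map <- function(fmap, pad = FALSE) {
  d <- dim(fmap)
  if (is.null(d) || length(d) != 3L) stop("fmap must be an (H, W, C) array")
  H <- d[1]; W <- d[2]; C <- d[3]
  if (C < 64L) {
    if (!pad) stop("feature map has ", C, " channels; need >= 64")
    fmap <- fmap[, , rep(seq_len(C), length.out = 64L), drop = FALSE]
    C <- 64L
  }
  rg <- contiguous_groups(H, 3L)
  cg <- contiguous_groups(W, 3L)
  ch <- contiguous_groups(C, 64L)
  out <- matrix(0, 9L, 64L)
  step <- 1L
  for (i in 1:3) {
    for (j in 1:3) {
      block <- fmap[rg[[i]], cg[[j]], , drop = FALSE]
      region_mean <- apply(block, 3L, mean)
      out[step, ] <- vapply(ch, function(g) mean(region_mean[g]), numeric(1))
      step <- step + 1L
    }
  }
  out
}

# Global average pooling of an (H, W, C) map to a C-vector.
global_avg_pool <- function(fmap) apply(fmap, 3L, mean)

# Stable hash of the backbone weights, used to verify the frozen contract.
backbone_weight_hash <- function(backbone) {
  v <- unlist(backbone$weights, use.names = FALSE)
  sum(v * seq_along(v)) + sum(v^2)
}
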