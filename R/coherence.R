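# Welch-averaged auto/cross spectra of two channels (Hann window).
welch_cross <- function(x, y, fs, segment_s = 2, overlap = 0.5) {
  L <- as_count(segment_s * fs, "segment_s * fs")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  n <- length(x)
  stop_if(n < L + step, "coherence needs >= 2 segments (got %d)", max(0L, n %/% L))
  starts <- seq(1L, n - L + 1L, by = step)
  stop_if(length(starts) < 2L, "coherence needs >= 2 segments (got %d)", length(starts))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))   # Hann
  nf <- L %/% 2 + 1L
  Sxx <- Syy <- numeric(nf)
  Sxy <- complex(nf)
  for (s0 in starts) {
    idx <- s0:(s0 + L - 1L)
    xs <- (x[idx] - mean(x[idx])) * w
    ys <- (y[idx] - mean(y[idx])) * w
    X <- stats::fft(xs)[seq_len(nf)]
    Y <- stats::fft(ys)[seq_len(nf)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  list(freq = (seq_len(nf) - 1L) * fs / L,
       Sxx = Sxx, Syy = Syy, Sxy = Sxy, n_segments = length(starts))
}

#' Magnitude-squared coherence between a channel pair
#'
#' Welch segment-averaged cross-spectra; coherence
#' `|Sxy|^2 / (Sxx * Syy)` per frequency, a symmetric functional
#' connectivity measure in [0, 1]. The default 2-s segments give a native
#' 0.5-Hz frequency step.
#'
#' @param rec a [recording()], already band-limited to the range of
#'   interest (the standard pipeline band-passes 0.5-250 Hz first).
#' @param pair length-2 vector of channel ids (or indices).
#' @param segment_s Welch segment length (s), default 2.
#' @param overlap fractional segment overlap, default 0.5.
#' @param fmin_hz,fmax_hz returned frequency range (defaults 0.5-100 Hz).
#' @return An object of class `"coherence_pair"`: list with `pair`,
#'   `freq`, `coherence`, `n_segments`, `fs`, plus `null` (permutation x
#'   frequency matrix) and `significant` once [surrogate_null()] /
#'   [flag_significant()] have been applied.
#' @export
coherence <- function(rec, pair, segment_s = 2, overlap = 0.5,
                      fmin_hz = 0.5, fmax_hz = 100) {
  stopifnot(inherits(rec, "recording"), length(pair) == 2L)
  sub <- select_channels(rec, pair)
  wc <- welch_cross(sub$signal[1, ], sub$signal[2, ], rec$fs,
                    segment_s, overlap)
  keep <- wc$freq >= fmin_hz - 1e-9 & wc$freq <= fmax_hz + 1e-9
  coh <- Mod(wc$Sxy)^2 / (wc$Sxx * wc$Syy)
  coh[!is.finite(coh)] <- 0
  structure(list(pair = sub$channels$id, freq = wc$freq[keep],
                 coherence = pmin(coh[keep], 1),
                 n_segments = wc$n_segments, fs = rec$fs,
                 segment_s = segment_s, overlap = overlap,
                 fmin_hz = fmin_hz, fmax_hz = fmax_hz,
                 null = NULL, significant = NULL),
            class = "coherence_pair")
}

#' @export
print.coherence_pair <- function(x, ...) {
  cat(sprintf("<coherence_pair> %s ~ %s, %.3g-%.3g Hz (%d segments)\n",
              x$pair[1], x$pair[2], min(x$freq), max(x$freq), x$n_segments))
  cat(sprintf("  peak coherence %.3f at %.3g Hz\n",
              max(x$coherence), x$freq[which.max(x$coherence)]))
  if (!is.null(x$null)) {
    cat(sprintf("  surrogate null: %d permutations%s\n", nrow(x$null),
                if (is.null(x$significant)) "" else
                  sprintf("; %d/%d bins significant", sum(x$significant),
                          length(x$significant))))
  }
  invisible(x)
}

#' @export
plot.coherence_pair <- function(x, ...) {
  graphics::plot(x$freq, x$coherence, type = "l", ylim = c(0, 1),
                 xlab = "frequency (Hz)", ylab = "coherence",
                 main = paste(x$pair, collapse = " ~ "), ...)
  if (!is.null(x$null)) {
    q95 <- apply(x$null, 2, stats::quantile, 0.95)
    graphics::lines(x$freq, q95, lty = 2, col = "grey40")
  }
  invisible(x)
}

# permute the order of fixed-length blocks of one vector; the trailing
# partial block stays in place (marginals are preserved exactly)
block_shuffle <- function(x, block_len) {
  nb <- length(x) %/% block_len
  if (nb < 2L) return(x)
  perm <- sample.int(nb)
  head_idx <- as.vector(vapply(perm, function(b)
    ((b - 1L) * block_len + 1L):(b * block_len), integer(block_len)))
  c(x[head_idx], x[seq_len(length(x) - nb * block_len) + nb * block_len])
}

#' Monte-Carlo block-shuffle surrogate null for coherence
#'
#' Builds the null distribution of the coherence spectrum by shuffling the
#' order of short blocks (default 500 ms) of *one* channel and recomputing
#' coherence, `n_perm` times (default 100). Block permutation preserves
#' the channel's samples, hence its mean, variance, and amplitude
#' histogram, while destroying cross-channel temporal structure. Shuffling
#' only one channel avoids the alignment classes that survive when both
#' channels are permuted identically.
#'
#' @inheritParams coherence
#' @param n_perm number of permutations (default 100); < 20 triggers a
#'   warning (unstable tail quantiles).
#' @param block_s shuffled block length in seconds (default 0.5).
#' @param seed integer RNG seed.
#' @return The [coherence()] object with `null` filled in
#'   (`n_perm` x n-frequencies matrix).
#' @export
surrogate_null <- function(rec, pair, n_perm = 100L, block_s = 0.5,
                           seed = NULL, segment_s = 2, overlap = 0.5,
                           fmin_hz = 0.5, fmax_hz = 100) {
  stopifnot(inherits(rec, "recording"))
  n_perm <- as_count(n_perm, "n_perm")
  if (n_perm < 20L) warning("n_perm < 20: tail quantiles will be unstable")
  block_len <- as_count(block_s * rec$fs, "block_s * fs")
  stop_if(ncol(rec$signal) < 2L * block_len, "recording must span >= 2 blocks")
  cp <- coherence(rec, pair, segment_s, overlap, fmin_hz, fmax_hz)
  sub <- select_channels(rec, pair)
  x <- sub$signal[1, ]; y <- sub$signal[2, ]
  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      ys <- block_shuffle(y, block_len)
      wc <- welch_cross(x, ys, rec$fs, segment_s, overlap)
      keep <- wc$freq >= fmin_hz - 1e-9 & wc$freq <= fmax_hz + 1e-9
      coh <- Mod(wc$Sxy)^2 / (wc$Sxx * wc$Syy)
      pmin(coh[keep], 1)
    }, numeric(length(cp$freq))))
  })
  cp$null <- null
  cp
}

#' Flag frequencies (and bands) exceeding the surrogate null
#'
#' A frequency bin is significant iff its observed coherence exceeds the
#' `(1 - alpha)` quantile of the surrogate null at that bin. If a band
#' table is supplied, band-mean coherence is likewise compared against the
#' null distribution of band means.
#'
#' @param pair a [coherence_pair][coherence] with `null` present (see
#'   [surrogate_null()]).
#' @param alpha significance level (default 0.05).
#' @param bands optional [band_table()] for band-level decisions.
#' @return The object with `significant` (logical per frequency),
#'   `null_quantile`, and, when `bands` is given, `band_means` (named
#'   numeric) and `band_significant` (named logical).
#' @export
flag_significant <- function(pair, alpha = 0.05, bands = NULL) {
  stopifnot(inherits(pair, "coherence_pair"))
  stop_if(is.null(pair$null), "no surrogate null present; run surrogate_null() first")
  q <- if (alpha >= 1) rep(-Inf, length(pair$freq)) else
    apply(pair$null, 2, stats::quantile, probs = 1 - alpha, type = 1)
  pair$alpha <- alpha
  pair$null_quantile <- q
  pair$significant <- pair$coherence > q
  if (!is.null(bands)) {
    bm <- coherence_band_means(pair$freq, pair$coherence, bands)
    nullbm <- t(apply(pair$null, 1, function(r)
      coherence_band_means(pair$freq, r, bands)))
    qb <- if (alpha >= 1) rep(-Inf, ncol(nullbm)) else
      apply(nullbm, 2, stats::quantile, probs = 1 - alpha, type = 1)
    pair$band_means <- bm
    pair$band_null_quantile <- qb
    pair$band_significant <- bm > qb
  }
  pair
}

coherence_band_means <- function(freq, coh, bands) {
  stopifnot(inherits(bands, "band_table"))
  step <- if (length(freq) > 1L) freq[2] - freq[1] else 0
  out <- vapply(seq_len(nrow(bands)), function(b) {
    hi <- min(bands$upper[b], bands$high[b] + step)
    sel <- freq >= bands$low[b] & freq < hi
    if (!any(sel)) NA_real_ else mean(coh[sel])
  }, numeric(1))
  names(out) <- bands$name
  out
}
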