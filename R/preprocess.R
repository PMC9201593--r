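#' Zero-phase Butterworth filtering
#'
#' Designs a Butterworth filter of the requested order and applies it
#' forward-backward (`signal::filtfilt`), so the net filter is zero-phase
#' with stop-band attenuation of an effective order `2 * order`. Zero
#' phase matters here: any phase distortion would corrupt the lags that
#' the directed-connectivity stage estimates.
#'
#' @param rec a [recording()].
#' @param kind one of `"lowpass"`, `"highpass"`, `"bandpass"`.
#' @param edges_hz cutoff (one value, or two for bandpass), strictly
#'   inside (0, fs/2).
#' @param order filter order (default 4, the conventional choice for
#'   neural data).
#' @return filtered [recording()].
#' @export
butterworth_filter <- function(rec, kind = c("lowpass", "highpass", "bandpass"),
                               edges_hz, order = 4L) {
  stopifnot(inherits(rec, "recording"))
  kind <- match.arg(kind)
  nyq <- rec$fs / 2
  stop_if(any(edges_hz <= 0) || any(edges_hz >= nyq),
          "filter edge(s) must lie strictly inside (0, %g) Hz", nyq)
  if (kind == "bandpass") {
    # cascaded zero-phase high-pass + low-pass: a joint band-pass design
    # with a very low normalized lower edge is numerically unstable
    stopifnot(length(edges_hz) == 2L, edges_hz[1] < edges_hz[2])
    rec <- butterworth_filter(rec, "highpass", edges_hz[1], order)
    return(butterworth_filter(rec, "lowpass", edges_hz[2], order))
  }
  stopifnot(length(edges_hz) == 1L)
  W <- edges_hz / nyq
  if (kind == "highpass") {
    # DC lies in the stop band: removing the channel mean first costs
    # nothing and suppresses multi-second start-up transients
    rec$signal <- rec$signal - rowMeans(rec$signal)
    # below W ~ 2e-5 the order-4 polynomial coefficients lose precision;
    # the order-2 prototype (still effective order 4 after the
    # forward-backward pass) is accurate there
    if (W < 2e-5) order <- min(order, 2L)
  }
  bf <- signal::butter(order, W,
                       type = if (kind == "lowpass") "low" else "high")
  out <- rec
  for (i in seq_len(nrow(rec$signal))) {
    out$signal[i, ] <- signal::filtfilt(bf, rec$signal[i, ])
  }
  assert_finite(out, "butterworth_filter")
}

#' Zero-phase notch filtering at line-noise frequencies
#'
#' One second-order IIR notch (biquad) per frequency, applied
#' forward-backward. Narrow by design: >= 20 dB attenuation at the notch
#' frequency, < 1 dB at +/- 5 Hz.
#'
#' @param rec a [recording()].
#' @param freqs_hz notch frequencies (e.g. `c(50, 100, 150)`); empty
#'   vector returns the input unchanged.
#' @param bandwidth_hz -3 dB notch width (default 2 Hz).
#' @return filtered [recording()].
#' @export
notch_filter <- function(rec, freqs_hz, bandwidth_hz = 2) {
  stopifnot(inherits(rec, "recording"))
  if (length(freqs_hz) == 0L) return(rec)
  nyq <- rec$fs / 2
  stop_if(any(freqs_hz <= 0) || any(freqs_hz >= nyq),
          "notch frequency must lie strictly inside (0, %g) Hz", nyq)
  out <- rec
  for (f0 in freqs_hz) {
    w0 <- 2 * pi * f0 / rec$fs
    Q <- f0 / bandwidth_hz
    alpha <- sin(w0) / (2 * Q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    flt <- signal::Arma(b = b / a[1], a = a / a[1])
    for (i in seq_len(nrow(out$signal))) {
      out$signal[i, ] <- signal::filtfilt(flt, out$signal[i, ])
    }
  }
  assert_finite(out, "notch_filter")
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean across all channels (the common grand
#' average reference) from every channel; after the operation the
#' per-sample mean across channels is exactly zero.
#'
#' @param rec a [recording()] with >= 2 channels.
#' @return re-referenced [recording()].
#' @export
rereference_common_average <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  stop_if(nrow(rec$signal) < 2L, "common-average reference needs >= 2 channels")
  rec$signal <- sweep(rec$signal, 2L, colMeans(rec$signal))
  rec
}

#' Cut a recording into fixed-length epochs
#'
#' Non-overlapping contiguous epochs from the start of the recording. Any
#' epoch that intersects a rejected sample (caller-supplied artifact mask)
#' is dropped.
#'
#' @param rec a [recording()].
#' @param epoch_s epoch length in seconds; `epoch_s * fs` must be an
#'   integer.
#' @param reject_mask optional logical vector (one element per sample);
#'   `TRUE` marks artifact samples.
#' @return An object of class `"epoch_set"`: list with `epochs` (array
#'   epoch x channel x sample), `fs`, `epoch_s`, `channels`, `n_dropped`,
#'   `kept` (indices of retained epochs).
#' @export
epoch_segments <- function(rec, epoch_s, reject_mask = NULL) {
  stopifnot(inherits(rec, "recording"))
  L <- as_count(epoch_s * rec$fs, "epoch_s * fs")
  n <- ncol(rec$signal)
  M <- n %/% L
  stop_if(M < 1L, "recording shorter than one epoch")
  keep <- rep(TRUE, M)
  if (!is.null(reject_mask)) {
    stopifnot(is.logical(reject_mask), length(reject_mask) == n)
    for (m in seq_len(M)) {
      idx <- ((m - 1L) * L + 1L):(m * L)
      if (any(reject_mask[idx])) keep[m] <- FALSE
    }
  }
  kept <- which(keep)
  stop_if(length(kept) == 0L, "no usable epochs after artifact rejection")
  ep <- array(0, c(length(kept), nrow(rec$signal), L))
  for (j in seq_along(kept)) {
    idx <- ((kept[j] - 1L) * L + 1L):(kept[j] * L)
    ep[j, , ] <- rec$signal[, idx, drop = FALSE]
  }
  structure(list(epochs = ep, fs = rec$fs, epoch_s = epoch_s,
                 channels = rec$channels, n_dropped = M - length(kept),
                 kept = kept),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g s @ %g Hz; %d dropped)\n",
              d[1], d[2], d[3], x$epoch_s, x$fs, x$n_dropped))
  invisible(x)
}

# split an integer decimation factor into stages <= 13 so the per-stage
# normalized anti-alias cutoff never gets numerically tiny
decimation_stages <- function(factor) {
  stages <- integer(0)
  f <- factor
  while (f > 13L) {
    s <- 0L
    for (cand in 13:2) if (f %% cand == 0L) { s <- cand; break }
    stop_if(s == 0L, "cannot decimate by %d: no integer stage factor <= 13", factor)
    stages <- c(stages, s)
    f <- f %/% s
  }
  c(stages, f)
}

#' Anti-aliased downsampling
#'
#' Zero-phase Butterworth anti-alias low-pass (order 8, cutoff at 0.49 of
#' the new Nyquist) followed by sample decimation; large factors are
#' decimated in cascaded integer stages. Content below 0.8 x the new
#' Nyquist is preserved within 5%; content above the new Nyquist is
#' attenuated far beyond 20 dB.
#'
#' @param rec a [recording()].
#' @param target_fs_hz new sampling rate; `fs / target_fs_hz` must be an
#'   integer.
#' @return downsampled [recording()].
#' @export
downsample <- function(rec, target_fs_hz) {
  stopifnot(inherits(rec, "recording"))
  stop_if(target_fs_hz >= rec$fs, "target rate must be below the current rate")
  ratio <- rec$fs / target_fs_hz
  stop_if(abs(ratio - round(ratio)) > 1e-9,
          "fs/target (%g) must be an integer decimation factor", ratio)
  for (s in decimation_stages(as.integer(round(ratio)))) {
    new_fs <- rec$fs / s
    bf <- signal::butter(8, 0.98 / s, type = "low")
    sig <- rec$signal
    for (i in seq_len(nrow(sig))) sig[i, ] <- signal::filtfilt(bf, sig[i, ])
    rec <- recording(sig[, seq(1L, ncol(sig), by = s), drop = FALSE],
                     new_fs, rec$channels)
  }
  assert_finite(rec, "downsample")
}
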