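#' Frequency-band table
#'
#' Ordered, non-overlapping frequency bands. Printed integer band edges
#' (e.g. "beta = 16-31 Hz") are interpreted half-open: the band covers
#' `[low, high + 1)` Hz, so adjacent printed bands tile without overlap
#' while deliberate gaps (e.g. around 50 Hz line noise) are preserved.
#'
#' @param name character vector of band names.
#' @param low_hz,high_hz printed lower/upper edges (Hz).
#' @param convention `"printed"` (upper bound `high + 1`, default) or
#'   `"exact"` (upper bound `high`).
#' @return data.frame of class `"band_table"` with columns `name`, `low`,
#'   `high`, `upper` (the exclusive upper bound used for membership).
#' @seealso [band_preset()]
#' @export
band_table <- function(name, low_hz, high_hz,
                       convention = c("printed", "exact")) {
  convention <- match.arg(convention)
  stopifnot(length(name) == length(low_hz), length(low_hz) == length(high_hz),
            all(low_hz < high_hz))
  upper <- if (convention == "printed") high_hz + 1 else high_hz
  o <- order(low_hz)
  bt <- data.frame(name = as.character(name)[o], low = low_hz[o],
                   high = high_hz[o], upper = upper[o],
                   stringsAsFactors = FALSE)
  stop_if(any(bt$upper[-nrow(bt)] > bt$low[-1] + 1e-12),
          "bands overlap under the half-open convention")
  structure(bt, class = c("band_table", "data.frame"))
}

#' Species band-table presets
#'
#' `"mouse"`: delta 0-3, theta 4-7, alpha 8-15, beta 16-31, low gamma
#' 32-49, medium gamma 51-75, high gamma 76-100 Hz (note the deliberate
#' gap at 50 Hz line noise). `"human"`: delta 0-3, theta 4-7, alpha 8-13,
#' beta 14-30, gamma 31-100 Hz. The mouse delta band starts at 0.1 Hz,
#' the effective lower edge after the 0.1-Hz high-pass.
#'
#' @param species `"mouse"` or `"human"`.
#' @return a [band_table()].
#' @export
band_preset <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  if (species == "mouse") {
    bt <- band_table(
      name = c("delta", "theta", "alpha", "beta",
               "low_gamma", "medium_gamma", "high_gamma"),
      low_hz  = c(0, 4, 8, 16, 32, 51, 76),
      high_hz = c(3, 7, 15, 31, 49, 75, 100))
  } else {
    bt <- band_table(
      name = c("delta", "theta", "alpha", "beta", "gamma"),
      low_hz  = c(0, 4, 8, 14, 31),
      high_hz = c(3, 7, 13, 30, 100))
  }
  bt$low[1] <- 0.1    # below the 0.1-Hz high-pass nothing is interpretable
  bt
}

#' Look up the band containing a frequency
#'
#' @param f_hz frequency (Hz), >= 0.
#' @param bands a [band_table()].
#' @return band name, or `NA_character_` if `f_hz` falls in a gap.
#' @examples
#' band_lookup(20, band_preset("mouse"))   # "beta"
#' band_lookup(50, band_preset("mouse"))   # NA: between low and medium gamma
#' @export
band_lookup <- function(f_hz, bands) {
  stopifnot(inherits(bands, "band_table"), all(f_hz >= 0))
  vapply(f_hz, function(f) {
    i <- which(f >= bands$low & f < bands$upper)
    if (length(i) == 1L) bands$name[i] else NA_character_
  }, character(1))
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric
# tridiagonal eigenproblem; cached per (n, nw, k).
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  W <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  diag_off <- (t[-1] * (n - t[-1]))[seq_len(n - 1)] / 2
  Tm <- diag(diag_main)
  Tm[cbind(seq_len(n - 1), 2:n)] <- diag_off
  Tm[cbind(2:n, seq_len(n - 1))] <- diag_off
  ev <- eigen(Tm, symmetric = TRUE)
  h <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    h[, j] <- h[, j] / sqrt(sum(h[, j]^2))
    if (sum(h[, j]) < 0) h[, j] <- -h[, j]
  }
  .dpss_cache[[key]] <- h
  h
}

#' Multitaper power spectrum
#'
#' DPSS (Slepian) multitaper power spectral density on short segments,
#' averaged over tapers, segments, and epochs. The frequency grid step is
#' set by zero-padding each segment to `fs / freq_step_hz` points, so a
#' 50-ms segment can be evaluated on a 0.25-Hz grid. Satisfies Parseval:
#' the PSD integrated over [0, Nyquist] matches the signal variance.
#'
#' @param x an [epoch_segments()] result or a [recording()] (treated as
#'   one epoch).
#' @param segment_s segment length in seconds (default 0.05);
#'   `segment_s * fs` must be >= 8 samples.
#' @param freq_step_hz frequency grid step (default 0.25 Hz).
#' @param fmin_hz,fmax_hz returned frequency range (defaults 0.1 and
#'   100 Hz), inside (0, Nyquist].
#' @param nw time-bandwidth product (default 2).
#' @param n_tapers number of DPSS tapers (default `2 * nw - 1`).
#' @return An object of class `"power_spectrum"`: list with `freq`,
#'   `power` (channels x frequencies, uV^2/Hz), `fs`, `channels`,
#'   `taper_count`, `segment_s`, `n_segments`.
#' @export
multitaper_power <- function(x, segment_s = 0.05, freq_step_hz = 0.25,
                             fmin_hz = 0.1, fmax_hz = 100,
                             nw = 2, n_tapers = 2 * nw - 1) {
  if (inherits(x, "recording")) {
    ep <- array(0, c(1L, nrow(x$signal), ncol(x$signal)))
    ep[1L, , ] <- x$signal
    x <- structure(list(epochs = ep, fs = x$fs, epoch_s = duration(x),
                        channels = x$channels, n_dropped = 0L),
                   class = "epoch_set")
  }
  stopifnot(inherits(x, "epoch_set"))
  fs <- x$fs
  nyq <- fs / 2
  stop_if(fmin_hz <= 0 || fmax_hz > nyq || fmin_hz >= fmax_hz,
          "frequency range must satisfy 0 < fmin < fmax <= Nyquist (%g Hz)", nyq)
  L <- as_count(segment_s * fs, "segment_s * fs")
  stop_if(L < 8L, "segment of %d samples too short (need >= 8)", L)
  nfft <- as_count(fs / freq_step_hz, "fs / freq_step_hz")
  stop_if(nfft < L, "freq_step_hz too coarse: fft length %d < segment %d", nfft, L)
  h <- dpss_tapers(L, nw, n_tapers)
  d <- dim(x$epochs)
  nseg_per <- d[3] %/% L
  stop_if(nseg_per < 1L, "epochs shorter than one segment")
  nf <- nfft %/% 2 + 1L
  acc <- matrix(0, d[2], nf)
  nseg <- 0L
  buf <- matrix(0, nfft, n_tapers)
  for (e in seq_len(d[1])) {
    for (s in seq_len(nseg_per)) {
      idx <- ((s - 1L) * L + 1L):(s * L)
      seg <- x$epochs[e, , idx, drop = FALSE]
      dim(seg) <- c(d[2], L)
      seg <- seg - rowMeans(seg)
      for (ch in seq_len(d[2])) {
        buf[] <- 0
        buf[seq_len(L), ] <- h * seg[ch, ]
        X <- stats::mvfft(buf)[seq_len(nf), , drop = FALSE]
        acc[ch, ] <- acc[ch, ] + rowMeans(Mod(X)^2)
      }
      nseg <- nseg + 1L
    }
  }
  psd <- acc / nseg / fs
  # one-sided: double everything except DC and (for even nfft) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nfft %% 2L == 0L) dbl[nf] <- 1
  psd <- sweep(psd, 2L, dbl, `*`)
  freq <- (seq_len(nf) - 1L) * freq_step_hz
  keep <- freq >= fmin_hz - 1e-9 & freq <= fmax_hz + 1e-9
  structure(list(freq = freq[keep],
                 power = psd[, keep, drop = FALSE],
                 full_freq = freq, full_power = psd,
                 fs = fs, channels = x$channels,
                 taper_count = n_tapers, segment_s = segment_s,
                 n_segments = nseg),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d channels, %.4g-%.4g Hz (step %.3g Hz), %d tapers x %d segments\n",
              nrow(x$power), min(x$freq), max(x$freq),
              x$freq[2] - x$freq[1], x$taper_count, x$n_segments))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, channels = NULL, log = "y", ...) {
  idx <- if (is.null(channels)) seq_len(nrow(x$power)) else
    match(channels, x$channels$id)
  graphics::matplot(x$freq, t(x$power[idx, , drop = FALSE]), type = "l",
                    lty = 1, log = log, xlab = "frequency (Hz)",
                    ylab = expression(paste("power (", mu, V^2, "/Hz)")), ...)
  invisible(x)
}

#' Per-band mean power
#'
#' Averages a power spectrum over the frequency bins belonging to each
#' band. A bin at frequency f belongs to band (low, high) when
#' `low <= f < high + step`, with `step` the spectrum's grid step (capped
#' by the band's lookup interval): the printed upper edge plus one grid
#' step, so adjacent printed bands tile the grid without sharing bins.
#'
#' @param spec a [multitaper_power()] result.
#' @param bands a [band_table()].
#' @return numeric matrix channels x bands (dimnames set).
#' @export
band_average <- function(spec, bands) {
  stopifnot(inherits(spec, "power_spectrum"), inherits(bands, "band_table"))
  step <- if (length(spec$freq) > 1L) spec$freq[2] - spec$freq[1] else 0
  out <- matrix(NA_real_, nrow(spec$power), nrow(bands),
                dimnames = list(spec$channels$id, bands$name))
  for (b in seq_len(nrow(bands))) {
    hi <- min(bands$upper[b], bands$high[b] + step)
    sel <- spec$freq >= bands$low[b] & spec$freq < hi
    stop_if(!any(sel), "band '%s' [%g, %g) contains no frequency bins",
            bands$name[b], bands$low[b], hi)
    out[, b] <- rowMeans(spec$power[, sel, drop = FALSE])
  }
  out
}
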