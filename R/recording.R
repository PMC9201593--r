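#' Multichannel continuous recording
#'
#' Container for a continuous multichannel signal (local field potential,
#' EEG, or wide-band extracellular voltage) together with its sampling rate
#' and per-channel metadata (cortical area and layer).
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channels optional data.frame with columns `id`, `area`, `layer`;
#'   one row per channel. Defaults to `ch1..chk`, area `"other"`, layer
#'   `"n/a"`.
#'
#' @return An object of class `"recording"`: a list with elements
#'   `signal`, `fs`, `channels`.
#' @examples
#' rec <- recording(matrix(rnorm(200), 2), fs = 100)
#' rec
#' @export
recording <- function(signal, fs, channels = NULL) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  stopifnot(is.matrix(signal), is.numeric(signal))
  stop_if(!is.numeric(fs) || length(fs) != 1L || fs <= 0, "fs must be a positive scalar")
  k <- nrow(signal)
  if (is.null(channels)) {
    channels <- data.frame(id = paste0("ch", seq_len(k)),
                           area = "other", layer = "n/a",
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(channels))
  stop_if(!all(c("id", "area", "layer") %in% names(channels)),
          "channels must have columns id, area, layer")
  stop_if(nrow(channels) != k, "channels has %d rows but signal has %d channels",
          nrow(channels), k)
  stop_if(anyDuplicated(channels$id) > 0, "channel ids must be unique")
  rownames(signal) <- channels$id
  structure(list(signal = signal, fs = as.numeric(fs), channels = channels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  dur <- ncol(x$signal) / x$fs
  cat(sprintf("<recording> %d channels x %d samples (%.6g s @ %g Hz)\n",
              nrow(x$signal), ncol(x$signal), dur, x$fs))
  tab <- table(paste(x$channels$area, x$channels$layer, sep = "/"))
  cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$signal)

#' Number of samples / duration of a recording
#' @param rec a [recording()].
#' @return `n_samples()`: integer sample count; `duration()`: seconds.
#' @export
n_samples <- function(rec) ncol(rec$signal)

#' @rdname n_samples
#' @export
duration <- function(rec) ncol(rec$signal) / rec$fs

#' Select channels from a recording
#'
#' @param rec a [recording()].
#' @param ids channel ids (character) or indices (numeric).
#' @return A [recording()] restricted to the requested channels, metadata
#'   preserved.
#' @export
select_channels <- function(rec, ids) {
  stopifnot(inherits(rec, "recording"))
  idx <- if (is.character(ids)) match(ids, rec$channels$id) else as.integer(ids)
  stop_if(anyNA(idx) || any(idx < 1L) || any(idx > nrow(rec$signal)),
          "unknown channel id(s)")
  recording(rec$signal[idx, , drop = FALSE], rec$fs,
            rec$channels[idx, , drop = FALSE])
}

# validity used after preprocessing steps: no non-finite samples may remain
assert_finite <- function(rec, where) {
  stop_if(!all(is.finite(rec$signal)), "non-finite samples after %s", where)
  rec
}
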