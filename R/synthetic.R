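#' Directed band-limited coupling specification
#'
#' Ground-truth description of one directed interaction injected by
#' [generate_band_coupled_lfp()]: a band-limited component of the source
#' channel is delayed by `lag_samples` and added, scaled by `gain`, to the
#' target channel. Strictly causal by construction (`lag_samples >= 1`).
#'
#' @param source,target channel ids.
#' @param band_hz numeric length-2, coupling band (Hz), strictly inside
#'   (0, fs/2) of the simulation it is used in.
#' @param lag_samples positive integer delay, in samples.
#' @param gain non-negative scaling of the injected component.
#' @return A list of class `"coupling_spec"`.
#' @export
coupling_spec <- function(source, target, band_hz, lag_samples, gain = 1) {
  stopifnot(length(band_hz) == 2L, band_hz[1] > 0, band_hz[2] > band_hz[1])
  lag_samples <- as_count(lag_samples, "lag_samples")
  stop_if(lag_samples < 1L, "lag_samples must be >= 1 (strictly causal)")
  stop_if(gain < 0, "gain must be >= 0")
  structure(list(source = source, target = target,
                 band_hz = as.numeric(band_hz),
                 lag_samples = lag_samples, gain = as.numeric(gain)),
            class = "coupling_spec")
}

#' Simulation configuration for band-coupled field potentials
#'
#' @param fs_hz sampling rate (Hz).
#' @param duration_s duration (s).
#' @param n_channels number of channels.
#' @param channel_labels optional data.frame (`id`, `area`, `layer`).
#' @param couplings list of [coupling_spec()] objects.
#' @param noise_exponent spectral exponent alpha of the 1/f^alpha
#'   background (default 1).
#' @param osc_sd standard deviation of the band-limited oscillation added
#'   to each coupling source (default 1, i.e. comparable to the unit-SD
#'   background).
#' @param mixing_matrix optional k x k full-rank instantaneous mixing
#'   matrix applied after coupling injection (volume conduction).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(fs_hz, duration_s, n_channels,
                       channel_labels = NULL, couplings = list(),
                       noise_exponent = 1, osc_sd = 1,
                       mixing_matrix = NULL, seed = NULL) {
  stop_if(duration_s <= 0, "duration_s must be > 0")
  n_channels <- as_count(n_channels, "n_channels")
  if (!is.null(mixing_matrix)) {
    stopifnot(is.matrix(mixing_matrix))
    stop_if(nrow(mixing_matrix) != n_channels || ncol(mixing_matrix) != n_channels,
            "mixing_matrix must be %d x %d", n_channels, n_channels)
    stop_if(qr(mixing_matrix)$rank < n_channels, "mixing_matrix must have full rank")
  }
  for (cp in couplings) {
    stopifnot(inherits(cp, "coupling_spec"))
    stop_if(cp$band_hz[2] >= fs_hz / 2,
            "coupling band [%g, %g] Hz not below Nyquist (%g Hz)",
            cp$band_hz[1], cp$band_hz[2], fs_hz / 2)
  }
  structure(list(fs_hz = fs_hz, duration_s = duration_s,
                 n_channels = n_channels, channel_labels = channel_labels,
                 couplings = couplings, noise_exponent = noise_exponent,
                 osc_sd = osc_sd, mixing_matrix = mixing_matrix, seed = seed),
            class = "sim_config")
}

#' Simulate a stable vector autoregressive process
#'
#' Oracle substrate for the directed-connectivity estimators: data with
#' exactly known VAR coefficients, hence exactly known partial directed
#' coherence.
#'
#' @param coeffs coefficient array `p x k x k`; `coeffs[r, , ]` multiplies
#'   the lag-`r` value (row = target, column = source).
#' @param noise_cov `k x k` symmetric positive-definite innovation
#'   covariance.
#' @param n_samples series length after burn-in.
#' @param seed integer RNG seed.
#' @param burn_in samples discarded at the start (default 1000).
#' @return numeric matrix `k x n_samples`.
#' @examples
#' A <- array(0, c(1, 2, 2)); A[1, , ] <- rbind(c(0.5, 0), c(0.4, 0.3))
#' x <- generate_var_process(A, diag(2), 1000, seed = 1)
#' @export
generate_var_process <- function(coeffs, noise_cov, n_samples, seed = NULL,
                                 burn_in = 1000L) {
  coeffs <- as_var_coeffs(coeffs)
  p <- dim(coeffs)[1]; k <- dim(coeffs)[2]
  stopifnot(is.matrix(noise_cov), nrow(noise_cov) == k, ncol(noise_cov) == k)
  rho <- var_spectral_radius(coeffs)
  stop_if(rho >= 1,
          "unstable VAR: companion-matrix spectral radius %.4f >= 1", rho)
  n_samples <- as_count(n_samples, "n_samples")
  L <- chol(noise_cov)
  with_seed(seed, {
    ntot <- n_samples + burn_in + p
    e <- matrix(stats::rnorm(ntot * k), nrow = k)
    e <- crossprod(L, e)             # t(L) %*% e, innovations with cov noise_cov
    x <- matrix(0, k, ntot)
    x[, seq_len(p)] <- e[, seq_len(p)]
    for (t in (p + 1L):ntot) {
      v <- e[, t]
      for (r in seq_len(p)) v <- v + coeffs[r, , ] %*% x[, t - r]
      x[, t] <- v
    }
    x[, (ntot - n_samples + 1L):ntot, drop = FALSE]
  })
}

as_var_coeffs <- function(coeffs) {
  if (is.matrix(coeffs)) coeffs <- array(coeffs, c(1L, dim(coeffs)))
  stopifnot(is.array(coeffs), length(dim(coeffs)) == 3L,
            dim(coeffs)[2] == dim(coeffs)[3])
  coeffs
}

var_companion <- function(coeffs) {
  p <- dim(coeffs)[1]; k <- dim(coeffs)[2]
  Fm <- matrix(0, k * p, k * p)
  for (r in seq_len(p)) Fm[seq_len(k), (r - 1L) * k + seq_len(k)] <- coeffs[r, , ]
  if (p > 1L) Fm[(k + 1L):(k * p), seq_len(k * (p - 1L))] <- diag(k * (p - 1L))
  Fm
}

#' Companion-form spectral radius of a VAR coefficient array
#' @param coeffs coefficient array `p x k x k` (or `k x k` matrix for p=1).
#' @return largest eigenvalue modulus; the process is stable iff < 1.
#' @export
var_spectral_radius <- function(coeffs) {
  coeffs <- as_var_coeffs(coeffs)
  max(Mod(eigen(var_companion(coeffs), only.values = TRUE)$values))
}

#' Stationary autocovariance of a VAR process (Yule-Walker solution)
#'
#' Solves the discrete Lyapunov equation of the companion form, giving the
#' exact lag-0..`max_lag` autocovariance the sample autocovariance of
#' [generate_var_process()] converges to.
#'
#' @inheritParams generate_var_process
#' @param max_lag largest lag to return.
#' @return array `(max_lag+1) x k x k`; element `[h+1, i, j]` is
#'   `Cov(x_i(t), x_j(t-h))`.
#' @export
var_autocovariance <- function(coeffs, noise_cov, max_lag = 1L) {
  coeffs <- as_var_coeffs(coeffs)
  p <- dim(coeffs)[1]; k <- dim(coeffs)[2]
  Fm <- var_companion(coeffs)
  Q <- matrix(0, k * p, k * p)
  Q[seq_len(k), seq_len(k)] <- noise_cov
  kp <- k * p
  G <- matrix(solve(diag(kp * kp) - kronecker(Fm, Fm), as.vector(Q)), kp, kp)
  out <- array(0, c(max_lag + 1L, k, k))
  # companion state covariance holds Cov(X_t, X_t) with X = (x_t, ..., x_{t-p+1})
  Gh <- G
  for (h in 0:max_lag) {
    if (h > 0L) Gh <- Fm %*% Gh
    out[h + 1L, , ] <- Gh[seq_len(k), seq_len(k)]
  }
  out
}

# 1/f^alpha noise via spectral shaping of white Gaussian noise: exact
# average slope control on the log-log periodogram
one_over_f_noise <- function(n, alpha, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * (fs / n)
  f[f > fs / 2] <- fs - f[f > fs / 2]          # fold to physical frequency
  shape <- c(0, f[-1]^(-alpha / 2))            # kill DC
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# causal band-pass (single-pass Butterworth): group delay keeps the
# injected coupling strictly causal on top of the explicit lag
causal_bandpass <- function(x, band, fs, order = 4L) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filter(bf, x))
}

#' Generate band-coupled 1/f field potentials
#'
#' Each channel is unit-SD 1/f^alpha background noise. For every
#' [coupling_spec()] a fresh band-limited oscillation is added to the
#' source channel, and a copy delayed by `lag_samples` and scaled by
#' `gain` is added to the target, so ground-truth directionality is
#' unambiguous and strictly causal. Optional full-rank instantaneous
#' mixing emulates volume conduction.
#'
#' @param config a [sim_config()].
#' @return A [recording()] with attribute `"ground_truth"` (list of
#'   couplings and generator settings).
#' @export
generate_band_coupled_lfp <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs_hz
  n <- as_count(config$fs_hz * config$duration_s, "fs_hz * duration_s")
  k <- config$n_channels
  chans <- config$channel_labels
  rec <- with_seed(config$seed, {
    sig <- t(vapply(seq_len(k), function(i)
      one_over_f_noise(n, config$noise_exponent, fs), numeric(n)))
    rec0 <- recording(sig, fs, chans)
    idx_of <- function(id) {
      i <- match(id, rec0$channels$id)
      stop_if(is.na(i), "coupling references unknown channel '%s'", id)
      i
    }
    for (cp in config$couplings) {
      si <- idx_of(cp$source); ti <- idx_of(cp$target)
      osc <- causal_bandpass(stats::rnorm(n), cp$band_hz, fs)
      osc <- osc / stats::sd(osc) * config$osc_sd
      sig[si, ] <- sig[si, ] + osc
      lag <- cp$lag_samples
      delayed <- c(rep(0, lag), osc[seq_len(n - lag)])
      sig[ti, ] <- sig[ti, ] + cp$gain * delayed
    }
    recording(sig, fs, chans)
  })
  if (!is.null(config$mixing_matrix)) {
    rec <- apply_instantaneous_mixing(rec, config$mixing_matrix)
  }
  attr(rec, "ground_truth") <- list(
    couplings = lapply(config$couplings, unclass),
    noise_exponent = config$noise_exponent,
    osc_sd = config$osc_sd,
    mixed = !is.null(config$mixing_matrix),
    seed = config$seed)
  rec
}

#' Apply instantaneous (zero-lag) channel mixing
#'
#' Emulates volume conduction: every output channel is a zero-lag linear
#' combination of the input channels. Channel metadata is preserved.
#'
#' @param rec a [recording()].
#' @param mixing full-rank `k x k` matrix.
#' @return A [recording()].
#' @export
apply_instantaneous_mixing <- function(rec, mixing) {
  stopifnot(inherits(rec, "recording"), is.matrix(mixing))
  k <- nrow(rec$signal)
  stop_if(nrow(mixing) != k || ncol(mixing) != k,
          "mixing must be %d x %d, got %d x %d", k, k, nrow(mixing), ncol(mixing))
  stop_if(qr(mixing)$rank < k, "mixing matrix is singular")
  out <- recording(mixing %*% rec$signal, rec$fs, rec$channels)
  attr(out, "ground_truth") <- attr(rec, "ground_truth")
  out
}

#' Default biphasic spike waveform template
#'
#' Negative-dominant biphasic shape (sharp negative trough followed by a
#' smaller positive rebound), total width `width_ms`, trough normalized to
#' `-amplitude`.
#'
#' @param fs_hz sampling rate (Hz).
#' @param width_ms template width in ms (default 1.5).
#' @param amplitude trough depth (positive number; default 1).
#' @return numeric vector of length `round(width_ms/1000 * fs_hz)`.
#' @export
spike_template <- function(fs_hz, width_ms = 1.5, amplitude = 1) {
  n <- as_count(round(width_ms / 1000 * fs_hz), "template length")
  t <- seq(0, width_ms, length.out = n)
  w <- -exp(-((t - 0.35 * width_ms) / (0.12 * width_ms))^2) +
    0.35 * exp(-((t - 0.68 * width_ms) / (0.20 * width_ms))^2)
  w / (-min(w)) * amplitude                      # trough at -amplitude
}

#' Generate a wide-band trace with embedded spikes
#'
#' Gaussian noise plus spike templates inserted at stated times; the
#' ground-truth spike times (time of each template's negative trough) are
#' returned alongside, so detector and sorter accuracy can be scored.
#'
#' @param fs_hz sampling rate, >= 20000 Hz.
#' @param duration_s trace duration (s).
#' @param spike_times_s list with one numeric vector of spike times per
#'   unit (s); within a unit, times must be >= 1 ms apart.
#' @param waveform_templates list of template vectors (dominant negative
#'   trough); see [spike_template()]. Must be at most 3.5 ms long
#'   (the extraction window).
#' @param noise_sd baseline Gaussian noise SD.
#' @param seed integer RNG seed.
#' @return list with `trace` (numeric), `fs_hz`, and `ground_truth`
#'   (data.frame `unit`, `time_s`).
#' @export
generate_spiking_trace <- function(fs_hz, duration_s, spike_times_s,
                                   waveform_templates, noise_sd = 1,
                                   seed = NULL) {
  stop_if(fs_hz < 20000, "fs_hz must be >= 20000 for wide-band spike traces")
  stopifnot(is.list(spike_times_s), is.list(waveform_templates),
            length(spike_times_s) == length(waveform_templates))
  n <- as_count(fs_hz * duration_s, "fs_hz * duration_s")
  max_len <- round(0.0035 * fs_hz)
  for (w in waveform_templates) {
    stop_if(length(w) > max_len,
            "template of %d samples exceeds the 3.5-ms extraction window (%d samples at %g Hz)",
            length(w), max_len, fs_hz)
    stop_if(min(w) >= 0 || -min(w) < max(w),
            "templates must have a dominant negative trough")
  }
  for (st in spike_times_s) {
    if (length(st) > 1L) {
      stop_if(min(diff(sort(st))) < 0.001,
              "spike times within a unit must be >= 1 ms apart")
    }
  }
  with_seed(seed, {
    trace <- stats::rnorm(n, 0, noise_sd)
    gt <- list()
    for (u in seq_along(spike_times_s)) {
      w <- waveform_templates[[u]]
      trough <- which.min(w)
      kept <- numeric(0)
      for (ts in spike_times_s[[u]]) {
        i0 <- round(ts * fs_hz) - trough + 1L
        if (i0 < 1L || i0 + length(w) - 1L > n) next
        idx <- i0:(i0 + length(w) - 1L)
        trace[idx] <- trace[idx] + w
        kept <- c(kept, (i0 + trough - 1L) / fs_hz)
      }
      if (length(kept)) gt[[length(gt) + 1L]] <-
          data.frame(unit = u, time_s = kept)
    }
    gt <- if (length(gt)) do.call(rbind, gt) else
      data.frame(unit = integer(0), time_s = numeric(0))
    list(trace = trace, fs_hz = fs_hz, ground_truth = gt)
  })
}

#' Generate a feature table with known mediation structure
#'
#' Linear structural equations with independent Gaussian disturbances:
#' `input -> {mediator1, mediator2} -> output` plus a direct
#' `input -> output` path. With `standardize = TRUE` (default) disturbance
#' variances are chosen so every variable has unit population variance,
#' making `path_coeffs` the standardized population coefficients.
#'
#' @param n number of rows (subjects), >= 10.
#' @param path_coeffs named list: `a1` (input->mediator1), `a2`
#'   (input->mediator2), `b1` (mediator1->output), `b2`
#'   (mediator2->output), `c` (direct input->output). Omitted entries are 0.
#' @param noise_sds optional named numeric (`input`, `mediator1`,
#'   `mediator2`, `output`): disturbance SDs. Overrides `standardize`.
#' @param standardize choose disturbance SDs for unit population variances.
#' @param seed integer RNG seed.
#' @return data.frame with columns `input`, `mediator1`, `mediator2`,
#'   `output`; attribute `"path_coeffs"` carries the truth.
#' @export
generate_mediation_dataset <- function(n, path_coeffs, noise_sds = NULL,
                                       standardize = TRUE, seed = NULL) {
  n <- as_count(n, "n")
  stop_if(n < 10L, "n must be >= 10")
  pc <- list(a1 = 0, a2 = 0, b1 = 0, b2 = 0, c = 0)
  pc[names(path_coeffs)] <- path_coeffs
  stop_if(!all(vapply(pc, is.finite, logical(1))), "path coefficients must be finite")
  if (is.null(noise_sds)) {
    if (standardize) {
      v1 <- 1 - pc$a1^2; v2 <- 1 - pc$a2^2
      stop_if(v1 <= 0 || v2 <= 0, "|a1|, |a2| must be < 1 to standardize")
      expl <- pc$b1^2 + pc$b2^2 + pc$c^2 +
        2 * pc$b1 * pc$b2 * pc$a1 * pc$a2 +
        2 * pc$b1 * pc$c * pc$a1 + 2 * pc$b2 * pc$c * pc$a2
      stop_if(expl >= 1, "output variance explained (%.3f) must be < 1 to standardize", expl)
      noise_sds <- c(input = 1, mediator1 = sqrt(v1), mediator2 = sqrt(v2),
                     output = sqrt(1 - expl))
    } else {
      noise_sds <- c(input = 1, mediator1 = 1, mediator2 = 1, output = 1)
    }
  }
  sd_of <- function(v) { s <- noise_sds[[v]]; stop_if(is.null(s) || s < 0,
    "noise_sds must include a non-negative '%s'", v); s }
  with_seed(seed, {
    input <- stats::rnorm(n, 0, sd_of("input"))
    m1 <- pc$a1 * input + stats::rnorm(n, 0, sd_of("mediator1"))
    m2 <- pc$a2 * input + stats::rnorm(n, 0, sd_of("mediator2"))
    output <- pc$b1 * m1 + pc$b2 * m2 + pc$c * input +
      stats::rnorm(n, 0, sd_of("output"))
    out <- data.frame(input = input, mediator1 = m1, mediator2 = m2,
                      output = output)
    attr(out, "path_coeffs") <- pc
    out
  })
}
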