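#' Select one channel per (area, layer) group by theta power
#'
#' The directed-connectivity stage uses one channel per area and layer,
#' chosen as the channel with the highest theta-band (4-7 Hz) mean power
#' within the group. Exact ties resolve deterministically to the channel
#' listed first in the channel table.
#'
#' @param power a [multitaper_power()] result.
#' @param area,layer group labels to select within.
#' @param bands band table used to locate theta (default mouse preset).
#' @return the selected channel id (character).
#' @export
select_channel_by_theta <- function(power, area, layer,
                                    bands = band_preset("mouse")) {
  stopifnot(inherits(power, "power_spectrum"))
  grp <- which(power$channels$area == area & power$channels$layer == layer)
  stop_if(length(grp) == 0L, "no channels in group (%s, %s)", area, layer)
  bm <- band_average(power, bands)
  theta <- bm[grp, "theta"]
  power$channels$id[grp[which.max(theta)]]
}

as_series <- function(x) {
  if (inherits(x, "recording")) {
    list(x = x$signal, fs = x$fs, ids = x$channels$id)
  } else {
    stopifnot(is.matrix(x))
    ids <- rownames(x) %||% paste0("ch", seq_len(nrow(x)))
    list(x = x, fs = NULL, ids = ids)
  }
}

# lagged design for VAR(p): rows t = p+1..n; column (r-1)*k + j holds
# x_j(t - r)
var_design <- function(x, p) {
  k <- nrow(x); n <- ncol(x)
  Y <- t(x[, (p + 1L):n, drop = FALSE])
  X <- matrix(0, n - p, k * p)
  for (r in seq_len(p)) {
    X[, (r - 1L) * k + seq_len(k)] <- t(x[, (p + 1L - r):(n - r), drop = FALSE])
  }
  list(Y = Y, X = X)
}

#' Select a VAR model order by AIC
#'
#' Fits a stationary VAR for each order `p` in `1..p_max` on the full
#' series and returns the order minimizing
#' `log det(Sigma_hat) + 2 p k^2 / N`; ties go to the smaller order.
#'
#' @param x numeric matrix `k x n` (or a [recording()]).
#' @param p_max largest order tried (default 20).
#' @return integer order.
#' @export
select_var_order <- function(x, p_max = 20L) {
  s <- as_series(x)
  k <- nrow(s$x); n <- ncol(s$x)
  aic <- vapply(seq_len(p_max), function(p) {
    d <- var_design(s$x, p)
    fit <- stats::lm.fit(d$X, d$Y)
    res <- as.matrix(fit$residuals)
    Sig <- crossprod(res) / nrow(res)
    determinant(Sig, logarithm = TRUE)$modulus + 2 * p * k^2 / nrow(res)
  }, numeric(1))
  which.min(aic)
}

#' Sliding-window vector autoregressive fit
#'
#' Ordinary-least-squares VAR estimates in sliding windows (default 2-s
#' windows, 0.5-s step), the time-varying coefficient sequence behind the
#' time-resolved partial directed coherence. Intended for series already
#' downsampled to ~200 Hz. Windows whose companion matrix is unstable
#' (spectral radius >= 1) trigger a warning, not an error.
#'
#' @param x numeric matrix `k x n`, or a [recording()].
#' @param order VAR order `p`, or `"auto"` for AIC selection via
#'   [select_var_order()].
#' @param window_s,step_s window length and hop in seconds.
#' @param fs sampling rate; taken from the recording if omitted.
#' @param check_stability compute the per-window companion spectral
#'   radius and warn about unstable windows (default TRUE; surrogate
#'   refits skip it).
#' @return An object of class `"tvar_model"`: list with `A` (array
#'   windows x p x k x k), `sigma` (array windows x k x k), `centers_s`,
#'   `order`, `fs`, `k`, `ids`.
#' @export
fit_tvar <- function(x, order = "auto", window_s = 2, step_s = 0.5, fs = NULL,
                     check_stability = TRUE) {
  s <- as_series(x)
  fs <- fs %||% s$fs
  stop_if(is.null(fs), "fs must be supplied for a plain matrix input")
  k <- nrow(s$x); n <- ncol(s$x)
  p <- if (identical(order, "auto")) select_var_order(s$x) else
    as_count(order, "order")
  Lw <- as_count(window_s * fs, "window_s * fs")
  step <- as_count(step_s * fs, "step_s * fs")
  stop_if(Lw <= 3 * k * p, "window of %d samples too short for k=%d, p=%d (need > %d)",
          Lw, k, p, 3 * k * p)
  stop_if(n < Lw + p, "series shorter than one window")
  d <- var_design(s$x, p)
  starts <- seq(1L, nrow(d$X) - Lw + 1L, by = step)
  W <- length(starts)
  A <- array(0, c(W, p, k, k))
  Sg <- array(0, c(W, k, k))
  unstable <- 0L
  for (w in seq_len(W)) {
    rows <- starts[w]:(starts[w] + Lw - 1L)
    Xw <- d$X[rows, , drop = FALSE]
    # normal equations when well-conditioned (fast path); otherwise
    # truncated-SVD least squares, which drops directions with
    # negligible singular value (minimum-norm solution) -- strongly
    # low-pass content and notch nulls make lagged copies nearly
    # collinear, and inverting those directions would amplify noise
    Yw <- d$Y[rows, , drop = FALSE]
    XtX <- crossprod(Xw)
    B <- tryCatch({
      R <- chol(XtX)
      rc <- 1 / kappa(R, norm = "1")
      if (rc < 1e-10) stop("ill-conditioned")
      backsolve(R, forwardsolve(t(R), crossprod(Xw, Yw)))
    }, error = function(e) {
      sv <- svd(Xw)
      pos <- sv$d > 1e-10 * sv$d[1]
      stop_if(!any(pos), "rank-deficient regressor matrix in window %d", w)
      sv$v[, pos, drop = FALSE] %*%
        (crossprod(sv$u[, pos, drop = FALSE], Yw) / sv$d[pos])
    })
    res <- d$Y[rows, , drop = FALSE] - Xw %*% B
    Sg[w, , ] <- crossprod(res) / (Lw - k * p)
    for (r in seq_len(p)) {
      A[w, r, , ] <- t(B[(r - 1L) * k + seq_len(k), , drop = FALSE])
    }
    if (check_stability &&
        var_spectral_radius(array(A[w, , , ], c(p, k, k))) >= 1) {
      unstable <- unstable + 1L
    }
  }
  if (unstable > 0L) {
    warning(sprintf("%d of %d windows have an unstable companion matrix", unstable, W))
  }
  structure(list(A = A, sigma = Sg,
                 centers_s = (starts - 1L + p + Lw / 2) / fs,
                 order = p, fs = fs, k = k, ids = s$ids,
                 window_s = window_s, step_s = step_s),
            class = "tvar_model")
}

#' @export
print.tvar_model <- function(x, ...) {
  cat(sprintf("<tvar_model> k=%d channels, order p=%d, %d windows of %g s (step %g s) @ %g Hz\n",
              x$k, x$order, dim(x$A)[1], x$window_s, x$step_s, x$fs))
  invisible(x)
}

#' @export
coef.tvar_model <- function(object, ...) {
  apply(object$A, c(2, 3, 4), mean)      # time-averaged p x k x k
}

#' Partial directed coherence from VAR coefficients
#'
#' With `Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs)`, the partial
#' directed coherence from channel `j` to channel `i` is
#' `PDC(i<-j, f) = |Abar_ij(f)| / sqrt(sum_m |Abar_mj(f)|^2)`.
#' Values lie in [0, 1] and each column's squares sum to 1 exactly
#' (the outflow normalization of the measure).
#'
#' @param A coefficient array `p x k x k` (row = target, column = source),
#'   or a `k x k` matrix for p = 1.
#' @param f_hz frequencies (Hz), vector allowed.
#' @param fs_hz sampling rate of the series the coefficients were fit at.
#' @return array `length(f_hz) x k x k`; `[f, i, j]` is `PDC(i<-j)`.
#'   A `k x k` matrix if `f_hz` is scalar.
#' @export
pdc_from_coefficients <- function(A, f_hz, fs_hz) {
  A <- as_var_coeffs(A)
  stop_if(!all(is.finite(A)), "coefficients must be finite")
  p <- dim(A)[1]; k <- dim(A)[2]
  nf <- length(f_hz)
  E <- exp(-2i * pi * outer(f_hz, seq_len(p)) / fs_hz)   # nf x p
  Amat <- matrix(aperm(A, c(1, 2, 3)), nrow = p)          # p x (k*k), col (j-1)k+i
  Abar <- -(E %*% Amat)                                   # nf x k^2
  diag_cols <- (seq_len(k) - 1L) * k + seq_len(k)
  Abar[, diag_cols] <- Abar[, diag_cols] + 1
  a2 <- Re(Abar)^2 + Im(Abar)^2                           # nf x k^2
  denom <- matrix(0, nf, k * k)                           # sum over targets i
  for (j in seq_len(k)) {
    cols <- (j - 1L) * k + seq_len(k)
    denom[, cols] <- rowSums(a2[, cols, drop = FALSE])
  }
  pdc <- sqrt(a2 / denom)
  pdc[!is.finite(pdc)] <- 0
  dim(pdc) <- c(nf, k, k)                                 # [f, i, j]
  if (nf == 1L) {
    pdc <- array(pdc, c(k, k))
  }
  pdc
}

#' Time-resolved partial directed coherence
#'
#' Evaluates the PDC of every window of a [fit_tvar()] model on a
#' frequency grid, averages over windows, then over the bins of each
#' frequency band: one scalar per ordered channel pair per band.
#'
#' @param model a [fit_tvar()] result.
#' @param bands a [band_table()].
#' @param freq_step_hz evaluation grid step (default 0.5 Hz).
#' @param fmax_hz upper edge of the grid (default 100 Hz, capped below
#'   Nyquist).
#' @return An object of class `"tpdc_result"`: list with `freq`,
#'   `pdc_freq` (window-averaged, nf x k x k), `band` (named list of
#'   k x k matrices, `[i, j]` = influence j -> i), `pairs` (long
#'   data.frame `source`, `target`, `band`, `tpdc`), `ids`.
#' @export
tpdc <- function(model, bands = band_preset("mouse"),
                 freq_step_hz = 0.5, fmax_hz = 100) {
  stopifnot(inherits(model, "tvar_model"), inherits(bands, "band_table"))
  fmax <- min(fmax_hz, model$fs / 2 - 1e-9)
  f <- seq(freq_step_hz, fmax, by = freq_step_hz)
  W <- dim(model$A)[1]; p <- model$order; k <- model$k
  acc <- array(0, c(length(f), k, k))
  for (w in seq_len(W)) {
    acc <- acc + pdc_from_coefficients(array(model$A[w, , , ], c(p, k, k)),
                                       f, model$fs)
  }
  acc <- acc / W
  band_list <- list()
  rows <- list()
  for (b in seq_len(nrow(bands))) {
    hi <- min(bands$upper[b], bands$high[b] + freq_step_hz)
    sel <- f >= bands$low[b] & f < hi
    stop_if(!any(sel), "band '%s' has no bins on the evaluation grid (0, %g] Hz",
            bands$name[b], fmax)
    M <- apply(acc[sel, , , drop = FALSE], c(2, 3), mean)
    dimnames(M) <- list(model$ids, model$ids)
    band_list[[bands$name[b]]] <- M
    for (j in seq_len(k)) for (i in seq_len(k)) {
      if (i == j) next
      rows[[length(rows) + 1L]] <- data.frame(
        source = model$ids[j], target = model$ids[i],
        band = bands$name[b], tpdc = M[i, j], stringsAsFactors = FALSE)
    }
  }
  structure(list(freq = f, pdc_freq = acc, band = band_list,
                 pairs = do.call(rbind, rows), ids = model$ids,
                 order = p, fs = model$fs),
            class = "tpdc_result")
}

#' @export
print.tpdc_result <- function(x, ...) {
  cat(sprintf("<tpdc_result> k=%d channels, %d bands, order p=%d\n",
              length(x$ids), length(x$band), x$order))
  top <- x$pairs[order(-x$pairs$tpdc), ][seq_len(min(5L, nrow(x$pairs))), ]
  cat("  strongest influences:\n")
  for (r in seq_len(nrow(top))) {
    cat(sprintf("    %s -> %s [%s] %.3f\n", top$source[r], top$target[r],
                top$band[r], top$tpdc[r]))
  }
  invisible(x)
}

# band-resolved TPDC matrices for a series, fitting the TVAR internally;
# shared by time_reversal_test
tpdc_band_matrices <- function(x, fs, order, bands, window_s, step_s,
                               freq_step_hz, fmax_hz) {
  m <- fit_tvar(x, order = order, window_s = window_s, step_s = step_s,
                fs = fs, check_stability = FALSE)
  tpdc(m, bands, freq_step_hz, fmax_hz)$band
}

#' Time-reversal significance test for directed influence
#'
#' For each unordered channel pair and band, the directional asymmetry
#' `delta = TPDC(a -> b) - TPDC(b -> a)` is computed on the forward data,
#' on the time-reversed data, and on block-shuffled surrogates. A directed
#' edge is significant iff `|delta|` exceeds the surrogate-calibrated
#' `(1 - alpha)` quantile of `|delta|` under the null *and* `delta`
#' reverses sign when the series is time-reversed. A genuinely lagged
#' (causal) interaction flips under time reversal; purely instantaneous
#' mixing (volume conduction) does not, so it is screened out.
#'
#' @param x numeric matrix `k x n` or a [recording()] (downsampled to the
#'   TVAR working rate, typically 200 Hz).
#' @param fs sampling rate (taken from the recording if omitted).
#' @param bands a [band_table()].
#' @param order VAR order, or `"auto"` (selected once on the forward
#'   series, then fixed for every refit).
#' @param window_s,step_s sliding-window parameters, see [fit_tvar()].
#' @param n_surr number of block-shuffle surrogates for the asymmetry
#'   threshold (default 19, matching alpha = 0.05).
#' @param alpha significance level (default 0.05).
#' @param block_s surrogate block length (s).
#' @param seed integer RNG seed for the surrogates.
#' @param freq_step_hz,fmax_hz PDC evaluation grid.
#' @return data.frame of class `"trt_result"`: `a`, `b`, `band`, `delta`
#'   (TPDC(a->b) - TPDC(b->a)), `rev_delta`, `threshold`, `significant`,
#'   `direction` (`"a->b"`, `"b->a"`, or `NA` when not significant).
#' @export
time_reversal_test <- function(x, fs = NULL, bands = band_preset("mouse"),
                               order = "auto", window_s = 2, step_s = 0.5,
                               n_surr = 19L, alpha = 0.05, block_s = 0.5,
                               seed = NULL, freq_step_hz = 0.5, fmax_hz = 100) {
  s <- as_series(x)
  fs <- fs %||% s$fs
  stop_if(is.null(fs), "fs must be supplied for a plain matrix input")
  k <- nrow(s$x)
  p <- if (identical(order, "auto")) select_var_order(s$x) else
    as_count(order, "order")
  Tf <- tpdc_band_matrices(s$x, fs, p, bands, window_s, step_s,
                           freq_step_hz, fmax_hz)
  Tr <- tpdc_band_matrices(s$x[, ncol(s$x):1, drop = FALSE], fs, p, bands,
                           window_s, step_s, freq_step_hz, fmax_hz)
  block_len <- as_count(block_s * fs, "block_s * fs")
  Tsurr <- with_seed(seed, {
    lapply(seq_len(n_surr), function(i) {
      xs <- s$x
      for (ch in seq_len(k)) xs[ch, ] <- block_shuffle(xs[ch, ], block_len)
      tpdc_band_matrices(xs, fs, p, bands, window_s, step_s,
                         freq_step_hz, fmax_hz)
    })
  })
  rows <- list()
  for (bn in names(Tf)) {
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      # delta > 0: influence a -> b dominates
      d_f <- Tf[[bn]][b, a] - Tf[[bn]][a, b]
      d_r <- Tr[[bn]][b, a] - Tr[[bn]][a, b]
      d_s <- vapply(Tsurr, function(Ts) abs(Ts[[bn]][b, a] - Ts[[bn]][a, b]),
                    numeric(1))
      thr <- stats::quantile(d_s, probs = 1 - alpha, type = 1, names = FALSE)
      sig <- abs(d_f) > thr && sign(d_r) == -sign(d_f) && d_f != 0
      rows[[length(rows) + 1L]] <- data.frame(
        a = s$ids[a], b = s$ids[b], band = bn,
        delta = d_f, rev_delta = d_r, threshold = thr,
        significant = sig,
        direction = if (!sig) NA_character_ else
          if (d_f > 0) sprintf("%s->%s", s$ids[a], s$ids[b]) else
            sprintf("%s->%s", s$ids[b], s$ids[a]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "order") <- p
  attr(out, "alpha") <- alpha
  class(out) <- c("trt_result", "data.frame")
  out
}
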