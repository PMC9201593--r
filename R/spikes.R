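#' Detect spikes by negative-amplitude thresholding
#'
#' Local minima below `-threshold_sd * sigma` with a 1-ms dead time;
#' events whose trough magnitude exceeds `artifact_sd * sigma` are
#' treated as artifacts and excluded, as are events too close to the
#' trace edges for a full waveform. The noise scale `sigma` is by default
#' the robust estimate `median(|x|) / 0.6745`, which is not inflated by
#' the spikes themselves; `noise_sd = "raw"` uses the plain SD of the
#' trace instead.
#'
#' The input trace is expected to be band-passed to the spike band
#' (0.3-3 kHz) beforehand; see [butterworth_filter()].
#'
#' @param trace numeric wide-band (filtered) trace.
#' @param fs_hz sampling rate (Hz), >= 20000 for the standard -0.5/+3-ms
#'   waveform window.
#' @param threshold_sd detection threshold in noise SDs (default 5).
#' @param artifact_sd artifact exclusion threshold in noise SDs
#'   (default 30).
#' @param refractory_ms detector dead time after an accepted event
#'   (default 1 ms).
#' @param noise_sd `"robust"` (default) or `"raw"`.
#' @return An object of class `"spike_events"`: list with `times_s`,
#'   `index`, `amplitude`, `waveforms` (events x samples, spanning -0.5 to
#'   +3 ms around the trough, trough at the -0.5-ms offset position),
#'   `sigma`, `fs_hz`, `n_artifacts`, `duration_s`.
#' @export
detect_spikes <- function(trace, fs_hz, threshold_sd = 5, artifact_sd = 30,
                          refractory_ms = 1, noise_sd = c("robust", "raw")) {
  noise_sd <- match.arg(noise_sd)
  pre <- round(0.0005 * fs_hz)
  post <- round(0.003 * fs_hz)
  wlen <- pre + post              # = round(3.5 ms * fs)
  stop_if(length(trace) < wlen + 1L,
          "trace shorter than one waveform window (%d samples)", wlen)
  sigma <- if (noise_sd == "robust") robust_sigma(trace) else stats::sd(trace)
  thr <- -threshold_sd * sigma
  dead <- max(1L, round(refractory_ms / 1000 * fs_hz))
  n <- length(trace)
  below <- which(trace < thr)
  below <- below[below > 1L & below < n]
  # local minima among threshold crossings
  cand <- below[trace[below] <= trace[below - 1L] & trace[below] < trace[below + 1L]]
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= dead) { keep <- c(keep, i); last <- i }
  }
  # full waveform must fit
  keep <- keep[keep - pre >= 1L & keep + post - 1L <= n]
  amp <- trace[keep]
  artifact <- abs(amp) > artifact_sd * sigma
  n_artifacts <- sum(artifact)
  keep <- keep[!artifact]
  amp <- amp[!artifact]
  # sub-sample trough alignment: the trough position is refined on a
  # dense cubic-spline grid (robust even for broad, flat troughs where a
  # 3-point parabola is noise-dominated) and the waveform is resampled
  # on the aligned grid. Without this, sampling jitter splits one unit
  # into several feature-space clouds.
  wf <- if (length(keep)) {
    t(vapply(keep, function(i) {
      lo <- max(1L, i - pre - 4L); hi <- min(n, i + post + 4L)
      sf <- stats::splinefun(lo:hi, trace[lo:hi], method = "natural")
      fine <- seq(max(lo, i - 3), min(hi, i + 3), by = 0.05)
      delta <- fine[which.min(sf(fine))] - i
      delta <- max(-2, min(2, delta))
      sf((i - pre):(i + post - 1L) + delta)
    }, numeric(wlen)))
  } else matrix(0, 0L, wlen)
  structure(list(times_s = (keep - 1L) / fs_hz, index = keep,
                 amplitude = amp, waveforms = wf, sigma = sigma,
                 fs_hz = fs_hz, threshold_sd = threshold_sd,
                 artifact_sd = artifact_sd, n_artifacts = n_artifacts,
                 duration_s = n / fs_hz),
            class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> %d events over %.4g s (%.2f Hz), sigma=%.3g, %d artifacts excluded\n",
              length(x$times_s), x$duration_s,
              length(x$times_s) / x$duration_s, x$sigma, x$n_artifacts))
  invisible(x)
}

# orthonormal Haar DWT; length is padded (edge value) to a multiple of
# 2^levels. Returns details (finest first) followed by the approximation.
haar_dwt <- function(x, levels = 4L) {
  m <- 2L^levels
  if (length(x) %% m != 0L) {
    x <- c(x, rep(x[length(x)], m - length(x) %% m))
  }
  out <- numeric(0)
  a <- x
  for (l in seq_len(levels)) {
    ev <- a[seq(1L, length(a), 2L)]
    od <- a[seq(2L, length(a), 2L)]
    out <- c(out, (ev - od) / sqrt(2))
    a <- (ev + od) / sqrt(2)
  }
  c(out, a)
}

# Kolmogorov-Smirnov deviation of a sample from a Gaussian with matched
# moments; coefficients that deviate most from normality are the ones
# that separate units (multimodality shows up as KS deviation)
ks_deviation <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s < .Machine$double.eps) return(0)
  as.numeric(suppressWarnings(
    stats::ks.test(v, "pnorm", mean(v), s)$statistic))
}

#' Wavelet feature extraction with KS normality ranking
#'
#' 4-level Haar wavelet decomposition of each spike waveform; coefficients
#' are ranked by the Kolmogorov-Smirnov deviation of their across-event
#' distribution from a fitted Gaussian, and the top `n_features` are
#' retained. Constant coefficients have KS deviation 0 and are never
#' selected ahead of informative ones.
#'
#' @param events a [detect_spikes()] result, or a plain waveform matrix
#'   (events x samples).
#' @param n_features number of coefficients kept (default 10); needs at
#'   least `2 * n_features` events.
#' @param levels wavelet decomposition depth (default 4).
#' @return numeric matrix events x n_features, attribute `"selected"`
#'   giving the retained coefficient indices and `"ks"` their KS
#'   statistics.
#' @export
extract_features <- function(events, n_features = 10L, levels = 4L) {
  wf <- if (inherits(events, "spike_events")) events$waveforms else as.matrix(events)
  n <- nrow(wf)
  n_features <- as_count(n_features, "n_features")
  stop_if(n < 2L * n_features,
          "need >= %d events for %d features (got %d)", 2L * n_features,
          n_features, n)
  coefs <- t(apply(wf, 1L, haar_dwt, levels = levels))
  ks <- apply(coefs, 2L, ks_deviation)
  if (all(ks == 0)) warning("all coefficients degenerate (identical waveforms?)")
  sel <- order(ks, decreasing = TRUE)[seq_len(n_features)]
  out <- coefs[, sel, drop = FALSE]
  colnames(out) <- paste0("w", sel)
  attr(out, "selected") <- sel
  attr(out, "ks") <- ks[sel]
  out
}

#' Super-paramagnetic clustering of spike features
#'
#' Swendsen-Wang Monte-Carlo simulation of a q-state Potts model on the
#' K-nearest-neighbour graph of the feature vectors. At each temperature,
#' spin-spin pair correlations are estimated across sweeps; edges with
#' correlation > 0.5 define clusters. The working temperature is the
#' lowest temperature on the grid attaining the maximal number of
#' clusters with at least `min_cluster` members: the entry into the most
#' resolved super-paramagnetic plateau, where every genuinely dense
#' group has come apart from the others but none has yet eroded into
#' dust. Events in no retained cluster are left unassigned (0).
#'
#' @param features numeric matrix events x features (see
#'   [extract_features()]).
#' @param temperatures temperature grid (default `seq(0, 0.2, 0.005)`;
#'   narrow super-paramagnetic windows between cluster splitting and
#'   erosion can be missed on a coarser grid).
#' @param k_neighbors K for the neighbour graph (default 11).
#' @param min_cluster minimum cluster size (default 20); with fewer
#'   events than this, everything is unassigned.
#' @param q Potts states (default 20).
#' @param n_sweeps Monte-Carlo sweeps per temperature (default 150).
#' @param burn_in sweeps discarded before correlations are accumulated.
#' @param valley_threshold decision level of the density-valley
#'   statistic (pooled kernel density at the midpoint between two
#'   clusters' projected modes, relative to the density at the modes):
#'   cluster pairs above it are merged as fragments of one dense group,
#'   and a cluster whose 2-means bipartition scores below it is split
#'   into two units. Default 0.5; genuine unit pairs measure <= ~0.25
#'   and cuts through one cloud >= ~0.85.
#' @param force_assign after the cluster cores are fixed at the working
#'   temperature, attach out-of-core events to the nearest core centroid
#'   when they fall within that core's own feature-space spread (the
#'   force-membership step of standard spike sorters); events beyond
#'   every core's gate stay unassigned. Default TRUE.
#' @param seed integer RNG seed for the Monte-Carlo iteration.
#' @return An object of class `"spc_clustering"`: list with `assignments`
#'   (integer per event; 0 = unassigned), `working_temp`, `temps`,
#'   `size_by_temp` (largest cluster size per temperature), `n_clusters`.
#' @export
spc_cluster <- function(features, temperatures = seq(0, 0.2, by = 0.005),
                        k_neighbors = 11L, min_cluster = 20L, q = 20L,
                        n_sweeps = 150L, burn_in = 20L, force_assign = TRUE,
                        valley_threshold = 0.5, seed = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < min_cluster) {
    return(structure(list(assignments = rep(0L, n), working_temp = NA_real_,
                          temps = temperatures, size_by_temp = NULL,
                          n_clusters = 0L),
                     class = "spc_clustering"))
  }
  D <- as.matrix(stats::dist(features))
  kk <- min(k_neighbors, n - 1L)
  edges <- matrix(0L, 0L, 2L)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(kk + 1L)]
    edges <- rbind(edges, cbind(i, nb))
  }
  # symmetrize to an undirected edge set
  e <- unique(t(apply(edges, 1L, sort)))
  d <- D[e]
  a <- mean(d)
  khat <- 2 * nrow(e) / n
  J <- (1 / khat) * exp(-d^2 / (2 * a^2))
  with_seed(seed, {
    assign_at <- vector("list", length(temperatures))
    max_size <- numeric(length(temperatures))
    for (ti in seq_along(temperatures)) {
      Tt <- temperatures[ti]
      s <- sample.int(q, n, replace = TRUE)
      p_freeze <- if (Tt <= 0) rep(1, nrow(e)) else 1 - exp(-J / Tt)
      corr <- numeric(nrow(e))
      n_acc <- 0L
      for (sw in seq_len(n_sweeps)) {
        same <- s[e[, 1L]] == s[e[, 2L]]
        frozen <- same & (stats::runif(nrow(e)) < p_freeze)
        g <- igraph::graph_from_edgelist(e[frozen, , drop = FALSE],
                                         directed = FALSE)
        g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
        comp <- igraph::components(g)$membership[seq_len(n)]
        s <- sample.int(q, max(comp), replace = TRUE)[comp]
        if (sw > burn_in) {
          corr <- corr + (s[e[, 1L]] == s[e[, 2L]])
          n_acc <- n_acc + 1L
        }
      }
      corr <- corr / n_acc
      linked <- corr > 0.5
      g <- igraph::graph_from_edgelist(e[linked, , drop = FALSE],
                                       directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
      comp <- igraph::components(g)$membership[seq_len(n)]
      assign_at[[ti]] <- comp
      max_size[ti] <- max(tabulate(comp))
    }
    n_big <- vapply(assign_at, function(comp)
      sum(tabulate(comp) >= min_cluster), integer(1))
    if (max(n_big) == 0L) {
      return(structure(list(assignments = rep(0L, n), working_temp = NA_real_,
                            temps = temperatures, size_by_temp = max_size,
                            n_clusters = 0L),
                       class = "spc_clustering"))
    }
    # working temperature: the lowest temperature attaining the maximal
    # number of clusters >= min_cluster -- the entry into the most
    # resolved super-paramagnetic plateau, where every dense group has
    # come apart but none has yet eroded toward dust
    ti <- which.max(n_big)
    comp <- assign_at[[ti]]
    sizes <- tabulate(comp)
    good <- which(sizes >= min_cluster)
    assignments <- integer(n)
    for (u in seq_along(good)) assignments[comp == good[u]] <- u
    assignments <- spc_split_clusters(features, assignments, valley_threshold,
                                      min_cluster)
    assignments <- spc_merge_cores(features, assignments, valley_threshold)
    if (force_assign && any(assignments > 0L)) {
      assignments <- spc_force_membership(features, assignments)
    }
    structure(list(assignments = assignments,
                   working_temp = temperatures[ti], temps = temperatures,
                   size_by_temp = max_size,
                   n_clusters = length(unique(assignments[assignments > 0L]))),
              class = "spc_clustering")
  })
}

# valley statistic deciding whether two event sets are distinct units:
# both sets are projected onto the axis joining their centroids and the
# pooled kernel density is compared at the midpoint between the two
# projected means versus at the means themselves. Two genuine units
# leave a deep density valley between their modes (ratio near 0); any
# boundary cut through a single cloud leaves none (ratio near 1),
# regardless of how the boundary truncates the two sides.
spc_valley <- function(features, ia, ib) {
  mu1 <- colMeans(features[ia, , drop = FALSE])
  mu2 <- colMeans(features[ib, , drop = FALSE])
  u <- mu1 - mu2
  nu <- sqrt(sum(u^2))
  if (nu < .Machine$double.eps) return(1)
  u <- u / nu
  p1 <- features[ia, , drop = FALSE] %*% u
  p2 <- features[ib, , drop = FALSE] %*% u
  den <- stats::density(c(p1, p2))
  at <- function(x) stats::approx(den$x, den$y, x, rule = 2)$y
  at((mean(p1) + mean(p2)) / 2) /
    max(min(at(mean(p1)), at(mean(p2))), .Machine$double.eps)
}

# split clusters whose optimal bipartition reveals a deep density
# valley: the KNN Potts dynamics cannot resolve two units whose clouds
# touch, but their 2-means bipartition then shows the bimodality
spc_split_clusters <- function(features, assignments, valley_threshold,
                               min_cluster) {
  repeat {
    changed <- FALSE
    for (u in sort(unique(assignments[assignments > 0L]))) {
      idx <- which(assignments == u)
      if (length(idx) < 2L * min_cluster) next
      km <- stats::kmeans(features[idx, , drop = FALSE], 2L, nstart = 10)
      ia <- idx[km$cluster == 1L]; ib <- idx[km$cluster == 2L]
      if (length(ia) < min_cluster || length(ib) < min_cluster) next
      if (spc_valley(features, ia, ib) < valley_threshold) {
        assignments[ib] <- max(assignments) + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  assignments
}

# merge cluster pairs with no density valley between them (Monte-Carlo
# fragments of one dense group)
spc_merge_cores <- function(features, assignments, valley_threshold) {
  repeat {
    ids <- sort(unique(assignments[assignments > 0L]))
    if (length(ids) < 2L) break
    best <- NULL; best_ratio <- -Inf
    for (a in seq_along(ids)[-length(ids)]) for (b in (a + 1L):length(ids)) {
      ratio <- spc_valley(features, which(assignments == ids[a]),
                          which(assignments == ids[b]))
      if (ratio > best_ratio) { best_ratio <- ratio; best <- c(a, b) }
    }
    if (best_ratio <= valley_threshold) break
    assignments[assignments == ids[best[2]]] <- ids[best[1]]
  }
  # relabel compactly by decreasing size
  ids <- sort(unique(assignments[assignments > 0L]))
  if (length(ids)) {
    sz <- vapply(ids, function(u) sum(assignments == u), integer(1))
    new <- integer(length(assignments))
    for (u in seq_along(ids[order(-sz)])) {
      new[assignments == ids[order(-sz)][u]] <- u
    }
    assignments <- new
  }
  assignments
}

# attach events outside the super-paramagnetic cluster cores to the
# nearest core centroid, if they fall within the core's own spread
# (distance <= the core's 99th-percentile member distance * 1.1);
# points farther than every core's gate stay unassigned
spc_force_membership <- function(features, assignments) {
  ids <- sort(unique(assignments[assignments > 0L]))
  cent <- lapply(ids, function(u)
    colMeans(features[assignments == u, , drop = FALSE]))
  gate <- vapply(seq_along(ids), function(ui) {
    d <- sqrt(rowSums(sweep(features[assignments == ids[ui], , drop = FALSE],
                            2L, cent[[ui]])^2))
    stats::quantile(d, 0.99, names = FALSE) * 1.1
  }, numeric(1))
  for (i in which(assignments == 0L)) {
    d <- vapply(seq_along(ids), function(ui)
      sqrt(sum((features[i, ] - cent[[ui]])^2)), numeric(1))
    best <- which.min(d)
    if (d[best] <= gate[best]) assignments[i] <- ids[best]
  }
  assignments
}

#' @export
print.spc_clustering <- function(x, ...) {
  cat(sprintf("<spc_clustering> %d clusters at T=%.3g; %d/%d events assigned\n",
              x$n_clusters, x$working_temp, sum(x$assignments > 0L),
              length(x$assignments)))
  invisible(x)
}

#' Assemble unit clusters from events and assignments
#'
#' @param events a [detect_spikes()] result.
#' @param assignments integer vector from [spc_cluster()] (0 =
#'   unassigned).
#' @return list of class `"unit_clusters"`; each element has `id`,
#'   `times_s`, `amplitude`, `mean_waveform`, `n`, `firing_rate_hz`.
#' @export
unit_clusters <- function(events, assignments) {
  stopifnot(inherits(events, "spike_events"),
            length(assignments) == length(events$times_s))
  ids <- sort(unique(assignments[assignments > 0L]))
  units <- lapply(ids, function(u) {
    sel <- assignments == u
    list(id = u, times_s = events$times_s[sel],
         amplitude = events$amplitude[sel],
         mean_waveform = colMeans(events$waveforms[sel, , drop = FALSE]),
         n = sum(sel),
         firing_rate_hz = sum(sel) / events$duration_s)
  })
  structure(units, class = "unit_clusters",
            duration_s = events$duration_s,
            n_unassigned = sum(assignments == 0L))
}

#' @export
print.unit_clusters <- function(x, ...) {
  cat(sprintf("<unit_clusters> %d units (%d events unassigned)\n",
              length(x), attr(x, "n_unassigned")))
  for (u in x) {
    cat(sprintf("  unit %d: %d spikes, %.2f Hz, trough %.3g\n",
                u$id, u$n, u$firing_rate_hz, min(u$mean_waveform)))
  }
  invisible(x)
}

#' Single-unit quality screen
#'
#' Drops units that are incompletely separated or unstable: a unit is
#' rejected if its inter-spike-interval refractory violations exceed
#' `max_violation_frac`, or if its mean trough amplitude in the first and
#' second half of the recording differs by more than `max_drift_frac`
#' (drift / instability).
#'
#' @param units a [unit_clusters()] list.
#' @param refractory_ms refractory period (default 1 ms).
#' @param max_violation_frac maximum tolerated ISI-violation fraction
#'   (default 0.02).
#' @param max_drift_frac maximum tolerated first-half vs second-half
#'   amplitude change (default 0.30).
#' @return A `"unit_clusters"` list containing only the retained units;
#'   attribute `"quality"` is a data.frame of the per-unit measurements
#'   and decisions.
#' @export
quality_filter <- function(units, refractory_ms = 1,
                           max_violation_frac = 0.02,
                           max_drift_frac = 0.30) {
  stopifnot(inherits(units, "unit_clusters"))
  dur <- attr(units, "duration_s")
  rows <- lapply(units, function(u) {
    viol <- if (u$n < 2L) 0 else
      mean(diff(sort(u$times_s)) < refractory_ms / 1000)
    half <- dur / 2
    a1 <- mean(abs(u$amplitude[u$times_s < half]))
    a2 <- mean(abs(u$amplitude[u$times_s >= half]))
    drift <- if (!is.finite(a1) || !is.finite(a2)) Inf else
      abs(a1 - a2) / mean(c(a1, a2))
    data.frame(id = u$id, n = u$n, isi_violation_frac = viol,
               amplitude_drift_frac = drift,
               keep = viol <= max_violation_frac && drift <= max_drift_frac)
  })
  qc <- do.call(rbind, rows)
  kept <- units[qc$keep]
  structure(kept, class = "unit_clusters",
            duration_s = dur, n_unassigned = attr(units, "n_unassigned"),
            quality = qc)
}

#' Firing rate of a unit
#'
#' @param cluster a single unit (element of [unit_clusters()]) or a spike
#'   count.
#' @param duration_s recording duration (s), > 0.
#' @return rate in Hz (`count / duration`).
#' @examples
#' firing_rate(436, 600)   # 0.7267 Hz
#' @export
firing_rate <- function(cluster, duration_s) {
  stop_if(duration_s <= 0, "duration_s must be > 0")
  n <- if (is.list(cluster)) cluster$n else as.numeric(cluster)
  n / duration_s
}

#' Full spike-sorting pipeline on one channel
#'
#' Convenience wrapper: band-pass to the spike band, detect, extract
#' features, cluster, screen quality.
#'
#' @param trace raw wide-band trace (numeric).
#' @param fs_hz sampling rate.
#' @param bandpass_hz spike band (default `c(300, 3000)`).
#' @param threshold_sd,artifact_sd see [detect_spikes()].
#' @param n_features see [extract_features()].
#' @param min_cluster,seed see [spc_cluster()].
#' @param quality apply [quality_filter()] (default TRUE).
#' @return list with `events`, `clustering`, `units`.
#' @export
sort_spikes <- function(trace, fs_hz, bandpass_hz = c(300, 3000),
                        threshold_sd = 5, artifact_sd = 30,
                        n_features = 10L, min_cluster = 20L, seed = NULL,
                        quality = TRUE) {
  rec <- recording(matrix(trace, nrow = 1L), fs_hz)
  rec <- butterworth_filter(rec, "bandpass", bandpass_hz, order = 2L)
  ev <- detect_spikes(rec$signal[1L, ], fs_hz, threshold_sd, artifact_sd)
  if (length(ev$times_s) < max(min_cluster, 2L * n_features)) {
    units <- unit_clusters(ev, rep(0L, length(ev$times_s)))
    return(list(events = ev, clustering = NULL, units = units))
  }
  feats <- extract_features(ev, n_features)
  cl <- spc_cluster(feats, min_cluster = min_cluster, seed = seed)
  units <- unit_clusters(ev, cl$assignments)
  if (quality) units <- quality_filter(units)
  list(events = ev, clustering = cl, units = units)
}
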