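# Shared fixture builders; everything is generated in code at test time.

# Poisson-like spike times with an enforced 2.5-ms separation
gen_unit_times <- function(n, dur, min_gap = 0.0025) {
  t <- sort(stats::runif(n, 0.05, dur - 0.05))
  t[c(TRUE, diff(t) > min_gap)]
}

# standard labelled three-unit spiking fixture at SNR `amp`
spike_fixture <- function(seed, dur = 30, fs = 20000, amp = 8) {
  set.seed(seed)
  st <- list(gen_unit_times(150, dur), gen_unit_times(120, dur),
             gen_unit_times(100, dur))
  tpl <- list(spike_template(fs, 1.0, amp), spike_template(fs, 1.5, amp),
              spike_template(fs, 2.2, amp))
  tr <- generate_spiking_trace(fs, dur, st, tpl, noise_sd = 1, seed = seed * 13)
  list(trace = tr$trace, fs = fs, dur = dur, truth = tr$ground_truth)
}

# label detected events by nearest ground-truth spike (0 = unmatched)
match_events <- function(times_s, truth, tol_s = 2e-4) {
  vapply(times_s, function(t) {
    i <- which.min(abs(truth$time_s - t))
    if (abs(truth$time_s[i] - t) < tol_s) truth$unit[i] else 0L
  }, integer(1))
}

# greedy injective accuracy of assignments vs true labels (>0 only)
assignment_accuracy <- function(lab, asn) {
  keep <- lab > 0
  tab <- as.matrix(table(factor(lab[keep], sort(unique(lab[keep]))),
                         factor(asn[keep], 0:max(1, max(asn)))))
  correct <- 0; used <- character(0)
  for (u in order(-rowSums(tab))) {
    cols <- setdiff(colnames(tab), c("0", used))
    if (!length(cols)) next
    cb <- cols[which.max(tab[u, cols])]
    correct <- correct + tab[u, cb]
    used <- c(used, cb)
  }
  correct / sum(keep)
}

# two-channel beta-coupled field-potential recording
coupled_lfp <- function(seed, fs = 200, dur = 60, gain = 1, lag = 10L,
                        band = c(16, 31), mixing = NULL) {
  generate_band_coupled_lfp(sim_config(
    fs_hz = fs, duration_s = dur, n_channels = 2L,
    couplings = list(coupling_spec("ch1", "ch2", band, lag, gain)),
    mixing_matrix = mixing, seed = seed))
}

# independent (uncoupled) two-channel recording
independent_lfp <- function(seed, fs = 200, dur = 60, mixing = NULL) {
  generate_band_coupled_lfp(sim_config(
    fs_hz = fs, duration_s = dur, n_channels = 2L,
    mixing_matrix = mixing, seed = seed))
}

# study-condition mediation truth: strong paths at the scale seen in
# cortical mediation analyses (standardized ~0.2-0.7)
mediation_truth <- function() list(a1 = 0.7, a2 = 0.6, b1 = 0.5, b2 = 0.4,
                                   c = 0.2)

mediation_truth_vec <- function() {
  tr <- mediation_truth()
  stats::setNames(
    c(tr$a1, tr$a2, tr$b1, tr$b2, tr$c),
    c("input->mediator1", "input->mediator2", "mediator1->output",
      "mediator2->output", "input->output"))
}
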