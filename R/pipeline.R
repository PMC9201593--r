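#' Run the full analysis pipeline
#'
#' Orchestrates preprocess -> spectral power -> coherence (+ surrogate
#' null) -> TPDC (+ time-reversal test) -> spike sorting -> SEM over one
#' or more subjects, writing per-stage TSV/JSON outputs and a manifest
#' (inputs, seeds, package version, per-file md5 hashes) so a run is
#' fully reproducible: identical config + seed gives identical hashes.
#'
#' The config is a nested list (or a YAML file path, read with the yaml
#' package). Top-level fields:
#' \describe{
#'   \item{stages}{character subset of `c("preprocess", "power",
#'     "coherence", "tpdc", "spikes", "sem")`.}
#'   \item{subjects}{character vector of recording paths, *or*}
#'   \item{simulate}{list: `n_subjects`, `fs_hz`, `duration_s`, plus
#'     band-coupled generator settings (`band_hz`, `lag_samples`,
#'     `gain`).}
#'   \item{preprocess}{`highpass`, `lowpass`, `notch` (Hz).}
#'   \item{power}{`segment_s`, `freq_step_hz`.}
#'   \item{coherence}{`n_perm`, `block_s`, `segment_s`.}
#'   \item{tpdc}{`downsample_to`, `order`, `window_s`, `step_s`,
#'     `n_surr`.}
#'   \item{spikes}{`fs_hz`, `duration_s`, `rate_hz`, `amplitude_sd`.}
#'   \item{sem}{`data` (optional TSV path of a feature table; otherwise
#'     the per-subject features assembled by the earlier stages are
#'     used, which requires the spikes stage), `model` (path DSL,
#'     optional).}
#'   \item{band_preset}{`"mouse"` (default) or `"human"`.}
#' }
#'
#' @param config list or YAML path.
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; per-subject seeds are derived from
#'   it deterministically.
#' @return the manifest (list), invisibly; written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    stop_if(!requireNamespace("yaml", quietly = TRUE),
            "the yaml package is required to read config files")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- seed %||% config$seed %||% 1L
  stages <- config$stages %||% c("preprocess", "power", "coherence", "tpdc")
  bands <- band_preset(config$band_preset %||% "mouse")
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  files <- list()
  put <- function(stage, fname, writer) {
    path <- file.path(out_dir, fname)
    writer(path)
    files[[stage]] <<- c(files[[stage]], fname)
    path
  }

  # ---- inputs ---------------------------------------------------------
  subjects <- run_stage("input", {
    if (!is.null(config$subjects)) {
      lapply(config$subjects, read_recording)
    } else {
      sim <- config$simulate %||% list()
      ns <- sim$n_subjects %||% 1L
      lapply(seq_len(ns), function(i) {
        cfg <- sim_config(
          fs_hz = sim$fs_hz %||% 1000,
          duration_s = sim$duration_s %||% 30,
          n_channels = 2L,
          channel_labels = data.frame(
            id = c("rfa_l5", "cfa_l23"),
            area = c("RFA", "CFA"), layer = c("L5", "L2/3"),
            stringsAsFactors = FALSE),
          couplings = list(coupling_spec(
            "rfa_l5", "cfa_l23",
            band_hz = sim$band_hz %||% c(16, 31),
            lag_samples = sim$lag_samples %||% 10L,
            gain = sim$gain %||% 1)),
          seed = seed * 1000L + i)
        generate_band_coupled_lfp(cfg)
      })
    }
  })
  feats <- data.frame(subject = seq_along(subjects))

  # ---- preprocess -----------------------------------------------------
  if ("preprocess" %in% stages) {
    pp <- config$preprocess %||% list()
    subjects <- run_stage("preprocess", lapply(subjects, function(rec) {
      nyq <- rec$fs / 2
      if (nrow(rec$signal) > 1L) rec <- rereference_common_average(rec)
      hp <- pp$highpass %||% 0.1
      lp <- min(pp$lowpass %||% 250, nyq * 0.9)
      rec <- butterworth_filter(rec, "bandpass", c(hp, lp))
      nf <- (pp$notch %||% c(50, 100, 150))
      notch_filter(rec, nf[nf < nyq])
    }))
  }

  # ---- spectral power -------------------------------------------------
  powers <- NULL
  if ("power" %in% stages) {
    pw <- config$power %||% list()
    powers <- run_stage("power", lapply(subjects, function(rec)
      multitaper_power(rec, segment_s = pw$segment_s %||% 0.05,
                       freq_step_hz = pw$freq_step_hz %||% 0.25,
                       fmax_hz = min(100, rec$fs / 2))))
    bm <- lapply(seq_along(powers), function(i) {
      b <- band_average(powers[[i]], bands)
      data.frame(subject = i, channel = rownames(b),
                 band = rep(colnames(b), each = nrow(b)),
                 power = as.vector(b), stringsAsFactors = FALSE)
    })
    put("power", "band_power.tsv",
        function(p) write_table_tsv(do.call(rbind, bm), p))
    feats$power_beta <- vapply(powers, function(ps)
      mean(band_average(ps, bands)[, "beta"]), numeric(1))
  }

  # ---- coherence ------------------------------------------------------
  if ("coherence" %in% stages) {
    co <- config$coherence %||% list()
    cohs <- run_stage("coherence", lapply(seq_along(subjects), function(i) {
      rec <- subjects[[i]]
      pair <- rec$channels$id[1:2]
      cp <- surrogate_null(rec, pair,
                           n_perm = co$n_perm %||% 100L,
                           block_s = co$block_s %||% 0.5,
                           segment_s = co$segment_s %||% 2,
                           fmax_hz = min(100, rec$fs / 2 - 1),
                           seed = seed * 1000L + 500L + i)
      flag_significant(cp, alpha = co$alpha %||% 0.05, bands = bands)
    }))
    tab <- do.call(rbind, lapply(seq_along(cohs), function(i) {
      cp <- cohs[[i]]
      data.frame(subject = i, band = names(cp$band_means),
                 coherence = unname(cp$band_means),
                 null_q = unname(cp$band_null_quantile),
                 significant = unname(cp$band_significant))
    }))
    put("coherence", "band_coherence.tsv", function(p) write_table_tsv(tab, p))
    feats$coherence_beta <- vapply(cohs, function(cp)
      unname(cp$band_means["beta"]), numeric(1))
  }

  # ---- TPDC + TRT -----------------------------------------------------
  if ("tpdc" %in% stages) {
    tp <- config$tpdc %||% list()
    trts <- run_stage("tpdc", lapply(seq_along(subjects), function(i) {
      rec <- subjects[[i]]
      target_fs <- tp$downsample_to %||% 200
      if (rec$fs >= 2 * target_fs) {
        # decimate by the integer factor closest to the requested rate
        rec <- downsample(rec, rec$fs / floor(rec$fs / target_fs))
      }
      time_reversal_test(rec, bands = bands,
                         order = tp$order %||% "auto",
                         window_s = tp$window_s %||% 2,
                         step_s = tp$step_s %||% 0.5,
                         n_surr = tp$n_surr %||% 19L,
                         fmax_hz = min(100, rec$fs / 2 - 1),
                         seed = seed * 1000L + 700L + i)
    }))
    tab <- do.call(rbind, lapply(seq_along(trts), function(i)
      cbind(subject = i, as.data.frame(trts[[i]]))))
    put("tpdc", "tpdc_trt.tsv", function(p) write_table_tsv(tab, p))
    beta <- tab[tab$band == "beta", ]
    feats$tpdc_beta <- beta$delta[match(feats$subject, beta$subject)]
  }

  # ---- spikes ---------------------------------------------------------
  if ("spikes" %in% stages) {
    sp <- config$spikes %||% list()
    sorted <- run_stage("spikes", lapply(seq_along(subjects), function(i) {
      sfs <- sp$fs_hz %||% 20000
      sdur <- sp$duration_s %||% 10
      rate <- sp$rate_hz %||% 5
      amp <- sp$amplitude_sd %||% 8
      st <- with_seed(seed * 1000L + 900L + i, {
        t0 <- cumsum(stats::rexp(ceiling(rate * sdur * 2), rate)) + 0.01
        t0[t0 < sdur - 0.01][diff(c(0, t0[t0 < sdur - 0.01])) > 0.002]
      })
      tr <- generate_spiking_trace(sfs, sdur, list(st),
                                   list(spike_template(sfs, amplitude = amp)),
                                   noise_sd = 1,
                                   seed = seed * 1000L + 900L + i)
      sort_spikes(tr$trace, sfs, seed = seed * 1000L + 950L + i)
    }))
    tab <- do.call(rbind, lapply(seq_along(sorted), function(i) {
      us <- sorted[[i]]$units
      if (length(us) == 0L) {
        data.frame(subject = i, unit = NA_integer_, n = 0L, rate_hz = 0)
      } else {
        do.call(rbind, lapply(us, function(u)
          data.frame(subject = i, unit = u$id, n = u$n,
                     rate_hz = u$firing_rate_hz)))
      }
    }))
    put("spikes", "units.tsv", function(p) write_table_tsv(tab, p))
    feats$su_rate <- vapply(sorted, function(s) {
      if (length(s$units) == 0L) 0 else
        sum(vapply(s$units, `[[`, numeric(1), "firing_rate_hz"))
    }, numeric(1))
  }

  # ---- feature table --------------------------------------------------
  if (ncol(feats) > 1L) {
    put("features", "features.tsv", function(p) write_table_tsv(feats, p))
  }

  # ---- SEM ------------------------------------------------------------
  if ("sem" %in% stages) {
    sm <- config$sem %||% list()
    fit <- run_stage("sem", {
      if (!is.null(sm$data)) {
        dat <- utils::read.delim(sm$data)
        spec <- if (!is.null(sm$model)) parse_path_dsl(sm$model) else
          build_mediation_spec("input", c("mediator1", "mediator2"), "output")
      } else {
        need <- c("tpdc_beta", "coherence_beta", "power_beta", "su_rate")
        stop_if(!"su_rate" %in% names(feats), "missing SU input")
        stop_if(!all(need %in% names(feats)),
                "missing feature column(s): %s",
                paste(setdiff(need, names(feats)), collapse = ", "))
        dat <- feats
        spec <- build_mediation_spec("tpdc_beta",
                                     c("coherence_beta", "power_beta"),
                                     "su_rate")
      }
      fit_ml(spec, dat)
    })
    put("sem", "sem_fit.json", function(p)
      jsonlite::write_json(list(paths = fit$paths, chi2 = fit$chi2,
                                df = fit$df, rmsea = fit$rmsea,
                                aic = fit$aic, n = fit$n),
                           p, auto_unbox = TRUE, digits = NA))
  }

  # ---- manifest -------------------------------------------------------
  all_files <- unlist(files, use.names = FALSE)
  hashes <- as.list(tools::md5sum(file.path(out_dir, all_files)))
  names(hashes) <- all_files
  manifest <- list(
    package = "motorconn",
    version = as.character(utils::packageVersion("motorconn")),
    seed = seed,
    stages = stages,
    n_subjects = length(subjects),
    config = config,
    files = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
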