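# Orchestration: stream a synthetic study through preprocessing and
# time-frequency decomposition, run the three analyses (group contrast,
# medication interaction, EMG controls) plus the Bayes layer, and write a
# machine-readable report.

# average a per-sample time course into the TFR output bins
bin_timecourse <- function(x, times_in, times_out) {
  half <- if (length(times_out) > 1) diff(times_out)[1] / 2 else Inf
  vapply(times_out, function(tc) mean(x[abs(times_in - tc) <= half]),
         numeric(1))
}

process_session <- function(rec, config, tmin = -1.5, tmax = 3.5,
                            thresholds = ptp_thresholds(emg = Inf, acc = Inf),
                            movement_window = c(0, 0.5), z_thr = 3,
                            min_dur = 0.02, compute_emg = TRUE) {
  info <- rec$info
  grad_ch <- which(info$type == "grad")
  acc_ch <- which(info$type == "acc")
  emg_ch <- which(info$type == "emg")

  acc_norm <- accelerometer_norm(rec$data[, acc_ch], rec$sfreq)
  acc_rec <- list(data = matrix(acc_norm, ncol = 1),
                  info = data.frame(name = "ACC_NORM", type = "acc",
                                    pair = NA, unit = "z"),
                  sfreq = rec$sfreq, events = rec$events)
  acc_ep <- epoch_continuous(acc_rec, tmin, tmax)

  epochs <- epoch_continuous(rec, tmin, tmax, channels = grad_ch)
  epochs <- reject_amplitude_jumps(epochs, thresholds)
  # movement flags are computed on all epochable trials, then intersected
  # with the trials that survived the amplitude rejection
  flags <- flag_accidental_movements(acc_ep$data[, 1, ], acc_ep$times,
                                     movement_window, z_thr, min_dur)
  flagged_ids <- acc_ep$trial_ids[flags]
  epochs <- drop_trials(epochs, which(epochs$trial_ids %in% flagged_ids),
                        "movement")

  emg <- NULL
  if (compute_emg && length(emg_ch)) {
    emg_ep <- epoch_continuous(rec, tmin, tmax, channels = emg_ch)
    keep <- emg_ep$trial_ids %in% epochs$trial_ids
    emg <- preprocess_emg(emg_ep$data[keep, 1, ], rec$sfreq)
    emg$times <- emg_ep$times
  }
  list(epochs = epochs, emg = emg, n_kept = dim(epochs$data)[1],
       rejection_log = epochs$rejection_log)
}

#' Simulate and reduce a study to per-subject analysis features
#'
#' Streams every subject-session through the full reduction: simulate the
#' continuous recording, epoch, reject amplitude jumps and accidental
#' movements, select the subject's peak channel pair from the evoked
#' response across sessions, subtract the evoked response, decompose the
#' selected pair with Morlet wavelets, combine the pair, log-transform and
#' baseline-correct, and restrict to the analysis band. EMG epochs are
#' conditioned alongside. Recordings are discarded as soon as their
#' features are extracted, so large studies fit in memory.
#'
#' @param config A [sim_config()].
#' @param band Analysis band in Hz (default `c(8, 30)`).
#' @param freqs TFR frequencies (default 2--40 Hz).
#' @param tfr_times TFR output grid (default -1.25 to 2.5 s, 50 ms steps).
#' @param baseline Baseline window (default `c(-1.25, -0.2)` s).
#' @param compute_emg Condition the EMG channel too (default `TRUE`).
#' @param verbose Print progress.
#' @return A `study_features`: list with `grids` (list over subjects of
#'   `freqs x times` matrices per session, baseline-corrected log power),
#'   `raw_baseline` (per subject-session mean raw power per frequency over
#'   the baseline window), `emg` (binned rectified averages), `subjects`,
#'   `n_kept` (kept-trial table), `selection` (peak pair per subject),
#'   `freqs`, `times`, `config`.
#' @export
extract_study_features <- function(config, band = c(8, 30), freqs = 2:40,
                                   tfr_times = seq(-1.25, 2.5, by = 0.05),
                                   baseline = c(-1.25, -0.2),
                                   compute_emg = TRUE, verbose = FALSE) {
  subjects <- simulate_subject_table(config)
  ns <- config$n_sessions
  grids <- raw_base <- emg_tc <- vector("list", nrow(subjects))
  sel_pairs <- integer(nrow(subjects))
  kept <- list()
  band_freqs <- freqs[freqs >= band[1] & freqs <= band[2]]
  for (i in seq_len(nrow(subjects))) {
    if (verbose) message("subject ", subjects$subject[i])
    sess <- vector("list", ns)
    for (s in seq_len(ns)) {
      rec <- simulate_session(config, subjects$group[i], s,
                              session_seed(config$seed, i, s))
      sess[[s]] <- process_session(rec, config, compute_emg = compute_emg)
      rm(rec)
    }
    sel <- select_peak_pair(lapply(sess, `[[`, "epochs"))
    sel_pairs[i] <- sel$pair
    pair_ch <- c(2 * sel$pair - 1, 2 * sel$pair)
    g_i <- rb_i <- vector("list", ns)
    e_i <- vector("list", ns)
    for (s in seq_len(ns)) {
      ep <- sess[[s]]$epochs
      ep$data <- ep$data[, pair_ch, , drop = FALSE]
      ep$info <- ep$info[pair_ch, , drop = FALSE]
      ep <- subtract_evoked(ep)
      tfr <- morlet_tfr(ep, freqs = freqs, times = tfr_times)
      tfr$power <- combine_pairs(tfr$power, domain = "power",
                                 pairs = c(1, 1))
      corr <- extract_band(baseline_log_correct(tfr, baseline), band)
      g_i[[s]] <- corr$power[1, , ]
      bsel <- tfr$times >= baseline[1] & tfr$times <= baseline[2]
      raw_band <- tfr$power[1, match(band_freqs, freqs), bsel, drop = FALSE]
      rb_i[[s]] <- apply(raw_band, 2, mean, na.rm = TRUE)
      if (compute_emg)
        e_i[[s]] <- bin_timecourse(sess[[s]]$emg$average,
                                   sess[[s]]$emg$times, tfr_times)
      kept[[length(kept) + 1]] <-
        data.frame(subject = subjects$subject[i], group = subjects$group[i],
                   session = s, count = sess[[s]]$n_kept)
    }
    grids[[i]] <- g_i
    raw_base[[i]] <- rb_i
    emg_tc[[i]] <- e_i
    rm(sess)
  }
  structure(list(grids = grids, raw_baseline = raw_base,
                 emg = if (compute_emg) emg_tc else NULL,
                 subjects = subjects, n_kept = do.call(rbind, kept),
                 selection = sel_pairs, freqs = band_freqs,
                 times = tfr_times, config = config),
            class = "study_features")
}

#' @export
print.study_features <- function(x, ...) {
  cat(sprintf("Study features: %d subjects x %d session(s); %d x %d analysis grid (%g-%g Hz)\n",
              nrow(x$subjects), x$config$n_sessions, length(x$freqs),
              length(x$times), min(x$freqs), max(x$freqs)))
  invisible(x)
}

# stack per-subject session grids into subjects x freqs x times
stack_grids <- function(features, idx, session) {
  g1 <- features$grids[[idx[1]]][[session]]
  out <- array(NA_real_, c(length(idx), nrow(g1), ncol(g1)))
  for (k in seq_along(idx)) out[k, , ] <- features$grids[[idx[k]]][[session]]
  out
}

#' Between-group contrast of the induced response
#'
#' Compares the baseline-corrected log time-frequency responses between
#' healthy controls and patients with an independent-samples cluster
#' permutation test; by default the patients' first session (the
#' off-medication state) against the controls' first session. The t-map is
#' oriented HC minus PD, so an attenuated patient rebound appears as a
#' positive cluster.
#'
#' @param features A `study_features`.
#' @param session_pd,session_hc Session used for each group (default 1).
#' @param n_perm,seed,... Passed to [permutation_cluster_test()].
#' @return A `cluster_test`.
#' @export
run_group_contrast <- function(features, session_pd = 1, session_hc = 1,
                               n_perm = 1000, seed = NULL, ...) {
  pd <- which(features$subjects$group == "pd")
  hc <- which(features$subjects$group == "hc")
  permutation_cluster_test(stack_grids(features, hc, session_hc),
                           stack_grids(features, pd, session_pd),
                           design = "independent", n_perm = n_perm,
                           seed = seed, freqs = features$freqs,
                           times = features$times, ...)
}

#' Medication analyses: interaction and within-patient session contrast
#'
#' Runs the pseudo-2x2 group-by-session interaction (which regresses out
#' the retest effect, leaving a medication-specific effect) and the plain
#' paired session contrast within the patient group.
#'
#' @param features A `study_features` with 2 sessions.
#' @param n_perm,seed,... Passed to the underlying tests.
#' @return List with `interaction` and `within_pd` (`cluster_test`s).
#' @export
run_medication_analysis <- function(features, n_perm = 1000, seed = NULL,
                                    ...) {
  if (features$config$n_sessions < 2)
    stop("medication analysis needs two sessions")
  all_idx <- seq_len(nrow(features$subjects))
  s1 <- stack_grids(features, all_idx, 1)
  s2 <- stack_grids(features, all_idx, 2)
  inter <- interaction_contrast(s1, s2, features$subjects$group,
                                times = features$times,
                                freqs = features$freqs, n_perm = n_perm,
                                seed = seed, ...)
  pd <- which(features$subjects$group == "pd")
  within <- permutation_cluster_test(stack_grids(features, pd, 1),
                                     stack_grids(features, pd, 2),
                                     design = "paired", n_perm = n_perm,
                                     seed = seed, freqs = features$freqs,
                                     times = features$times, ...)
  list(interaction = inter, within_pd = within)
}

stack_emg <- function(features, idx, session) {
  do.call(rbind, lapply(idx, function(i) features$emg[[i]][[session]]))
}

#' EMG control analyses
#'
#' Confirms the passive movements are not accompanied by differential
#' muscle activation: movement-vs-baseline contrasts within each group and
#' session, a between-group contrast, and a within-patient between-session
#' contrast, all as 1-D cluster permutation tests on the rectified EMG
#' averages. Six p-values are reported.
#'
#' @param features A `study_features` with EMG conditioned.
#' @param n_perm,seed,... Passed to [emg_cluster_tests()].
#' @return Named list of `cluster_test`s: `move_pd_s1`, `move_pd_s2`,
#'   `move_hc_s1`, `move_hc_s2`, `between_group_s1`, `between_session_pd`.
#' @export
run_emg_controls <- function(features, n_perm = 1000, seed = NULL, ...) {
  if (is.null(features$emg)) stop("study features lack EMG time courses")
  pd <- which(features$subjects$group == "pd")
  hc <- which(features$subjects$group == "hc")
  tt <- features$times
  ns <- features$config$n_sessions
  out <- list()
  for (g in c("pd", "hc")) {
    idx <- if (g == "pd") pd else hc
    for (s in seq_len(min(2, ns))) {
      out[[sprintf("move_%s_s%d", g, s)]] <-
        emg_cluster_tests(stack_emg(features, idx, s), times = tt,
                          contrast = "movement_vs_baseline", n_perm = n_perm,
                          seed = seed, ...)
    }
  }
  out$between_group_s1 <-
    emg_cluster_tests(stack_emg(features, hc, 1), stack_emg(features, pd, 1),
                      times = tt, contrast = "between_group", n_perm = n_perm,
                      seed = seed, ...)
  if (ns >= 2)
    out$between_session_pd <-
      emg_cluster_tests(stack_emg(features, pd, 1), stack_emg(features, pd, 2),
                        times = tt, contrast = "between_session",
                        n_perm = n_perm, seed = seed, ...)
  out
}

min_cluster_p <- function(ct) {
  if (length(ct$clusters) == 0) return(NA_real_)
  min(vapply(ct$clusters, `[[`, numeric(1), "monte_carlo_p"))
}

#' Baseline-power regression inputs from study features
#'
#' Builds the per-subject-per-session table relating the mean
#' baseline-corrected response within a cluster to the mean raw baseline
#' band power over the cluster's frequency rows.
#'
#' @param features A `study_features`.
#' @param cluster A cluster from a [run_group_contrast()] result (its
#'   `members` index the analysis grid).
#' @return Data frame with `subject`, `group`, `session`, `baseline`,
#'   `rebound`.
#' @export
cluster_regression_table <- function(features, cluster) {
  rows <- list()
  frows <- sort(unique(cluster$members[, 1]))
  for (i in seq_len(nrow(features$subjects))) {
    for (s in seq_len(features$config$n_sessions)) {
      g <- features$grids[[i]][[s]]
      rows[[length(rows) + 1]] <- data.frame(
        subject = features$subjects$subject[i],
        group = features$subjects$group[i], session = s,
        baseline = mean(features$raw_baseline[[i]][[s]][frows]),
        rebound = mean(g[cluster$members], na.rm = TRUE))
    }
  }
  do.call(rbind, rows)
}

#' Run the complete study analysis
#'
#' Simulates a study, extracts features, and runs the three analyses plus
#' the Bayes layer (kept-trial-count ANOVA Bayes factors, the
#' baseline-power regression comparison on the primary cluster, and
#' subject-variable Bayes factors).
#'
#' @param config A [sim_config()].
#' @param n_perm Permutations for all cluster tests (default 1000).
#' @param out_dir Optional directory: when given, [write_report()] is
#'   called.
#' @param verbose Print progress.
#' @return A `study_report` list; see [write_report()] for the serialized
#'   form.
#' @export
run_study <- function(config, n_perm = 1000, out_dir = NULL, verbose = FALSE) {
  features <- extract_study_features(config, verbose = verbose)
  seed_stats <- session_seed(config$seed, 9999L, 1L)
  group <- run_group_contrast(features, n_perm = n_perm, seed = seed_stats)
  medication <- if (config$n_sessions >= 2)
    run_medication_analysis(features, n_perm = n_perm, seed = seed_stats)
  emg <- run_emg_controls(features, n_perm = n_perm, seed = seed_stats)

  counts <- count_anova_bf(features$n_kept)
  primary <- if (length(group$clusters)) group$clusters[[1]] else NULL
  regression <- if (!is.null(primary) && config$n_sessions >= 2)
    regression_model_bf(cluster_regression_table(features, primary))
  subj <- features$subjects
  pdrows <- subj$group == "pd"
  subject_bfs <- list(
    age = jzs_ttest_bf(subj$age[pdrows], subj$age[!pdrows])$bf10,
    sex = multinomial_bf(table(factor(subj$sex[pdrows], c("F", "M"))),
                         table(factor(subj$sex[!pdrows], c("F", "M"))))$bf10,
    updrs_off = jzs_ttest_bf(subj$updrs_off[pdrows],
                             subj$updrs_off[!pdrows])$bf10)
  report <- structure(list(
    config = config, config_hash = config_hash(config), n_perm = n_perm,
    selection = features$selection, n_kept = features$n_kept,
    group_contrast = group, medication = medication, emg = emg,
    trial_count_bfs = counts, baseline_regression = regression,
    subject_bfs = subject_bfs, features = features),
    class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (config ", x$config_hash, ")\n", sep = "")
  cat(sprintf("  kept trials: median %g (range %g-%g)\n",
              stats::median(x$n_kept$count), min(x$n_kept$count),
              max(x$n_kept$count)))
  cat("-- group contrast (HC - PD, session 1) --\n")
  print(x$group_contrast)
  if (!is.null(x$medication)) {
    cat(sprintf("-- medication: interaction p = %.3g, within-PD p = %.3g --\n",
                min_cluster_p(x$medication$interaction),
                min_cluster_p(x$medication$within_pd)))
  }
  cat(sprintf("-- EMG controls: %s --\n",
              paste(sprintf("%s=%.2f", names(x$emg),
                            vapply(x$emg, function(e) {
                              p <- min_cluster_p(e); if (is.na(p)) 1 else p
                            }, numeric(1))), collapse = ", ")))
  cat(sprintf("-- trial counts: BF session %.3g, group %.3g, interaction %.3g --\n",
              x$trial_count_bfs$bf_session$bf10,
              x$trial_count_bfs$bf_group$bf10,
              x$trial_count_bfs$bf_interaction$bf10))
  if (!is.null(x$baseline_regression))
    cat(sprintf("-- baseline power: BF(H1/H0) %.3g, BF(H2/H0) %.3g --\n",
                x$baseline_regression$bf_h1_h0$bf10,
                x$baseline_regression$bf_h2_h0$bf10))
  invisible(x)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialization, recorded in every report so
#' outputs are traceable to their configuration.
#'
#' @param config Any serializable list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

cluster_summary_list <- function(ct) {
  if (is.null(ct)) return(NULL)
  list(method = ct$method, n_perm = ct$n_perm, df = ct$tmap$df,
       clusters = lapply(ct$clusters, function(cl)
         list(sign = cl$sign, mass = cl$mass, p = cl$monte_carlo_p,
              significant = cl$significant,
              time_range = cl$time_range, freq_range = cl$freq_range,
              onset = cl$time_range[1],
              duration = diff(cl$time_range))))
}

#' Serialize a study report
#'
#' Writes `report.json` (cluster geometry, p-values, Bayes factors,
#' trial-count table, configuration hash and seeds) and a human-readable
#' `summary.txt` into `out_dir`. Re-running with the same configuration and
#' seed reproduces the files byte-for-byte.
#'
#' @param report A `study_report` from [run_study()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the path to `report.json`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bf_or_null <- function(x) if (is.null(x)) NULL else x$bf10
  out <- list(
    config_hash = report$config_hash,
    seed = report$config$seed,
    n_perm = report$n_perm,
    n_kept = report$n_kept,
    selection = report$selection,
    group_contrast = cluster_summary_list(report$group_contrast),
    interaction = cluster_summary_list(report$medication$interaction),
    within_pd = cluster_summary_list(report$medication$within_pd),
    emg = lapply(report$emg, function(e)
      list(p = min_cluster_p(e), n_clusters = length(e$clusters))),
    trial_count_bfs = lapply(report$trial_count_bfs, bf_or_null),
    baseline_regression = if (!is.null(report$baseline_regression))
      lapply(report$baseline_regression, bf_or_null),
    subject_bfs = report$subject_bfs)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, na = "null")
  con <- file(file.path(out_dir, "summary.txt"), "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(path)
}
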