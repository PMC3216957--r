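#' Performance versus recording length
#'
#' Evaluates each measure on truncated prefixes of the recording and
#' reports the TPR at the operating FPR for every length.
#'
#' @param spikes A [spike_trains()] object (the recorded, sub-sampled
#'   neurons).
#' @param truth The matching [ground_truth()].
#' @param lengths_min Recording lengths in minutes (prefixes of the data).
#' @param measures,delays,hote_pk_order,hote_ci_order,tau_ms,T_ms Passed to
#'   [connectivity_scores()].
#' @param bin_ms Bin width for the rasters.
#' @param fpr_readout,weak_mV Passed to [evaluate_scores()].
#' @return A data.frame `length_min`, `measure`, `tpr`, `weight_fraction`.
#' @export
sweep_recording_length <- function(spikes, truth,
                                   lengths_min = c(1, 5, 15, 30),
                                   measures = c("HOTEPk", "HOTECI", "TEPk",
                                                "TECI", "NCCPk", "NCCCI",
                                                "D1TE"),
                                   bin_ms = 1, delays = 1:30,
                                   hote_pk_order = c(1, 3),
                                   hote_ci_order = c(3, 2),
                                   tau_ms = 5, T_ms = 30,
                                   fpr_readout = 0.01, weak_mV = 1) {
  stopifnot(all(lengths_min > 0),
            all(lengths_min * 60000 <= spikes$duration_ms))
  out <- list()
  for (len in lengths_min) {
    sub <- truncate_trains(spikes, len * 60000)
    raster <- bin_spikes(sub, bin_ms)
    sc <- connectivity_scores(raster, measures, delays = delays,
                              hote_pk_order = hote_pk_order,
                              hote_ci_order = hote_ci_order,
                              tau_ms = tau_ms, T_ms = T_ms)
    for (m in names(sc)) {
      ev <- evaluate_scores(sc[[m]], truth, fpr_readout, weak_mV)
      out[[length(out) + 1]] <- data.frame(
        length_min = len, measure = m, tpr = ev$tpr,
        weight_fraction = ev$weight_fraction)
    }
  }
  do.call(rbind, out)
}

#' Performance versus bin width
#'
#' Rebins the spikes at each width (binary clipping), adapts the delay grid
#' to cover about 30 ms of real time and the coincidence window to the
#' bins closest to 5 ms (see [window_bins_for()]), and reports the TPR at
#' the operating FPR.
#'
#' @inheritParams sweep_recording_length
#' @param bin_sizes_ms Bin widths to test (ms).
#' @return A data.frame `bin_ms`, `measure`, `tpr`.
#' @export
sweep_bin_size <- function(spikes, truth, bin_sizes_ms = c(1, 2, 5, 10, 17,
                                                           25, 40),
                           measures = c("TEPk", "TECI", "D1TE", "HOTEPk",
                                        "HOTECI"),
                           hote_pk_order = c(1, 3),
                           hote_ci_order = c(3, 2),
                           tau_ms = 5, T_ms = 30,
                           fpr_readout = 0.01, weak_mV = 1) {
  out <- list()
  for (bin in bin_sizes_ms) {
    raster <- bin_spikes(spikes, bin)
    grid <- delay_grid_for_bin(bin, T_ms)
    use <- measures
    if (length(grid) < 2)  # no curve to take a coincidence window of
      use <- setdiff(use, c("TECI", "HOTECI", "NCCCI", "NCCHCI"))
    sc <- connectivity_scores(raster, use, delays = grid,
                              hote_pk_order = hote_pk_order,
                              hote_ci_order = hote_ci_order,
                              tau_ms = tau_ms, T_ms = max(T_ms, 2 * bin))
    for (m in names(sc)) {
      ev <- evaluate_scores(sc[[m]], truth, fpr_readout, weak_mV)
      out[[length(out) + 1]] <- data.frame(bin_ms = bin, measure = m,
                                           tpr = ev$tpr)
    }
  }
  do.call(rbind, out)
}

#' Optimize the higher-order TE message lengths
#'
#' Computes the TPR at the operating FPR over the full grid of target
#' history lengths `k` and source message lengths `l`, for both the peak
#' and coincidence-index collapse, and reports the best cell of each.
#' The `(k = 1, l = 1)` cell is delayed TE by definition.
#'
#' @inheritParams sweep_recording_length
#' @param raster A [spike_raster()].
#' @param k_range,l_range Integer grids (default 1--5 each).
#' @return A list with `tpr_pk` and `tpr_ci` (k x l matrices), `best_pk`
#'   and `best_ci` (named `c(k, l)` vectors).
#' @export
optimize_order <- function(raster, truth, k_range = 1:5, l_range = 1:5,
                           delays = 1:30, tau_ms = 5, T_ms = 30,
                           fpr_readout = 0.01, weak_mV = 1) {
  tpr_pk <- matrix(NA_real_, length(k_range), length(l_range),
                   dimnames = list(k = k_range, l = l_range))
  tpr_ci <- tpr_pk
  for (a in seq_along(k_range)) for (b in seq_along(l_range)) {
    ps <- te_profiles(raster, k = k_range[a], l = l_range[b],
                      delays = delays)
    ev_pk <- evaluate_scores(score_matrix(ps, "pk"), truth,
                             fpr_readout, weak_mV)
    ev_ci <- evaluate_scores(
      score_matrix(ps, "ci", tau_ms = tau_ms, T_ms = T_ms), truth,
      fpr_readout, weak_mV)
    tpr_pk[a, b] <- ev_pk$tpr
    tpr_ci[a, b] <- ev_ci$tpr
  }
  best <- function(m) {
    w <- which(m == max(m), arr.ind = TRUE)[1, ]
    c(k = k_range[w[1]], l = l_range[w[2]])
  }
  list(tpr_pk = tpr_pk, tpr_ci = tpr_ci,
       best_pk = best(tpr_pk), best_ci = best(tpr_ci))
}
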