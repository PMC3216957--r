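#' Label ordered neuron pairs against the ground truth
#'
#' Pairs with a synapse of magnitude above the weak-weight threshold are
#' positives; pairs with a (necessarily excitatory) synapse at or below the
#' threshold are excluded from ROC analysis -- they are neither relabeled
#' negative nor counted as positives, since STDP drives many weights to
#' near zero where they carry almost no input; pairs with no synapse are
#' negatives.  Self-pairs are never part of the universe.
#'
#' @param truth A [ground_truth()] object covering the recorded neurons.
#' @param weak_mV Weak-weight threshold in mV (default 1).
#' @return A data.frame over all ordered pairs of distinct recorded
#'   neurons: `pre`, `post` (neuron ids), `label`
#'   (`"positive"`/`"negative"`/`"excluded"`), `weight_mV` (signed),
#'   `pre_type`.
#' @export
classify_pairs <- function(truth, weak_mV = 1) {
  stopifnot(inherits(truth, "spk_truth"), weak_mV >= 0)
  n <- length(truth$neuron_ids)
  pre_i <- rep(seq_len(n), times = n)
  post_i <- rep(seq_len(n), each = n)
  keep <- pre_i != post_i
  pre_i <- pre_i[keep]
  post_i <- post_i[keep]
  w <- truth$weight_mV[cbind(pre_i, post_i)]
  adj <- truth$adjacency[cbind(pre_i, post_i)]
  label <- ifelse(adj & abs(w) > weak_mV, "positive",
                  ifelse(adj, "excluded", "negative"))
  data.frame(
    pre = truth$neuron_ids[pre_i], post = truth$neuron_ids[post_i],
    label = label, weight_mV = w, pre_type = truth$neuron_type[pre_i]
  )
}

#' ROC curve of connection scores against pair labels
#'
#' Sweeps a discrimination threshold down the sorted scores (tied scores
#' enter simultaneously; missing scores rank last) and reports the true
#' positive rate, false positive rate and purity (positive predictive
#' value) at every threshold.
#'
#' @param score Numeric scores, larger = stronger putative connection.
#' @param label `"positive"` / `"negative"` labels aligned with `score`
#'   (other values are dropped).
#' @return A data.frame of class `"roc_result"` with columns `threshold`
#'   (descending, `Inf` first for the empty set), `tp`, `fp`, `tpr`,
#'   `fpr`, `purity`.
#' @export
roc_curve <- function(score, label) {
  keep <- label %in% c("positive", "negative")
  score <- score[keep]
  pos <- label[keep] == "positive"
  np <- sum(pos)
  nn <- sum(!pos)
  if (np == 0 || nn == 0)
    stop("ROC needs at least one positive and one negative pair")
  sweep <- roc_sweep(score, pos)
  out <- data.frame(
    threshold = c(Inf, sweep$threshold),
    tp = c(0, sweep$tp), fp = c(0, sweep$fp)
  )
  out$tpr <- out$tp / np
  out$fpr <- out$fp / nn
  out$purity <- ifelse(out$tp + out$fp > 0,
                       out$tp / (out$tp + out$fp), NA_real_)
  class(out) <- c("roc_result", "data.frame")
  out
}

# cumulative TP/FP (and optional extra cumulants) at each distinct
# threshold, ties entering together, NA scores as one final block
roc_sweep <- function(score, pos, extras = NULL) {
  score[is.na(score)] <- -Inf
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  block_end <- cumsum(rle(s)$lengths)  # last index of each tied block
  res <- list(
    threshold = s[block_end],
    tp = cumsum(pos[ord])[block_end],
    fp = cumsum(!pos[ord])[block_end]
  )
  for (nm in names(extras))
    res[[nm]] <- cumsum(extras[[nm]][ord])[block_end]
  res
}

# linear interpolation of a cumulative quantity at a target FPR, using the
# upper envelope of the sweep (max y at each distinct FPR)
interp_at_fpr <- function(fpr, y, target) {
  o <- order(fpr, y)
  fpr <- fpr[o]
  y <- y[o]
  keep <- !duplicated(fpr, fromLast = TRUE)  # max y per distinct fpr
  x <- fpr[keep]
  yy <- y[keep]
  if (x[1] > 0) {
    x <- c(0, x)
    yy <- c(0, yy)
  }
  approx(x, yy, xout = target, rule = 2)$y
}

#' Evaluate a score matrix against the ground truth
#'
#' Full evaluation protocol: pair labeling with weak-synapse exclusion, ROC
#' sweep, and the readouts at a fixed false positive rate (0.01 by
#' default, obtained by linear interpolation between bracketing sweep
#' points): TPR, purity, the fraction of total synaptic weight carried by
#' the true positives, and the breakdown of identified connections by
#' presynaptic type.
#'
#' The weight-fraction denominator is the summed magnitude of all synapses
#' among the recorded pairs, including the weak excluded ones and the
#' inhibitory ones.
#'
#' @param scores A [score_matrix()] data.frame (columns `pre`, `post`,
#'   `score`), or any data.frame with those columns.
#' @param truth A [ground_truth()] over the recorded neurons.
#' @param fpr_readout Operating false positive rate.
#' @param weak_mV Weak-weight exclusion threshold (mV).
#' @return A list of class `"spk_evaluation"`: `roc` (a [roc_curve()]
#'   data.frame), `tpr`, `purity`, `weight_fraction`, `breakdown` (list
#'   `exc_tp`, `inh_tp`, `fp`, `inhibitory_fraction`), plus the pair-pool
#'   sizes.
#' @export
evaluate_scores <- function(scores, truth, fpr_readout = 0.01,
                            weak_mV = 1) {
  stopifnot(is.data.frame(scores),
            all(c("pre", "post", "score") %in% names(scores)))
  labels <- classify_pairs(truth, weak_mV)
  key <- function(d) paste(d$pre, d$post)
  m <- match(key(labels), key(scores))
  labels$score <- scores$score[m]  # unmatched pairs get NA = ranked last

  pool <- labels[labels$label != "excluded", ]
  np <- sum(pool$label == "positive")
  nn <- sum(pool$label == "negative")
  if (np == 0 || nn == 0)
    stop("ROC needs at least one positive and one negative pair")
  pos <- pool$label == "positive"
  sweep <- roc_sweep(pool$score, pos, extras = list(
    w_tp = ifelse(pos, abs(pool$weight_mV), 0),
    exc_tp = as.numeric(pos & pool$pre_type == "exc"),
    inh_tp = as.numeric(pos & pool$pre_type == "inh")
  ))
  fpr <- sweep$fp / nn
  tpr <- sweep$tp / np
  roc <- data.frame(threshold = c(Inf, sweep$threshold),
                    tp = c(0, sweep$tp), fp = c(0, sweep$fp),
                    tpr = c(0, tpr), fpr = c(0, fpr))
  roc$purity <- ifelse(roc$tp + roc$fp > 0,
                       roc$tp / (roc$tp + roc$fp), NA_real_)
  class(roc) <- c("roc_result", "data.frame")

  total_weight <- sum(abs(labels$weight_mV))
  tp_at <- interp_at_fpr(fpr, sweep$tp, fpr_readout)
  fp_at <- interp_at_fpr(fpr, sweep$fp, fpr_readout)
  exc_at <- interp_at_fpr(fpr, sweep$exc_tp, fpr_readout)
  inh_at <- interp_at_fpr(fpr, sweep$inh_tp, fpr_readout)
  structure(list(
    roc = roc,
    fpr_readout = fpr_readout,
    tpr = tp_at / np,
    purity = if (tp_at + fp_at > 0) tp_at / (tp_at + fp_at) else NA_real_,
    weight_fraction = interp_at_fpr(fpr, sweep$w_tp, fpr_readout) /
      total_weight,
    breakdown = list(
      exc_tp = exc_at, inh_tp = inh_at, fp = fp_at,
      inhibitory_fraction = if (exc_at + inh_at > 0)
        inh_at / (exc_at + inh_at) else NA_real_
    ),
    n_positive = np, n_negative = nn,
    n_excluded = sum(labels$label == "excluded"),
    total_weight_mV = total_weight
  ), class = "spk_evaluation")
}

#' @export
print.spk_evaluation <- function(x, ...) {
  cat(sprintf(
    "<spk_evaluation> TPR %.3f, purity %.3f, weight fraction %.3f at FPR %g\n",
    x$tpr, x$purity, x$weight_fraction, x$fpr_readout))
  cat(sprintf("  pairs: %d positive, %d negative, %d excluded\n",
              x$n_positive, x$n_negative, x$n_excluded))
  invisible(x)
}

#' TPR at a fixed FPR from an ROC curve
#'
#' @param roc A [roc_curve()] result.
#' @param fpr Target false positive rate.
#' @return Interpolated TPR.
#' @export
tpr_at_fpr <- function(roc, fpr = 0.01) {
  stopifnot(inherits(roc, "roc_result"))
  interp_at_fpr(roc$fpr[-1], roc$tpr[-1], fpr)
}
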