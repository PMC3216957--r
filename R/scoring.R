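#' Peak of a delay profile
#'
#' The maximum value of the profile and the delay at which it occurs; ties
#' break toward the smallest delay.
#'
#' @param p A [delay_profile()] or a numeric vector (delays taken as
#'   `1..length`).
#' @return A list with `value` and `delay` (both `NA` if the profile is
#'   all missing).
#' @export
peak_score <- function(p) {
  if (inherits(p, "delay_profile")) {
    vals <- p$values
    delays <- p$delays
  } else {
    vals <- as.numeric(p)
    delays <- seq_along(vals)
  }
  stopifnot(length(vals) > 0)
  if (all(is.na(vals))) return(list(value = NA_real_, delay = NA_integer_))
  w <- which.max(vals)  # first maximum = smallest delay
  list(value = vals[w], delay = delays[w])
}

#' Coincidence-index window size in bins
#'
#' The odd number of bins whose total span is closest to the target window
#' (5 ms by default), with ties broken toward fewer bins.  Reproduces the
#' conventions: 1-ms bins use 5 bins, 2-ms bins use 3 bins, 4-ms bins use
#' 1 bin.
#'
#' @param bin_ms Bin width (ms).
#' @param target_ms Desired window span (ms).
#' @return An odd integer bin count.
#' @export
window_bins_for <- function(bin_ms, target_ms = 5) {
  stopifnot(bin_ms >= 1, target_ms > 0)
  cand <- seq(1, 2 * ceiling(target_ms / bin_ms) + 1, by = 2)
  err <- abs(cand * bin_ms - target_ms)
  cand[which.min(err)]  # which.min returns the first (smaller) on ties
}

#' Coincidence index of a delay profile
#'
#' The fraction of a non-negative profile's area that falls inside a small
#' window centered on its peak:
#' \deqn{CI = \frac{\sum_{d \in W(t_p, \tau)} M(d)}{\sum_{d=1}^{T} M(d)}}
#' where the window `W` spans [window_bins_for()]`(bin_ms, tau_ms)` bins
#' centered on the peak delay; at the edges of the delay grid the window
#' is shifted inward (never wrapped) so its width is preserved.  Sharply
#' peaked profiles give CI near 1; a flat profile gives `window/T` (5/30
#' with the defaults at 1-ms bins).
#'
#' @param p A [delay_profile()] (at least two delays; a single-delay
#'   measure such as D1TE produces no curve to take a window of).
#' @param tau_ms Coincidence window span (ms).
#' @param T_ms Total window span (ms); the profile is restricted to delays
#'   within `T_ms`.
#' @param bin_ms Bin width (ms); taken from the profile set by the batch
#'   interface, default 1.
#' @return CI in (0, 1], or `NA` when the profile is missing or has zero
#'   total area.
#' @export
coincidence_index <- function(p, tau_ms = 5, T_ms = 30, bin_ms = 1) {
  stopifnot(inherits(p, "delay_profile"))
  keep <- p$delays * bin_ms <= T_ms
  vals <- p$values[keep]
  if (length(vals) < 2)
    stop("coincidence index needs a profile over at least two delays")
  if (all(is.na(vals))) return(NA_real_)
  if (any(vals < -1e-9, na.rm = TRUE))
    stop("coincidence index requires a non-negative profile ",
         "(take the absolute value first)")
  vals <- pmax(vals, 0)  # clear float-level negatives of the TE estimator
  tot <- sum(vals, na.rm = TRUE)
  if (tot <= 0) return(NA_real_)
  w <- window_bins_for(bin_ms, tau_ms)
  pk <- which.max(vals)
  win <- ci_window(pk, w, length(vals))
  sum(vals[win], na.rm = TRUE) / tot
}

# window of `w` bins centered on the peak, shifted inward (never wrapped)
# at the edges of the delay grid so its width is preserved; truncated only
# when the grid itself is narrower than the window
ci_window <- function(pk, w, n) {
  half <- (w - 1) / 2
  lo <- min(max(1, pk - half), max(1, n - w + 1))
  lo:min(n, lo + w - 1)
}

#' Collapse delay profiles into connection scores
#'
#' Applies [peak_score()] or [coincidence_index()] to every pair of a
#' profile set, yielding one strength per ordered pair -- the input to ROC
#' thresholding.  For NCC profiles the absolute value is taken first
#' (`absolute = TRUE`), both to make the CI well defined and to let
#' anti-correlations from inhibitory synapses count toward a connection.
#'
#' @param ps A `"profile_set"` from [te_profiles()] or [cc_profiles()].
#' @param method `"pk"` (peak) or `"ci"` (coincidence index).
#' @param tau_ms,T_ms Coincidence-index windows, see [coincidence_index()].
#' @param absolute Take `abs()` of the profiles first; defaults to `TRUE`
#'   for NCC, which is signed.
#' @return A data.frame with columns `pre`, `post`, `score`, `peak_delay`,
#'   `measure`, `method` (class `"score_matrix"`).
#' @export
score_matrix <- function(ps, method = c("pk", "ci"), tau_ms = 5, T_ms = 30,
                         absolute = identical(ps$measure, "NCC")) {
  stopifnot(inherits(ps, "profile_set"))
  method <- match.arg(method)
  vals <- ps$values
  if (absolute) vals <- abs(vals)
  if (method == "ci" && length(ps$delays) < 2)
    stop("coincidence index needs profiles over at least two delays ",
         "(not available for D1TE)")
  n <- nrow(vals)
  score <- numeric(n)
  pk_delay <- integer(n)
  if (method == "pk") {
    all_na <- rowSums(!is.na(vals)) == 0
    wmax <- max.col(replace(vals, is.na(vals), -Inf), ties.method = "first")
    score <- vals[cbind(seq_len(n), wmax)]
    pk_delay <- ps$delays[wmax]
    score[all_na] <- NA_real_
    pk_delay[all_na] <- NA_integer_
  } else {
    keep <- ps$delays * ps$bin_ms <= T_ms
    if (sum(keep) < 2)
      stop("coincidence index needs at least two delays within T_ms")
    vk <- vals[, keep, drop = FALSE]
    if (any(vk < -1e-9, na.rm = TRUE))
      stop("coincidence index requires non-negative profiles")
    vk[vk < 0] <- 0  # clear float-level negatives of the TE estimator
    all_na <- rowSums(!is.na(vk)) == 0
    w <- window_bins_for(ps$bin_ms, tau_ms)
    half <- (w - 1) / 2
    nb <- ncol(vk)
    pk <- max.col(replace(vk, is.na(vk), -Inf), ties.method = "first")
    tot <- rowSums(vk, na.rm = TRUE)
    # centered window, shifted inward at the grid edges (see ci_window)
    base <- pmin(pmax(1, pk - half), max(1, nb - w + 1))
    num <- numeric(n)
    for (off in 0:(w - 1)) {
      cols <- base + off
      inside <- cols <= nb
      add <- vk[cbind(seq_len(n), pmin(cols, nb))]
      add[!inside | is.na(add)] <- 0
      num <- num + add
    }
    score <- ifelse(tot > 0, num / tot, NA_real_)
    pk_delay <- ps$delays[keep][pk]
    score[all_na] <- NA_real_
    pk_delay[all_na] <- NA_integer_
  }
  out <- data.frame(pre = ps$pairs$pre, post = ps$pairs$post,
                    score = score, peak_delay = pk_delay,
                    measure = ps$measure, method = toupper(method))
  class(out) <- c("score_matrix", "data.frame")
  out
}
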