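#' Normalized cross-correlation (NCC) delay profile
#'
#' For binary series `i` (target) and `j` (source),
#' \deqn{NCC(\tau) = \frac{1}{N \sigma_i \sigma_j}
#'   \sum_t (i(t+\tau) - \bar i)(j(t) - \bar j)}
#' with the sum over the overlap window at lag `tau`, global means and
#' population (divide-by-N) standard deviations, and `N` the total number
#' of bins.  At `tau = 0` the self-pair gives exactly 1.
#'
#' @param i,j Binary (0/1) vectors of equal length (target, source).
#' @param delays Integer lags in bins (>= 0); positive lags mean the source
#'   precedes the target.
#' @return A [delay_profile()]; values are `NA` if either series has zero
#'   variance.
#' @export
ncc <- function(i, j, delays = 1:30) {
  cc_pair(i, j, delays, "NCC")
}

#' Normalized cross-correlation histogram (NCCH) delay profile
#'
#' The coincidence count normalized by the geometric mean of the spike
#' counts:
#' \deqn{NCCH(\tau) = \frac{\sum_t i(t+\tau)\, j(t)}{\sqrt{n_i n_j}}.}
#' In the sparse-spike limit NCC converges to NCCH.
#'
#' @inheritParams ncc
#' @return A [delay_profile()]; values are `NA` if either series is silent.
#' @export
ncch <- function(i, j, delays = 1:30) {
  cc_pair(i, j, delays, "NCCH")
}

cc_pair <- function(i, j, delays, variant) {
  si <- as_bin_series(i)
  sj <- as_bin_series(j)
  stopifnot(si$n == sj$n, all(delays >= 0))
  raw <- cc_counts_cpp(list(si$bins, sj$bins), si$n, as.integer(delays),
                       cbind(1L, 2L))
  vals <- cc_assemble(raw$coin[1, ], raw$n_from[1, ], raw$n_to[2, ],
                      length(si$bins), length(sj$bins), si$n, delays,
                      variant)
  delay_profile(vals, delays, measure = variant)
}

# shared NCC/NCCH arithmetic from raw coincidence and window counts
cc_assemble <- function(coin, ni_win, nj_win, ni, nj, D, delays, variant) {
  if (variant == "NCCH") {
    if (ni == 0 || nj == 0) return(rep(NA_real_, length(delays)))
    return(coin / sqrt(as.numeric(ni) * nj))
  }
  mi <- ni / D
  mj <- nj / D
  si <- sqrt(mi * (1 - mi))
  sj <- sqrt(mj * (1 - mj))
  if (si == 0 || sj == 0) return(rep(NA_real_, length(delays)))
  num <- coin - mi * nj_win - mj * ni_win + (D - delays) * mi * mj
  num / (D * si * sj)
}

#' Cross-correlation profiles for all ordered pairs of a raster
#'
#' Batch computation of [ncc()] or [ncch()] profiles over the same delay
#' grid used for transfer entropy, so that the peak / coincidence-index
#' scoring machinery is shared.
#'
#' @param raster A [spike_raster()].
#' @param variant `"ncc"` or `"ncch"`.
#' @param delays Integer lags in bins (>= 0).
#' @param pairs As in [te_profiles()].
#' @return A `"profile_set"`; pairs with zero variance (or, for NCCH,
#'   silent neurons) have `NA` profiles and are excluded downstream.
#' @export
cc_profiles <- function(raster, variant = c("ncc", "ncch"), delays = 1:30,
                        pairs = NULL) {
  stopifnot(inherits(raster, "spike_raster"), all(delays >= 0))
  variant <- toupper(match.arg(variant))
  pr <- resolve_pairs(raster, pairs)
  bins <- raster_bins(raster)
  D <- ncol(raster$bits)
  raw <- cc_counts_cpp(bins, D, as.integer(delays), pr$idx)
  counts <- lengths(bins)
  vals <- matrix(NA_real_, nrow(pr$idx), length(delays))
  for (p in seq_len(nrow(pr$idx))) {
    ti <- pr$idx[p, 1]
    sj <- pr$idx[p, 2]
    vals[p, ] <- cc_assemble(raw$coin[p, ], raw$n_from[ti, ],
                             raw$n_to[sj, ], counts[ti], counts[sj],
                             D, delays, variant)
  }
  profile_set(vals, pr$pairs, delays, variant, raster$bin_ms)
}
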