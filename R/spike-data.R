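#' Spike train collection
#'
#' A light container for per-neuron spike times.  Times are in ms from the
#' start of the recording, sorted and strictly increasing within a neuron,
#' and must lie in `[0, duration_ms)`.
#'
#' @param times List of numeric vectors of spike times (ms).
#' @param duration_ms Length of the recording (ms).
#' @param neuron_ids Integer labels, by default `1..n`.
#' @return An object of class `"spk_spike_trains"`.
#' @export
spike_trains <- function(times, duration_ms,
                         neuron_ids = seq_along(times)) {
  stopifnot(is.list(times), duration_ms > 0,
            length(neuron_ids) == length(times))
  for (k in seq_along(times)) {
    tt <- times[[k]]
    if (length(tt) == 0) next
    if (is.unsorted(tt, strictly = TRUE))
      stop("spike times of neuron ", neuron_ids[k],
           " are not strictly increasing")
    if (tt[1] < 0 || tt[length(tt)] >= duration_ms)
      stop("spike times of neuron ", neuron_ids[k],
           " fall outside [0, duration_ms)")
  }
  structure(list(times = times, duration_ms = duration_ms,
                 neuron_ids = neuron_ids),
            class = "spk_spike_trains")
}

#' @export
print.spk_spike_trains <- function(x, ...) {
  cat(sprintf("<spk_spike_trains> %d neurons, %.1f s, %d spikes\n",
              length(x$times), x$duration_ms / 1000,
              sum(lengths(x$times))))
  invisible(x)
}

#' Truncate spike trains to an initial prefix
#'
#' @param spikes A [spike_trains()] object.
#' @param duration_ms New (shorter) duration in ms.
#' @return A [spike_trains()] object containing only spikes before
#'   `duration_ms`.
#' @export
truncate_trains <- function(spikes, duration_ms) {
  stopifnot(inherits(spikes, "spk_spike_trains"),
            duration_ms > 0, duration_ms <= spikes$duration_ms)
  spike_trains(lapply(spikes$times, function(tt) tt[tt < duration_ms]),
               duration_ms = duration_ms, neuron_ids = spikes$neuron_ids)
}

#' Bin spike trains into a binary raster
#'
#' Bin `b` (1-based) covers the half-open interval
#' `[(b-1) * bin_ms, b * bin_ms)` and is set to 1 if at least one spike
#' falls in it; multiple spikes clip to 1, since every connectivity measure
#' in the package is defined on binary states.  The raster has
#' `floor(duration_ms / bin_ms)` bins; spikes beyond the last full bin are
#' dropped.
#'
#' @param spikes A [spike_trains()] object.
#' @param bin_ms Bin width in ms (>= 1).
#' @return A [spike_raster()].
#' @examples
#' st <- spike_trains(list(c(3, 3.4, 7)), duration_ms = 10)
#' which(as.matrix(bin_spikes(st, 1)$bits)[1, ])  # bins 4 and 8 (spikes at 3 and 7 ms)
#' which(as.matrix(bin_spikes(st, 5)$bits)[1, ])  # bins 1 and 2
#' @export
bin_spikes <- function(spikes, bin_ms = 1) {
  stopifnot(inherits(spikes, "spk_spike_trains"), bin_ms >= 1)
  nbins <- floor(spikes$duration_ms / bin_ms)
  n <- length(spikes$times)
  ii <- integer(0)
  jj <- integer(0)
  for (k in seq_len(n)) {
    b <- unique(floor(spikes$times[[k]] / bin_ms) + 1)
    b <- b[b <= nbins]
    ii <- c(ii, rep.int(k, length(b)))
    jj <- c(jj, b)
  }
  bits <- Matrix::sparseMatrix(i = ii, j = jj, dims = c(n, nbins),
                               repr = "C")
  spike_raster(bits, bin_ms = bin_ms, neuron_ids = spikes$neuron_ids)
}

#' Binary spike raster
#'
#' The universal analysis substrate: a neurons x time-bins binary matrix
#' with its bin width.  Entries must be 0/1; internally the pattern is kept
#' sparse.
#'
#' @param bits A binary matrix (base or `Matrix` sparse), neurons in rows.
#' @param bin_ms Bin width in ms.
#' @param neuron_ids Integer labels, default `1..n`.
#' @return An object of class `"spike_raster"` with fields `bits`
#'   (an `ngCMatrix`), `bin_ms` and `neuron_ids`.
#' @export
spike_raster <- function(bits, bin_ms = 1, neuron_ids = seq_len(nrow(bits))) {
  stopifnot(bin_ms > 0, length(neuron_ids) == nrow(bits))
  if (is.matrix(bits)) {
    if (!all(bits %in% c(0, 1)))
      stop("raster entries must be binary (0/1)")
    bits <- methods::as(methods::as(Matrix::Matrix(bits, sparse = TRUE),
                                    "nMatrix"), "CsparseMatrix")
  } else if (methods::is(bits, "Matrix")) {
    if (!methods::is(bits, "nMatrix")) {
      if (!all(bits@x %in% c(0, 1)))
        stop("raster entries must be binary (0/1)")
      bits <- methods::as(bits, "nMatrix")
    }
    bits <- methods::as(bits, "CsparseMatrix")
  } else stop("unsupported raster matrix type")
  structure(list(bits = bits, bin_ms = bin_ms,
                 neuron_ids = as.integer(neuron_ids)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "<spike_raster> %d neurons x %d bins (%g ms), density %.4f\n",
    nrow(x$bits), ncol(x$bits), x$bin_ms,
    Matrix::nnzero(x$bits) / prod(dim(x$bits))))
  invisible(x)
}

#' @export
dim.spike_raster <- function(x) dim(x$bits)

# 0-based sorted bin indices per neuron, the form the compiled kernels use
raster_bins <- function(raster) {
  tr <- methods::as(raster$bits, "TsparseMatrix")
  n <- nrow(raster$bits)
  out <- vector("list", n)
  sp <- split(tr@j, factor(tr@i, levels = 0:(n - 1)))
  for (k in seq_len(n)) out[[k]] <- sort(sp[[k]])
  out
}

# binary 0/1 vector (or a 1-row raster) -> 0-based spike bin indices
as_bin_series <- function(x) {
  if (inherits(x, "spike_raster")) {
    stopifnot(nrow(x$bits) == 1)
    return(list(bins = raster_bins(x)[[1]], n = ncol(x$bits)))
  }
  x <- as.numeric(x)
  if (!all(x %in% c(0, 1))) stop("series must be binary (0/1)")
  list(bins = which(x == 1) - 1L, n = length(x))
}

#' Convert a raster to spike trains
#'
#' Each set bin becomes one spike at the bin's left edge.
#'
#' @param raster A [spike_raster()].
#' @return A [spike_trains()] object.
#' @export
raster_to_trains <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  bins <- raster_bins(raster)
  spike_trains(lapply(bins, function(b) b * raster$bin_ms),
               duration_ms = ncol(raster$bits) * raster$bin_ms,
               neuron_ids = raster$neuron_ids)
}
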