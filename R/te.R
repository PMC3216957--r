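#' Delay profile of a connectivity measure
#'
#' One ordered neuron pair's measure values across a grid of candidate
#' delays.
#'
#' @param values Numeric vector of measure values (bits for TE variants,
#'   dimensionless for cross-correlation).
#' @param delays Integer delays (bins), same length as `values`.
#' @param measure Label, e.g. `"TE"` or `"NCC"`.
#' @param pair Optional `c(pre, post)` neuron ids (source, target).
#' @return An object of class `"delay_profile"`.
#' @export
delay_profile <- function(values, delays = seq_along(values),
                          measure = "measure", pair = NULL) {
  stopifnot(length(values) == length(delays))
  structure(list(values = as.numeric(values), delays = as.integer(delays),
                 measure = measure, pair = pair),
            class = "delay_profile")
}

#' @export
print.delay_profile <- function(x, ...) {
  cat(sprintf("<delay_profile> %s, delays %d..%d\n", x$measure,
              min(x$delays), max(x$delays)))
  print(stats::setNames(x$values, x$delays))
  invisible(x)
}

#' Count spike word patterns for transfer entropy
#'
#' Tallies, over every valid time position `t`, the joint binary word made
#' of the target's next state `i[t+1]`, its `k`-bin history ending at `t`,
#' and the source's `l`-bin message ending at `t+1-d` (all indices 1-based
#' in R, but the convention is easiest read 0-based as in the details).
#' Only positions whose word contains at least one spike are visited; the
#' count of the all-zero word is inferred from the number of valid
#' positions, which makes the cost proportional to the number of spikes
#' rather than the number of bins.
#'
#' Valid positions are those where every referenced bin exists, so
#' `n_valid = D - max(k, d + l - 1)` for series of `D` bins; no padding is
#' used.
#'
#' @param i,j Binary (0/1) vectors of equal length: target and source
#'   series.
#' @param k Target history length in bins (1--5 in typical use).
#' @param l Source message length in bins.
#' @param d Delay in bins (>= 1).
#' @return An object of class `"pattern_counts"`: a `2 x 2^k x 2^l` count
#'   array indexed by (next state, history word, message word), plus
#'   `n_valid`.
#' @examples
#' cp <- count_patterns(c(0, 1, 0, 1, 0, 1), c(0, 1, 0, 1, 0, 1))
#' cp$counts
#' @export
count_patterns <- function(i, j, k = 1, l = 1, d = 1) {
  si <- as_bin_series(i)
  sj <- as_bin_series(j)
  stopifnot(si$n == sj$n, k >= 1, l >= 1, d >= 1)
  res <- count_patterns_cpp(si$bins, sj$bins, si$n, as.integer(k),
                            as.integer(l), as.integer(d))
  # C layout has the message word fastest; present as (next, history, message)
  arr <- aperm(array(res$counts, dim = c(2L^l, 2L^k, 2L)), 3:1)
  dimnames(arr) <- list(
    i_next = c("0", "1"),
    i_word = binary_labels(k),
    j_word = binary_labels(l)
  )
  structure(list(counts = arr, n_valid = res$n_valid,
                 k = as.integer(k), l = as.integer(l), d = as.integer(d)),
            class = "pattern_counts")
}

binary_labels <- function(nbit) {
  vapply(0:(2^nbit - 1), function(x)
    paste(rev(as.integer(intToBits(x)[1:nbit])), collapse = ""), "")
}

#' Plug-in transfer entropy from pattern counts
#'
#' The raw (maximum-likelihood) estimator
#' \deqn{TE = \sum p(i_{t+1}, i^{(k)}_t, j^{(l)}_{t+1-d})
#'   \log_2 \frac{p(i_{t+1} \mid i^{(k)}_t, j^{(l)}_{t+1-d})}
#'               {p(i_{t+1} \mid i^{(k)}_t)}}
#' in bits, with probabilities estimated as count ratios over `n_valid`
#' (never smoothed) and the convention that terms with zero joint count
#' contribute 0.  For a binary target the result lies in \[0, 1\] bits.
#'
#' @param x A [count_patterns()] result, or a `2 x 2^k x 2^l` count array.
#' @param n_valid Number of counted positions (taken from `x` when it is a
#'   `"pattern_counts"`).
#' @param correction `"none"` (the default, matching the reference
#'   procedure) or `"miller-madow"`, which applies the first-order
#'   support-size correction to each of the four entropies making up the
#'   transfer entropy.
#' @return Transfer entropy in bits.
#' @export
te_from_counts <- function(x, n_valid = NULL,
                           correction = c("none", "miller-madow")) {
  correction <- match.arg(correction)
  if (inherits(x, "pattern_counts")) {
    n_valid <- x$n_valid
    x <- x$counts
  }
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[1] == 2)
  if (is.null(n_valid)) n_valid <- sum(x)
  stopifnot(n_valid > 0, isTRUE(all.equal(sum(x), n_valid)))
  c_hist_msg <- apply(x, c(2, 3), sum)  # summed over next state
  c_next_hist <- apply(x, c(1, 2), sum) # summed over message word
  c_hist <- apply(x, 2, sum)
  te <- 0
  for (a in 1:2) for (b in seq_len(dim(x)[2])) for (g in seq_len(dim(x)[3])) {
    cc <- x[a, b, g]
    if (cc <= 0) next
    te <- te + cc * log2((cc * c_hist[b]) /
                           (c_hist_msg[b, g] * c_next_hist[a, b]))
  }
  te <- unname(te / n_valid)
  if (correction == "miller-madow") {
    # TE = H(next,hist) - H(hist) - H(next,hist,msg) + H(hist,msg);
    # each plug-in entropy is corrected by (support - 1) / (2 n ln 2)
    m <- c(sum(c_next_hist > 0), -sum(c_hist > 0), -sum(x > 0),
           sum(c_hist_msg > 0))
    te <- te + sum(m - sign(m)) / (2 * n_valid * log(2))
  }
  te
}

#' Transfer entropy at a single one-bin delay (D1TE)
#'
#' The conventional form of transfer entropy for spike trains: one-bin
#' histories (`k = l = 1`) and a delay of one bin, i.e. how much the
#' source's previous bin improves prediction of the target's next bin
#' beyond the target's own previous bin.
#'
#' @inheritParams count_patterns
#' @return Transfer entropy in bits.
#' @export
d1te <- function(i, j) {
  te_from_counts(count_patterns(i, j, k = 1, l = 1, d = 1))
}

#' Delayed transfer entropy
#'
#' Evaluates first-order transfer entropy (`k = l = 1`) at each candidate
#' delay: the target's history stays at one bin back, while the source bin
#' is shifted `d` bins into the past.  At `d = 1` this reduces exactly to
#' [d1te()].  Peaks of the resulting profile indicate the conduction delay
#' of a putative synapse.
#'
#' @inheritParams count_patterns
#' @param delays Integer delays in bins, default 1--30.
#' @return A [delay_profile()] in bits.
#' @export
delayed_te <- function(i, j, delays = 1:30) {
  hote(i, j, k = 1, l = 1, delays = delays)
}

#' Higher-order transfer entropy
#'
#' Generalizes [delayed_te()] to multi-bin words: the target history is the
#' `k`-bin block ending at `t` and the source message is the `l`-bin block
#' ending at `t+1-d`, so bursts spanning several bins can carry the
#' predictive signal.  With `k = l = 1` this is identical to delayed TE.
#'
#' @inheritParams count_patterns
#' @param delays Integer delays in bins.
#' @return A [delay_profile()] in bits.
#' @export
hote <- function(i, j, k = 1, l = 1, delays = 1:30) {
  stopifnot(all(delays >= 1))
  vals <- vapply(delays, function(d)
    te_from_counts(count_patterns(i, j, k = k, l = l, d = d)), numeric(1))
  delay_profile(vals, delays,
                measure = if (k == 1 && l == 1) "TE" else "HOTE")
}

#' Transfer entropy profiles for all ordered pairs of a raster
#'
#' Batch computation (compiled, sparse pattern counting) of the transfer
#' entropy delay profile for ordered neuron pairs of a [spike_raster()].
#'
#' @param raster A [spike_raster()].
#' @param k,l Target history / source message lengths in bins.
#' @param delays Integer delays in bins.
#' @param pairs Optional 2-column matrix or data.frame `(pre, post)` of
#'   neuron ids (source, target); default all ordered pairs of distinct
#'   neurons.
#' @return An object of class `"profile_set"`: `values` (pairs x delays
#'   matrix, bits), `pairs` (data.frame `pre`, `post` of neuron ids),
#'   `delays`, `measure`, `bin_ms`.
#' @export
te_profiles <- function(raster, k = 1, l = 1, delays = 1:30, pairs = NULL) {
  stopifnot(inherits(raster, "spike_raster"), k >= 1, l >= 1,
            all(delays >= 1))
  pr <- resolve_pairs(raster, pairs)
  vals <- te_profiles_cpp(raster_bins(raster), ncol(raster$bits),
                          as.integer(k), as.integer(l),
                          as.integer(delays), pr$idx)
  measure <- if (k == 1 && l == 1) {
    if (length(delays) == 1 && delays == 1) "D1TE" else "TE"
  } else "HOTE"
  profile_set(vals, pr$pairs, delays, measure, raster$bin_ms,
              k = k, l = l)
}

profile_set <- function(values, pairs, delays, measure, bin_ms, ...) {
  structure(list(values = values, pairs = pairs,
                 delays = as.integer(delays), measure = measure,
                 bin_ms = bin_ms, ...),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %s: %d pairs x %d delays (bin %g ms)\n",
              x$measure, nrow(x$values), length(x$delays), x$bin_ms))
  invisible(x)
}

# normalize a pairs spec into neuron-id data.frame + index matrix for C++;
# C++ kernels take (target, source) index pairs
resolve_pairs <- function(raster, pairs) {
  ids <- raster$neuron_ids
  if (is.null(pairs)) {
    n <- nrow(raster$bits)
    grid <- expand.grid(post = seq_len(n), pre = seq_len(n))
    grid <- grid[grid$pre != grid$post, , drop = FALSE]
    idx <- cbind(grid$post, grid$pre)
    pairs_df <- data.frame(pre = ids[grid$pre], post = ids[grid$post])
  } else {
    pairs <- as.data.frame(pairs)
    stopifnot(ncol(pairs) == 2)
    names(pairs) <- c("pre", "post")
    pre_i <- match(pairs$pre, ids)
    post_i <- match(pairs$post, ids)
    if (anyNA(pre_i) || anyNA(post_i))
      stop("pair refers to a neuron id not present in the raster")
    idx <- cbind(post_i, pre_i)
    pairs_df <- data.frame(pre = pairs$pre, post = pairs$post)
  }
  list(pairs = pairs_df, idx = idx)
}
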