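#' Read and write spike event lists
#'
#' Plain-text event list: one `neuron_id<TAB>time_ms` per line, sorted by
#' time, with optional `#`-prefixed header lines carrying `duration_ms`
#' and `neuron_ids` so the recording length and silent neurons survive a
#' round trip.
#'
#' @param spikes A [spike_trains()] object.
#' @param path File path.
#' @return `read_events()` returns a [spike_trains()] object;
#'   `write_events()` returns `path` invisibly.
#' @export
write_events <- function(spikes, path) {
  stopifnot(inherits(spikes, "spk_spike_trains"))
  ev <- data.frame(
    neuron = rep(spikes$neuron_ids, lengths(spikes$times)),
    time = as.numeric(unlist(spikes$times, use.names = FALSE))
  )
  ev <- ev[order(ev$time, ev$neuron), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# duration_ms=%s", format(spikes$duration_ms, digits = 15)),
    sprintf("# neuron_ids=%s", paste(spikes$neuron_ids, collapse = ","))
  ), con)
  if (nrow(ev) > 0)
    writeLines(sprintf("%d\t%s", ev$neuron,
                       format(ev$time, digits = 15, trim = TRUE,
                              scientific = FALSE)), con)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  body <- body[nzchar(trimws(lines[body]))]
  duration <- NA_real_
  ids <- NULL
  for (h in hdr) {
    if (grepl("duration_ms=", h, fixed = TRUE))
      duration <- as.numeric(sub(".*duration_ms=", "", h))
    if (grepl("neuron_ids=", h, fixed = TRUE))
      ids <- as.integer(strsplit(sub(".*neuron_ids=", "", h), ",")[[1]])
  }
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) == 0) {
    flat <- unlist(parts, use.names = FALSE)
    neuron <- suppressWarnings(as.integer(flat[c(TRUE, FALSE)]))
    time <- suppressWarnings(as.numeric(flat[c(FALSE, TRUE)]))
    bad <- which(is.na(neuron) | is.na(time))
  }
  if (length(bad) > 0)
    stop("malformed event line ", body[bad[1]], ": ", lines[body[bad[1]]])
  if (length(body) == 0) {
    neuron <- integer(0)
    time <- numeric(0)
  }
  if (is.null(ids)) ids <- sort(unique(neuron))
  if (is.na(duration))
    duration <- if (length(time)) max(time) + 1 else 1
  times <- lapply(split(time, factor(neuron, levels = ids)), sort)
  names(times) <- NULL
  spike_trains(times, duration_ms = duration, neuron_ids = ids)
}

#' Read and write binary spike rasters
#'
#' The raster's sparse pattern is stored as a MatrixMarket file, with a
#' DCF sidecar (`<path>.meta`) holding the bin width and neuron ids.
#'
#' @param raster A [spike_raster()].
#' @param path File path (conventionally `.mtx`).
#' @return `read_raster()` returns a [spike_raster()]; `write_raster()`
#'   returns `path` invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  Matrix::writeMM(methods::as(raster$bits, "dMatrix"), path)
  write.dcf(data.frame(bin_ms = raster$bin_ms,
                       neuron_ids = paste(raster$neuron_ids,
                                          collapse = ",")),
            paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  bits <- Matrix::readMM(path)
  if (!methods::is(bits, "nMatrix") && !all(bits@x %in% c(0, 1)))
    stop("raster file contains non-binary entries")
  meta <- read.dcf(paste0(path, ".meta"))
  spike_raster(bits, bin_ms = as.numeric(meta[1, "bin_ms"]),
               neuron_ids = as.integer(
                 strsplit(meta[1, "neuron_ids"], ",")[[1]]))
}

#' Read and write delay-profile sets
#'
#' Long-format CSV with columns `pre`, `post`, `delay`, `value` plus a
#' DCF sidecar (`<path>.meta`) holding the measure name, bin width and
#' any message-length order.
#'
#' @param ps A `"profile_set"` from [te_profiles()] or [cc_profiles()].
#' @param path File path (conventionally `.csv`).
#' @return `read_profiles()` returns a `"profile_set"`;
#'   `write_profiles()` returns `path` invisibly.
#' @export
write_profiles <- function(ps, path) {
  stopifnot(inherits(ps, "profile_set"))
  nd <- length(ps$delays)
  df <- data.frame(
    pre = rep(ps$pairs$pre, nd),
    post = rep(ps$pairs$post, nd),
    delay = rep(ps$delays, each = nrow(ps$values)),
    value = as.vector(ps$values)
  )
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  meta <- data.frame(measure = ps$measure, bin_ms = ps$bin_ms,
                     k = if (is.null(ps$k)) NA else ps$k,
                     l = if (is.null(ps$l)) NA else ps$l)
  write.dcf(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  stopifnot(all(c("pre", "post", "delay", "value") %in% names(df)))
  meta <- read.dcf(paste0(path, ".meta"))
  delays <- sort(unique(df$delay))
  key <- paste(df$pre, df$post)
  pairs <- df[!duplicated(key), c("pre", "post")]
  rownames(pairs) <- NULL
  vals <- matrix(NA_real_, nrow(pairs), length(delays))
  row <- match(key, paste(pairs$pre, pairs$post))
  col <- match(df$delay, delays)
  vals[cbind(row, col)] <- df$value
  k <- unname(suppressWarnings(as.integer(meta[1, "k"])))
  l <- unname(suppressWarnings(as.integer(meta[1, "l"])))
  profile_set(vals, pairs, delays, unname(meta[1, "measure"]),
              as.numeric(meta[1, "bin_ms"]),
              k = if (is.na(k)) NULL else k,
              l = if (is.na(l)) NULL else l)
}

#' Read and write ground-truth connectivity tables
#'
#' CSV with header `pre,post,weight_mV,delay_ms` and 0-based neuron
#' indices, one row per synapse.  A TSV sidecar (`<path>.neurons`) stores
#' each recorded neuron's id and type so that synapse-free neurons and
#' types survive a round trip; without it, types are inferred from the
#' sign of outgoing weights.
#'
#' @param truth A [ground_truth()] object.
#' @param path File path (conventionally `.csv`).
#' @return `read_ground_truth()` returns a [ground_truth()]-style
#'   `"spk_truth"`; `write_ground_truth()` returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "spk_truth"))
  df <- as.data.frame(truth)
  df$pre <- df$pre - 1L
  df$post <- df$post - 1L
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  write.table(
    data.frame(neuron_id = truth$neuron_ids - 1L,
               type = truth$neuron_type),
    paste0(path, ".neurons"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  stopifnot(all(c("pre", "post", "weight_mV", "delay_ms") %in% names(df)))
  sidecar <- paste0(path, ".neurons")
  if (file.exists(sidecar)) {
    nn <- read.table(sidecar, sep = "\t", header = TRUE)
    ids <- nn$neuron_id + 1L
    type <- nn$type
  } else {
    ids <- sort(unique(c(df$pre, df$post))) + 1L
    inh <- unique(df$pre[df$weight_mV < 0]) + 1L
    type <- ifelse(ids %in% inh, "inh", "exc")
  }
  n <- length(ids)
  pos <- match(df$pre + 1L, ids)
  pos2 <- match(df$post + 1L, ids)
  if (anyNA(pos) || anyNA(pos2))
    stop("synapse refers to a neuron missing from the neuron table")
  w <- matrix(0, n, n)
  d <- matrix(0L, n, n)
  w[cbind(pos, pos2)] <- df$weight_mV
  d[cbind(pos, pos2)] <- as.integer(df$delay_ms)
  structure(list(weight_mV = w, delay_ms = d, adjacency = d > 0,
                 neuron_type = type, neuron_ids = ids),
            class = "spk_truth")
}
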