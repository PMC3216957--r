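#' Compute a suite of connectivity score matrices
#'
#' Runs the standard battery of measures on a raster and returns one
#' [score_matrix()] per measure.  Measure names combine the delay-profile
#' measure (D1TE; TE = delayed TE; HOTE = higher-order TE; NCC; NCCH) with
#' the collapsing method (Pk = peak, CI = coincidence index).  D1TE has a
#' single delay, so no CI variant exists for it.
#'
#' @param raster A [spike_raster()].
#' @param measures Character vector from `D1TE`, `TEPk`, `TECI`, `HOTEPk`,
#'   `HOTECI`, `NCCPk`, `NCCCI`, `NCCHPk`, `NCCHCI`.
#' @param delays Delay grid in bins shared by all profile measures.
#' @param hote_pk_order,hote_ci_order `c(k, l)` message lengths used by the
#'   HOTE peak / CI variants (defaults are the orders that maximize
#'   performance at 1-ms bins: `k = 1, l = 3` for the peak and
#'   `k = 3, l = 2` for the CI).
#' @param tau_ms,T_ms Coincidence-index windows.
#' @param pairs As in [te_profiles()].
#' @return Named list of score data.frames.
#' @export
connectivity_scores <- function(raster,
                                measures = c("HOTEPk", "HOTECI", "TEPk",
                                             "TECI", "NCCPk", "NCCCI",
                                             "D1TE"),
                                delays = 1:30,
                                hote_pk_order = c(1, 3),
                                hote_ci_order = c(3, 2),
                                tau_ms = 5, T_ms = 30, pairs = NULL) {
  known <- c("D1TE", "TEPk", "TECI", "HOTEPk", "HOTECI",
             "NCCPk", "NCCCI", "NCCHPk", "NCCHCI")
  stopifnot(all(measures %in% known))
  out <- list()
  if (any(measures %in% c("TEPk", "TECI"))) {
    ps <- te_profiles(raster, k = 1, l = 1, delays = delays, pairs = pairs)
    ps$measure <- "TE"
    if ("TEPk" %in% measures) out$TEPk <- score_matrix(ps, "pk")
    if ("TECI" %in% measures)
      out$TECI <- score_matrix(ps, "ci", tau_ms = tau_ms, T_ms = T_ms)
  }
  if ("HOTEPk" %in% measures) {
    ps <- te_profiles(raster, k = hote_pk_order[1], l = hote_pk_order[2],
                      delays = delays, pairs = pairs)
    out$HOTEPk <- score_matrix(ps, "pk")
  }
  if ("HOTECI" %in% measures) {
    ps <- te_profiles(raster, k = hote_ci_order[1], l = hote_ci_order[2],
                      delays = delays, pairs = pairs)
    out$HOTECI <- score_matrix(ps, "ci", tau_ms = tau_ms, T_ms = T_ms)
  }
  if ("D1TE" %in% measures) {
    ps <- te_profiles(raster, k = 1, l = 1, delays = 1, pairs = pairs)
    out$D1TE <- score_matrix(ps, "pk")
    out$D1TE$measure <- "D1TE"
  }
  for (v in c("NCC", "NCCH")) {
    want <- measures[startsWith(measures, v) &
                       measures %in% paste0(v, c("Pk", "CI"))]
    if (length(want) == 0) next
    ps <- cc_profiles(raster, tolower(v), delays = delays, pairs = pairs)
    if (paste0(v, "Pk") %in% want)
      out[[paste0(v, "Pk")]] <- score_matrix(ps, "pk",
                                             absolute = (v == "NCC"))
    if (paste0(v, "CI") %in% want)
      out[[paste0(v, "CI")]] <- score_matrix(ps, "ci", tau_ms = tau_ms,
                                             T_ms = T_ms,
                                             absolute = (v == "NCC"))
  }
  out[intersect(measures, names(out))]
}

# delay grid covering ~30 ms of real time at a given bin width; at widths
# above half the span this leaves a single delay, where the peak measures
# coincide with D1TE and the coincidence index is undefined
delay_grid_for_bin <- function(bin_ms, span_ms = 30) {
  seq_len(max(1, floor(span_ms / bin_ms)))
}
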