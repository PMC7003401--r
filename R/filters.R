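#' Indel filter
#'
#' Removes consensus pairs whose T/C relationship requires a gap: T is
#' aligned to C globally with free end gaps (match +1, mismatch -1, gap -2
#' by default); if no purely gapless superposition attains the optimal
#' score, the optimum needs an internal gap — the hallmark of a somatic
#' indel masquerading as substitutions — and the pair is discarded.
#'
#' @param pair A [assemble_pair()] result.
#' @param params A [filter_params()].
#' @return List with `keep`, `opt_score`, `gapless_score`,
#'   `gapless_offset`.
#' @export
indel_filter <- function(pair, params = filter_params()) {
  .indel_filter_cpp(pair$T, pair$C, params$indel_match,
                    params$indel_mismatch, params$indel_gap)
}

#' Masking filter
#'
#' Replaces `T[j]` with `C[j]` at every overlapping column where at least
#' two bases of F^c's column carry allele ratio strictly greater than `e`
#' — the signature of a germline SNP whose alleles split across the tumour
#' and control consensuses.  Columns with zero filtered counts are skipped.
#'
#' @param pair A [assemble_pair()] result (kept by [indel_filter()]).
#' @param params A [filter_params()].
#' @return `pair` with `T_masked` (T after masking), `masking_events`
#'   (1-based masked T columns) and the original `T` retained.
#' @export
masking_filter <- function(pair, params = filter_params()) {
  res <- .masking_filter_cpp(pair$T, pair$C, pair$offset_TC,
                             pair$Fc$counts, params$e)
  pair$T_masked <- res$masked
  pair$masking_events <- res$events
  pair
}

#' Multi-locus filter
#'
#' Discards pairs whose frequency matrices fire the masking indicator at
#' `mask_discard_threshold` or more distinct columns — the signature of an
#' alignment chimera built from reads of several genomic copies of a shared
#' repeat.  Events are counted from F^c and (by default) also from F^t.
#'
#' @param pair A [masking_filter()] result.
#' @param params A [filter_params()].
#' @return List with `keep` and `events` (distinct firing columns,
#'   1-based in T's frame).
#' @export
multi_locus_filter <- function(pair, params = filter_params()) {
  ev <- .multi_locus_events_cpp(pair$Ft$counts, pair$Fc$counts,
                                pair$offset_TC, params$e,
                                params$multi_locus_use_ft)
  list(keep = length(ev) < params$mask_discard_threshold, events = ev)
}
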