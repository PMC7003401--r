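#' Build a generalised suffix array
#'
#' Indexes every suffix of length `>= min_prefix` of every segment (and of
#' each segment's reverse complement when `include_revcomp = TRUE`, the
#' auxiliary-array configuration) in lexicographic order.  Suffix comparison
#' treats running off a segment end as smallest; ties between identical
#' suffixes break by (segment, offset).
#'
#' @param segments A [segment_set()] (or data.frame with `sequence`, `qual`,
#'   `origin`).
#' @param include_revcomp Also index reverse complements (auxiliary array).
#' @param min_prefix Minimum indexed suffix length; also the section prefix
#'   length (default 30).
#' @param full_order Order suffixes fully lexicographically (the
#'   documented contract).  `FALSE` sorts by the 30-character section key
#'   only, leaving within-section order arbitrary — everything downstream
#'   of section partitioning is invariant to it, and the pipeline uses this
#'   to skip all deep suffix comparisons at scale.
#' @return An object of class `gsa`.
#' @export
build_gsa <- function(segments, include_revcomp = FALSE, min_prefix = 30L,
                      full_order = TRUE) {
  origin_int <- as.integer(segments$origin == "control")
  corpus <- .corpus_build_cpp(segments$sequence, segments$qual, origin_int)
  ptr <- .gsa_build_cpp(corpus, isTRUE(include_revcomp),
                        as.integer(min_prefix), isTRUE(full_order))
  structure(list(ptr = ptr, corpus = corpus, segments = segments,
                 min_prefix = as.integer(min_prefix),
                 includes_revcomp = isTRUE(include_revcomp),
                 n = .gsa_size_cpp(ptr)),
            class = "gsa")
}

#' @export
print.gsa <- function(x, ...) {
  cat("gsa:", format(x$n, big.mark = ","), "suffixes over",
      nrow(x$segments), "segment(s); min_prefix =", x$min_prefix,
      if (x$includes_revcomp) "(with reverse complements)" else "", "\n")
  invisible(x)
}

#' GSA entry table
#'
#' Materialises the sorted suffix table with exact adjacent LCP values.
#' Intended for small arrays (tests, debugging); the TSV dump of an array is
#' `write.table(gsa_entries(g), ...)`.
#'
#' @param gsa A [build_gsa()] result.
#' @return data.frame with `rank`, `segment`, `offset` (0-based), `origin`,
#'   `lcp` (of ranks i-1, i; `NA` for rank 1), `orientation`,
#'   `source_segment`.
#' @export
gsa_entries <- function(gsa) .gsa_entries_cpp(gsa$ptr)

#' Partition a GSA into sections
#'
#' Sections are the maximal runs of consecutive entries in which every
#' adjacent pair shares a prefix of length `>= min_prefix`; singleton runs
#' are size-1 sections and every entry belongs to exactly one section.
#'
#' @param gsa A [build_gsa()] result.
#' @param prefix_len Also compute each section's exact shared prefix length
#'   (O(section size) per section; disable for very large arrays).
#' @return data.frame with `lo`, `hi` (0-based, half-open entry ranks),
#'   `tumour_suffixes`, `control_suffixes`, `prefix_len`.
#' @export
split_sections <- function(gsa, prefix_len = TRUE) {
  .gsa_sections_cpp(gsa$ptr, isTRUE(prefix_len))
}

#' Select tumour-enriched sections
#'
#' A section is enriched when it contains at least `pmss` tumour-read
#' suffixes and its control-suffix fraction does not exceed `e_cont` —
#' i.e. with the default `e_cont = 0` the section must consist exclusively
#' of tumour suffixes.  `e_cont > 0` tolerates tumour-in-normal
#' contamination placing a few control suffixes inside a genuinely somatic
#' section.
#'
#' @param sections data.frame from [split_sections()].
#' @param params A [detection_params()].
#' @return The enriched subset of `sections`.
#' @export
enriched_sections <- function(sections, params = detection_params()) {
  tot <- sections$tumour_suffixes + sections$control_suffixes
  keep <- sections$tumour_suffixes >= params$pmss &
    sections$control_suffixes <= params$e_cont * tot
  sections[keep, , drop = FALSE]
}

#' Extract tumour reads contributing to enriched sections
#'
#' The deduplicated set of tumour segments contributing at least one suffix
#' to at least one enriched section; control segments are never extracted.
#'
#' @param enriched data.frame of enriched sections (with `lo`, `hi`), or
#'   `NULL` to evaluate the enrichment predicate in place from `params`.
#' @param gsa The primary array the sections refer to.
#' @param params A [detection_params()] (used when `enriched` is `NULL`).
#' @return The extracted rows of the segment set underlying `gsa`.
#' @export
extract_block_reads <- function(enriched, gsa, params = detection_params()) {
  idx0 <- if (is.null(enriched)) {
    .gsa_extract_cpp(gsa$ptr, params$e_cont, params$pmss)
  } else {
    .gsa_extract_sections_cpp(gsa$ptr, enriched$lo, enriched$hi)
  }
  gsa$segments[idx0 + 1L, , drop = FALSE]
}

#' Construct variant blocks from an auxiliary array
#'
#' One block per auxiliary section holding at least `amss` suffixes.  Member
#' shifts place every member's section suffix at the same anchor column
#' (`shift = anchor - suffix_offset`, anchor = largest member offset), so
#' the block is a gapless multi-read alignment with leftmost column 0.
#'
#' @param aux_gsa Auxiliary array built with `include_revcomp = TRUE` from
#'   the extracted tumour reads.
#' @param params A [detection_params()].
#' @return An object of class `variant_blocks`.
#' @export
variant_blocks <- function(aux_gsa, params = detection_params()) {
  ptr <- .blocks_build_cpp(aux_gsa$ptr, params$amss)
  structure(list(ptr = ptr, gsa = aux_gsa, n = .blocks_size_cpp(ptr)),
            class = "variant_blocks")
}

#' @export
print.variant_blocks <- function(x, ...) {
  cat("variant_blocks:", x$n, "block(s)\n")
  invisible(x)
}

#' @method as.data.frame variant_blocks
#' @export
as.data.frame.variant_blocks <- function(x, ...) {
  df <- .blocks_df_cpp(x$ptr)
  # map auxiliary segment indices back to the segment identifiers
  df$segment_id <- x$gsa$segments$segment_id[df$segment_id]
  df$orientation <- c("forward", "revcomp")[df$orientation + 1L]
  df
}

#' Remove redundant variant blocks
#'
#' Among blocks whose member sets of (segment, orientation) are identical,
#' exactly one survives: the one with the lexicographically smallest
#' serialised member list.  Idempotent and order-insensitive.
#'
#' @param blocks A [variant_blocks()] object.
#' @return A deduplicated `variant_blocks` object.
#' @export
dedupe_blocks <- function(blocks) {
  ptr <- .blocks_dedupe_cpp(blocks$ptr)
  structure(list(ptr = ptr, gsa = blocks$gsa, n = .blocks_size_cpp(ptr)),
            class = "variant_blocks")
}
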