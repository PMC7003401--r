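#' Detect somatic SNVs in paired tumour-control reads
#'
#' Runs the five pipeline stages: preprocessing (optional exact-match
#' tumour-read prefilter, N-splitting), dual-suffix-array SNV detection,
#' consensus-pair construction, false-positive filtering, and SNV calling
#' against the reference.  The reference is used only by the prefilter, by
#' the optional consensus-level reference screen, and to compute final
#' coordinates; detection itself is mapping-free.
#'
#' @param tumour,control Reads: data.frames with `sequence` and `qual`
#'   (phred+33), or FASTQ paths.
#' @param reference Named character vector of reference sequences, FASTA
#'   path, or a [reference_index()].  `NULL` runs detection only (no
#'   coordinates, no emfilter, no screen).
#' @param params A [detection_params()].
#' @param filters A [filter_params()].
#' @param emfilter Apply the exact-match tumour-read prefilter (library
#'   default `FALSE`; the command-line front-end enables it by default).
#'   Does not change the final call set.
#' @param ref_screen Skip blocks whose tumour consensus occurs verbatim in
#'   the reference (either strand).  Such blocks cannot produce somatic
#'   calls under the filter cascade; screening them is a consensus-level
#'   extension of the exact-match prefilter that sharply reduces runtime at
#'   depth.  Set `FALSE` to process every block.
#' @param require_support Only call variants whose consensus base carries
#'   phred-filtered support on both sides (default `TRUE`).
#' @param pmss Optional vector of pMSS values to run; the (expensive)
#'   primary suffix array is shared across runs.  With more than one value
#'   the return value is a named list of results, one per pMSS.
#' @param verbose Print per-stage progress to stderr.
#' @return List of class `sarcall_result`: `calls` (chrom, pos 0-based,
#'   ref, alt, support, multiallelic) and `report` (per-stage counts); or a
#'   named list of such results when `pmss` has several values.
#' @export
detect_snvs <- function(tumour, control, reference, params = detection_params(),
                        filters = filter_params(), emfilter = FALSE,
                        ref_screen = !is.null(reference),
                        require_support = TRUE, pmss = params$pmss,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message("[sarcall] ", ...)
  if (is.character(tumour)) tumour <- read_fastq(tumour)
  if (is.character(control)) control <- read_fastq(control)
  ref <- if (!is.null(reference)) reference_index(reference) else NULL
  if (is.null(ref) && (emfilter || ref_screen))
    stop("configuration error: emfilter/ref_screen need a reference")

  report <- list(tumour_reads = nrow(tumour), control_reads = nrow(control))

  if (emfilter) {
    tumour <- exact_match_filter(tumour, ref)
    say("emfilter kept ", nrow(tumour), " tumour reads")
  }
  report$tumour_reads_kept <- nrow(tumour)

  # lean segment path: the pipeline never consumes segment identifiers, so
  # N-splitting and corpus construction are fused in C++ (split_on_n()
  # provides the bookkeeping variant of the same operation)
  built <- .corpus_build_split_cpp(tumour$sequence, tumour$qual,
                                   control$sequence, control$qual,
                                   params$min_prefix)
  report$tumour_segments <- built$tumour_segments
  report$control_segments <- built$control_segments

  empty_calls <- data.frame(chrom = character(), pos = numeric(),
                            ref = character(), alt = character(),
                            support = integer(), multiallelic = logical(),
                            stringsAsFactors = FALSE)
  pmss <- as.integer(pmss)
  finish <- function(report, params) {
    structure(list(calls = empty_calls, report = report, params = params,
                   filters = filters,
                   contigs = if (!is.null(ref)) ref$lengths else NULL),
              class = "sarcall_result")
  }
  if (built$tumour_segments == 0) {
    report$calls <- 0L
    out <- lapply(pmss, function(pm) finish(report, within_pmss(params, pm)))
    names(out) <- paste0("pmss", pmss)
    return(if (length(out) == 1) out[[1]] else out)
  }

  say("building primary suffix array over ",
      built$tumour_segments + built$control_segments, " segments")
  corpus <- built$corpus
  primary <- list(ptr = .gsa_build_cpp(corpus, FALSE, params$min_prefix,
                                       params$min_prefix != 30L),
                  corpus = corpus)
  report$primary_suffixes <- .gsa_size_cpp(primary$ptr)
  # pair outcomes are memoised on the tumour consensus and shared across
  # the pMSS legs of this call (mirror blocks and re-extracted loci reuse)
  cache <- .pair_cache_new_cpp()

  run_leg <- function(pm) {
    leg_params <- within_pmss(params, pm)
    leg_report <- report
    idx0 <- .gsa_extract_cpp(primary$ptr, params$e_cont, pm)
    leg_report$extracted_reads <- length(idx0)
    say("pMSS=", pm, ": extracted ", length(idx0),
        " tumour segments from enriched sections")
    if (length(idx0) == 0) {
      leg_report$calls <- 0L
      return(finish(leg_report, leg_params))
    }
    aux_corpus <- .gsa_subset_corpus_cpp(primary$corpus, idx0)
    aux_ptr <- .gsa_build_cpp(aux_corpus, TRUE, params$min_prefix,
                              params$min_prefix != 30L)
    leg_report$auxiliary_suffixes <- .gsa_size_cpp(aux_ptr)

    bptr <- .blocks_build_cpp(aux_ptr, params$amss)
    leg_report$blocks <- .blocks_size_cpp(bptr)
    bptr <- .blocks_dedupe_cpp(bptr)
    leg_report$blocks_deduped <- .blocks_size_cpp(bptr)
    say(leg_report$blocks, " blocks (", leg_report$blocks_deduped,
        " after dedup)")

    res <- .process_blocks_cpp(bptr, primary$ptr,
                               if (is.null(ref)) NULL else ref$ptr,
                               params$p, filters$e,
                               filters$mask_discard_threshold,
                               filters$multi_locus_use_ft,
                               params$max_mismatches,
                               isTRUE(ref_screen) && !is.null(ref),
                               isTRUE(require_support), filters$indel_match,
                               filters$indel_mismatch, filters$indel_gap,
                               cache)
    .gsa_release_cpp(aux_ptr)  # return the entry buffer to the reuse pool
    leg_report <- c(leg_report, res$stats)

    raw <- res$calls
    if (nrow(raw) > 0 && !is.null(ref)) raw$chrom <- ref$names[raw$chrom_idx]
    merged <- merge_calls(raw)
    leg_report$raw_calls <- nrow(raw)
    leg_report$calls <- nrow(merged)
    say(nrow(merged), " SNV calls")
    structure(list(calls = merged, report = leg_report, params = leg_params,
                   filters = filters,
                   contigs = if (!is.null(ref)) ref$lengths else NULL),
              class = "sarcall_result")
  }
  out <- lapply(pmss, run_leg)
  .gsa_release_cpp(primary$ptr)
  names(out) <- paste0("pmss", pmss)
  if (length(out) == 1) out[[1]] else out
}

within_pmss <- function(params, pm) {
  params$pmss <- as.integer(pm)
  params
}

#' @export
print.sarcall_result <- function(x, ...) {
  cat("sarcall result:", nrow(x$calls), "SNV call(s)\n")
  r <- x$report
  cat(sprintf(
    "  reads %d+%d | segments %d+%d | blocks %s (dedup %s) | pairs %s | calls %d\n",
    r$tumour_reads, r$control_reads, r$tumour_segments, r$control_segments,
    format(r$blocks %||% 0), format(r$blocks_deduped %||% 0),
    format(r$pairs_kept %||% 0), r$calls))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
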