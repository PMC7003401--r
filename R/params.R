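#' Detection parameters
#'
#' Parameters of suffix-array-based SNV detection.  Defaults follow the
#' published algorithm: sections require a shared prefix of `min_prefix = 30`
#' characters; a primary-array section is *enriched* when it contains at
#' least `pmss = 2` tumour-read suffixes and its control-suffix fraction is
#' at most `e_cont = 0` (i.e. by default the section must be tumour
#' exclusive; raising `e_cont` tolerates tumour-in-normal contamination);
#' auxiliary-array sections need at least `amss = 4` suffixes to form a
#' variant block; consensus construction counts only bases with phred
#' `>= p = 35`.
#'
#' @param min_prefix Minimum shared prefix length defining a section (bases).
#' @param e_cont Maximum tolerated control-suffix fraction inside an
#'   enriched section (proportion in `[0, 1)`).
#' @param pmss Minimum tumour-suffix count of an enriched primary section.
#' @param amss Minimum suffix count of an auxiliary section (block size).
#' @param p Phred threshold for consensus frequency matrices.
#' @param max_mismatches Maximum mismatches allowed when mapping a control
#'   consensus to the reference.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_prefix = 30L, e_cont = 0, pmss = 2L,
                             amss = 4L, p = 35L, max_mismatches = 5L) {
  stopifnot(min_prefix >= 1, pmss >= 1, e_cont >= 0, e_cont < 1,
            amss >= 1, p >= 0, max_mismatches >= 0)
  structure(list(min_prefix = as.integer(min_prefix), e_cont = e_cont,
                 pmss = as.integer(pmss), amss = as.integer(amss),
                 p = as.integer(p),
                 max_mismatches = as.integer(max_mismatches)),
            class = "detection_params")
}

#' False-positive filter parameters
#'
#' @param e Allele-ratio threshold of the masking indicator: a frequency
#'   matrix column fires when at least two bases have ratio strictly greater
#'   than `e` (default 0.1).
#' @param mask_discard_threshold Number of masking events at which the
#'   multi-locus filter discards a consensus pair (default 5).
#' @param multi_locus_use_ft Count multi-locus events from the tumour matrix
#'   F^t as well as from the control matrix F^c (default `TRUE`).
#' @param indel_match,indel_mismatch,indel_gap Alignment scores used by the
#'   indel filter's overlap alignment of T against C.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(e = 0.1, mask_discard_threshold = 5L,
                          multi_locus_use_ft = TRUE, indel_match = 1L,
                          indel_mismatch = -1L, indel_gap = -2L) {
  stopifnot(e >= 0, e < 1, mask_discard_threshold >= 1)
  structure(list(e = e,
                 mask_discard_threshold = as.integer(mask_discard_threshold),
                 multi_locus_use_ft = isTRUE(multi_locus_use_ft),
                 indel_match = as.integer(indel_match),
                 indel_mismatch = as.integer(indel_mismatch),
                 indel_gap = as.integer(indel_gap)),
            class = "filter_params")
}

#' Simulation configuration
#'
#' Describes one paired tumour-control targeted sequencing simulation:
#' a random reference, implanted isolated SNVs and clustered SNVs (sSRSC:
#' `k >= 2` somatic SNVs within a `ssrsc_window = 100` bp window), germline
#' SNPs shared by both samples, and uniform single-end read sampling with a
#' two-level phred error model (correct bases get `phred_high`, sequencing
#' errors get `phred_low`; a configurable fraction of errors may be
#' mis-assigned `phred_high` to exercise the phred filter imperfectly).
#'
#' The default per-base error rate 0.0035 makes roughly 70% of 100 bp
#' tumour reads exact reference matches, matching the exact-match fraction
#' reported for empirically profiled simulated data.
#'
#' @param ref_length Reference length in bases (>= 1000).
#' @param gc_fraction Target GC fraction of the reference.
#' @param coverage Fold coverage per dataset (per sample).
#' @param read_length Read length in bases (>= 30).
#' @param per_base_error_rate Probability of a sequencing error per base.
#' @param phred_high,phred_low Phred scores of correct / error bases.
#' @param hq_error_fraction Fraction of error bases mis-assigned
#'   `phred_high`.
#' @param n_snvs Number of isolated somatic SNVs.
#' @param allele_frequencies Allele frequencies recycled over isolated SNVs
#'   and clusters; every entry must lie in (0, 1].
#' @param ssrsc_count Number of somatic short-range SNV clusters.
#' @param ssrsc_k_range Integer interval for cluster sizes (default [2, 20]).
#' @param ssrsc_window Cluster window length in bases (default 100).
#' @param germline_snp_rate Per-base probability of a germline SNP (shared
#'   by tumour and control).
#' @param seed RNG seed; identical configurations produce byte-identical
#'   datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ref_length = 1e5, gc_fraction = 0.41, coverage = 30,
                       read_length = 100L, per_base_error_rate = 0.0035,
                       phred_high = 40L, phred_low = 20L,
                       hq_error_fraction = 0, n_snvs = 20L,
                       allele_frequencies = 0.5, ssrsc_count = 0L,
                       ssrsc_k_range = c(2L, 20L), ssrsc_window = 100L,
                       germline_snp_rate = 0.001, seed = 1L) {
  if (ref_length < 1000)
    stop("configuration error: ref_length must be at least 1000 bases")
  if (read_length < 30)
    stop("configuration error: read_length must be at least 30 bases")
  if (length(allele_frequencies) < 1 ||
      any(allele_frequencies <= 0 | allele_frequencies > 1))
    stop("configuration error: allele frequencies must lie in (0, 1]")
  stopifnot(coverage > 0, per_base_error_rate >= 0, per_base_error_rate < 1,
            gc_fraction >= 0, gc_fraction <= 1, n_snvs >= 0, ssrsc_count >= 0,
            length(ssrsc_k_range) == 2, ssrsc_k_range[1] >= 2,
            ssrsc_k_range[1] <= ssrsc_k_range[2], ssrsc_window >= 1,
            germline_snp_rate >= 0, germline_snp_rate < 1,
            hq_error_fraction >= 0, hq_error_fraction <= 1)
  structure(list(ref_length = ref_length, gc_fraction = gc_fraction,
                 coverage = coverage, read_length = as.integer(read_length),
                 per_base_error_rate = per_base_error_rate,
                 phred_high = as.integer(phred_high),
                 phred_low = as.integer(phred_low),
                 hq_error_fraction = hq_error_fraction,
                 n_snvs = as.integer(n_snvs),
                 allele_frequencies = as.numeric(allele_frequencies),
                 ssrsc_count = as.integer(ssrsc_count),
                 ssrsc_k_range = as.integer(ssrsc_k_range),
                 ssrsc_window = as.integer(ssrsc_window),
                 germline_snp_rate = germline_snp_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}
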