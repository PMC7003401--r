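# Deterministic constructed fixtures and a per-session cache for the heavy
# acceptance simulations.

# error-free reads copied from a haplotype: `starts` are 0-based; minus-strand
# reads are reverse-complemented with reversed (constant) qualities
reads_from_ref <- function(hap, starts, strands, len = 100L, q = 40L) {
  seqs <- substring(hap, starts + 1, starts + len)
  seqs[strands == 1] <- rc_chr(seqs[strands == 1])
  data.frame(id = sprintf("r%03d", seq_along(starts)), sequence = seqs,
             qual = strrep(intToUtf8(33L + q), len), start = starts,
             strand = strands, stringsAsFactors = FALSE)
}

# The canonical dual-suffix-array case: one somatic SNV covered by exactly
# two forward and two reverse tumour reads.  Each strand group forms
# tumour-exclusive primary sections of size 2 (>= pMSS = 2 but < 4); only
# the auxiliary array, which holds reverse complements, unites all four
# reads into sections of size >= aMSS = 4.
dual_strand_fixture <- function(seed = 42L) {
  ref <- make_reference(3000, gc = 0.5, seed = seed)
  pos <- 1500L
  ref_base <- substr(ref, pos + 1, pos + 1)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  hap <- paste0(substr(ref, 1, pos), alt_base,
                substr(ref, pos + 2, nchar(ref)))
  tumour <- reads_from_ref(hap, starts = c(1420L, 1440L, 1430L, 1450L),
                           strands = c(0L, 0L, 1L, 1L))
  cstarts <- as.integer(seq(1200L, 1800L, by = 10L))
  control <- reads_from_ref(ref, cstarts,
                            strands = rep_len(c(0L, 1L), length(cstarts)))
  list(reference = setNames(ref, "chrF"), tumour = tumour,
       control = control, pos = pos, ref_base = ref_base,
       alt_base = alt_base)
}

# ---------------------------------------------------------------------------
# acceptance-scale simulations, computed once per test session
# ---------------------------------------------------------------------------

.accept_cache <- new.env(parent = emptyenv())

# the rare-SNV series: 200 kb reference, 500x coverage, 40 SNVs per dataset,
# mean allele frequencies 50% ... <1% (0.5%), seeds 1-7
accept_afs <- c(0.5, 0.25, 0.1, 0.05, 0.02, 0.01, 0.005)

# datasets 6 and 7 (AF <= 1%) additionally run pMSS = 4 for the recall
# ordering criterion; the primary suffix array is shared between legs
accept_rare_run <- function(i) {
  key <- sprintf("rare_%d", i)
  if (!is.null(.accept_cache[[key]])) return(.accept_cache[[key]])
  cfg <- sim_config(ref_length = 2e5, coverage = 500, n_snvs = 40,
                    allele_frequencies = accept_afs[i], seed = i)
  sim <- simulate_dataset(cfg)
  pmss <- if (i >= 6) c(2L, 4L) else 2L
  res <- detect_snvs(sim$tumour, sim$control, sim$reference,
                     emfilter = TRUE, pmss = pmss)
  if (length(pmss) == 1) res <- setNames(list(res), paste0("pmss", pmss))
  out <- list(truth = sim$truth, results = res)
  .accept_cache[[key]] <- out
  out
}
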