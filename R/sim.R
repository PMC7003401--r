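#' Generate a random reference sequence
#'
#' Stands in for a sampled genomic target sequence: i.i.d. bases with a
#' target GC fraction.  Deterministic for a fixed seed.
#'
#' @param length Sequence length in bases (>= 1000).
#' @param gc Target GC fraction.
#' @param seed RNG seed.
#' @return An uppercase A/C/G/T string of exactly `length` bases.
#' @export
make_reference <- function(length, gc = 0.41, seed = 1L) {
  if (length < 1000)
    stop("configuration error: reference length must be at least 1000 bases")
  stopifnot(gc >= 0, gc <= 1)
  .make_reference_cpp(length, gc, seed)
}

#' Implant somatic variants into a reference
#'
#' Places `n_snvs` isolated SNVs and `ssrsc_count` clusters (sSRSC) of
#' `k` SNVs each, `k` drawn uniformly from `ssrsc_k_range`.  Isolated SNVs
#' are at least `ssrsc_window` bases from any other variant; cluster members
#' share one window and one allele frequency.  Allele frequencies are
#' recycled from `config$allele_frequencies` over isolated SNVs, then over
#' clusters.  Deterministic for a fixed `config$seed`.
#'
#' @param ref Reference string (or named length-1 character vector; the name
#'   becomes the chromosome name, default `"chr1"`).
#' @param config A [sim_config()].
#' @return A list with `truth` (chrom, pos 0-based, ref_base, alt_base, af,
#'   cluster_id) and `germline` (pos, ref_base, alt_base, het).
#' @export
implant_variants <- function(ref, config) {
  chrom <- if (!is.null(names(ref))) names(ref)[1] else "chr1"
  ref <- unname(ref)
  L <- nchar(ref)
  w <- config$ssrsc_window
  margin <- config$read_length
  slot <- 3L * w
  usable <- max(0L, (L - 2L * margin) %/% slot)
  n_slots <- config$n_snvs + config$ssrsc_count
  if (n_slots > usable)
    stop("configuration error: reference too short to place ", n_slots,
         " variant loci at >= ", w, " bp spacing")
  bases <- c("A", "C", "G", "T")
  refb <- strsplit(ref, "", fixed = TRUE)[[1]]

  res <- withr::with_seed(config$seed, {
    truth <- NULL
    if (n_slots > 0) {
      slots <- sort(sample.int(usable, n_slots))
      kinds <- rep(c("snv", "cluster"),
                   c(config$n_snvs, config$ssrsc_count))
      afs <- rep_len(config$allele_frequencies, n_slots)
      rows <- vector("list", n_slots)
      for (i in seq_len(n_slots)) {
        # middle third of the slot keeps >= w to both neighbouring slots
        base0 <- margin + (slots[i] - 1L) * slot + w
        if (kinds[i] == "snv") {
          pos <- base0 + sample.int(w, 1L) - 1L
          alt <- sample(setdiff(bases, refb[pos + 1L]), 1L)
          rows[[i]] <- data.frame(chrom = chrom, pos = pos,
                                  ref_base = refb[pos + 1L], alt_base = alt,
                                  af = afs[i], cluster_id = NA_character_,
                                  stringsAsFactors = FALSE)
        } else {
          kr <- seq(config$ssrsc_k_range[1], config$ssrsc_k_range[2])
          k <- if (length(kr) == 1L) kr else sample(kr, 1L)
          pos <- base0 + sort(sample.int(w, k)) - 1L
          alt <- vapply(pos, function(p)
            sample(setdiff(bases, refb[p + 1L]), 1L), "")
          rows[[i]] <- data.frame(chrom = chrom, pos = pos,
                                  ref_base = refb[pos + 1L], alt_base = alt,
                                  af = afs[i],
                                  cluster_id = sprintf("c%03d", i),
                                  stringsAsFactors = FALSE)
        }
      }
      truth <- do.call(rbind, rows)
    } else {
      truth <- data.frame(chrom = character(), pos = integer(),
                          ref_base = character(), alt_base = character(),
                          af = numeric(), cluster_id = character(),
                          stringsAsFactors = FALSE)
    }
    n_germ <- if (config$germline_snp_rate > 0)
      stats::rbinom(1L, L, config$germline_snp_rate) else 0L
    germline <- data.frame(pos = integer(), ref_base = character(),
                           alt_base = character(), het = logical(),
                           stringsAsFactors = FALSE)
    if (n_germ > 0) {
      gpos <- sort(sample.int(L, n_germ)) - 1L
      gpos <- setdiff(gpos, truth$pos)
      if (length(gpos) > 0) {
        galt <- vapply(gpos, function(p)
          sample(setdiff(bases, refb[p + 1L]), 1L), "")
        germline <- data.frame(pos = gpos, ref_base = refb[gpos + 1L],
                               alt_base = galt,
                               het = sample(c(TRUE, FALSE), length(gpos),
                                            replace = TRUE,
                                            prob = c(2 / 3, 1 / 3)),
                               stringsAsFactors = FALSE)
      }
    }
    list(truth = truth, germline = germline)
  })
  stopifnot(all(res$truth$ref_base != res$truth$alt_base))
  res
}

#' Simulate single-end reads for one sample
#'
#' Control reads are drawn from the reference plus germline SNPs; tumour
#' reads additionally carry the somatic alleles of the sites they overlap
#' with probability equal to the sites' allele frequency (one haplotype draw
#' per read; cluster members co-occur).  Every base is substituted with
#' probability `per_base_error_rate`; substituted bases receive `phred_low`
#' (or `phred_high` for a `hq_error_fraction` of them) and all other bases
#' `phred_high`.  Both strands are sampled uniformly.  The read count is
#' `round(coverage * ref_length / read_length)`.
#'
#' @param ref Reference string.
#' @param truth Somatic truth table (from [implant_variants()]).
#' @param germline Germline SNP table (from [implant_variants()]).
#' @param config A [sim_config()].
#' @param origin `"tumour"` or `"control"`.
#' @param seed RNG seed; defaults to a stream derived from `config$seed`
#'   and the origin.
#' @return data.frame with `id`, `sequence`, `qual`, `start` (0-based),
#'   `strand` (0 forward / 1 reverse).
#' @export
simulate_reads <- function(ref, truth, germline, config,
                           origin = c("tumour", "control"), seed = NULL) {
  origin <- match.arg(origin)
  ref <- unname(ref)
  stopifnot(config$read_length <= nchar(ref), config$coverage > 0)
  if (is.null(seed))
    seed <- config$seed * 8L + if (origin == "tumour") 1L else 2L
  n <- round(config$coverage * nchar(ref) / config$read_length)
  res <- .sim_reads_cpp(ref, as.integer(truth$pos), truth$alt_base,
                        truth$af, as.integer(germline$pos),
                        germline$alt_base, germline$het, n,
                        config$read_length, config$per_base_error_rate,
                        config$phred_high, config$phred_low,
                        config$hq_error_fraction, origin == "tumour", seed)
  data.frame(id = sprintf("%s%06d", substr(origin, 1, 1),
                          seq_len(length(res$sequence))),
             sequence = res$sequence, qual = res$qual, start = res$start,
             strand = res$strand, stringsAsFactors = FALSE)
}

#' Simulate a complete paired tumour-control dataset
#'
#' Convenience wrapper: reference, implanted variants, tumour and control
#' reads.  Identical configurations (including the seed) give byte-identical
#' output.
#'
#' @param config A [sim_config()].
#' @param chrom Chromosome name of the simulated reference.
#' @return A list with `reference` (named character), `truth`, `germline`,
#'   `tumour`, `control` and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), chrom = "chr1") {
  ref <- setNames(make_reference(config$ref_length, config$gc_fraction,
                                 config$seed), chrom)
  imp <- implant_variants(ref, config)
  tumour <- simulate_reads(ref, imp$truth, imp$germline, config, "tumour")
  control <- simulate_reads(ref, imp$truth, imp$germline, config, "control")
  list(reference = ref, truth = imp$truth, germline = imp$germline,
       tumour = tumour, control = control, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits `reference.fa`, `tumour.fastq`, `control.fastq` and `truth.vcf`
#' into `dir`.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fa"),
             tumour = file.path(dir, "tumour.fastq"),
             control = file.path(dir, "control.fastq"),
             truth = file.path(dir, "truth.vcf"))
  write_fasta(sim$reference, paths["reference"])
  write_fastq(sim$tumour, paths["tumour"])
  write_fastq(sim$control, paths["control"])
  contigs <- setNames(nchar(sim$reference), names(sim$reference))
  write_truth_vcf(sim$truth, paths["truth"], contigs)
  invisible(paths)
}

#' Evaluate SNV calls against a truth set
#'
#' A call is a hit iff its `(chrom, pos, alt)` triple matches a truth record
#' exactly.  Beyond overall precision and recall, computes the
#' cluster-stratified metrics `k_recall = k_hits / k_total` and
#' `k_precision = k_hits / (k_fp + k_hits)`, where a k-cluster is a truth
#' sSRSC of size `k`; `k_fp` counts false-positive calls falling inside a
#' genuine k-cluster's span plus the members of reported clusters (calls
#' chained at gaps <= `window`) composed entirely of false positives.
#'
#' @param calls data.frame with `chrom`, `pos` (0-based), `alt`.
#' @param truth Truth table with `chrom`, `pos`, `alt_base` (or `alt`),
#'   optional `cluster_id`.
#' @param window Cluster window length in bases (default 100).
#' @return A list of class `eval_result`: `hits`, `fp`, `fn`, `precision`,
#'   `recall`, `precision_defined`, and named vectors `k_total`, `k_hits`,
#'   `k_fp`, `k_recall`, `k_precision`.
#' @export
evaluate_calls <- function(calls, truth, window = 100L) {
  if (is.null(truth$alt)) truth$alt <- truth$alt_base
  if (is.null(calls$pos) || is.null(truth$pos))
    stop("validation error: calls and truth need 0-based `pos` columns")
  key <- function(d) paste(d$chrom, d$pos, d$alt, sep = ":")
  tk <- key(truth)
  ck <- if (nrow(calls) > 0) unique(key(calls)) else character()
  hits <- sum(tk %in% ck)
  fp <- length(setdiff(ck, tk))
  fn <- length(tk) - hits
  precision_defined <- (hits + fp) > 0
  precision <- if (precision_defined) hits / (hits + fp) else 0
  recall <- if (length(tk) > 0) hits / length(tk) else NA_real_

  # --- k-stratified metrics over truth clusters -----------------------------
  k_total <- k_hits <- k_fp <- integer(0)
  if (!is.null(truth$cluster_id) && any(!is.na(truth$cluster_id))) {
    cl <- split(seq_len(nrow(truth)), truth$cluster_id)
    ks <- sort(unique(vapply(cl, length, 0L)))
    k_total <- k_hits <- k_fp <- setNames(integer(length(ks)),
                                          as.character(ks))
    fp_keys <- setdiff(ck, tk)
    fp_df <- if (length(fp_keys) > 0) {
      parts <- strsplit(fp_keys, ":", fixed = TRUE)
      data.frame(chrom = vapply(parts, `[[`, "", 1),
                 pos = as.integer(vapply(parts, `[[`, "", 2)),
                 stringsAsFactors = FALSE)
    } else data.frame(chrom = character(), pos = integer())
    for (idx in cl) {
      k <- as.character(length(idx))
      k_total[k] <- k_total[k] + length(idx)
      k_hits[k] <- k_hits[k] + sum(tk[idx] %in% ck)
      span <- range(truth$pos[idx])
      k_fp[k] <- k_fp[k] + sum(fp_df$chrom == truth$chrom[idx[1]] &
                                 fp_df$pos >= span[1] & fp_df$pos <= span[2])
    }
    # reported clusters consisting entirely of false positives
    if (nrow(calls) > 0) {
      cc <- unique(calls[, c("chrom", "pos", "alt")])
      cc <- cc[order(cc$chrom, cc$pos), ]
      cc$is_fp <- !(key(cc) %in% tk)
      grp <- cumsum(c(TRUE, diff(cc$pos) > window |
                        cc$chrom[-1] != cc$chrom[-nrow(cc)]))
      for (g in split(seq_len(nrow(cc)), grp)) {
        k <- length(g)
        if (k >= 2 && all(cc$is_fp[g])) {
          kk <- as.character(k)
          if (!kk %in% names(k_fp)) {
            k_total[kk] <- 0L
            k_hits[kk] <- 0L
            k_fp[kk] <- 0L
          }
          k_fp[kk] <- k_fp[kk] + k
        }
      }
      ord <- order(as.integer(names(k_fp)))
      k_total <- k_total[ord]
      k_hits <- k_hits[ord]
      k_fp <- k_fp[ord]
    }
  }
  k_recall <- ifelse(k_total > 0, k_hits / k_total, NA_real_)
  k_precision <- ifelse(k_hits + k_fp > 0, k_hits / (k_hits + k_fp),
                        NA_real_)
  structure(list(hits = hits, fp = fp, fn = fn, precision = precision,
                 recall = recall, precision_defined = precision_defined,
                 k_total = k_total, k_hits = k_hits, k_fp = k_fp,
                 k_recall = k_recall, k_precision = k_precision),
            class = "eval_result")
}
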