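#' Read a FASTQ file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' character vectors (Sanger phred+33 qualities), the representation the
#' rest of the package works with.
#'
#' @param path FASTQ file (gz-transparent).
#' @return A data.frame with columns `id`, `sequence`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame (or list) with `sequence` and `qual`; optional
#'   `id` (defaults to `read1..readN`).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  ids <- reads$id
  if (is.null(ids)) ids <- paste0("read", seq_along(reads$sequence))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- ids
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a reference FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# minimal VCF 4.2 body formatter shared by the call and truth writers
.vcf_header <- function(contigs = NULL, info_lines = character(),
                        source = "sarcall") {
  h <- c("##fileformat=VCFv4.2", paste0("##source=", source))
  if (!is.null(contigs))
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      as.integer(contigs)))
  c(h, info_lines,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

#' Write SNV calls as VCF 4.2
#'
#' Positions are 0-based internally and 1-based in the emitted VCF.
#'
#' @param calls data.frame with `chrom`, `pos` (0-based), `ref`, `alt` and
#'   optionally `support`.
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths.
#' @param params Optional `detection_params` recorded in the header.
#' @export
write_vcf <- function(calls, path, contigs = NULL, params = NULL) {
  info_lines <- c(
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Number of consensus pairs reporting the call\">",
    "##INFO=<ID=MULTIALLELIC,Number=0,Type=Flag,Description=\"Another ALT was called at this site\">")
  src <- "sarcall"
  if (!is.null(params))
    src <- sprintf("sarcall (pMSS=%d,aMSS=%d,e_cont=%g,p=%d)", params$pmss,
                   params$amss, params$e_cont, params$p)
  lines <- .vcf_header(contigs, info_lines, src)
  if (nrow(calls) > 0) {
    support <- if (is.null(calls$support)) rep(1L, nrow(calls)) else
      calls$support
    info <- paste0("SUPPORT=", support)
    if (!is.null(calls$multiallelic))
      info <- ifelse(calls$multiallelic, paste0(info, ";MULTIALLELIC"), info)
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", calls$chrom,
                              as.integer(calls$pos) + 1L, calls$ref,
                              calls$alt, info))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a truth VCF for a simulated dataset
#'
#' @param truth Truth table from [implant_variants()] (`pos` 0-based).
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths.
#' @export
write_truth_vcf <- function(truth, path, contigs = NULL) {
  info_lines <- c(
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Simulated somatic allele frequency\">",
    "##INFO=<ID=CLUSTER,Number=1,Type=String,Description=\"sSRSC cluster label\">")
  lines <- .vcf_header(contigs, info_lines, "sarcall simulate")
  if (nrow(truth) > 0) {
    info <- paste0("AF=", format(truth$af, trim = TRUE, scientific = FALSE))
    info <- ifelse(is.na(truth$cluster_id), info,
                   paste0(info, ";CLUSTER=", truth$cluster_id))
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", truth$chrom,
                              as.integer(truth$pos) + 1L, truth$ref_base,
                              truth$alt_base, info))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF of SNVs
#'
#' Minimal reader for the VCFs this package writes (and any SNV-only VCF
#' with one ALT per record).  Positions come back 0-based.
#'
#' @param path VCF path.
#' @return data.frame with `chrom`, `pos` (0-based), `ref`, `alt`, and, when
#'   present in INFO, `af`, `cluster_id`, `support`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, "", i)
  info <- get(8)
  grab <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- regexpr(paste0("(^|;)", key, "=[^;]*"), info) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  data.frame(chrom = get(1), pos = as.integer(get(2)) - 1L, ref = get(4),
             alt = get(5), af = suppressWarnings(as.numeric(grab("AF"))),
             cluster_id = grab("CLUSTER"),
             support = suppressWarnings(as.integer(grab("SUPPORT"))),
             stringsAsFactors = FALSE)
}
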