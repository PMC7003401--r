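#' Map a control consensus to the reference
#'
#' Built-in seed-and-extend backend: every 30-mer of C (both strands) seeds
#' a candidate leftmost coordinate in the reference suffix array; candidates
#' are extended gaplessly over the full length of C and the placement with
#' the fewest mismatches wins if it is unique and within
#' `params$max_mismatches`.  Ties are reported as ambiguous (unmapped).
#'
#' @param C Control consensus string.
#' @param reference A [reference_index()] (or coercible).
#' @param params A [detection_params()].
#' @return List with `mapped`, `chrom`, `m` (0-based leftmost coordinate),
#'   `strand`, `mismatches`, `unique`.
#' @export
map_control <- function(C, reference, params = detection_params()) {
  ref <- reference_index(reference)
  res <- .map_control_cpp(C, ref$ptr, params$max_mismatches)
  res$chrom <- ref$names[res$chrom]
  res
}

#' Call SNVs from a filtered consensus pair
#'
#' Emits one call per single-character T/C mismatch at columns both
#' consensuses cover: `mu = m + i` with `i` the 0-based mismatch index in
#' C's frame.  For minus-strand mappings both sequences are implicitly
#' reverse-complemented first.  Columns whose consensus base lacks
#' phred-filtered support on either side are not called (a variant must be
#' backed by at least one base with phred `>= p`).
#'
#' @param pair A pair that passed all filters (uses `T_masked` when
#'   present).
#' @param mapping A [map_control()] result.
#' @param require_support Drop calls at support-less columns (default TRUE).
#' @return data.frame with `chrom`, `pos` (0-based `mu`), `ref`, `alt`.
#' @export
call_snvs <- function(pair, mapping, require_support = TRUE) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  if (!isTRUE(mapping$mapped)) return(empty)
  Tm <- if (!is.null(pair$T_masked)) pair$T_masked else pair$T
  tc <- strsplit(Tm, "", fixed = TRUE)[[1]]
  cc <- strsplit(pair$C, "", fixed = TRUE)[[1]]
  off <- pair$offset_TC
  ov_lo <- max(0L, off)
  ov_hi <- min(length(tc), off + length(cc)) - 1L
  if (ov_hi < ov_lo) return(empty)
  ov <- ov_lo:ov_hi
  j <- ov[tc[ov + 1L] != cc[ov - off + 1L]]
  if (isTRUE(require_support))
    j <- j[pair$support_T[j + 1L] & pair$support_C[j - off + 1L]]
  if (length(j) == 0) return(empty)
  i <- j - off  # 0-based index in C's frame
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (identical(mapping$strand, "-")) {
    mu <- mapping$m + (length(cc) - 1L - i)
    data.frame(chrom = mapping$chrom, pos = mu,
               ref = unname(comp[cc[i + 1L]]),
               alt = unname(comp[tc[j + 1L]]), stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = mapping$chrom, pos = mapping$m + i,
               ref = cc[i + 1L], alt = tc[j + 1L], stringsAsFactors = FALSE)
  }
}

#' Merge per-pair calls into a final call set
#'
#' Identical `(chrom, pos, ref, alt)` records merge with summed support;
#' records sharing a site but disagreeing on ALT are all kept and flagged
#' multiallelic.  Output sorts by `(chrom, pos, alt)`.
#'
#' @param calls data.frame with `chrom`, `pos`, `ref`, `alt` (one row per
#'   per-pair call).
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `support`,
#'   `multiallelic`.
#' @export
merge_calls <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      support = integer(), multiallelic = logical(),
                      stringsAsFactors = FALSE))
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[[`, "", 1),
                    pos = as.numeric(vapply(parts, `[[`, "", 2)),
                    ref = vapply(parts, `[[`, "", 3),
                    alt = vapply(parts, `[[`, "", 4),
                    support = as.integer(agg$Freq),
                    stringsAsFactors = FALSE)
  site <- paste(out$chrom, out$pos, sep = ":")
  out$multiallelic <- site %in% site[duplicated(site)]
  out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
}
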