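#' Phred-filtered frequency matrix of a gapless alignment
#'
#' Tallies per-column base counts of an alignment given as reads plus
#' integer column shifts.  `counts` excludes bases with phred `< p`;
#' `any_phred_counts` includes every base.
#'
#' @param alignment data.frame with `sequence`, `qual` (phred+33), `shift`.
#' @param p Phred threshold (default 35).
#' @return List of class `frequency_matrix`: `counts` and
#'   `any_phred_counts` (4 x W integer matrices, rows A,C,G,T), and `start`
#'   (alignment-frame column of matrix column 1).
#' @export
frequency_matrix <- function(alignment, p = 35L) {
  res <- .consensus_views_cpp(alignment$sequence, alignment$qual,
                              as.integer(alignment$shift), as.integer(p))
  structure(list(counts = res$counts,
                 any_phred_counts = res$any_phred_counts,
                 start = res$start),
            class = "frequency_matrix")
}

#' Phred-filtered consensus string of a frequency matrix
#'
#' Per column: the base with the numerically largest phred-filtered count;
#' ties resolve by the any-phred count among the tied bases, then by the
#' lexicographically smallest base.  Columns whose filtered counts are all
#' zero fall back to the any-phred tally entirely (keeping the consensus
#' gapless) and carry no phred support.
#'
#' @param F A [frequency_matrix()] (or list with `counts`,
#'   `any_phred_counts`).
#' @return The consensus string, with attribute `support`: logical vector
#'   marking columns whose consensus base has phred-filtered support.
#' @export
consensus_string <- function(F) {
  res <- .consensus_from_f_cpp(F$counts, F$any_phred_counts)
  structure(res$consensus, support = res$support)
}

#' Recruit control reads covering a tumour consensus
#'
#' Control-read-derived suffixes whose first 30 characters exactly equal a
#' 30-mer of `T` (or of its reverse complement) are located by suffix-array
#' interval search; each matching read is placed at the implied shift in
#' `T`'s frame (reverse-strand recruits are reverse-complemented first).  A
#' read matching at several placements keeps the placement with the most
#' supporting 30-mers and is dropped on an exact tie.
#'
#' @param T Tumour consensus string (length >= 30).
#' @param gsa The primary array (contains the control segments).
#' @return data.frame with `segment_id`, `shift`, `revcomp`, `votes`.
#' @export
recruit_control <- function(T, gsa) {
  stopifnot(nchar(T) >= 30)
  df <- .recruit_control_cpp(T, gsa$ptr)
  df$segment_id <- gsa$segments$segment_id[df$segment]
  df$sequence <- gsa$segments$sequence[df$segment]
  df$qual <- gsa$segments$qual[df$segment]
  rc <- df$revcomp
  if (any(rc)) {
    df$sequence[rc] <- .revcomp_cpp(df$sequence[rc])
    df$qual[rc] <- vapply(df$qual[rc], function(q)
      paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = ""), "")
  }
  df[, c("segment_id", "shift", "revcomp", "votes", "sequence", "qual")]
}

#' Assemble a tumour-control consensus pair
#'
#' Builds the tumour consensus `T` from the block alignment and the control
#' consensus `C` from a recruited control alignment in `T`'s coordinate
#' frame.  Pairs without any recruited control read are discarded (`NULL`):
#' calling without control evidence is never attempted.
#'
#' @param block_alignment data.frame with `sequence`, `qual`, `shift`
#'   (tumour reads, already oriented).
#' @param recruited data.frame with `sequence`, `qual`, `shift` (control
#'   reads in `T`'s frame, already oriented), e.g. from
#'   [recruit_control()].
#' @param p Phred threshold (default 35).
#' @return List of class `consensus_pair` with `T`, `C`, `offset_TC`
#'   (column of `C[1]` in `T`'s frame), `Ft`, `Fc`, `support_T`,
#'   `support_C`; or `NULL` when recruitment is empty.
#' @export
assemble_pair <- function(block_alignment, recruited, p = 35L) {
  if (is.null(recruited) || nrow(recruited) == 0) return(NULL)
  rt <- .consensus_views_cpp(block_alignment$sequence, block_alignment$qual,
                             as.integer(block_alignment$shift),
                             as.integer(p))
  rc <- .consensus_views_cpp(recruited$sequence, recruited$qual,
                             as.integer(recruited$shift), as.integer(p))
  structure(list(T = rt$consensus, C = rc$consensus,
                 offset_TC = rc$start - rt$start,
                 Ft = list(counts = rt$counts,
                           any_phred_counts = rt$any_phred_counts),
                 Fc = list(counts = rc$counts,
                           any_phred_counts = rc$any_phred_counts),
                 support_T = rt$support, support_C = rc$support),
            class = "consensus_pair")
}
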