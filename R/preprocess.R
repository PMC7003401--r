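#' Construct a segment set
#'
#' A segment set is the unit of suffix-array construction: N-free read
#' substrings with aligned phred strings and a tumour/control origin label.
#'
#' @param sequence Character vector of A/C/G/T strings.
#' @param qual Character vector of phred+33 quality strings (same lengths).
#' @param origin `"tumour"` or `"control"`, recycled.
#' @param id Segment identifiers (default `seg1..segN`).
#' @param source Source read identifiers (default = `id`).
#' @return data.frame of class `segment_set`.
#' @export
segment_set <- function(sequence, qual, origin, id = NULL, source = NULL) {
  origin <- rep_len(origin, length(sequence))
  stopifnot(all(origin %in% c("tumour", "control")),
            length(qual) == length(sequence),
            all(nchar(qual) == nchar(sequence)))
  if (is.null(id)) id <- sprintf("seg%d", seq_along(sequence))
  if (is.null(source)) source <- id
  structure(data.frame(segment_id = id, source_read_id = source,
                       sequence = sequence, qual = qual, origin = origin,
                       stringsAsFactors = FALSE),
            class = c("segment_set", "data.frame"))
}

#' Split reads at N characters
#'
#' Reads are split at `'N'`s; the maximal N-free substrings of length
#' `>= min_len` are kept in left-to-right order with phred strings sliced in
#' step, shorter fragments are discarded.
#'
#' @param reads data.frame with `sequence` and `qual` (phred+33); optional
#'   `id` and `origin`.
#' @param origin Origin label when `reads$origin` is absent.
#' @param min_len Minimum segment length to keep (default 30).
#' @return A [segment_set()] (possibly empty).
#' @export
split_on_n <- function(reads, origin = "tumour", min_len = 30L) {
  res <- .split_on_n_cpp(reads$sequence, reads$qual, as.integer(min_len))
  ids <- if (is.null(reads$id)) paste0("read", seq_along(reads$sequence)) else
    reads$id
  org <- if (is.null(reads$origin)) rep(origin, length(reads$sequence)) else
    reads$origin
  segment_set(res$sequence, res$qual, org[res$source],
              id = paste0(ids[res$source], "/", res$part),
              source = ids[res$source])
}

#' Build a reference index
#'
#' Suffix-array index over the reference used by the exact-match prefilter
#' and by control-consensus mapping.
#'
#' @param reference Named character vector of sequences, or a FASTA path.
#' @return An object of class `reference_index`.
#' @export
reference_index <- function(reference) {
  if (inherits(reference, "reference_index")) return(reference)
  if (is.character(reference) && length(reference) == 1 &&
      !grepl("^[ACGTacgt]+$", reference) && file.exists(reference))
    reference <- read_fasta(reference)
  if (is.null(names(reference)))
    names(reference) <- paste0("chr", seq_along(reference))
  ptr <- .ref_index_cpp(names(reference), toupper(reference))
  structure(list(ptr = ptr, names = names(reference),
                 lengths = setNames(nchar(reference), names(reference))),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat("reference_index:", length(x$names), "sequence(s),",
      format(sum(x$lengths), big.mark = ","), "bp\n")
  invisible(x)
}

#' Exact-match tumour-read prefilter (emfilter)
#'
#' Discards tumour reads that occur as exact, full-length, gapless
#' substrings of the reference on either strand; all other reads are kept
#' verbatim.  Control reads are never filtered.  The filter is idempotent
#' and, because detection never uses mapping coordinates, it does not change
#' the final call set — it only shrinks suffix-array construction input.
#'
#' @param tumour_reads data.frame with `sequence` (and any other columns,
#'   preserved).
#' @param reference A [reference_index()] (or something coercible).
#' @return The kept subset of `tumour_reads`.
#' @export
exact_match_filter <- function(tumour_reads, reference) {
  if (is.null(reference))
    stop("configuration error: emfilter enabled but no reference given")
  ref <- reference_index(reference)
  keep <- .emfilter_cpp(tumour_reads$sequence, ref$ptr)
  tumour_reads[keep, , drop = FALSE]
}
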