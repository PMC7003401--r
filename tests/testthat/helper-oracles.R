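# Brute-force oracles, independent of the package's suffix-array code paths:
# plain string enumeration, radix sorting and quadratic scans.

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

rev_str <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

# enumerate and sort all suffixes of length >= min_prefix; ties between
# identical suffix strings break by (segment, offset).  Standard string
# comparison already sorts a proper prefix before its extensions, matching
# the end-of-segment-smallest convention.
oracle_gsa <- function(sequences, min_prefix = 30L) {
  rows <- list()
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    L <- nchar(s)
    if (L < min_prefix) next
    for (o in 0:(L - min_prefix)) {
      rows[[length(rows) + 1]] <-
        data.frame(suffix = substr(s, o + 1, L), segment = i, offset = o,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(suffix = character(), segment = integer(),
                      offset = integer(), lcp = integer()))
  df <- do.call(rbind, rows)
  df <- df[order(df$suffix, df$segment, df$offset, method = "radix"), ]
  rownames(df) <- NULL
  df$lcp <- c(NA_integer_,
              vapply(seq_len(nrow(df) - 1), function(i)
                oracle_lcp(df$suffix[i], df$suffix[i + 1]), 0L))
  df
}

oracle_lcp <- function(a, b) {
  m <- min(nchar(a), nchar(b))
  if (m == 0) return(0L)
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  d <- which(av[1:m] != bv[1:m])
  if (length(d) == 0) m else d[1] - 1L
}

# maximal runs of adjacent LCP >= min_prefix over an oracle_gsa table
oracle_sections <- function(odf, min_prefix = 30L) {
  n <- nrow(odf)
  if (n == 0)
    return(data.frame(lo = numeric(), hi = numeric()))
  brk <- c(TRUE, odf$lcp[-1] < min_prefix)
  lo <- which(brk) - 1L
  data.frame(lo = as.numeric(lo), hi = as.numeric(c(lo[-1], n)))
}

# per-column tallies of a gapless alignment (shift = column of base 1)
oracle_freq_matrix <- function(seqs, quals, shifts, p) {
  lo <- min(shifts)
  hi <- max(shifts + nchar(seqs))
  W <- hi - lo
  counts <- any <- matrix(0L, 4, W, dimnames = list(c("A", "C", "G", "T"),
                                                    NULL))
  for (i in seq_along(seqs)) {
    b <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    q <- utf8ToInt(quals[i]) - 33L
    for (j in seq_along(b)) {
      col <- shifts[i] - lo + j
      any[b[j], col] <- any[b[j], col] + 1L
      if (q[j] >= p) counts[b[j], col] <- counts[b[j], col] + 1L
    }
  }
  list(counts = counts, any = any, start = lo)
}

# quadratic recruitment oracle: every (control read, read offset, T
# position) triple on both strands; per read the placement with the most
# matching 30-mers wins, ties drop the read
oracle_recruit <- function(T, control_seqs) {
  hits <- list()
  for (i in seq_along(control_seqs)) {
    votes <- list()
    for (ori in c("fwd", "rc")) {
      r <- if (ori == "fwd") control_seqs[i] else rc_chr(control_seqs[i])
      L <- nchar(r)
      for (f in 0:(L - 30)) {
        kmer <- substr(r, f + 1, f + 30)
        qs <- 0:(nchar(T) - 30)
        for (q in qs) {
          if (substr(T, q + 1, q + 30) == kmer) {
            s <- q - f
            key <- paste(ori, s)
            votes[[key]] <- (votes[[key]] %||0% 0L) + 1L
          }
        }
      }
    }
    if (length(votes) == 0) next
    v <- unlist(votes)
    best <- which(v == max(v))
    if (length(best) > 1) next  # unresolved conflict: dropped
    key <- strsplit(names(v)[best], " ", fixed = TRUE)[[1]]
    hits[[length(hits) + 1]] <-
      data.frame(segment = i, shift = as.integer(key[2]),
                 revcomp = key[1] == "rc", votes = unname(v[best]),
                 stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(segment = integer(), shift = integer(),
                      revcomp = logical(), votes = integer()))
  do.call(rbind, hits)
}

`%||0%` <- function(x, d) if (is.null(x)) d else x

# random N-free read set over a random reference for property tests
random_segments <- function(n, len, seed, ref_len = 400) {
  withr::with_seed(seed, {
    ref <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
                 collapse = "")
    starts <- sample.int(ref_len - len + 1, n, replace = TRUE)
    seqs <- substring(ref, starts, starts + len - 1)
    flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
    seqs[flip] <- rc_chr(seqs[flip])
    quals <- vapply(seq_len(n), function(i)
      intToUtf8(33L + sample(c(20L, 40L), len, replace = TRUE)), "")
    origin <- sample(c("tumour", "control"), n, replace = TRUE)
    segment_set(seqs, quals, origin)
  })
}
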