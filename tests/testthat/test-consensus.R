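test_that("frequency_matrix filters by phred and matches brute force", {
  al <- data.frame(sequence = c("AAC", "AAC", "CGC"),
                   qual = c("II5", "II(", "III"),  # '(' = q7, '5' = q20
                   shift = c(0L, 0L, 1L), stringsAsFactors = FALSE)
  F <- frequency_matrix(al, p = 35)
  o <- oracle_freq_matrix(al$sequence, al$qual, al$shift, 35)
  expect_equal(unname(F$counts), unname(o$counts))
  expect_equal(unname(F$any_phred_counts), unname(o$any))

  # p = 0: no filtering
  F0 <- frequency_matrix(al, p = 0)
  expect_equal(F0$counts, F0$any_phred_counts)

  # alignments must be N-free (segments are split upstream)
  expect_error(frequency_matrix(data.frame(sequence = "ACNT", qual = "IIII",
                                           shift = 0L)), "non-ACGT")

  # property: random alignments equal the brute-force tally
  for (seed in 1:8) {
    segs <- withr::with_seed(seed, {
      n <- sample(2:6, 1)
      data.frame(
        sequence = vapply(seq_len(n), function(i)
          paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""), ""),
        qual = vapply(seq_len(n), function(i)
          intToUtf8(33L + sample(0:45, 20, TRUE)), ""),
        shift = sample(0:9, n, TRUE), stringsAsFactors = FALSE)
    })
    F <- frequency_matrix(segs, p = 35)
    o <- oracle_freq_matrix(segs$sequence, segs$qual, segs$shift, 35)
    expect_equal(unname(F$counts), unname(o$counts))
    expect_equal(unname(F$any_phred_counts), unname(o$any))
  }
})

test_that("consensus tie cascade: filtered count, any-phred count, lexicographic", {
  mk <- function(counts, any) list(counts = counts, any_phred_counts = any)
  m <- function(...) matrix(c(...), nrow = 4,
                            dimnames = list(c("A", "C", "G", "T"), NULL))
  # plain majority
  expect_equal(as.character(consensus_string(mk(m(3, 1, 0, 0), m(3, 1, 0, 0)))),
               "A")
  # tie A/C on filtered counts, any-phred breaks towards A
  expect_equal(as.character(consensus_string(mk(m(2, 2, 0, 0), m(3, 2, 0, 0)))),
               "A")
  # full tie resolves to the lexicographically smallest base
  expect_equal(as.character(consensus_string(mk(m(2, 0, 0, 2), m(2, 0, 0, 2)))),
               "A")
  # all-zero filtered column falls back to the any-phred tally, unsupported
  s <- consensus_string(mk(m(0, 0, 0, 0), m(1, 0, 0, 4)))
  expect_equal(as.character(s), "T")
  expect_false(attr(s, "support"))
})

test_that("bases below p never influence the consensus", {
  base_al <- data.frame(sequence = c("ACGTACGTACGTACGTACGTACGTACGTACGTAC",
                                     "ACGTACGTACGTACGTACGTACGTACGTACGTAC"),
                        qual = strrep("I", 34), shift = 0L,
                        stringsAsFactors = FALSE)
  s0 <- consensus_string(frequency_matrix(base_al))
  # add a read of garbage at phred 20: nothing changes
  noisy <- rbind(base_al,
                 data.frame(sequence = strrep("T", 34),
                            qual = strrep("5", 34), shift = 0L))
  s1 <- consensus_string(frequency_matrix(noisy))
  expect_equal(as.character(s1), as.character(s0))
})

test_that("recruit_control equals the quadratic brute-force search", {
  for (seed in 1:8) {
    ref <- make_reference(1200, seed = seed + 100)
    T <- substr(ref, 301, 420)
    ctl <- withr::with_seed(seed, {
      starts <- sample(0:1100, 12, replace = TRUE)
      seqs <- substring(ref, starts + 1, starts + 100)
      flip <- sample(c(TRUE, FALSE), 12, TRUE)
      seqs[flip] <- rc_chr(seqs[flip])
      seqs
    })
    segs <- segment_set(ctl, rep(strrep("I", 100), length(ctl)), "control")
    g <- build_gsa(segs)
    got <- recruit_control(T, g)
    want <- oracle_recruit(T, ctl)
    got <- got[order(match(got$segment_id, segs$segment_id)), ]
    expect_equal(match(got$segment_id, segs$segment_id), want$segment)
    expect_equal(got$shift, want$shift)
    expect_equal(got$revcomp, want$revcomp)
    expect_equal(got$votes, want$votes)
  }
})

test_that("reverse-complement recruits are oriented into T's frame", {
  ref <- make_reference(1000, seed = 55)
  T <- substr(ref, 101, 200)
  ctl <- rc_chr(T)  # a control read equal to revcomp(T)
  g <- build_gsa(segment_set(ctl, strrep("I", 100), "control"))
  rec <- recruit_control(T, g)
  expect_equal(nrow(rec), 1)
  expect_true(rec$revcomp)
  expect_equal(rec$shift, 0L)
  expect_equal(rec$sequence, T)  # returned pre-oriented
})

test_that("assemble_pair builds T/C and discards empty recruitment", {
  ref <- make_reference(1000, seed = 66)
  block <- data.frame(sequence = rep(substr(ref, 101, 200), 4),
                      qual = strrep("I", 100), shift = 0L,
                      stringsAsFactors = FALSE)
  rec <- data.frame(sequence = rep(substr(ref, 81, 220), 4),
                    qual = strrep("I", 140), shift = -20L,
                    stringsAsFactors = FALSE)
  pair <- assemble_pair(block, rec)
  expect_s3_class(data.frame(), "data.frame")
  expect_equal(pair$T, substr(ref, 101, 200))
  expect_equal(pair$C, substr(ref, 81, 220))
  expect_equal(pair$offset_TC, -20L)

  # a tumour-only alt column propagates into T but not C
  alt <- block
  v <- 50
  substr(alt$sequence[1], v, v) <- "A"
  substr(alt$sequence[2], v, v) <- "A"
  substr(alt$sequence[3], v, v) <- "A"
  substr(alt$sequence[4], v, v) <- "A"
  pair2 <- assemble_pair(alt, rec)
  if (substr(ref, 100 + v, 100 + v) != "A") {
    d <- which(strsplit(pair2$T, "")[[1]] !=
                 strsplit(substr(pair2$C, 21, 120), "")[[1]])
    expect_equal(d, v)
  }

  expect_null(assemble_pair(block, rec[0, ]))
})

test_that("dedupe_blocks is idempotent and order-insensitive", {
  core <- substr(make_reference(1000, seed = 3), 101, 160)
  seqs <- c(core, substr(core, 1, 55), paste0("ACGTA", substr(core, 1, 55)))
  segs <- segment_set(seqs, strrep("I", nchar(seqs)), "tumour")
  aux <- build_gsa(segs, include_revcomp = TRUE)
  vb <- variant_blocks(aux, detection_params(amss = 3))
  dd <- dedupe_blocks(vb)
  expect_lt(dd$n, vb$n)  # overlapping sections with equal member sets merge
  dd2 <- dedupe_blocks(dd)
  expect_equal(as.data.frame(dd2), as.data.frame(dd))
  # survivors have pairwise distinct (segment, orientation) member sets
  df <- as.data.frame(dd)
  keys <- vapply(split(df, df$block), function(b)
    paste(sort(paste(b$segment_id, b$orientation)), collapse = "|"), "")
  expect_equal(anyDuplicated(keys), 0L)
})
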