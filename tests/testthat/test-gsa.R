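test_that("build_gsa reproduces hand-computed suffix orders", {
  seg <- segment_set("ACA", "III", "tumour")
  g <- build_gsa(seg, min_prefix = 1)
  e <- gsa_entries(g)
  # brute force: "A"@2 < "ACA"@0 < "CA"@1
  expect_equal(e$offset, c(2L, 0L, 1L))
  expect_equal(e$lcp, c(NA, 1L, 0L))

  # palindromic read: its reverse complement contributes identical suffixes
  seg2 <- segment_set("ACGT", "IIII", "tumour")
  g2 <- build_gsa(seg2, include_revcomp = TRUE, min_prefix = 4)
  e2 <- gsa_entries(g2)
  expect_equal(nrow(e2), 2)
  expect_equal(e2$offset, c(0L, 0L))
  expect_equal(e2$lcp[2], 4L)
})

test_that("an empty corpus yields an empty GSA and no sections", {
  seg <- segment_set(character(0), character(0), character(0))
  g <- build_gsa(seg)
  expect_equal(g$n, 0)
  expect_equal(nrow(split_sections(g)), 0)
  expect_equal(nrow(gsa_entries(g)), 0)
})

test_that("GSA order, LCP and sections match brute force on random corpora", {
  for (seed in 1:12) {
    n <- 5 + (seed %% 4) * 15
    len <- 40 + (seed %% 3) * 20
    segs <- random_segments(n, len, seed)
    for (mp in c(30L, if (seed %% 4 == 0) 12L)) {
      g <- build_gsa(segs, min_prefix = mp)
      e <- gsa_entries(g)
      o <- oracle_gsa(segs$sequence, min_prefix = mp)
      expect_equal(e$segment, o$segment)
      expect_equal(e$offset, o$offset)
      expect_equal(e$lcp, o$lcp)
      sec <- split_sections(g)
      osec <- oracle_sections(o, mp)
      expect_equal(sec$lo, osec$lo)
      expect_equal(sec$hi, osec$hi)
      # tallies: every entry in exactly one section, counts consistent
      expect_equal(sum(sec$tumour_suffixes + sec$control_suffixes), nrow(e))
      # soundness: the shared prefix of each section is >= min_prefix
      expect_true(all(sec$prefix_len >= mp))
    }
  }
})

test_that("key-only ordering yields identical sections and extraction", {
  segs <- random_segments(60, 60, 99)
  g_full <- build_gsa(segs)
  g_key <- build_gsa(segs, full_order = FALSE)
  sf <- split_sections(g_full, prefix_len = FALSE)
  sk <- split_sections(g_key, prefix_len = FALSE)
  expect_equal(sf[c("lo", "hi", "tumour_suffixes", "control_suffixes")],
               sk[c("lo", "hi", "tumour_suffixes", "control_suffixes")])
  p <- detection_params()
  expect_identical(extract_block_reads(NULL, g_full, p)$segment_id,
                   extract_block_reads(NULL, g_key, p)$segment_id)
})

test_that("enrichment predicate selects tumour-exclusive sections", {
  sec <- data.frame(lo = c(0, 10, 20, 30), hi = c(10, 20, 30, 40),
                    tumour_suffixes = c(2L, 1L, 3L, 5L),
                    control_suffixes = c(0L, 0L, 3L, 1L))
  p0 <- detection_params()  # e_cont = 0, pmss = 2
  e0 <- enriched_sections(sec, p0)
  expect_equal(e0$lo, 0)  # only the pure section with >= 2 tumour suffixes
  # pmss = 1 admits the singleton pure section
  expect_equal(enriched_sections(sec, detection_params(pmss = 1))$lo,
               c(0, 10))
  # e_cont relaxation admits contaminated sections up to the allowance
  e2 <- enriched_sections(sec, detection_params(e_cont = 0.2))
  expect_equal(e2$lo, c(0, 30))  # 1/6 <= 0.2 passes; 3/6 does not
})

test_that("extraction deduplicates and never extracts control reads", {
  seqs <- c(strrep("A", 35), strrep("A", 40), strrep("A", 33))
  segs <- segment_set(seqs, strrep("I", nchar(seqs)),
                      c("tumour", "tumour", "control"))
  g <- build_gsa(segs)
  sec <- split_sections(g)
  en <- enriched_sections(sec, detection_params(pmss = 1))
  expect_equal(nrow(en), 0)  # poly-A sections all contain the control read

  segs2 <- segment_set(c(strrep("C", 35), strrep("C", 40), strrep("A", 33)),
                       strrep("I", c(35, 40, 33)),
                       c("tumour", "tumour", "control"))
  g2 <- build_gsa(segs2)
  ex <- extract_block_reads(NULL, g2, detection_params())
  expect_equal(sort(ex$segment_id), c("seg1", "seg2"))  # each read once

  # explicit-section route agrees with the fused predicate
  en2 <- enriched_sections(split_sections(g2), detection_params())
  ex2 <- extract_block_reads(en2, g2)
  expect_equal(sort(ex2$segment_id), sort(ex$segment_id))
})

test_that("variant blocks align members on the shared anchor column", {
  # four reads containing one 30-mer at offsets 0, 5, 10, 15
  core <- substr(make_reference(1000, seed = 3), 101, 130)
  pads <- substr(make_reference(1000, seed = 4), 1, 60)
  seqs <- vapply(c(0, 5, 10, 15), function(o)
    paste0(substr(pads, 1, o), core,
           substr(pads, 21, 50 - o)), "")
  segs <- segment_set(seqs, strrep("I", nchar(seqs)), "tumour")
  aux <- build_gsa(segs, include_revcomp = TRUE)
  vb <- variant_blocks(aux, detection_params(amss = 4))
  df <- as.data.frame(vb)
  fwd <- df[df$orientation == "forward", ]
  core_block <- fwd[order(fwd$segment_id), ]
  expect_true(nrow(core_block) >= 4)
  # brute-force check: members of one block place the shared 30-mer on the
  # same columns
  b1 <- df[df$block == df$block[1], ]
  starts <- b1$shift
  expect_equal(length(unique(starts + 0)), length(starts))  # shifts distinct
  # anchor convention: leftmost alignment column is 0
  expect_true(all(tapply(df$shift, df$block, min) == 0))
  # the core section aligns the four reads at shifts 15, 10, 5, 0
  shift_sets <- tapply(df$shift, df$block, function(s)
    paste(sort(s), collapse = ","))
  expect_true("0,5,10,15" %in% shift_sets)

  # threshold: a section of size 3 builds no block at amss = 4
  segs3 <- segs[1:3, ]
  class(segs3) <- c("segment_set", "data.frame")
  aux3 <- build_gsa(segs3, include_revcomp = TRUE)
  vb3 <- variant_blocks(aux3, detection_params(amss = 4))
  expect_equal(vb3$n, 0)
})

test_that("raising pmss or amss never adds sections or blocks", {
  segs <- random_segments(80, 60, 7)
  g <- build_gsa(segs)
  sec <- split_sections(g, prefix_len = FALSE)
  n_prev <- Inf
  for (pm in 1:5) {
    n_now <- nrow(enriched_sections(sec, detection_params(pmss = pm)))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
  ex <- extract_block_reads(NULL, g, detection_params(pmss = 1))
  if (nrow(ex) > 0) {
    aux <- build_gsa(ex, include_revcomp = TRUE)
    b_prev <- Inf
    for (am in 2:6) {
      b_now <- variant_blocks(aux, detection_params(amss = am))$n
      expect_lte(b_now, b_prev)
      b_prev <- b_now
    }
  }
})

test_that("dual-array case: 2+2 strand coverage needs the auxiliary array", {
  fx <- dual_strand_fixture()
  segs <- segment_set(c(fx$tumour$sequence, fx$control$sequence),
                      c(fx$tumour$qual, fx$control$qual),
                      rep(c("tumour", "control"),
                          c(nrow(fx$tumour), nrow(fx$control))))
  g <- build_gsa(segs)
  # pMSS = 2 extracts both strand groups from their size-2 pure sections
  ex2 <- extract_block_reads(NULL, g, detection_params(pmss = 2))
  expect_equal(nrow(ex2), 4)
  # pMSS = 4 extracts nothing: each strand group only reaches 2
  ex4 <- extract_block_reads(NULL, g, detection_params(pmss = 4))
  expect_equal(nrow(ex4), 0)
  # the auxiliary array (with reverse complements) unites the four reads
  aux <- build_gsa(ex2, include_revcomp = TRUE)
  vb <- dedupe_blocks(variant_blocks(aux, detection_params(amss = 4)))
  expect_gt(vb$n, 0)
  df <- as.data.frame(vb)
  sizes <- table(df$block)
  expect_true(any(sizes >= 4))
})
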