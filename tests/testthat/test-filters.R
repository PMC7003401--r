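mk_pair <- function(T, C, offset_TC = 0L, Fc = NULL, Ft = NULL) {
  count_of <- function(s) {
    m <- matrix(0L, 4, nchar(s), dimnames = list(c("A", "C", "G", "T"),
                                                 NULL))
    b <- strsplit(s, "")[[1]]
    for (j in seq_along(b)) m[b[j], j] <- 10L
    m
  }
  if (is.null(Fc)) Fc <- list(counts = count_of(C))
  if (is.null(Ft)) Ft <- list(counts = count_of(T))
  structure(list(T = T, C = C, offset_TC = offset_TC, Fc = Fc, Ft = Ft),
            class = "consensus_pair")
}

test_that("indel filter discards pairs whose optimum needs a gap", {
  ref <- make_reference(1000, seed = 12)
  T <- substr(ref, 101, 180)
  # C = T with one base deleted: forced internal gap
  C_del <- paste0(substr(T, 1, 40), substr(T, 42, 80))
  expect_false(indel_filter(mk_pair(T, C_del))$keep)
  # one substitution: gapless optimum
  C_sub <- T
  substr(C_sub, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                   substr(T, 40, 40))[1]
  expect_true(indel_filter(mk_pair(T, C_sub))$keep)
  # identity
  expect_true(indel_filter(mk_pair(T, T))$keep)
})

test_that("masking fires on >= 2 control alleles strictly above e", {
  T <- strrep("A", 5)
  C <- strrep("C", 5)
  m <- function(a, c) matrix(c(a, c, 0L, 0L), nrow = 4,
                             dimnames = list(c("A", "C", "G", "T"), NULL))
  # column (A:9, C:1): ratio 0.1 is NOT > 0.1 -> no mask
  Fc <- list(counts = cbind(m(9L, 1L), m(8L, 2L), m(10L, 0L),
                            m(0L, 0L), m(5L, 5L)))
  pair <- mk_pair(T, C, 0L, Fc = Fc)
  res <- masking_filter(pair, filter_params(e = 0.1))
  # columns: 1 no (boundary), 2 yes (0.2 > 0.1), 3 no (single allele),
  # 4 skipped (zero sum), 5 yes
  expect_equal(res$masking_events, c(2L, 5L))
  expect_equal(res$T_masked, "ACAAC")
  expect_equal(res$T, T)  # original retained

  # masking is idempotent: masked columns now agree with C
  pair2 <- res
  pair2$T <- res$T_masked
  res2 <- masking_filter(pair2, filter_params(e = 0.1))
  expect_equal(res2$T_masked, res$T_masked)
  expect_equal(res2$masking_events, res$masking_events)
})

test_that("lowering e never decreases the masking-event count", {
  withr::with_seed(4, {
    Fc <- list(counts = matrix(rpois(4 * 30, 3), nrow = 4,
                               dimnames = list(c("A", "C", "G", "T"), NULL)))
  })
  T <- strrep("A", 30)
  C <- strrep("C", 30)
  prev <- -1L
  for (e in c(0.4, 0.3, 0.2, 0.1, 0.05, 0)) {
    n <- length(masking_filter(mk_pair(T, C, 0L, Fc = Fc),
                               filter_params(e = e))$masking_events)
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("multi-locus filter discards at >= 5 event columns", {
  two_allele <- matrix(c(5L, 5L, 0L, 0L), nrow = 4)
  clean <- matrix(c(10L, 0L, 0L, 0L), nrow = 4)
  mk_fc <- function(k, total = 10) {
    m <- clean[, rep(1, total), drop = FALSE]
    if (k > 0) m[, seq_len(k)] <- two_allele[, rep(1, k)]
    rownames(m) <- c("A", "C", "G", "T")
    m
  }
  T <- strrep("A", 10)
  C <- strrep("A", 10)
  for (k in c(0L, 4L, 5L, 7L)) {
    pair <- mk_pair(T, C, 0L, Fc = list(counts = mk_fc(k)),
                    Ft = list(counts = mk_fc(0)))
    res <- multi_locus_filter(pair, filter_params())
    expect_equal(length(res$events), k)
    expect_equal(res$keep, k < 5)
  }
  # events from F^t count too (same column counted once)
  pair <- mk_pair(T, C, 0L, Fc = list(counts = mk_fc(3)),
                  Ft = list(counts = mk_fc(3)))
  expect_equal(length(multi_locus_filter(pair, filter_params())$events), 3)
  pair2 <- mk_pair(T, C, 0L, Fc = list(counts = mk_fc(3)),
                   Ft = list(counts = mk_fc(5)))
  res2 <- multi_locus_filter(pair2, filter_params())
  expect_equal(length(res2$events), 5)
  expect_false(res2$keep)
  # the F^t route can be disabled
  res3 <- multi_locus_filter(pair2,
                             filter_params(multi_locus_use_ft = FALSE))
  expect_equal(length(res3$events), 3)
  expect_true(res3$keep)
})

test_that("a heterozygous SNP site yields no somatic call end to end", {
  ref <- setNames(make_reference(4000, seed = 31), "chrS")
  pos <- 2000L
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, pos + 1, pos + 1))[1]
  hap <- ref
  substr(hap, pos + 1, pos + 1) <- alt
  # both samples heterozygous: half their reads carry the SNP allele
  starts <- as.integer(seq(1800L, 2200L, by = 5L))
  mk <- function(phase_offset) {
    hap_of <- rep_len(c(TRUE, FALSE), length(starts))
    if (phase_offset) hap_of <- !hap_of
    seqs <- ifelse(hap_of,
                   substring(hap, starts + 1, starts + 100),
                   substring(unname(ref), starts + 1, starts + 100))
    st <- rep_len(c(0L, 1L, 1L, 0L), length(starts))
    seqs[st == 1] <- rc_chr(seqs[st == 1])
    data.frame(sequence = seqs, qual = strrep("I", 100),
               stringsAsFactors = FALSE)
  }
  res <- detect_snvs(mk(FALSE), mk(TRUE), ref)
  expect_equal(nrow(res$calls), 0)
})

test_that("a two-copy repeat chimera is discarded by the multi-locus filter", {
  # two reference copies of a shared 30-mer with divergent flanks; tumour
  # reads mix the copies so their alignment disagrees at many columns
  base <- make_reference(2000, gc = 0.5, seed = 77)
  core <- substr(base, 1001, 1030)
  flankA <- substr(base, 1, 60)
  flankB <- substr(base, 101, 160)
  flankC <- substr(base, 201, 260)
  flankD <- substr(base, 301, 360)
  ref <- setNames(paste0(flankA, core, flankB, strrep("T", 40), flankC,
                         core, flankD), "chrR")
  # tumour reads carry the core with one private alt each side, drawn from
  # both copies; controls tile the reference
  t1 <- paste0(substr(flankA, 31, 60), core, substr(flankB, 1, 30))
  t2 <- paste0(substr(flankC, 31, 60), core, substr(flankD, 1, 30))
  # 3:2 copy mix keeps the tumour consensus anchored on copy 1, so control
  # recruitment succeeds and the divergent flank columns become F^t events
  tum <- data.frame(sequence = c(t1, t1, t1, t2, t2),
                    qual = strrep("I", 90), stringsAsFactors = FALSE)
  # add a tumour-exclusive substitution inside the core so the section is
  # tumour-pure and reads are extracted
  for (i in 1:5) {
    s <- tum$sequence[i]
    substr(s, 45, 45) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s, 45, 45))[1]
    tum$sequence[i] <- s
  }
  cst <- as.integer(seq(0L, nchar(ref) - 90L, by = 7L))
  ctl <- data.frame(sequence = substring(unname(ref), cst + 1, cst + 90),
                    qual = strrep("I", 90), stringsAsFactors = FALSE)
  res <- detect_snvs(tum, ctl, ref, ref_screen = FALSE)
  expect_gte(res$report$multi_locus_discarded %||0% 0, 1)
  expect_equal(nrow(res$calls), 0)
})
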