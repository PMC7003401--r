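test_that("make_reference is deterministic, length-exact and GC-calibrated", {
  r1 <- make_reference(1000, gc = 0.5, seed = 1)
  r2 <- make_reference(1000, gc = 0.5, seed = 1)
  expect_identical(r1, r2)
  expect_equal(nchar(r1), 1000)
  expect_true(grepl("^[ACGT]+$", r1))
  expect_false(identical(r1, make_reference(1000, gc = 0.5, seed = 2)))

  expect_true(grepl("^[GC]+$", make_reference(1000, gc = 1, seed = 1)))

  r <- make_reference(1e5, gc = 0.41, seed = 7)
  gc <- mean(strsplit(r, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.41), 0.02)  # ~6.5 binomial sd at n = 1e5

  expect_error(make_reference(999), "configuration error")
})

test_that("implant_variants respects spacing, clustering and AF assignment", {
  ref <- make_reference(1e5, seed = 3)
  cfg <- sim_config(ref_length = 1e5, n_snvs = 20L,
                    allele_frequencies = 0.5, ssrsc_count = 0L, seed = 9)
  imp <- implant_variants(ref, cfg)
  tr <- imp$truth
  expect_equal(nrow(tr), 20)
  expect_true(all(diff(sort(tr$pos)) >= 100))
  expect_true(all(tr$ref_base != tr$alt_base))
  expect_equal(tr$ref_base,
               substring(ref, tr$pos + 1, tr$pos + 1))
  expect_true(all(tr$af == 0.5))

  cfg2 <- sim_config(ref_length = 1e5, n_snvs = 0L, ssrsc_count = 5L,
                     ssrsc_k_range = c(2L, 2L), seed = 9)
  imp2 <- implant_variants(ref, cfg2)
  tr2 <- imp2$truth
  expect_equal(nrow(tr2), 10)
  expect_equal(length(unique(tr2$cluster_id)), 5)
  spans <- tapply(tr2$pos, tr2$cluster_id, function(p) diff(range(p)))
  expect_true(all(spans < 100))
  # members of distinct clusters stay >= window apart
  expect_true(all(diff(sort(tapply(tr2$pos, tr2$cluster_id, min))) >= 100))

  cfg3 <- sim_config(ref_length = 1e5, n_snvs = 0L, ssrsc_count = 0L,
                     seed = 1)
  expect_equal(nrow(implant_variants(ref, cfg3)$truth), 0)

  # reference too short for the requested loci
  cfg4 <- sim_config(ref_length = 1000, n_snvs = 50L, seed = 1)
  expect_error(implant_variants(make_reference(1000, seed = 1), cfg4),
               "too short")
})

test_that("simulate_reads: count, determinism, zero-error substrings, AF", {
  cfg <- sim_config(ref_length = 1e4, coverage = 30, read_length = 100L,
                    per_base_error_rate = 0, germline_snp_rate = 0,
                    n_snvs = 2L, allele_frequencies = 1, seed = 5)
  ref <- make_reference(cfg$ref_length, seed = cfg$seed)
  imp <- implant_variants(ref, cfg)
  rt <- simulate_reads(ref, imp$truth, imp$germline, cfg, "tumour")
  expect_equal(nrow(rt), round(30 * 1e4 / 100))

  rt2 <- simulate_reads(ref, imp$truth, imp$germline, cfg, "tumour")
  expect_identical(rt, rt2)

  # zero error rate: every read is a substring of a haplotype or its rc
  hap <- ref
  for (i in seq_len(nrow(imp$truth)))
    substr(hap, imp$truth$pos[i] + 1, imp$truth$pos[i] + 1) <-
      imp$truth$alt_base[i]
  ok <- vapply(rt$sequence, function(s) {
    grepl(s, ref, fixed = TRUE) || grepl(s, hap, fixed = TRUE) ||
      grepl(rc_chr(s), ref, fixed = TRUE) || grepl(rc_chr(s), hap,
                                                   fixed = TRUE)
  }, TRUE)
  expect_true(all(ok))

  # AF 1.0 site: every covering tumour read carries the alt
  pos <- imp$truth$pos[1]
  cov <- rt[rt$start <= pos & rt$start + 100 > pos, ]
  base_at <- function(row) {
    s <- if (row$strand == 1) rc_chr(row$sequence) else row$sequence
    substr(s, pos - row$start + 1, pos - row$start + 1)
  }
  bases <- vapply(seq_len(nrow(cov)), function(i) base_at(cov[i, ]), "")
  expect_true(all(bases == imp$truth$alt_base[1]))

  # both strands sampled
  expect_true(all(c(0, 1) %in% rt$strand))
})

test_that("allele-frequency recovery at depth", {
  cfg <- sim_config(ref_length = 5e3, coverage = 1000, read_length = 100L,
                    per_base_error_rate = 0, germline_snp_rate = 0,
                    n_snvs = 3L, allele_frequencies = 0.3, seed = 21)
  sim <- simulate_dataset(cfg)
  for (i in seq_len(nrow(sim$truth))) {
    pos <- sim$truth$pos[i]
    cov <- sim$tumour[sim$tumour$start <= pos &
                        sim$tumour$start + 100 > pos, ]
    bases <- vapply(seq_len(nrow(cov)), function(j) {
      s <- if (cov$strand[j] == 1) rc_chr(cov$sequence[j]) else
        cov$sequence[j]
      substr(s, pos - cov$start[j] + 1, pos - cov$start[j] + 1)
    }, "")
    frac <- mean(bases == sim$truth$alt_base[i])
    sd3 <- 3 * sqrt(0.3 * 0.7 / nrow(cov))
    expect_lt(abs(frac - 0.3), sd3 + 1e-9)
  }
})

test_that("error bases carry phred_low and clean bases phred_high", {
  cfg <- sim_config(ref_length = 5e3, coverage = 20, read_length = 100L,
                    per_base_error_rate = 0.05, germline_snp_rate = 0,
                    n_snvs = 0L, seed = 2)
  sim <- simulate_dataset(cfg)
  r <- sim$control
  # reconstruct each read's true bases from the reference, compare quals
  mism_low <- match_high <- 0L
  for (i in seq_len(50)) {
    s <- r$sequence[i]; q <- utf8ToInt(r$qual[i]) - 33L
    if (r$strand[i] == 1) { s <- rc_chr(s); q <- rev(q) }
    truth <- substr(sim$reference, r$start[i] + 1, r$start[i] + 100)
    tb <- strsplit(truth, "")[[1]]; sb <- strsplit(s, "")[[1]]
    mism_low <- mism_low + sum(sb != tb & q == 20L)
    match_high <- match_high + sum(sb == tb & q == 40L)
    expect_equal(sum(sb != tb & q == 40L), 0)  # hq_error_fraction = 0
  }
  expect_gt(mism_low, 0)
  expect_gt(match_high, 0)
})

test_that("dataset output is byte-identical per seed and round-trips files", {
  cfg <- sim_config(ref_length = 2000, coverage = 5, n_snvs = 2L, seed = 17)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1, s2)

  dir <- withr::local_tempdir()
  paths <- write_dataset(s1, dir)
  rt <- read_fastq(paths["tumour"])
  expect_equal(rt$sequence, s1$tumour$sequence)
  expect_equal(rt$qual, s1$tumour$qual)
  expect_equal(unname(read_fasta(paths["reference"])),
               unname(s1$reference))
  tv <- read_vcf(paths["truth"])
  expect_equal(tv$pos, s1$truth$pos)
  expect_equal(tv$ref, s1$truth$ref_base)
  expect_equal(tv$alt, s1$truth$alt_base)
  expect_equal(tv$af, s1$truth$af)
})

test_that("evaluate_calls computes precision, recall and k metrics", {
  truth <- data.frame(chrom = "c", pos = c(10L, 500L, 900L, 905L),
                      ref_base = "A", alt_base = "T", af = 0.5,
                      cluster_id = c(NA, NA, "k1", "k1"),
                      stringsAsFactors = FALSE)
  # identity: perfect scores
  calls <- data.frame(chrom = "c", pos = truth$pos, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(unname(ev$k_recall["2"]), 1)

  # empty calls: recall 0, precision reported 0 with flag
  ev0 <- evaluate_calls(calls[0, ], truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 0)
  expect_false(ev0$precision_defined)

  # half the cluster SNVs found: k_recall = 0.5; wrong alt is not a hit
  calls2 <- data.frame(chrom = "c", pos = c(900L, 905L), ref = "A",
                       alt = c("T", "G"), stringsAsFactors = FALSE)
  ev2 <- evaluate_calls(calls2, truth)
  expect_equal(unname(ev2$k_recall["2"]), 0.5)
  expect_equal(ev2$fp, 1)  # the wrong-alt call, inside the cluster span
  expect_equal(unname(ev2$k_fp["2"]), 1)

  # an entirely false-positive reported cluster contributes k to k_fp
  calls3 <- data.frame(chrom = "c", pos = c(2000L, 2050L), ref = "A",
                       alt = "G", stringsAsFactors = FALSE)
  ev3 <- evaluate_calls(calls3, truth)
  expect_equal(unname(ev3$k_fp["2"]), 2)
  expect_equal(unname(ev3$k_precision["2"]), 0)
})
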