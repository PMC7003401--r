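test_that("map_control: exact, strand, mismatches and ambiguity", {
  ref <- setNames(make_reference(3000, seed = 41), "chrM")
  C <- substr(ref, 501, 580)
  m <- map_control(C, ref)
  expect_true(m$mapped)
  expect_equal(m$m, 500)
  expect_equal(m$strand, "+")
  expect_equal(m$mismatches, 0)
  expect_equal(m$chrom, "chrM")

  mrc <- map_control(rc_chr(C), ref)
  expect_true(mrc$mapped)
  expect_equal(mrc$m, 500)
  expect_equal(mrc$strand, "-")

  # a few mismatches still map; more than max_mismatches do not
  C2 <- C
  for (i in c(10, 30, 50)) substr(C2, i, i) <-
      setdiff(c("A", "C", "G", "T"), substr(C2, i, i))[1]
  m2 <- map_control(C2, ref)
  expect_true(m2$mapped)
  expect_equal(m2$mismatches, 3)
  expect_false(map_control(C2, ref,
                           detection_params(max_mismatches = 2))$mapped)

  # identical two-locus placements are ambiguous
  dup <- setNames(paste0(substr(ref, 1, 1000), substr(ref, 1, 1000)),
                  "chrD")
  md <- map_control(substr(ref, 101, 180), dup)
  expect_false(md$mapped)
  expect_false(md$unique)
})

test_that("call_snvs applies mu = m + i in C's frame, both strands", {
  pair <- structure(list(T = "AAATAAAAAA", C = "AAAAAAAAAA",
                         offset_TC = 0L,
                         support_T = rep(TRUE, 10),
                         support_C = rep(TRUE, 10)),
                    class = "consensus_pair")
  mapping <- list(mapped = TRUE, chrom = "chr2", m = 1000, strand = "+")
  calls <- call_snvs(pair, mapping)
  expect_equal(calls$pos, 1003)  # i = 3 (0-based index 3 differs)
  expect_equal(calls$ref, "A")
  expect_equal(calls$alt, "T")

  # identity: zero calls
  pair0 <- pair
  pair0$T <- pair0$C
  expect_equal(nrow(call_snvs(pair0, mapping)), 0)

  # minus strand: coordinates reflect, bases complement
  mm <- list(mapped = TRUE, chrom = "chr2", m = 1000, strand = "-")
  cm <- call_snvs(pair, mm)
  expect_equal(cm$pos, 1000 + (10 - 1 - 3))
  expect_equal(cm$ref, "T")
  expect_equal(cm$alt, "A")

  # offset frames: T shifted right of C
  pair2 <- structure(list(T = "GGGG", C = "AAGGGGAA", offset_TC = -2L,
                          support_T = rep(TRUE, 4),
                          support_C = rep(TRUE, 8)),
                     class = "consensus_pair")
  expect_equal(nrow(call_snvs(pair2, mapping)), 0)
  pair2$T <- "GGCG"
  c2 <- call_snvs(pair2, mapping)
  expect_equal(c2$pos, 1000 + 4)  # i = 4 in C's frame
  expect_equal(c2$ref, "G")
  expect_equal(c2$alt, "C")

  # unsupported columns are not called
  pair3 <- pair
  pair3$support_T[4] <- FALSE
  expect_equal(nrow(call_snvs(pair3, mapping)), 0)
  expect_equal(nrow(call_snvs(pair3, mapping, require_support = FALSE)), 1)
})

test_that("merge_calls merges support, flags multiallelics and sorts", {
  raw <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr1", "chr1"),
                    pos = c(100, 100, 99, 100, 50),
                    ref = c("A", "A", "C", "A", "G"),
                    alt = c("T", "T", "G", "G", "C"),
                    stringsAsFactors = FALSE)
  m <- merge_calls(raw)
  expect_equal(m$pos, c(50, 99, 100, 100))
  expect_equal(m$support[m$pos == 100 & m$alt == "T"], 2L)
  expect_true(all(m$multiallelic[m$pos == 100]))
  expect_false(any(m$multiallelic[m$pos != 100]))
  expect_equal(nrow(merge_calls(raw[0, ])), 0)
})

test_that("VCF writer emits 1-based records that round-trip and parse externally", {
  calls <- data.frame(chrom = "chr1", pos = c(99L, 100L), ref = c("A", "C"),
                      alt = c("T", "G"), support = c(2L, 5L),
                      multiallelic = FALSE, stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path, contigs = c(chr1 = 10000L))
  lines <- readLines(path)
  expect_true(any(grepl("^##fileformat=VCFv4.2$", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(as.integer(sub("^chr1\t(\\d+)\t.*", "\\1", body)),
               c(100L, 101L))  # 0-based + 1
  back <- read_vcf(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$support, calls$support)

  # cross-check with an independent VCF parser
  v <- VariantAnnotation::readVcf(path)
  expect_equal(unname(BiocGenerics::start(v)), c(100L, 101L))
  expect_equal(as.character(VariantAnnotation::ref(v)), calls$ref)
  expect_equal(as.character(unlist(VariantAnnotation::alt(v))), calls$alt)
})
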