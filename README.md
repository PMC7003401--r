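# sarcall — reference-free somatic SNV calling with generalised suffix arrays

sarcall detects somatic single-nucleotide variants in paired tumour–control
short-read data **without read mapping**. Instead of organising reads by
alignment coordinates — which fail exactly where tumours are most
interesting (clustered substitutions, low-frequency subclones) — it sorts
every read suffix of length ≥ 30 into a generalised suffix array (GSA) and
reads the biology off the array's structure:

* suffixes sharing a ≥ 30-character prefix form one contiguous *section*
  (≈ one genomic locus);
* a section containing at least `pMSS = 2` tumour-read suffixes and (up to
  a contamination allowance `e_cont`, default 0) **no** control suffixes
  betrays a tumour-exclusive allele;
* the reads of enriched sections are re-indexed with their reverse
  complements in an *auxiliary* array, whose sections of ≥ `aMSS = 4`
  suffixes become *variant blocks* — gapless multi-read alignments. The
  two-array design is what lets variants with 2 forward + 2 reverse
  supporting reads (typical of allele frequencies ≤ 1%) survive the
  error-rejection threshold;
* each block yields a phred-filtered tumour consensus `T` (only bases with
  phred ≥ `p = 35` count); control reads sharing a 30-mer with `T` are
  recruited into a control consensus `C`; indel, SNP-masking and
  multi-locus (repeat) filters remove the recurrent false-positive modes;
* remaining single-character `T`/`C` mismatches are reported at reference
  coordinate `μ = m + i` (`m` = mapping coordinate of `C`, `i` = mismatch
  index in `C`'s frame) as VCF 4.2.

The reference genome is used only by the optional exact-match prefilter
(*emfilter*) and for the final coordinates — never for detection.

The package also ships a paired tumour–control read **simulator** (isolated
SNVs, clustered sSRSC hypermutation, germline SNPs, two-level phred error
model, truth VCF) and an **evaluator** (precision/recall plus
cluster-size-stratified k-recall / k-precision), so the method's behaviour
can be reproduced at desk scale.

## Worked example

```r
library(sarcall)

cfg <- sim_config(ref_length = 20000, coverage = 50, n_snvs = 10,
                  allele_frequencies = 1.0, per_base_error_rate = 0,
                  germline_snp_rate = 0, seed = 5)
sim <- simulate_dataset(cfg)
res <- detect_snvs(sim$tumour, sim$control, sim$reference, emfilter = TRUE)
res$calls
#>    chrom   pos ref alt support multiallelic
#> 6   chr1  2018   A   T     132        FALSE
#> 7   chr1  3237   G   C     136        FALSE
#> 8   chr1  4446   T   A     128        FALSE
#> 9   chr1  6275   A   G     162        FALSE
#> 10  chr1  8926   T   A     118        FALSE
#> 1   chr1 12285   A   T     132        FALSE
#> 2   chr1 16473   T   A     150        FALSE
#> 3   chr1 17089   G   T     128        FALSE
#> 4   chr1 19453   A   C     126        FALSE
#> 5   chr1 19778   A   T     146        FALSE

ev <- evaluate_calls(res$calls, sim$truth)
c(precision = ev$precision, recall = ev$recall)
#> precision    recall
#>         1         1
```

All ten implanted SNVs are recovered at their exact 0-based coordinates
(`pos`), with the control base as `ref`, the tumour base as `alt`, and
`support` counting the consensus pairs that reported each call. At the
other end of the frequency range, the same pipeline on a 500× targeted
dataset with 40 SNVs at 1% allele frequency recovers 22/40 with zero false
positives at `pmss = 2`, but only 8/40 at `pmss = 4` — the dual-array
design at work (see `tests/testthat/test-acceptance.R`).

Command-line front-end (simulate → call → evaluate):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sarcall.R", package = "sarcall"))')
Rscript $CLI simulate --out-dir sim --ref-length 100000 --coverage 50 --seed 7
Rscript $CLI call --tumour sim/tumour.fastq --control sim/control.fastq \
                  --reference sim/reference.fa --out calls.vcf
Rscript $CLI evaluate --calls calls.vcf --truth sim/truth.vcf
```

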