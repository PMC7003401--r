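---
title: "Reference-free somatic SNV calling with generalised suffix arrays"
author: "sarcall maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free somatic SNV calling with generalised suffix arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcall)
```

## The model

Mapping-based somatic SNV callers organise reads by aligning them to a
reference genome and then compare tumour against control pileups at each
coordinate. When reads derive from loci that diverge substantially from the
reference — clustered substitutions, dense subclonal variation — their
mapping coordinates are frequently wrong and sensitivity collapses. sarcall
instead organises the reads by comparing them *to each other* inside a
generalised suffix array (GSA), so that detection needs no mapping and no
reference; the reference is consulted only by an optional exact-match
prefilter and, at the very end, to express calls in genome coordinates.

The pipeline has five stages.

**1. Preprocessing.** Tumour reads that occur as exact, full-length, gapless
substrings of the reference on either strand carry no variant information
and may be discarded (*emfilter*); this only shrinks the index, it cannot
change the calls, because detection never uses the alignment coordinates.
All reads are then split at `N` characters and the N-free pieces of length
≥ 30 are kept.

**2. Suffix-array detection.** A *primary* GSA indexes every suffix of
length ≥ 30 of every segment. Because the array is lexicographically
sorted, all suffixes sharing a common prefix of ≥ 30 characters form one
contiguous *section*; such suffixes are taken to cover the same genomic
locus. Each section is scored by its tumour and control suffix counts. A
section is **enriched** when

* it contains at least `pMSS` (default 2) tumour-read suffixes, and
* its control-suffix fraction is at most `e_cont` (default 0) — i.e. by
  default the section is tumour-exclusive; a positive `e_cont` tolerates
  tumour-in-normal contamination.

A somatic allele changes the local sequence, so the suffixes spanning it
form sections that contain *only* tumour suffixes; sections at unremarkable
loci always mix tumour and control suffixes and are never enriched. Note
the wording of the published description ("the number of tumour-read-derived
suffixes divided by the total number of suffixes is greater than e_cont")
taken literally is vacuous at `e_cont = 0`; the tumour-exclusivity reading
adopted here is the one under which the parameter's stated purpose
(contamination tolerance), the dual-array design and the pMSS-dependent
sensitivity results are all coherent.

Reads appear in the primary array as sequenced, so a variant covered by
a few reads on *each* strand splits its evidence across two disjoint
sections. This is the reason for the **dual-array design**: reads touching
any enriched section are extracted and re-indexed, together with their
reverse complements, in an *auxiliary* GSA. There the two strand groups
merge, and every auxiliary section holding at least `aMSS` (default 4)
suffixes becomes a **variant block** — a gapless multi-read alignment whose
member shifts come directly from the suffix offsets. Relaxing the primary
threshold to `pMSS = 2` while keeping `aMSS = 4` is what makes variants at
allele frequencies ≤ 1% detectable without admitting lone sequencing
errors.

**3. Consensus pairs.** Redundant blocks (identical member sets) are
removed; each surviving block yields a phred-filtered tumour consensus `T`:
per alignment column the counts of A, C, G, T with phred ≥ `p` (default
35) form the frequency matrix `F`, and the consensus base is the column
argmax, with ties broken by the any-phred counts among the tied bases and
then by the lexicographically smallest base. Columns whose filtered counts
are all zero fall back to the any-phred tally (keeping the consensus
gapless) but are flagged *unsupported*. Control reads sharing a
30-character exact match with `T` (or its reverse complement) are then
recruited through the primary array — each match fixes the read's shift in
`T`'s frame; a read matching at several shifts keeps the shift with the
most matching 30-mers and is dropped on a tie — and build the control
consensus `C` the same way. Pairs with no recruited control read are
discarded: calling without control evidence is never attempted.

**4. Filtering.** Three filters remove the recurrent false-positive modes:

* *indel filter* — `T` is aligned to `C` globally with free end gaps
  (match +1, mismatch −1, gap −2); if no gapless superposition reaches the
  optimal score, the difference between `T` and `C` requires an internal
  gap — a somatic indel masquerading as substitutions — and the pair is
  discarded. (The published internals of this filter are in supplementary
  material that is not available; the discard-on-gap contract implemented
  here is this package's own design, chosen to provably remove
  indel-induced substitution artefacts.)
* *masking filter* — at any column where ≥ 2 bases of `F^c` have allele
  ratio strictly greater than `e` (default 0.1), `T` is overwritten with
  `C`: two well-supported control alleles are the signature of a germline
  SNP, not a somatic variant.
* *multi-locus filter* — if the pair's frequency matrices fire that same
  two-allele indicator at ≥ 5 distinct columns, the pair is discarded
  wholesale: alignments built from several genomic copies of a shared
  repeat disagree at many columns at once. Events are counted from `F^c`
  and, by default, also from `F^t` (a column counts once); the published
  text attributes events to both matrices while the masking rule itself
  reads only `F^c`, so the `F^t` contribution is switchable
  (`filter_params(multi_locus_use_ft = )`).

**5. Calling.** `C` is mapped to the reference by a built-in seed-and-extend
backend (every 30-mer on both strands seeds a candidate, gapless extension,
fewest mismatches wins, ties are ambiguous and skipped). Every remaining
single-character mismatch at a column covered by both consensuses becomes a
call at coordinate `mu = m + i`, where `m` is the leftmost 0-based mapping
coordinate of `C` and `i` the mismatch index *in C's frame* (for
minus-strand mappings both sequences are implicitly reverse-complemented
first). Output is VCF 4.2 with 1-based positions, `REF` from the control
consensus and `ALT` from the tumour consensus; identical records from
overlapping pairs merge with summed `SUPPORT`.

The published coordinate formula indexes "within the tumour consensus
sequence" yet adds the index to C's mapping coordinate; the two agree only
when both consensuses start at the same column. Computing `i` in C's frame
is the only reading that produces correct coordinates when the frames are
offset, and is what this package does.

### The phred-support rule

A mismatch column is only called when the consensus base carries at least
one phred-≥ p observation on *both* sides (`require_support = TRUE`). The
fallback consensus of an all-low-quality column would otherwise convert
coincident sequencing errors — e.g. four reads sharing the same
low-quality miscall at one position of a deep pileup, which at 500–1000×
happens hundreds of times per megabase — directly into calls. The
published account states that a variant needs `aMSS` reads supporting the
allele at phred ≥ 35, which the all-zero fallback column plainly fails;
the rule makes that requirement explicit at the calling step.

### The consensus-level reference screen

`detect_snvs(ref_screen = TRUE)` (the default when a reference is given)
skips recruitment and filtering for blocks whose tumour consensus matches
the reference at every *supported* column, on either strand. Under the
filter cascade such a block cannot produce a somatic call: its supported
columns equal the reference, unsupported columns are never called, and a
control consensus differing from the reference at a well-covered column
implies a two-allele SNP column that the masking filter overwrites. The
screen is therefore a consensus-level extension of the exact-match
prefilter — the same reference-only shortcut the published pipeline
already embraces — and reduces runtime several-fold at depth, because the
vast majority of blocks assemble loci where the tumour agrees with the
reference. `ref_screen = FALSE` processes every block; the test suite
checks that both settings produce identical call sets on simulated data.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_prefix` | 30 bases | section prefix length; also the shortest indexed suffix |
| `pmss` | 2 suffixes | minimum tumour suffixes of an enriched primary section |
| `e_cont` | 0 | tolerated control-suffix fraction in an enriched section |
| `amss` | 4 suffixes | minimum auxiliary-section size forming a block |
| `p` | 35 (phred) | consensus frequency-matrix quality threshold |
| `e` | 0.1 | masking indicator allele-ratio threshold (strict `>`) |
| `mask_discard_threshold` | 5 events | multi-locus discard threshold |
| `max_mismatches` | 5 | mapping mismatch ceiling for the control consensus |

Raising `pmss` towards 4 recovers the older single-array behaviour: rare
variants whose per-strand coverage is below the threshold become
undetectable. Raising `e` weakens SNP masking; lowering it can mask true
variants that share a column with sequencing errors.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` builds a paired tumour–control targeted-sequencing
experiment at desk scale: an i.i.d. random reference with a target GC
fraction (default 0.41, human-like), implanted isolated SNVs (pairwise
separation ≥ the cluster window) and clustered SNVs (sSRSC: `k ≥ 2` SNVs
within a 100 bp window, all on one haplotype), shared germline SNPs
(default 10⁻³ per base, 2:1 het:hom), and uniform single-end sampling of
both strands with `round(coverage × L / read length)` reads per sample.

Sequencing errors use a **two-level phred model**: every base is
substituted independently with probability `per_base_error_rate`;
substituted bases get `phred_low = 20`, all others `phred_high = 40`, and
an optional `hq_error_fraction` of errors is mis-assigned the high score
to exercise the phred filter imperfectly. The default error rate of
0.0035/base is calibrated so that ~70% of 100 bp tumour reads are exact
reference matches — the exact-match fraction reported for simulations
built with an empirical error profile. `hq_error_fraction` defaults to 0:
in empirically profiled data errors concentrate at low-quality cycles by
construction, so a high-quality error is a rarity rather than a fixed
share; a nonzero value is exercised in unit tests.

The simulator deliberately omits: quality-by-cycle structure, indels,
structural variants, CNVs, PCR duplicates, insert-size structure (mates
are simulated as independent single-end reads — the caller never uses
pairing), GC-coverage bias, and genuine genomic repeat structure (the
reference is i.i.d., so 30-mers are essentially unique). A green test on
this world therefore establishes the suffix-array machinery, the phred
arithmetic, the filter cascade and the coordinate algebra — it does not
establish robustness to repeat-rich references or empirical quality
profiles, which is exactly the gap the multi-locus filter and the masking
parameter `e` exist to manage on real data.

Per-read allele assignment draws one Bernoulli(`AF`) per read for the
somatic sites it overlaps (cluster members share one allele frequency, so
co-occurrence on reads is preserved) and one Bernoulli(0.5) per overlapped
heterozygous SNP. All randomness flows through one fixed Mersenne-Twister
stream per (seed, sample), with hand-rolled draw functions rather than the
C++ standard library's distribution objects, so identical configurations
give byte-identical FASTQ and VCF output on every platform.

## Numerical and degenerate-input choices

* Suffix comparison treats running off a segment end as lexicographically
  smallest; suffixes never cross segment boundaries. Ties between
  identical suffixes order by (segment, offset).
* Only suffixes of length ≥ `min_prefix` are indexed — shorter suffixes
  can never satisfy the shared-prefix requirement, so no section changes.
* With `min_prefix = 30`, a section is exactly the set of suffixes sharing
  one 30-mer prefix. The pipeline exploits this with a key-only sort
  (`full_order = FALSE`): within-section suffix order is arbitrary but
  nothing downstream observes it; the public `build_gsa()` default keeps
  exact lexicographic order.
* `pMSS`/`aMSS` count *suffixes*, not distinct reads; a read with an
  internal ≥ 30 bp repeat can be counted twice. Accepted as documented.
* Recruitment resolves a read matching at several shifts by the number of
  supporting 30-mers (a proxy for the longest matching extension) and
  drops the read on an exact tie.
* Blocks are deduplicated on the member multiset of (source segment,
  orientation); among equals the lexicographically smallest serialised
  member list survives, making the survivor set order-insensitive.
* An empty recruitment, an unmapped or ambiguous control consensus, and a
  tumour consensus shorter than 30 bases each discard the pair with a
  counted reason; empty tumour input yields an empty call set and exit
  code 0.
* Corpora are limited to 4 Gbases of indexed text (32-bit suffix
  positions); this bounds memory at roughly 16 bytes per suffix.
* Pair outcomes are memoised on the tumour consensus together with its
  support and F^t indicator masks (canonicalised over orientation):
  everything downstream of the consensus depends only on that key plus
  structures shared within one `detect_snvs()` call, and a block and its
  reverse-complement mirror provably yield the same absolute calls. The
  memo is shared across the pMSS legs of a multi-pMSS run; it changes no
  output, only runtime.
* Execution is sequential; a thread-count option exists at the command
  line for interface compatibility and the output is byte-identical for
  every value.

## Known limitations

* The indel filter implements a stated contract (discard on forced gap),
  not the unavailable published internals; pairs spanning indels are
  dropped rather than trimmed, so indels are invisible rather than called.
* Coordinates require a unique gapless mapping of the control consensus;
  variants inside long perfect repeats are reported as ambiguous and
  skipped rather than guessed.
* The evaluator chains reported calls into clusters at gaps ≤ the window
  length when scoring cluster-level false positives; other clusterings of
  reported calls are defensible and would shift `k_precision` slightly.
* Multi-allelic sites are reported as flagged duplicate records rather
  than merged VCF `ALT` lists.
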