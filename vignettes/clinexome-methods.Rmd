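---
title: "Methods: coverage QC, variant flagging and trio de novo filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage QC, variant flagging and trio de novo filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinexome)
```

## Scope and model

`clinexome` implements the bespoke post-alignment, post-calling stages of a
clinical exome pipeline. Read alignment, duplicate marking and variant
calling are deliberately outside its scope: the package starts from a
coordinate-sorted, duplicate-marked BAM and a Platypus-style VCF, the point
at which generic tooling ends and clinically motivated, rule-based
processing begins. Four analyses are provided:

1. **Coverage QC.** Per-base coverage and quality metrics over BED targets,
   pass/fail evaluation against a good-quality depth threshold, and
   annotation of failing subregions in transcript (c.) coordinates so a
   laboratory can design fill-in assays (typically Sanger) directly from
   the report.
2. **Variant post-processing.** Parsing, allele-fraction computation,
   high/low quality flagging, intergenic-call removal and a fixed-column
   clinical TSV.
3. **Consequence classification.** A deliberately simplified class
   vocabulary sufficient to partition variants into protein-altering and
   protein-truncating groups, with both extreme (most-5′ and most-3′)
   representations of every indel.
4. **Trio analysis.** Identification of candidate de novo variants in a
   proband–parent trio by allele subtraction plus quality and parental
   coverage filters.

A deterministic synthetic-fixture generator is a first-class module: all
tests and the acceptance script run against generated references,
alignments, call sets and trios with known truth.

## Coverage metrics

For each base of a target, `pileup_profile()` reports:

| metric | definition |
|---|---|
| COV | depth of spanning, non-duplicate, primary reads |
| QCOV | spanning reads with mapping quality ≥ `mq_good` |
| MEDMQ | median mapping quality of spanning reads |
| FLMQ | fraction of spanning reads with mapping quality < `mq_good` |
| MEDBQ | median base quality of aligned read bases |
| FLBQ | fraction of aligned bases with base quality < `bq_low` |

Numerical conventions: a read "spans" a base when the base falls inside a
reference-consuming aligned block (CIGAR M/=/X) **or** a deletion (D); a
deleted position counts toward depth and mapping-quality metrics but
contributes no base quality, matching conventional pileup depth. Duplicate,
secondary, supplementary and unmapped reads are excluded from every metric.
Fraction and median metrics are undefined (reported `.`) at bases with no
contributing reads.

Defaults: `mq_good = 20` (inclusive) is the good-mapping-quality cutoff
used in clinical coverage definitions; `qcov_threshold = 15` (inclusive) is
the minimum acceptable good-quality depth; `bq_low = 10` marks clearly
unreliable base calls. All three are configurable; the 15× and MQ ≥ 20
values are the conventional clinical reporting thresholds, while `bq_low`
has no single field-wide convention and its default is simply documented
here.

A region passes QC only when **every** base reaches the QCOV threshold:
the clinical use case is fill-in of any under-covered base, so a minimum,
not an average, drives the flag. Failing bases are reported as maximal runs
(`failed_subregions()`), each annotated against every overlapping
transcript as `GENE:c.X-c.Y`.

## Transcript model and c. coordinates

Transcript databases are tab-separated with 0-based half-open exon and CDS
bounds (the UCSC/BED dialect); all API positions are 1-based (the VCF
dialect). Coding exonic bases map to `c.1..c.L` in translation order,
5′UTR bases to `c.-N`, 3′UTR bases to `c.*N`. Intronic bases anchor to the
nearest exon boundary: positions in the transcript-5′ half of an intron
anchor downstream of the donor (`c.N+k`), the 3′ half upstream of the
acceptor (`c.N-k`), and the exact midpoint anchors to the donor side. The
whole map is a bijection over the transcript span, which the test suite
verifies by exhaustive enumeration against an independent oracle.

Default-transcript selection keeps transcripts on chromosomes 1–22, X or Y
with both start and stop codons that are not known pseudogenes, then
prefers CCDS membership. Because several CCDS transcripts can remain, a
deterministic total order completes the choice: longest coding length,
then longest total exonic length, then lexicographically smallest
transcript identifier. The tie-break beyond "CCDS first" is this package's
own declared order; it guarantees permutation invariance, which matters
more for reproducibility than the specific secondary keys.

"Intergenic" (for call removal) means outside every transcript's genomic
span *including introns*: intronic calls must survive to annotation
because splice-region variants are clinically reportable.

## Quality flags

Platypus-style calls are flagged:

* base substitutions: **high** iff QUAL ≥ 100;
* insertions/deletions: **high** iff VAF = TR/TC ≥ 0.2 **and** FILTER is
  exactly `PASS`;
* anything with missing QUAL/TR/TC: **low**, never an error mid-pipeline.

All thresholds are inclusive ("at least"). Complex variants (both alleles
longer than 1 and not anchored) use the indel rule, since the QUAL rule is
defined for base substitutions only; this choice is configurable in spirit
(the thresholds are parameters) and documented here because the governing
rule for complex calls is genuinely underdetermined. Multi-allelic rows
are split per ALT allele with TR matched positionally and TC shared.
Indels of length ≤ 10 bp are "short", > 10 bp "long"; long indels are a
rare class with materially worse false-detection behaviour in short-read
data, which is why the boundary is carried through all outputs.

## Indel representations and consequence classes

An indel inside a repeat has several equally correct VCF representations.
`shift_indel()` walks the edit to both extremes and returns the most-5′
and most-3′ anchored forms; applying either to the reference yields the
identical sequence (tested by brute-force apply-edit equivalence on
hundreds of random indels). Classification uses the most-5′ form; both
forms are reported so users can re-evaluate under the other convention.
Trio matching also normalizes both sides to the most-5′ form, so a
deletion recorded at the left end of a homopolymer in one family member
matches the same deletion recorded at the right end in another.

The class vocabulary is `SY`, `NSY`, `SG`, `FS`, `IF`, `ESS`, `SS`, `EE`,
`INT`, `UTR`. CDS substitutions are translated with the standard genetic
code (SY/NSY/SG); coding indels are FS when length mod 3 ≠ 0, else IF;
intronic positions within 1–2 bp of an exon boundary are ESS, within
3–8 bp SS, otherwise INT; untranslated exonic positions are UTR; positions
in the first/last 3 bases of an internal exon are EE unless a more severe
class applies (SG always wins; coding indels keep FS/IF precedence over
EE by the severity order). Variants spanning several zones take the most
severe applicable class, with severity
SG > FS > ESS > NSY > EE > IF > SS > SY > UTR > INT.

These windows are declared simplifications: they capture the standard
splice-region conventions but are not guaranteed to reproduce any external
annotator class-for-class (in particular the exact extent of the
exon-edge class, and stop-loss substitutions, which fall outside the
vocabulary and are classified NSY). The groupings that downstream analyses
rely on are exact: protein-altering = {NSY, EE, IF, ESS, SG, FS},
protein-truncating = {ESS, SG, FS} ⊂ protein-altering.

## Trio de novo filtering

A proband call is a candidate de novo variant when

1. its normalized allele is absent from both parents,
2. its quality flag is high,
3. its TC is ≥ 15, and
4. good-quality depth (QCOV, MQ ≥ 20) at the variant position is ≥ 15 in
   both parents.

Parental matching is exact-allele and ignores the parents' own quality
flags — a low-quality parental call still counts as "present", which is
conservative against false de novo claims. Parental depth uses QCOV by
default because coverage adequacy elsewhere in the pipeline is defined in
mapping-quality-filtered terms; `use_qcov = FALSE` switches to raw COV for
users who prefer the unfiltered definition. For indels the depth is taken
at the anchor base of the most-5′ representation.

## The fixture generator

`fixture_spec()` describes a small synthetic study: contig lengths,
transcript count, target depth, read/fragment lengths, and the fractions
of low-mapping-quality (5%), low-base-quality (5%) and duplicate (5%)
reads, with 50× usable depth of 100-bp paired reads as the default —
typical values for a modern clinical exome. Identical specs produce
byte-identical files, and every generator emits a truth table (read spans
and qualities; intended variant flags; de novo assignments) so oracles
never re-parse generated files.

What the generator emulates: controlled depth with Poisson-like per-base
variation (uniform random fragment placement), mixed-quality read
populations, PCR-duplicate flags, VCF records engineered to sit on either
side of every flag threshold, homopolymer tracts on request, and trios
with inherited variants deliberately written in different indel
representations across family members.

What it does not emulate: sequencing errors, alignment artefacts
(soft-clipping, split reads), GC-dependent coverage bias, allele-specific
coverage at heterozygous sites, or caller behaviour. Passing tests
therefore demonstrate that the *post-calling logic* is correct under
controlled inputs; they say nothing about upstream caller sensitivity on
real data, which can only be established with validated experimental
datasets.

Test problem sizes were chosen to exercise every code path while keeping
the suite quick on a single CPU: 1-kb targets at 30–50× for pileup
checks (twenty seeds), one hundred random transcripts for coordinate-map
enumeration, five hundred random indels for representation equivalence,
and trios with 200 inherited plus 5 de novo variants.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile()
spec <- fixture_spec(seed = 7)
trio <- make_trio(spec, dir, n_inherited = 200, n_denovo = 5)

ref <- load_reference(trio$reference)
proband <- flag_variants(parse_vcf(trio$proband_vcf))
cand <- subtract_parents(proband, parse_vcf(trio$father_vcf),
                         parse_vcf(trio$mother_vcf), ref)
kept <- apply_denovo_filters(cand, trio$father_bam, trio$mother_bam, ref)
db <- load_transcript_db(trio$transcripts)
kept <- annotate_variants(kept, db, ref)
partition_by_consequence(kept)
```

## Known limitations

* The consequence classes are a simplification; clinical-grade annotation
  (full HGVS/CSN strings, protein-level effects) is out of scope.
* Genotype-aware trio analysis (Mendelian-error models, mosaicism) is not
  attempted; matching is presence/absence of the exact allele.
* Recovering constituent substitutions from merged MNP-style complex calls
  is out of scope; such records are flagged with the indel rule and
  classified as complex.
* Coverage profiles are computed per region in memory; very large BED
  files should be processed in batches.
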