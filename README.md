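# clinexome

Post-alignment, post-calling stages of a clinical exome pipeline, as a
tested R package. Clinical laboratories that sequence exomes need three
things that generic tooling does not provide out of the box: a per-base
answer to *"which target bases failed to reach reportable coverage, and
where is that in the gene?"*; a simple, validated high/low quality flag on
every variant call; and, for trio referrals, a short list of candidate
de novo variants. `clinexome` implements exactly those stages, starting
from a coordinate-sorted duplicate-marked BAM and a Platypus-style VCF.
Alignment, duplicate marking and variant calling are upstream and out of
scope.

## What it computes

**Coverage QC.** For every base of every BED target: depth (COV),
good-mapping-quality depth (QCOV, MQ ≥ 20), median/fraction summaries of
mapping and base quality (MEDMQ, FLMQ, MEDBQ, FLBQ). A region passes only
if min(QCOV) ≥ 15; failing bases are reported as maximal runs annotated in
transcript coordinates, e.g. `BRCA1:c.1500-c.1550`, ready for Sanger
fill-in design.

**Variant flagging.** With VAF = TR/TC (supporting / total reads):

- base substitution: `high` ⇔ QUAL ≥ 100
- insertion/deletion: `high` ⇔ VAF ≥ 0.2 **and** FILTER == `PASS`

Thresholds are inclusive; records missing TR/TC/QUAL are `low`.
Multi-allelic rows are split per ALT; intergenic calls (outside every
transcript span, introns included) are removed. Indels ≤ 10 bp are
"short", > 10 bp "long".

**Indel representations and consequences.** Every indel is reported in
its most-5′ and most-3′ anchored representation (both apply to the same
edited sequence). A simplified class vocabulary
(SY/NSY/SG/FS/IF/ESS/SS/EE/INT/UTR) supports the partitions
protein-altering = {NSY, EE, IF, ESS, SG, FS} and protein-truncating =
{ESS, SG, FS}.

**Trio de novo candidates.** Proband calls absent from both parents
(matched on 5′-normalized alleles) that are `high`, have TC ≥ 15, and
≥ 15× good-quality parental depth at the site in both parents.

**Synthetic fixtures.** A deterministic generator
(`fixture_spec()`, `make_reference()`, `simulate_alignments()`,
`spike_variants()`, `make_trio()`) produces reference FASTA, transcript
databases, BED targets, indexed alignments, call sets and trios with known
truth — the whole package is testable without controlled human data.

## Worked example: trio de novo analysis on a synthetic fixture

```r
library(clinexome)

dir <- tempfile()
spec <- fixture_spec(seed = 7)                      # 50x paired-end study
trio <- make_trio(spec, dir, n_inherited = 200, n_denovo = 5)

ref <- load_reference(trio$reference)
proband <- flag_variants(parse_vcf(trio$proband_vcf))
cand <- subtract_parents(proband, parse_vcf(trio$father_vcf),
                         parse_vcf(trio$mother_vcf), ref)
kept <- apply_denovo_filters(cand, trio$father_bam, trio$mother_bam, ref)
db <- load_transcript_db(trio$transcripts)
kept <- annotate_variants(kept, db, ref)
kept[, c("chrom", "pos", "ref", "alt", "vtype", "vaf", "flag",
         "gene", "class", "father_qcov", "mother_qcov")]
```

```
 chrom   pos ref      alt        vtype vaf flag    gene class father_qcov mother_qcov
  chr1  1496   T        G substitution 0.5 high GENE001   INT          41          45
  chr1  6462   A   AGAAGA    insertion 0.5 high GENE002    FS          48          45
  chr1  8885   T TTGGTATT    insertion 0.5 high GENE003    FS          50          40
  chr1  9515   T       TT    insertion 0.5 high GENE003    FS          52          44
  chr1 12758   G     GAAA    insertion 0.5 high GENE004   INT          46          43
```

All five spiked de novo variants (and only those) survive the filters:
each is high quality at allele fraction 0.5, and both parents provide
≥ 40× good-quality depth at every site. The two intronic insertions (INT)
are not protein-altering; the three frameshifts (FS) are
protein-truncating:

```r
partition_by_consequence(kept)
#> protein-altering: 3   protein-truncating: 3
```

The single-sample pipeline is one call (`run_pipeline(run_config(...))`)
or one command:

```sh
Rscript inst/cli/clinexome.R run \
  --bam sample.bam --vcf sample.vcf --bed targets.bed \
  --transcripts transcripts.tsv --ref reference.fa --out out/sample
```

writing `out/sample_regions.tsv`, `out/sample_failed.tsv`,
`out/sample_variants.tsv` and `out/sample_manifest.json` (parameters and
output checksums). Trio mode adds `--father-vcf/--mother-vcf` and
`--father-bam/--mother-bam` and writes `out/sample_denovo.tsv`.

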