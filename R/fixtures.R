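# Deterministic synthetic-fixture generator.
#
# The generator emulates the inputs a clinical exome pipeline consumes after
# alignment and calling: a small reference genome, a transcript database,
# BED targets, coordinate-sorted indexed alignments with controlled depth
# and quality, variant calls with controlled TR/TC/QUAL/FILTER, and
# proband-parent trios with known de novo truth. Every generator is a pure
# function of the fixture spec (identical spec => identical files) and emits
# a machine-readable truth table so test oracles never need to re-parse the
# generated files.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic fixture bundle
#'
#' Defaults describe a realistic clinical exome slice: 50x mean depth of
#' 100-bp paired reads (250-bp fragments), 5% of reads with poor mapping
#' quality, 5% with poor base quality and 5% duplicates, on a 100-kb contig
#' carrying a handful of multi-exon transcripts.
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param contig_lengths Named integer vector of contig lengths (bp).
#' @param n_transcripts Transcripts laid out per fixture.
#' @param depth Target mean read depth over each simulated region.
#' @param read_length,fragment_length Read/fragment sizes (bp).
#' @param low_mq_fraction Fraction of reads given mapping quality
#'   `mq_low_value` (< 20).
#' @param low_bq_fraction Fraction of reads whose bases all get base quality
#'   `bq_low_value` (< 10).
#' @param dup_fraction Fraction of reads flagged as PCR duplicates.
#' @param mq_high_value,mq_low_value,bq_high_value,bq_low_value Quality
#'   values used for the good/poor read populations.
#' @param homopolymers Optional data.frame (`chrom`, `pos`, `base`, `len`)
#'   of homopolymer tracts to embed in the reference, the context in which
#'   short-read indel calling is known to struggle.
#' @param variants Optional variant truth data.frame (`chrom`, `pos`,
#'   `type` in sub/ins/del, `len`, `flag` in high/low) for
#'   [spike_variants()].
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 42L,
                         contig_lengths = c(chr1 = 100000L),
                         n_transcripts = 6L,
                         depth = 50,
                         read_length = 100L,
                         fragment_length = 250L,
                         low_mq_fraction = 0.05,
                         low_bq_fraction = 0.05,
                         dup_fraction = 0.05,
                         mq_high_value = 60L, mq_low_value = 10L,
                         bq_high_value = 35L, bq_low_value = 5L,
                         homopolymers = NULL,
                         variants = NULL) {
  stopifnot(all(contig_lengths >= 1000L), read_length > 0L,
            fragment_length >= read_length)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate the reference FASTA of a fixture
#'
#' Uniform-random ACGT sequence per contig, with declared homopolymer tracts
#' overwritten at their positions; written with a samtools (.fai) index.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Path to the FASTA file (index alongside).
#' @export
make_reference <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "reference.fa")
  seqs <- with_seed(spec$seed, {
    lapply(spec$contig_lengths, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
  })
  if (!is.null(spec$homopolymers)) {
    for (i in seq_len(nrow(spec$homopolymers))) {
      h <- spec$homopolymers[i, ]
      tract <- strrep(h$base, h$len)
      substr(seqs[[h$chrom]], h$pos, h$pos + h$len - 1L) <- tract
    }
  }
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- names(spec$contig_lengths)
  Biostrings::writeXStringSet(dss, path)
  Rsamtools::indexFa(path)
  path
}

#' Generate random valid transcripts
#'
#' Transcripts are laid out left to right without overlap: 2-5 exons of
#' 120-300 bp separated by 200-600 bp introns, CDS bounds inside the first
#' and last exons (leaving UTR on both sides), random strand, roughly half
#' flagged CCDS.
#'
#' @param n Number of transcripts.
#' @param chrom Contig name.
#' @param contig_len Contig length (bp).
#' @param seed Integer seed.
#' @param start_at First available genomic position (default 1000).
#' @return A `"transcript_db"` list of [transcript()] objects.
#' @export
random_transcripts <- function(n, chrom, contig_len, seed = 1L,
                               start_at = 1000L) {
  with_seed(seed, {
    out <- vector("list", n)
    cursor <- as.integer(start_at)
    for (i in seq_len(n)) {
      n_ex <- sample(2:5, 1L)
      ex_len <- sample(120:300, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(200:600, n_ex - 1L, replace = TRUE) else integer(0L)
      starts <- integer(n_ex); ends <- integer(n_ex)
      g <- cursor
      for (k in seq_len(n_ex)) {
        starts[k] <- g
        ends[k] <- g + ex_len[k]
        g <- ends[k] + if (k < n_ex) in_len[k] else 0L
      }
      # CDS bounds: inside first/last exon, >= 20 bp of UTR on each side
      cds_start <- starts[1L] + sample(20:(ex_len[1L] - 40L), 1L)
      cds_end <- ends[n_ex] - sample(20:(ex_len[n_ex] - 40L), 1L)
      if (g + 1500L > contig_len)
        stop("contig too short for ", n, " transcripts")
      out[[i]] <- transcript(
        gene_symbol = sprintf("GENE%03d", i),
        transcript_id = sprintf("TX%03d", i),
        chrom = chrom,
        strand = sample(c("+", "-"), 1L),
        exon_starts = starts, exon_ends = ends,
        cds_start = cds_start, cds_end = cds_end,
        is_ccds = stats::runif(1L) < 0.5)
      cursor <- g + sample(800:1500, 1L)
    }
    structure(out, class = "transcript_db")
  })
}

#' Generate and write the fixture transcript database
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return List with `db` (transcripts) and `path` (TSV file).
#' @export
make_transcript_db <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- names(spec$contig_lengths)[1L]
  db <- random_transcripts(spec$n_transcripts, chrom,
                           spec$contig_lengths[[1L]],
                           seed = spec$seed + 1L)
  path <- file.path(dir, "transcripts.tsv")
  write_transcript_db(db, path)
  list(db = db, path = path)
}

#' Write BED targets
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive); written as standard 0-based half-open BED.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, regions$start - 1L, regions$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED targets
#'
#' @param path BED path (3+ columns, 0-based half-open).
#' @return data.frame with 1-based inclusive `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Convert SAM text to a sorted, indexed BAM
#'
#' @param sam Path to a SAM file with a header.
#' @param bam_prefix Destination path without the `.bam` extension.
#' @return Path to the indexed BAM.
#' @export
sam_to_bam <- function(sam, bam_prefix) {
  bam <- Rsamtools::asBam(sam, bam_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

phred_string <- function(q, len) {
  strrep(rawToChar(as.raw(q + 33L)), len)
}

#' Simulate aligned reads over target regions
#'
#' Error-free paired reads are placed uniformly over each region (extended by
#' one fragment length) so interior coverage is approximately `spec$depth`.
#' Declared fractions of reads receive low mapping quality, low base quality,
#' or a duplicate flag. A truth table records every read's span and
#' qualities so pileup oracles can recount coverage without parsing the BAM.
#'
#' @param spec A [fixture_spec()].
#' @param reference Path to the fixture FASTA ([make_reference()]).
#' @param regions data.frame of 1-based inclusive `chrom`, `start`, `end`.
#' @param out_prefix Output path prefix (writes `<prefix>.sam`,
#'   `<prefix>.bam`, `<prefix>.bam.bai`).
#' @param seed_offset Added to `spec$seed` so multiple alignment files from
#'   one spec differ (e.g. the two parents of a trio).
#' @return List with `bam` (path) and `truth` (data.frame: `qname`, `chrom`,
#'   `start`, `end`, `mapq`, `bq`, `dup`).
#' @export
simulate_alignments <- function(spec, reference, regions, out_prefix,
                                seed_offset = 0L) {
  ref <- load_reference(reference)
  rl <- spec$read_length
  fl <- max(spec$fragment_length, 2L * rl)
  rows <- with_seed(spec$seed + 100L + seed_offset, {
    out <- vector("list", nrow(regions))
    for (r in seq_len(nrow(regions))) {
      chrom <- regions$chrom[r]
      clen <- nchar(ref[[chrom]])
      lo <- max(1L, regions$start[r] - fl + 1L)
      hi <- min(regions$end[r], clen - fl + 1L)
      window <- hi - lo + 1L
      depth <- if (!is.null(regions$depth)) regions$depth[r] else spec$depth
      # interior coverage = 2*rl*n_frag/window; inflate for flagged duplicates
      # so the target depth refers to usable (non-duplicate) reads
      n_frag <- max(0L, round(depth * window / (2L * rl) /
                                max(1e-9, 1 - spec$dup_fraction)))
      if (n_frag == 0L) { out[[r]] <- NULL; next }
      s1 <- sample(lo:hi, n_frag, replace = TRUE)
      s2 <- s1 + fl - rl
      starts <- c(s1, s2)
      n_read <- 2L * n_frag
      mapq <- ifelse(stats::runif(n_read) < spec$low_mq_fraction,
                     spec$mq_low_value, spec$mq_high_value)
      bq <- ifelse(stats::runif(n_read) < spec$low_bq_fraction,
                   spec$bq_low_value, spec$bq_high_value)
      dup <- stats::runif(n_read) < spec$dup_fraction
      out[[r]] <- data.frame(
        qname = sprintf("r%02d_%06d", r, rep(seq_len(n_frag), 2L)),
        chrom = chrom, start = as.integer(starts),
        end = as.integer(starts) + rl - 1L,
        mapq = as.integer(mapq), bq = as.integer(bq), dup = dup,
        mate = rep(c(1L, 2L), each = n_frag),
        frag_start = rep(as.integer(s1), 2L),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  if (is.null(rows))
    rows <- data.frame(qname = character(), chrom = character(),
                       start = integer(), end = integer(), mapq = integer(),
                       bq = integer(), dup = logical(), mate = integer(),
                       frag_start = integer(), stringsAsFactors = FALSE)

  sam <- paste0(out_prefix, ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(spec$contig_lengths),
                   as.integer(spec$contig_lengths)))
  body <- character(nrow(rows))
  if (nrow(rows)) {
    flag <- ifelse(rows$mate == 1L, 99L, 147L) + ifelse(rows$dup, 1024L, 0L)
    mate_start <- rows$frag_start + ifelse(rows$mate == 1L, fl - rl, 0L)
    tlen <- ifelse(rows$mate == 1L, fl, -fl)
    seqs <- vapply(seq_len(nrow(rows)), function(i)
      ref_slice(ref, rows$chrom[i], rows$start[i], rows$end[i]), character(1L))
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
                    rows$qname, flag, rows$chrom, rows$start, rows$mapq,
                    rl, mate_start, tlen, seqs,
                    vapply(rows$bq, phred_string, character(1L), len = rl))
  }
  writeLines(c(hdr, body), sam)
  bam <- sam_to_bam(sam, out_prefix)
  truth <- rows[, c("qname", "chrom", "start", "end", "mapq", "bq", "dup")]
  list(bam = bam, truth = truth)
}

# Build concrete REF/ALT alleles and VCF fields for one truth variant.
realize_variant <- function(ref, chrom, pos, type, len, flag, seed) {
  base <- ref_slice(ref, chrom, pos, pos)
  with_seed(seed, {
    if (type == "sub") {
      ra <- base
      aa <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
      qual <- if (flag == "high") 100 + round(stats::runif(1L, 0, 100))
              else round(stats::runif(1L, 20, 99))
      tr <- 30L; tc <- 60L; filter <- "PASS"
    } else if (type == "ins") {
      ra <- base
      aa <- paste0(base, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
      qual <- round(stats::runif(1L, 50, 200))
    } else if (type == "del") {
      ra <- ref_slice(ref, chrom, pos, pos + len)
      aa <- base
      qual <- round(stats::runif(1L, 50, 200))
    } else stop("unknown variant type: ", type)
    if (type != "sub") {
      if (flag == "high") {
        tr <- 30L; tc <- 60L; filter <- "PASS"   # VAF 0.5
      } else if (stats::runif(1L) < 0.5) {
        tr <- 5L; tc <- 60L; filter <- "PASS"    # VAF < 0.2
      } else {
        tr <- 30L; tc <- 60L; filter <- "badReads"
      }
    }
    list(chrom = chrom, pos = pos, ref = ra, alt = aa, qual = qual,
         filter = filter, tr = tr, tc = tc)
  })
}

write_simple_vcf <- function(records, path, contigs) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           "##INFO=<ID=TR,Number=A,Type=Integer,Description=\"Reads supporting the variant\">",
           "##INFO=<ID=TC,Number=1,Type=Integer,Description=\"Total reads at the site\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(records)) {
    o <- order(records$chrom, records$pos)
    records <- records[o, , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\tTR=%d;TC=%d",
                    records$chrom, records$pos, records$ref, records$alt,
                    formatC(records$qual, format = "g"), records$filter,
                    records$tr, records$tc)
  } else body <- character(0L)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Spike truth variants into a VCF
#'
#' Each truth variant gets REF/ALT alleles consistent with the fixture
#' reference and QUAL/FILTER/TR/TC values chosen so [assign_quality_flag()]
#' reproduces the intended flag: high substitutions get QUAL >= 100, high
#' indels get VAF 0.5 with FILTER PASS, low indels get either VAF < 0.2 or
#' a non-PASS filter.
#'
#' @param spec A [fixture_spec()] whose `variants` field holds the truth
#'   table (`chrom`, `pos`, `type`, `len`, `flag`).
#' @param reference Path to the fixture FASTA.
#' @param path Output VCF path.
#' @return List with `path` and `truth` (the truth table augmented with the
#'   emitted `ref`, `alt`, `qual`, `filter`, `tr`, `tc`).
#' @export
spike_variants <- function(spec, reference, path) {
  ref <- load_reference(reference)
  tv <- spec$variants
  if (is.null(tv) || nrow(tv) == 0L) stop("fixture spec declares no variants")
  recs <- lapply(seq_len(nrow(tv)), function(i) {
    realize_variant(ref, tv$chrom[i], tv$pos[i], tv$type[i],
                    if (is.null(tv$len)) 1L else tv$len[i], tv$flag[i],
                    seed = spec$seed + 200L + i)
  })
  recs <- do.call(rbind, lapply(recs, as.data.frame,
                                stringsAsFactors = FALSE))
  write_simple_vcf(recs, path, spec$contig_lengths)
  truth <- cbind(tv, recs[, c("ref", "alt", "qual", "filter", "tr", "tc")])
  list(path = path, truth = truth)
}

#' Generate a proband-parent trio fixture with known de novo truth
#'
#' Parents and proband share `n_inherited` variants (a mix of substitutions
#' and short indels; a subset of the inherited indels is written in its
#' most-3' representation in the mother's VCF while the proband carries the
#' most-5' form, exercising representation-aware matching). `n_denovo`
#' high-quality variants appear only in the proband. Parental alignments
#' cover each de novo site at the per-site depths in `denovo_father_depth` /
#' `denovo_mother_depth` (default 30x).
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @param n_inherited,n_denovo Variant counts.
#' @param denovo_father_depth,denovo_mother_depth Scalar or per-site
#'   parental depths at the de novo sites; default `spec$depth` (parents
#'   sequenced to the same depth as the proband).
#' @return List with paths (`reference`, `transcripts`, `proband_vcf`,
#'   `father_vcf`, `mother_vcf`, `father_bam`, `mother_bam`), the transcript
#'   `db`, and `truth` (list with `inherited` and `denovo` tables).
#' @export
make_trio <- function(spec, dir, n_inherited = 200L, n_denovo = 5L,
                      denovo_father_depth = spec$depth,
                      denovo_mother_depth = spec$depth) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- make_reference(spec, dir)
  ref <- load_reference(reference)
  chrom <- names(spec$contig_lengths)[1L]
  n_total <- n_inherited + n_denovo

  # grow the transcript layout until it can host all variant sites on a
  # 35-bp grid (sites >= 30 bp apart so edits never interact)
  site_pool <- function(db) {
    spans <- vapply(db, transcript_span, integer(2L))
    unlist(lapply(seq_len(ncol(spans)), function(k)
      seq.int(spans[1L, k] + 5L, spans[2L, k] - 30L, by = 35L)))
  }
  tspec <- spec
  repeat {
    tdb <- make_transcript_db(tspec, dir)
    pool <- site_pool(tdb$db)
    if (length(pool) >= n_total * 1.2) break
    tspec$n_transcripts <- tspec$n_transcripts + 4L
  }

  sites <- with_seed(spec$seed + 300L, sort(sample(pool, n_total)))
  types <- with_seed(spec$seed + 301L, {
    sample(c("sub", "ins", "del"), n_total, replace = TRUE,
           prob = c(0.5, 0.25, 0.25))
  })
  lens <- with_seed(spec$seed + 302L, sample(1:8, n_total, replace = TRUE))
  is_denovo <- with_seed(spec$seed + 303L,
                         seq_len(n_total) %in% sample(n_total, n_denovo))
  flags <- with_seed(spec$seed + 304L, {
    f <- sample(c("high", "low"), n_total, replace = TRUE, prob = c(0.8, 0.2))
    f[is_denovo] <- "high"
    f
  })
  tv <- data.frame(chrom = chrom, pos = sites, type = types, len = lens,
                   flag = flags, denovo = is_denovo,
                   stringsAsFactors = FALSE)
  vspec <- spec
  vspec$variants <- tv
  all_calls <- spike_variants(vspec, reference, file.path(dir, "all.vcf"))
  truth <- all_calls$truth
  unlink(file.path(dir, "all.vcf"))

  proband <- truth
  inherited <- truth[!truth$denovo, , drop = FALSE]
  father <- inherited
  mother <- inherited
  # rewrite a subset of the mother's inherited indels in most-3' form
  shiftable <- which(inherited$type %in% c("ins", "del"))
  flip <- with_seed(spec$seed + 305L, {
    if (length(shiftable) > 1L)
      sample(shiftable, ceiling(length(shiftable) / 2))
    else shiftable
  })
  for (i in flip) {
    sh <- shift_indel(ref, mother$chrom[i], mother$pos[i], mother$ref[i],
                      mother$alt[i])
    mother$pos[i] <- sh$pos_3prime
    mother$ref[i] <- sh$ref_3prime
    mother$alt[i] <- sh$alt_3prime
  }

  paths <- list(
    proband_vcf = file.path(dir, "proband.vcf"),
    father_vcf = file.path(dir, "father.vcf"),
    mother_vcf = file.path(dir, "mother.vcf"))
  write_simple_vcf(proband, paths$proband_vcf, spec$contig_lengths)
  write_simple_vcf(father, paths$father_vcf, spec$contig_lengths)
  write_simple_vcf(mother, paths$mother_vcf, spec$contig_lengths)

  dn <- truth[truth$denovo, , drop = FALSE]
  fd <- rep_len(denovo_father_depth, nrow(dn))
  md <- rep_len(denovo_mother_depth, nrow(dn))
  win <- 150L
  father_regions <- data.frame(chrom = dn$chrom, start = dn$pos - win,
                               end = dn$pos + win, depth = fd)
  mother_regions <- data.frame(chrom = dn$chrom, start = dn$pos - win,
                               end = dn$pos + win, depth = md)
  fa <- simulate_alignments(spec, reference, father_regions,
                            file.path(dir, "father"), seed_offset = 1L)
  mo <- simulate_alignments(spec, reference, mother_regions,
                            file.path(dir, "mother"), seed_offset = 2L)

  list(reference = reference, transcripts = tdb$path, db = tdb$db,
       proband_vcf = paths$proband_vcf, father_vcf = paths$father_vcf,
       mother_vcf = paths$mother_vcf,
       father_bam = fa$bam, mother_bam = mo$bam,
       truth = list(inherited = inherited, denovo = dn,
                    father_truth = fa$truth, mother_truth = mo$truth))
}
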