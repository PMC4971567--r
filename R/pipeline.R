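# Single-command orchestration: coverage QC over BED targets + variant
# post-processing/annotation, with an optional trio mode. Each sample is
# processed independently (no cross-sample state), and a JSON manifest
# records every parameter and output checksum so a run can be audited and
# reproduced.

#' Annotate flagged variants against default transcripts
#'
#' Adds `gene`, `transcript`, `class`, `csn_5prime` and `csn_3prime` columns.
#' Each variant is classified against the default transcript of every
#' overlapping gene and reports the most severe class (severity order
#' SG > FS > ESS > NSY > EE > IF > SS > SY > UTR > INT). The 5'/3' columns
#' hold the two anchored representations (`pos:REF>ALT`) for pure indels and
#' `"."` otherwise.
#'
#' @param records Flagged variant data.frame ([flag_variants()]).
#' @param db Transcript database (defaults are selected internally via
#'   [build_default_transcripts()]).
#' @param ref A [load_reference()] genome.
#' @return The augmented data.frame.
#' @export
annotate_variants <- function(records, db, ref) {
  defaults <- build_default_transcripts(db)
  n <- nrow(records)
  records$gene <- rep(NA_character_, n)
  records$transcript <- rep(NA_character_, n)
  records$class <- rep(NA_character_, n)
  records$csn_5prime <- rep(NA_character_, n)
  records$csn_3prime <- rep(NA_character_, n)
  if (n == 0L) return(records)
  for (i in seq_len(n)) {
    hits <- overlapping_transcripts(defaults, records$chrom[i], records$pos[i])
    if (length(hits) == 0L) next
    cls <- vapply(hits, function(t)
      tryCatch(assign_class(records[i, ], t, ref),
               error = function(e) NA_character_), character(1L))
    ok <- !is.na(cls)
    if (!any(ok)) next
    best <- which.min(match(cls[ok], consequence_classes))
    hit <- which(ok)[best]
    records$gene[i] <- hits[[hit]]$gene_symbol
    records$transcript[i] <- hits[[hit]]$transcript_id
    records$class[i] <- cls[ok][best]
    if (records$vtype[i] %in% c("insertion", "deletion")) {
      sh <- shift_indel(ref, records$chrom[i], records$pos[i],
                        records$ref[i], records$alt[i])
      records$csn_5prime[i] <- sprintf("%d:%s>%s", sh$pos_5prime,
                                       sh$ref_5prime, sh$alt_5prime)
      records$csn_3prime[i] <- sprintf("%d:%s>%s", sh$pos_3prime,
                                       sh$ref_3prime, sh$alt_3prime)
    }
  }
  records
}

#' Build a validated run configuration
#'
#' @param bam,vcf,bed,transcripts,reference Input paths.
#' @param out_prefix Output path prefix.
#' @param qual_high Substitution QUAL threshold (default 100).
#' @param vaf_high Indel VAF threshold (default 0.2).
#' @param qcov Minimum good-quality depth per base (default 15).
#' @param mq_good Mapping-quality cutoff (default 20).
#' @param bq_low Base-quality cutoff (default 10).
#' @param short_indel_max Short/long indel boundary (default 10).
#' @param mode `"single"` or `"trio"`.
#' @param father_vcf,mother_vcf,father_bam,mother_bam Trio-mode inputs.
#' @param write_vcf Also write the post-processed VCF.
#' @param write_profiles Also write the per-base profile table.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(bam, vcf, bed, transcripts, reference, out_prefix,
                       qual_high = 100, vaf_high = 0.2, qcov = 15L,
                       mq_good = 20L, bq_low = 10L, short_indel_max = 10L,
                       mode = c("single", "trio"),
                       father_vcf = NULL, mother_vcf = NULL,
                       father_bam = NULL, mother_bam = NULL,
                       write_vcf = FALSE, write_profiles = FALSE) {
  mode <- match.arg(mode)
  cfg <- list(bam = bam, vcf = vcf, bed = bed, transcripts = transcripts,
              reference = reference, out_prefix = out_prefix,
              qual_high = qual_high, vaf_high = vaf_high,
              qcov = as.integer(qcov), mq_good = as.integer(mq_good),
              bq_low = as.integer(bq_low),
              short_indel_max = as.integer(short_indel_max), mode = mode,
              father_vcf = father_vcf, mother_vcf = mother_vcf,
              father_bam = father_bam, mother_bam = mother_bam,
              write_vcf = isTRUE(write_vcf),
              write_profiles = isTRUE(write_profiles))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  thresholds <- c(cfg$qual_high, cfg$vaf_high, cfg$qcov, cfg$mq_good,
                  cfg$bq_low, cfg$short_indel_max)
  if (any(thresholds < 0)) stop("configuration error: negative threshold")
  inputs <- c(bam = cfg$bam, vcf = cfg$vcf, bed = cfg$bed,
              transcripts = cfg$transcripts, reference = cfg$reference)
  if (cfg$mode == "trio") {
    trio_inputs <- c(father_vcf = cfg$father_vcf, mother_vcf = cfg$mother_vcf,
                     father_bam = cfg$father_bam, mother_bam = cfg$mother_bam)
    if (length(trio_inputs) < 4L)
      stop("configuration error: trio mode requires both parental VCFs and BAMs")
    inputs <- c(inputs, trio_inputs)
  }
  missing <- inputs[!file.exists(unlist(inputs))]
  if (length(missing))
    stop("configuration error: missing input file(s): ",
         paste(sprintf("%s=%s", names(missing), missing), collapse = ", "))
  invisible(cfg)
}

#' Run the pipeline
#'
#' Executes coverage QC over every BED target, then variant post-processing
#' (flagging, intergenic removal, annotation), writing
#' `<prefix>_regions.tsv`, `<prefix>_failed.tsv`, `<prefix>_variants.tsv`,
#' optionally `<prefix>_variants.vcf` and `<prefix>_profiles.tsv`, a trio
#' candidate table `<prefix>_denovo.tsv` in trio mode, and
#' `<prefix>_manifest.json` recording parameters and output checksums.
#' Partial outputs are removed if any stage fails.
#'
#' @param cfg A [run_config()].
#' @return Named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(cfg) {
  validate_run_config(cfg)
  outputs <- character(0L)
  on_fail <- function(e) {
    file.remove(outputs[file.exists(outputs)])
    stop("pipeline stage failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    db <- load_transcript_db(cfg$transcripts)
    ref <- load_reference(cfg$reference)
    regions <- read_bed(cfg$bed)

    profiles <- lapply(seq_len(nrow(regions)), function(i)
      pileup_profile(cfg$bam, regions$chrom[i], regions$start[i],
                     regions$end[i], mq_good = cfg$mq_good,
                     bq_low = cfg$bq_low))
    summaries <- lapply(profiles, region_summary,
                        qcov_threshold = cfg$qcov, db = db)
    outputs <- write_coverage_report(
      summaries, cfg$out_prefix,
      profiles = if (cfg$write_profiles) profiles else NULL)

    records <- flag_variants(parse_vcf(cfg$vcf), qual_high = cfg$qual_high,
                             vaf_high = cfg$vaf_high,
                             short_indel_max = cfg$short_indel_max)
    split <- remove_intergenic(records, db)
    kept <- annotate_variants(split$kept, db, ref)
    variants_path <- paste0(cfg$out_prefix, "_variants.tsv")
    write_variant_tsv(kept, variants_path)
    outputs <- c(outputs, variants_path)
    if (cfg$write_vcf) {
      vcf_path <- paste0(cfg$out_prefix, "_variants.vcf")
      contigs <- Rsamtools::scanBamHeader(cfg$bam)[[1L]]$targets
      write_variant_vcf(kept, vcf_path, contigs = contigs)
      outputs <- c(outputs, vcf_path)
    }

    if (cfg$mode == "trio") {
      father <- parse_vcf(cfg$father_vcf)
      mother <- parse_vcf(cfg$mother_vcf)
      cand <- subtract_parents(kept, father, mother, ref)
      cand <- apply_denovo_filters(cand, cfg$father_bam, cfg$mother_bam, ref,
                                   qcov_threshold = cfg$qcov,
                                   mq_good = cfg$mq_good)
      denovo_path <- paste0(cfg$out_prefix, "_denovo.tsv")
      write_denovo_tsv(cand, denovo_path)
      outputs <- c(outputs, denovo_path)
    }

    manifest_path <- paste0(cfg$out_prefix, "_manifest.json")
    manifest <- list(
      tool = "clinexome",
      version = as.character(utils::packageVersion("clinexome")),
      parameters = cfg[c("qual_high", "vaf_high", "qcov", "mq_good",
                         "bq_low", "short_indel_max", "mode")],
      inputs = lapply(cfg[c("bam", "vcf", "bed", "transcripts",
                            "reference")], basename),
      outputs = as.list(stats::setNames(
        as.character(tools::md5sum(outputs)), basename(outputs))))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    outputs <- c(outputs, manifest_path)
    invisible(stats::setNames(outputs, NULL))
  }, error = on_fail)
}

# De novo candidate table: the variant columns plus parental coverage.
write_denovo_tsv <- function(cand, path) {
  tmp <- tempfile(fileext = ".tsv")
  write_variant_tsv(cand, tmp)
  tab <- utils::read.delim(tmp, colClasses = "character")
  unlink(tmp)
  tab$FATHER_QCOV <- if (nrow(tab)) cand$father_qcov else integer(0L)
  tab$MOTHER_QCOV <- if (nrow(tab)) cand$mother_qcov else integer(0L)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
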