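# Platypus-output post-processing: parse VCF records (splitting
# multi-allelic rows), compute the variant allele fraction from TR/TC,
# classify variant type and indel length, and assign the high/low quality
# flag:
#   base substitutions : high iff QUAL >= 100
#   indels             : high iff VAF >= 0.2 AND FILTER == "PASS"
# Thresholds are inclusive; records with missing TR/TC/QUAL are always low.

#' Parse a Platypus-style VCF into a variant table
#'
#' Multi-allelic rows are split into one record per ALT allele; TR (reads
#' supporting the variant) is matched positionally to the ALT order and TC
#' (total reads at the site) is shared across alleles. TR/TC are looked up in
#' INFO first, then in the first sample's FORMAT fields. Records missing
#' TR or TC get `NA` (with a warning naming the record) and are flagged low
#' downstream.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `filter`, `tr`, `tc`, `line` (source record index).
#' @export
parse_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(), filter = character(),
                      tr = integer(), tc = integer(), line = integer(),
                      stringsAsFactors = FALSE))

  grab <- function(tag) {
    v <- suppressWarnings(vcfR::extract.info(vcf, element = tag))
    if (is.null(v) || all(is.na(v))) {
      gt <- tryCatch(suppressWarnings(vcfR::extract.gt(vcf, element = tag)),
                     error = function(e) NULL)
      if (!is.null(gt)) v <- gt[, 1L]
    }
    if (is.null(v)) v <- rep(NA_character_, n)
    as.character(v)
  }
  tr_raw <- grab("TR")
  tc_raw <- grab("TC")

  out <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    trs <- if (is.na(tr_raw[i])) rep(NA_integer_, length(alts))
           else suppressWarnings(as.integer(strsplit(tr_raw[i], ",", fixed = TRUE)[[1L]]))
    if (length(trs) < length(alts))
      trs <- c(trs, rep(NA_integer_, length(alts) - length(trs)))
    tc <- suppressWarnings(as.integer(tc_raw[i]))
    if (is.na(tr_raw[i]) || is.na(tc_raw[i]))
      warning("VCF record ", i, " (", fix[i, "CHROM"], ":", fix[i, "POS"],
              "): missing TR/TC; record will be flagged low", call. = FALSE)
    out[[i]] <- data.frame(
      chrom = fix[i, "CHROM"],
      pos = as.integer(fix[i, "POS"]),
      ref = fix[i, "REF"],
      alt = alts,
      qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
      filter = fix[i, "FILTER"],
      tr = trs[seq_along(alts)],
      tc = tc,
      line = i,
      row.names = NULL,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Variant allele fraction from TR/TC
#'
#' @param tr Reads supporting the variant (vectorized).
#' @param tc Total reads at the site.
#' @return `tr / tc` in `[0, 1]`; 0 (with a warning) where `tc == 0`; `NA`
#'   where either count is missing.
#' @export
variant_allele_fraction <- function(tr, tc) {
  bad <- !is.na(tr) & !is.na(tc) & tr > tc
  if (any(bad))
    stop("TR > TC for ", sum(bad), " record(s): inconsistent read counts")
  zero <- !is.na(tc) & tc == 0L
  if (any(zero & !is.na(tr)))
    warning("TC == 0 at ", sum(zero), " site(s); VAF reported as 0")
  vaf <- tr / tc
  vaf[zero] <- 0
  vaf
}

#' Classify variant type and indel length
#'
#' VCF-anchored alleles: equal-length single bases are substitutions; a REF
#' that is a prefix of ALT is an insertion (and vice versa for deletions);
#' anything else is complex, with the length difference (or the REF length
#' when the alleles are equal length) as its indel length. Indels of length
#' <= `short_indel_max` (default 10 bp) are "short", longer ones "long";
#' substitutions have no length class.
#'
#' @param ref,alt Allele strings (vectorized, equal length).
#' @param short_indel_max Short/long boundary (inclusive; default 10).
#' @return data.frame with columns `vtype` (substitution, insertion,
#'   deletion, complex), `indel_len`, `length_class` (short, long, `"n/a"`).
#' @export
classify_variant_type <- function(ref, alt, short_indel_max = 10L) {
  ref <- as.character(ref); alt <- as.character(alt)
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("empty REF or ALT allele")
  if (any(ref == alt)) stop("REF equals ALT for some record(s)")
  lr <- nchar(ref); la <- nchar(alt)
  vtype <- rep("complex", length(ref))
  vtype[lr == 1L & la == 1L] <- "substitution"
  ins <- la > lr & substr(alt, 1L, lr) == ref
  del <- lr > la & substr(ref, 1L, la) == alt
  vtype[ins] <- "insertion"
  vtype[del] <- "deletion"
  indel_len <- abs(la - lr)
  indel_len[vtype == "complex" & lr == la] <- lr[vtype == "complex" & lr == la]
  indel_len[vtype == "substitution"] <- 0L
  length_class <- ifelse(vtype == "substitution", "n/a",
                         ifelse(indel_len <= short_indel_max, "short", "long"))
  data.frame(vtype = vtype, indel_len = as.integer(indel_len),
             length_class = length_class, stringsAsFactors = FALSE)
}

#' Assign the high/low quality flag
#'
#' Base substitutions are high quality when QUAL >= `qual_high`. Insertions,
#' deletions and complex variants are high quality when the variant allele
#' fraction is >= `vaf_high` and FILTER equals `"PASS"` exactly. All
#' thresholds are inclusive; any missing QUAL/TR/TC yields low.
#'
#' @param vtype Variant type from [classify_variant_type()] (vectorized).
#' @param qual VCF QUAL.
#' @param filter VCF FILTER string.
#' @param tr,tc Supporting/total read counts.
#' @param qual_high Substitution QUAL threshold (default 100).
#' @param vaf_high Indel VAF threshold (default 0.2).
#' @return Character vector, `"high"` or `"low"`.
#' @export
assign_quality_flag <- function(vtype, qual, filter, tr, tc,
                                qual_high = 100, vaf_high = 0.2) {
  vaf <- suppressWarnings(variant_allele_fraction(tr, tc))
  is_sub <- vtype == "substitution"
  high <- ifelse(is_sub,
                 !is.na(qual) & qual >= qual_high,
                 !is.na(vaf) & vaf >= vaf_high & filter == "PASS")
  ifelse(high, "high", "low")
}

#' Classify and flag a parsed variant table
#'
#' Adds `vtype`, `indel_len`, `length_class`, `vaf` and `flag` columns to the
#' output of [parse_vcf()].
#'
#' @param records data.frame from [parse_vcf()].
#' @param qual_high,vaf_high,short_indel_max Flag-rule thresholds.
#' @return The augmented data.frame.
#' @export
flag_variants <- function(records, qual_high = 100, vaf_high = 0.2,
                          short_indel_max = 10L) {
  if (nrow(records) == 0L) {
    records$vtype <- character(0L); records$indel_len <- integer(0L)
    records$length_class <- character(0L); records$vaf <- numeric(0L)
    records$flag <- character(0L)
    return(records)
  }
  cls <- classify_variant_type(records$ref, records$alt, short_indel_max)
  records$vtype <- cls$vtype
  records$indel_len <- cls$indel_len
  records$length_class <- cls$length_class
  records$vaf <- suppressWarnings(variant_allele_fraction(records$tr, records$tc))
  records$flag <- assign_quality_flag(records$vtype, records$qual,
                                      records$filter, records$tr, records$tc,
                                      qual_high, vaf_high)
  records
}

#' Remove intergenic calls
#'
#' Partitions records by whether the variant position falls within the
#' genomic span (introns included) of at least one transcript.
#'
#' @param records Variant data.frame with `chrom` and `pos` columns.
#' @param db A list of [transcript()] objects.
#' @return List with `kept` and `removed` data.frames
#'   (`kept` + `removed` = input).
#' @export
remove_intergenic <- function(records, db) {
  if (nrow(records) == 0L) return(list(kept = records, removed = records))
  spans <- data.frame(
    chrom = vapply(db, `[[`, character(1L), "chrom"),
    start = vapply(db, function(t) transcript_span(t)[1L], integer(1L)),
    end = vapply(db, function(t) transcript_span(t)[2L], integer(1L)),
    stringsAsFactors = FALSE)
  hit <- vapply(seq_len(nrow(records)), function(i) {
    any(spans$chrom == records$chrom[i] &
          spans$start <= records$pos[i] & spans$end >= records$pos[i])
  }, logical(1L))
  list(kept = records[hit, , drop = FALSE],
       removed = records[!hit, , drop = FALSE])
}

variant_tsv_columns <- c("chrom", "pos", "ref", "alt", "type", "qual",
                         "filter", "tr", "tc", "vaf", "flag", "gene",
                         "transcript", "class", "csn_5prime", "csn_3prime")

#' Write the clinical tab-separated variant output
#'
#' One row per kept record with the fixed column set CHROM, POS, REF, ALT,
#' TYPE, QUAL, FILTER, TR, TC, VAF, FLAG, GENE, TRANSCRIPT, CLASS,
#' CSN_5PRIME, CSN_3PRIME. Missing annotation columns in the input are
#' written as ".".
#'
#' @param records Flagged (and optionally annotated) variant data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(records, path) {
  n <- nrow(records)
  dot <- function(x) {
    if (is.null(x)) x <- rep(NA_character_, n)
    x <- as.character(x)
    ifelse(is.na(x) | !nzchar(x), ".", x)
  }
  out <- data.frame(
    CHROM = dot(records$chrom), POS = dot(records$pos),
    REF = dot(records$ref), ALT = dot(records$alt),
    TYPE = dot(records$vtype),
    QUAL = dot(records$qual), FILTER = dot(records$filter),
    TR = dot(records$tr), TC = dot(records$tc),
    VAF = if (n) ifelse(is.na(records$vaf), ".",
                      as.character(signif(records$vaf, 4)))
          else character(0L),
    FLAG = dot(records$flag),
    GENE = dot(records$gene),
    TRANSCRIPT = dot(records$transcript),
    CLASS = dot(records$class),
    CSN_5PRIME = dot(records$csn_5prime),
    CSN_3PRIME = dot(records$csn_3prime),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write flagged variants back to a minimal VCF
#'
#' Preserves the original fields and adds FLAG (high/low), and CLASS when
#' present, as INFO tags, so downstream annotation tools can consume the
#' post-processed call set.
#'
#' @param records Flagged variant data.frame.
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(records, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##INFO=<ID=TR,Number=A,Type=Integer,Description=\"Reads supporting the variant\">",
           "##INFO=<ID=TC,Number=1,Type=Integer,Description=\"Total reads at the site\">",
           "##INFO=<ID=FLAG,Number=1,Type=String,Description=\"high/low quality flag\">",
           "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Consequence class\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("TR=%s;TC=%s;FLAG=%s",
                  ifelse(is.na(records$tr), ".", records$tr),
                  ifelse(is.na(records$tc), ".", records$tc),
                  records$flag)
  if (!is.null(records$class))
    info <- paste0(info, ";CLASS=", ifelse(is.na(records$class), ".",
                                           records$class))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t%s",
                  records$chrom, records$pos, records$ref, records$alt,
                  ifelse(is.na(records$qual), ".",
                         formatC(records$qual, format = "g")),
                  records$filter, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
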