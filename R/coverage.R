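# Per-base coverage and quality metrics for clinical target QC.
#
# For each base of a BED target the profile records:
#   COV   - depth of spanning reads (aligned M/=/X blocks plus deletions);
#   QCOV  - the subset with mapping quality >= mq_good;
#   MEDMQ - median mapping quality of spanning reads;
#   FLMQ  - fraction of spanning reads with mapping quality < mq_good;
#   MEDBQ - median base quality of aligned read bases;
#   FLBQ  - fraction of aligned read bases with base quality < bq_low.
# Duplicate, secondary, supplementary and unmapped reads are excluded
# everywhere. Deleted read positions count toward depth and mapping-quality
# metrics but contribute no base quality.

#' Per-base coverage/quality profile of one target region
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param chrom Contig name (must exist in the BAM header).
#' @param start,end 1-based inclusive region bounds.
#' @param mq_good Mapping-quality cutoff defining "good" reads (inclusive;
#'   default 20, the clinical-coverage definition).
#' @param bq_low Base-quality cutoff defining "poor" bases (exclusive upper
#'   bound; default 10).
#' @return An object of class `"region_profile"`: a list with the region
#'   coordinates and numeric vectors `COV`, `QCOV`, `MEDBQ`, `FLBQ`, `MEDMQ`,
#'   `FLMQ`, one element per base. Median/fraction metrics are `NA` at bases
#'   with no contributing reads.
#' @export
pileup_profile <- function(bam, chrom, start, end, mq_good = 20L, bq_low = 10L) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  bai <- paste0(bam, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) not found for ", bam)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!(chrom %in% names(hdr)))
    stop("contig ", chrom, " not present in BAM header of ", bam)

  region_len <- end - start + 1L
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  param <- Rsamtools::ScanBamParam(
    which = gr, what = c("mapq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)

  prof <- list(chrom = chrom, start = start, end = end,
               mq_good = as.integer(mq_good), bq_low = as.integer(bq_low),
               COV = integer(region_len), QCOV = integer(region_len),
               MEDBQ = rep(NA_real_, region_len),
               FLBQ = rep(NA_real_, region_len),
               MEDMQ = rep(NA_real_, region_len),
               FLMQ = rep(NA_real_, region_len))
  class(prof) <- "region_profile"
  if (length(gal) == 0L) return(prof)

  cig <- GenomicAlignments::cigar(gal)
  mapq <- S4Vectors::mcols(gal)$mapq
  mapq[is.na(mapq)] <- 0L

  # spanning blocks (reference-consuming, deletions included)
  span <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = GenomicRanges::start(gal), ops = c("M", "D", "=", "X"))
  su <- unlist(span, use.names = FALSE)
  sidx <- rep(seq_along(gal), S4Vectors::elementNROWS(span))
  lo <- pmax(IRanges::start(su), start)
  hi <- pmin(IRanges::end(su), end)
  keep <- lo <= hi
  lo <- lo[keep]; hi <- hi[keep]
  bmq <- mapq[sidx[keep]]
  n <- hi - lo + 1L
  mq_dt <- data.table::data.table(
    p = sequence(n, from = lo - start + 1L),
    mq = rep(bmq, n))
  mq_stats <- mq_dt[, list(cov = .N, qcov = sum(mq >= mq_good),
                           med = stats::median(as.numeric(mq)),
                           fl = mean(mq < mq_good)), by = "p"]
  prof$COV[mq_stats$p] <- mq_stats$cov
  prof$QCOV[mq_stats$p] <- mq_stats$qcov
  prof$MEDMQ[mq_stats$p] <- mq_stats$med
  prof$FLMQ[mq_stats$p] <- mq_stats$fl

  # aligned-base blocks (M/=/X), mapped back to query space for base quality
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = GenomicRanges::start(gal), ops = c("M", "=", "X"))
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cig, ops = c("M", "=", "X"))
  quals <- as(S4Vectors::mcols(gal)$qual, "IntegerList")
  ru <- unlist(rr, use.names = FALSE)
  qu <- unlist(qr, use.names = FALSE)
  ridx <- rep(seq_along(gal), S4Vectors::elementNROWS(rr))
  rlo <- pmax(IRanges::start(ru), start)
  rhi <- pmin(IRanges::end(ru), end)
  keep <- rlo <= rhi
  if (any(keep)) {
    rlo <- rlo[keep]; rhi <- rhi[keep]
    qoff <- IRanges::start(qu)[keep] + (rlo - IRanges::start(ru)[keep])
    n <- rhi - rlo + 1L
    qual_flat <- unlist(quals, use.names = FALSE)
    qstarts <- cumsum(c(0L, S4Vectors::elementNROWS(quals)))[ridx[keep]]
    bq_dt <- data.table::data.table(
      p = sequence(n, from = rlo - start + 1L),
      bq = qual_flat[sequence(n, from = qstarts + qoff)])
    bq_stats <- bq_dt[, list(med = stats::median(as.numeric(bq)),
                             fl = mean(bq < bq_low)), by = "p"]
    prof$MEDBQ[bq_stats$p] <- bq_stats$med
    prof$FLBQ[bq_stats$p] <- bq_stats$fl
  }
  prof
}

#' @export
print.region_profile <- function(x, ...) {
  cat(sprintf("<region_profile %s:%d-%d, %d bases, min QCOV %s>\n",
              x$chrom, x$start, x$end, x$end - x$start + 1L,
              if (length(x$QCOV)) min(x$QCOV) else NA))
  invisible(x)
}

#' Maximal failing subregions of a profile
#'
#' Returns the maximal runs of consecutive bases whose good-quality depth
#' (QCOV) is below the threshold, as disjoint sorted 1-based genomic
#' intervals whose union is exactly the set of failing bases.
#'
#' @param profile A [pileup_profile()] result.
#' @param qcov_threshold Minimum acceptable QCOV (inclusive; default 15).
#' @return A data.frame with columns `chrom`, `start`, `end` (possibly
#'   zero rows).
#' @export
failed_subregions <- function(profile, qcov_threshold = 15L) {
  fail <- profile$QCOV < qcov_threshold
  r <- rle(fail)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(chrom = rep(profile$chrom, sum(keep)),
             start = profile$start + starts[keep] - 1L,
             end = profile$start + ends[keep] - 1L,
             stringsAsFactors = FALSE)
}

#' Summarise a target region's coverage quality
#'
#' A region passes when every base reaches the good-quality depth threshold
#' (QCOV >= `qcov_threshold`), the clinical fill-in criterion: any base below
#' threshold marks the region for orthogonal follow-up.
#'
#' @param profile A [pileup_profile()] result.
#' @param qcov_threshold Minimum acceptable QCOV (inclusive; default 15).
#' @param db Optional transcript database used to annotate failing
#'   subregions in transcript coordinates.
#' @return An object of class `"region_summary"`: list with `chrom`, `start`,
#'   `end`, `min_qcov`, `median_qcov`, `max_flmq`, `max_flbq`, `pass_flag`,
#'   and `failed` (data.frame of failing subregions with `csn` labels).
#' @export
region_summary <- function(profile, qcov_threshold = 15L, db = NULL) {
  fails <- failed_subregions(profile, qcov_threshold)
  if (!is.null(db) && nrow(fails)) {
    fails <- annotate_failed_regions(fails, db)
  } else if (nrow(fails)) {
    fails$csn <- "."
  } else {
    fails$csn <- character(0L)
  }
  structure(list(
    chrom = profile$chrom, start = profile$start, end = profile$end,
    min_qcov = min(profile$QCOV),
    median_qcov = stats::median(profile$QCOV),
    max_flmq = if (all(is.na(profile$FLMQ))) NA_real_ else max(profile$FLMQ, na.rm = TRUE),
    max_flbq = if (all(is.na(profile$FLBQ))) NA_real_ else max(profile$FLBQ, na.rm = TRUE),
    pass_flag = nrow(fails) == 0L,
    failed = fails), class = "region_summary")
}

#' Annotate failing intervals in transcript coordinates
#'
#' Each failing interval is labelled against every transcript whose span it
#' overlaps, in the `"GENE:c.X-c.Y"` form clinical laboratories use to design
#' fill-in (e.g. Sanger) assays; intervals in gene deserts are labelled `"."`.
#'
#' @param fails data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param db A list of [transcript()] objects.
#' @return The input expanded to one row per (interval, overlapping
#'   transcript) with an added `csn` column.
#' @export
annotate_failed_regions <- function(fails, db) {
  if (nrow(fails) == 0L) {
    fails$csn <- character(0L)
    return(fails)
  }
  out <- lapply(seq_len(nrow(fails)), function(i) {
    f <- fails[i, , drop = FALSE]
    hits <- Filter(function(t) {
      sp <- transcript_span(t)
      t$chrom == f$chrom && f$end >= sp[1L] && f$start <= sp[2L]
    }, db)
    if (length(hits) == 0L) {
      f$csn <- "."
      return(f)
    }
    labs <- vapply(hits, function(t) region_to_csn_label(t, f$start, f$end),
                   character(1L))
    f <- f[rep(1L, length(labs)), , drop = FALSE]
    f$csn <- labs
    f
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write tab-separated coverage reports
#'
#' Writes `<prefix>_regions.tsv` (one row per target region:
#' CHROM, START, END, MIN_QCOV, MEDIAN_QCOV, MAX_FLMQ, MAX_FLBQ, PASS),
#' `<prefix>_failed.tsv` (failing subregions: CHROM, START, END, CSN) and,
#' when `profiles` is supplied, `<prefix>_profiles.tsv` (per-base:
#' CHROM, POS, COV, QCOV, MEDBQ, FLBQ, MEDMQ, FLMQ). Undefined metrics are
#' written as ".".
#'
#' @param summaries List of [region_summary()] objects.
#' @param out_prefix Output path prefix.
#' @param profiles Optional list of [pileup_profile()] objects.
#' @return Character vector of the files written, invisibly.
#' @export
write_coverage_report <- function(summaries, out_prefix, profiles = NULL) {
  dot <- function(x, digits = 4) ifelse(is.na(x), ".",
                                        as.character(signif(x, digits)))
  reg <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(CHROM = s$chrom, START = s$start, END = s$end,
               MIN_QCOV = s$min_qcov, MEDIAN_QCOV = s$median_qcov,
               MAX_FLMQ = dot(s$max_flmq), MAX_FLBQ = dot(s$max_flbq),
               PASS = if (s$pass_flag) "PASS" else "FAIL",
               stringsAsFactors = FALSE)
  }))
  if (is.null(reg))
    reg <- data.frame(CHROM = character(), START = integer(), END = integer(),
                      MIN_QCOV = integer(), MEDIAN_QCOV = numeric(),
                      MAX_FLMQ = character(), MAX_FLBQ = character(),
                      PASS = character(), stringsAsFactors = FALSE)
  regions_path <- paste0(out_prefix, "_regions.tsv")
  utils::write.table(reg, regions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  fl <- do.call(rbind, lapply(summaries, function(s) {
    if (nrow(s$failed) == 0L) return(NULL)
    data.frame(CHROM = s$failed$chrom, START = s$failed$start,
               END = s$failed$end, CSN = s$failed$csn,
               stringsAsFactors = FALSE)
  }))
  if (is.null(fl))
    fl <- data.frame(CHROM = character(), START = integer(),
                     END = integer(), CSN = character(),
                     stringsAsFactors = FALSE)
  failed_path <- paste0(out_prefix, "_failed.tsv")
  utils::write.table(fl, failed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  written <- c(regions_path, failed_path)
  if (!is.null(profiles)) {
    pb <- do.call(rbind, lapply(profiles, function(p) {
      data.frame(CHROM = p$chrom, POS = seq.int(p$start, p$end),
                 COV = p$COV, QCOV = p$QCOV,
                 MEDBQ = dot(p$MEDBQ), FLBQ = dot(p$FLBQ),
                 MEDMQ = dot(p$MEDMQ), FLMQ = dot(p$FLMQ),
                 stringsAsFactors = FALSE)
    }))
    profiles_path <- paste0(out_prefix, "_profiles.tsv")
    utils::write.table(pb, profiles_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, profiles_path)
  }
  invisible(written)
}
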