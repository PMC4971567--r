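#' Construct a transcript model
#'
#' A transcript is the unit of annotation: an ordered set of exons on one
#' strand with coding-sequence (CDS) bounds. Exon coordinates use the 0-based
#' half-open convention of BED/UCSC files; all user-facing positions elsewhere
#' in the package are 1-based (VCF convention).
#'
#' @param gene_symbol Gene symbol, e.g. `"BRCA1"`.
#' @param transcript_id Transcript identifier, e.g. `"ENST00000357654"`.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of 0-based half-open exon
#'   bounds, sorted by genomic start, non-overlapping.
#' @param cds_start,cds_end 0-based genomic CDS bounds (end exclusive); both
#'   must fall within the exon span and enclose at least one exonic base.
#' @param is_ccds Is the transcript in the CCDS set?
#' @param has_start_codon,has_stop_codon Annotation completeness flags used by
#'   [filter_gene_candidates()].
#' @param is_pseudogene Known-pseudogene flag.
#' @return An object of class `"transcript"`.
#' @export
transcript <- function(gene_symbol, transcript_id, chrom, strand,
                       exon_starts, exon_ends, cds_start, cds_end,
                       is_ccds = FALSE, has_start_codon = TRUE,
                       has_stop_codon = TRUE, is_pseudogene = FALSE) {
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  t <- structure(
    list(gene_symbol = as.character(gene_symbol),
         transcript_id = as.character(transcript_id),
         chrom = as.character(chrom),
         strand = match.arg(strand, c("+", "-")),
         exon_starts = exon_starts, exon_ends = exon_ends,
         cds_start = cds_start, cds_end = cds_end,
         is_ccds = isTRUE(is_ccds),
         has_start_codon = isTRUE(has_start_codon),
         has_stop_codon = isTRUE(has_stop_codon),
         is_pseudogene = isTRUE(is_pseudogene)),
    class = "transcript")
  validate_transcript(t)
  t
}

validate_transcript <- function(t) {
  id <- t$transcript_id
  n <- length(t$exon_starts)
  if (n == 0L || length(t$exon_ends) != n)
    stop("transcript ", id, ": exon start/end vectors empty or of unequal length")
  if (any(t$exon_ends <= t$exon_starts))
    stop("transcript ", id, ": exon end <= exon start")
  if (is.unsorted(t$exon_starts, strictly = TRUE) ||
      (n > 1L && any(t$exon_starts[-1L] < t$exon_ends[-n])))
    stop("transcript ", id, ": exons must be sorted and non-overlapping")
  if (t$cds_start >= t$cds_end)
    stop("transcript ", id, ": cds_start must be < cds_end")
  if (t$cds_start < t$exon_starts[1L] || t$cds_end > t$exon_ends[n])
    stop("transcript ", id, ": CDS bounds outside the exon span")
  if (coding_length(t) < 1L)
    stop("transcript ", id, ": coding length must be >= 1")
  invisible(t)
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%d-%d [%s] %d exon(s), CDS %d-%d%s>\n",
              x$transcript_id, x$gene_symbol, x$chrom,
              x$exon_starts[1L] + 1L, x$exon_ends[length(x$exon_ends)],
              x$strand, length(x$exon_starts), x$cds_start + 1L, x$cds_end,
              if (x$is_ccds) ", CCDS" else ""))
  invisible(x)
}

# Genomic span, 1-based inclusive (introns included).
transcript_span <- function(t) {
  c(t$exon_starts[1L] + 1L, t$exon_ends[length(t$exon_ends)])
}

# Number of exonic bases within [cds_start, cds_end).
coding_length <- function(t) {
  sum(pmax(0L, pmin(t$exon_ends, t$cds_end) - pmax(t$exon_starts, t$cds_start)))
}

exonic_length <- function(t) sum(t$exon_ends - t$exon_starts)

#' Load a transcript database from a tab-separated file
#'
#' The file must have a header with columns GENE, TRANSCRIPT, CCDS, CHROM,
#' STRAND, EXON_STARTS, EXON_ENDS, CDS_START, CDS_END. EXON_STARTS/EXON_ENDS
#' are comma-separated lists of 0-based half-open bounds. Optional columns
#' HAS_START_CODON, HAS_STOP_CODON and PSEUDOGENE (true/false or 1/0) carry the
#' annotation-completeness flags; they default to complete, non-pseudogene.
#' The CCDS column may hold a boolean or a CCDS accession (any value other than
#' "", ".", "0", "false", "no" counts as CCDS membership).
#'
#' @param path Path to the tab-separated transcript database.
#' @return A list of [transcript()] objects, in file order, with class
#'   `"transcript_db"`.
#' @export
load_transcript_db <- function(path) {
  if (!file.exists(path)) stop("transcript database not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = TRUE)
  required <- c("GENE", "TRANSCRIPT", "CCDS", "CHROM", "STRAND",
                "EXON_STARTS", "EXON_ENDS", "CDS_START", "CDS_END")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("transcript database missing column(s): ", paste(missing, collapse = ", "))
  parse_bool <- function(x, default) {
    if (is.null(x)) return(default)
    !(tolower(trimws(x)) %in% c("", ".", "0", "false", "no", "f"))
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    line <- i + 1L  # header is line 1
    starts <- suppressWarnings(as.integer(strsplit(row$EXON_STARTS, ",")[[1L]]))
    ends <- suppressWarnings(as.integer(strsplit(row$EXON_ENDS, ",")[[1L]]))
    cs <- suppressWarnings(as.integer(row$CDS_START))
    ce <- suppressWarnings(as.integer(row$CDS_END))
    if (anyNA(starts) || anyNA(ends) || is.na(cs) || is.na(ce) ||
        !nzchar(row$TRANSCRIPT) || !(row$STRAND %in% c("+", "-")))
      stop("malformed transcript database row at line ", line)
    out[[i]] <- transcript(
      gene_symbol = row$GENE, transcript_id = row$TRANSCRIPT,
      chrom = row$CHROM, strand = row$STRAND,
      exon_starts = starts, exon_ends = ends, cds_start = cs, cds_end = ce,
      is_ccds = parse_bool(row$CCDS, FALSE),
      has_start_codon = parse_bool(df$HAS_START_CODON[i], TRUE),
      has_stop_codon = parse_bool(df$HAS_STOP_CODON[i], TRUE),
      is_pseudogene = parse_bool(df$PSEUDOGENE[i], FALSE))
  }
  structure(out, class = "transcript_db")
}

#' Write a transcript database to a tab-separated file
#'
#' Inverse of [load_transcript_db()]; used by the fixture generator.
#'
#' @param db A list of [transcript()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_db <- function(db, path) {
  rows <- lapply(db, function(t) {
    data.frame(GENE = t$gene_symbol, TRANSCRIPT = t$transcript_id,
               CCDS = if (t$is_ccds) "1" else "0",
               CHROM = t$chrom, STRAND = t$strand,
               EXON_STARTS = paste(t$exon_starts, collapse = ","),
               EXON_ENDS = paste(t$exon_ends, collapse = ","),
               CDS_START = t$cds_start, CDS_END = t$cds_end,
               HAS_START_CODON = if (t$has_start_codon) "1" else "0",
               HAS_STOP_CODON = if (t$has_stop_codon) "1" else "0",
               PSEUDOGENE = if (t$is_pseudogene) "1" else "0",
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter transcripts to default-set gene candidates
#'
#' Keeps transcripts on chromosomes 1-22, X or Y (with or without a "chr"
#' prefix) that have both a start and a stop codon and are not known
#' pseudogenes. Each excluded record carries a machine-readable reason, the
#' first violated rule in the order chromosome, incomplete_cds, pseudogene.
#'
#' @param records A list of [transcript()] objects.
#' @return A list with elements `included` (list of transcripts) and
#'   `excluded` (data.frame with columns `transcript_id`, `reason`).
#' @export
filter_gene_candidates <- function(records) {
  canonical <- c(as.character(1:22), "X", "Y")
  reason <- vapply(records, function(t) {
    chrom <- sub("^chr", "", t$chrom)
    if (!(chrom %in% canonical)) return("chromosome")
    if (!t$has_start_codon || !t$has_stop_codon) return("incomplete_cds")
    if (t$is_pseudogene) return("pseudogene")
    NA_character_
  }, character(1L))
  keep <- is.na(reason)
  list(included = records[keep],
       excluded = data.frame(
         transcript_id = vapply(records[!keep], `[[`, character(1L), "transcript_id"),
         reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Select the default transcript for one gene
#'
#' CCDS transcripts are preferred. Remaining ties are broken by longest coding
#' length, then longest total exonic length, then lexicographically smallest
#' transcript identifier, so the choice is deterministic and invariant under
#' permutation of the candidates.
#'
#' @param candidates Non-empty list of [transcript()] objects for one gene.
#' @return The selected [transcript()].
#' @export
select_default_transcript <- function(candidates) {
  if (length(candidates) == 0L)
    stop("select_default_transcript: empty candidate list")
  genes <- unique(vapply(candidates, `[[`, character(1L), "gene_symbol"))
  if (length(genes) > 1L)
    stop("select_default_transcript: candidates span multiple genes: ",
         paste(genes, collapse = ", "))
  pool <- candidates
  ccds <- Filter(function(t) t$is_ccds, pool)
  if (length(ccds)) pool <- ccds
  key <- order(-vapply(pool, coding_length, integer(1L)),
               -vapply(pool, exonic_length, integer(1L)),
               vapply(pool, `[[`, character(1L), "transcript_id"))
  pool[[key[1L]]]
}

#' Select default transcripts for a whole database
#'
#' Applies [filter_gene_candidates()] then [select_default_transcript()] per
#' gene, mirroring the construction of a clinical default transcript set.
#'
#' @param db A list of [transcript()] objects.
#' @return A `"transcript_db"` list with one transcript per eligible gene,
#'   ordered by gene symbol.
#' @export
build_default_transcripts <- function(db) {
  cand <- filter_gene_candidates(db)$included
  genes <- vapply(cand, `[[`, character(1L), "gene_symbol")
  structure(lapply(split(cand, genes), select_default_transcript),
            class = "transcript_db")
}

#' Transcripts whose genomic span contains a position
#'
#' The span runs from the first exon start to the last exon end, introns
#' included, so intronic (splice-region) variants are retained.
#'
#' @param db A list of [transcript()] objects.
#' @param chrom Contig name.
#' @param pos 1-based genomic position.
#' @return The sub-list of overlapping transcripts.
#' @export
overlapping_transcripts <- function(db, chrom, pos) {
  hits <- vapply(db, function(t) {
    sp <- transcript_span(t)
    t$chrom == chrom && pos >= sp[1L] && pos <= sp[2L]
  }, logical(1L))
  structure(db[hits], class = "transcript_db")
}
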