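# Proband-parent trio de novo candidate identification.
#
# Candidate filters: the proband call must (1) be absent from both parents
# after normalizing indel representations to their most-5' form, (2) carry
# the "high" quality flag, (3) have TC >= 15, and (4) have good-quality
# parental depth (QCOV, mapping quality >= 20) of at least 15x in both
# parents at the variant position. Parent matching is exact-allele and
# ignores the parents' own quality flags: a low-quality parental call still
# counts as "present", which is conservative against false de novo claims.

# Normalized identity key of a variant; pure indels are keyed at their
# most-5' representation so equivalent representations match.
variant_key <- function(records, ref) {
  if (nrow(records) == 0L) return(character(0L))
  cls <- classify_variant_type(records$ref, records$alt)
  vapply(seq_len(nrow(records)), function(i) {
    if (cls$vtype[i] %in% c("insertion", "deletion")) {
      sh <- shift_indel(ref, records$chrom[i], records$pos[i],
                        records$ref[i], records$alt[i])
      paste(records$chrom[i], sh$pos_5prime, sh$ref_5prime, sh$alt_5prime,
            sep = ":")
    } else {
      paste(records$chrom[i], records$pos[i], toupper(records$ref[i]),
            toupper(records$alt[i]), sep = ":")
    }
  }, character(1L))
}

# Anchor position used for parental-coverage lookup (most-5' anchor base
# for indels, the variant base itself for substitutions).
normalized_position <- function(records, ref) {
  if (nrow(records) == 0L) return(integer(0L))
  as.integer(vapply(strsplit(variant_key(records, ref), ":", fixed = TRUE),
                    `[[`, character(1L), 2L))
}

#' Proband variants absent from both parents
#'
#' @param proband,father,mother Variant data.frames with `chrom`, `pos`,
#'   `ref`, `alt` columns (e.g. [parse_vcf()] output, flagged or not).
#' @param ref A [load_reference()] genome, used to normalize indel
#'   representations before matching.
#' @return The proband rows whose normalized (chrom, pos, ref, alt) key
#'   occurs in neither parent.
#' @export
subtract_parents <- function(proband, father, mother, ref) {
  pk <- variant_key(proband, ref)
  parental <- c(variant_key(father, ref), variant_key(mother, ref))
  proband[!(pk %in% parental), , drop = FALSE]
}

#' Apply the de novo candidate filters
#'
#' @param candidates Flagged proband variants ([flag_variants()] output),
#'   typically after [subtract_parents()].
#' @param father_bam,mother_bam Indexed parental BAM paths.
#' @param ref A [load_reference()] genome (for indel anchor normalization).
#' @param qcov_threshold Minimum parental depth (default 15).
#' @param tc_threshold Minimum proband TC (default 15).
#' @param mq_good Mapping-quality cutoff for parental depth (default 20).
#' @param use_qcov If `FALSE`, parental depth uses plain COV instead of the
#'   mapping-quality-filtered QCOV.
#' @return The kept candidates with added `father_qcov` and `mother_qcov`
#'   columns.
#' @export
apply_denovo_filters <- function(candidates, father_bam, mother_bam, ref,
                                 qcov_threshold = 15L, tc_threshold = 15L,
                                 mq_good = 20L, use_qcov = TRUE) {
  for (f in c(father_bam, mother_bam))
    if (!file.exists(f)) stop("parental BAM not found: ", f)
  if (nrow(candidates) == 0L) {
    candidates$father_qcov <- integer(0L)
    candidates$mother_qcov <- integer(0L)
    return(candidates)
  }
  anchor <- normalized_position(candidates, ref)
  depth_at <- function(bam, chrom, pos) {
    p <- pileup_profile(bam, chrom, pos, pos, mq_good = mq_good)
    if (use_qcov) p$QCOV[1L] else p$COV[1L]
  }
  candidates$father_qcov <- vapply(seq_len(nrow(candidates)), function(i)
    depth_at(father_bam, candidates$chrom[i], anchor[i]), integer(1L))
  candidates$mother_qcov <- vapply(seq_len(nrow(candidates)), function(i)
    depth_at(mother_bam, candidates$chrom[i], anchor[i]), integer(1L))
  keep <- candidates$flag == "high" &
    !is.na(candidates$tc) & candidates$tc >= tc_threshold &
    candidates$father_qcov >= qcov_threshold &
    candidates$mother_qcov >= qcov_threshold
  candidates[keep, , drop = FALSE]
}

#' Partition candidates by consequence severity
#'
#' @param candidates Variant data.frame with a `class` column of consequence
#'   classes.
#' @return List with `protein_altering`, `protein_truncating` and `other`
#'   data.frames; truncating is a subset of altering, `other` holds the
#'   non-altering rest.
#' @export
partition_by_consequence <- function(candidates) {
  alt <- protein_altering(candidates$class)
  trunc <- protein_truncating(candidates$class)
  list(protein_altering = candidates[alt, , drop = FALSE],
       protein_truncating = candidates[trunc, , drop = FALSE],
       other = candidates[!alt, , drop = FALSE])
}
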