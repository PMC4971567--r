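# Simplified consequence classes and 5'/3' indel representations.
#
# Class vocabulary (a deliberate simplification of full clinical annotation):
#   SY  synonymous substitution        NSY non-synonymous substitution
#   SG  stop-gain substitution         FS  frameshifting coding indel
#   IF  in-frame coding indel          ESS essential splice site (intron +/-1-2)
#   SS  splice region (intron +/-3-8)  EE  first/last 3 bases of internal exon
#   INT other intronic                 UTR untranslated exonic
# Protein-altering = {NSY, EE, IF, ESS, SG, FS}; protein-truncating =
# {ESS, SG, FS}. Severity order (used when a variant spans zones):
# SG > FS > ESS > NSY > EE > IF > SS > SY > UTR > INT.

consequence_classes <- c("SG", "FS", "ESS", "NSY", "EE", "IF", "SS", "SY",
                         "UTR", "INT")

#' Protein-altering / protein-truncating class membership
#'
#' @param class Character vector of consequence classes.
#' @return Logical vector.
#' @export
protein_altering <- function(class) {
  bad <- !(class %in% consequence_classes)
  if (any(bad)) stop("unknown consequence class: ",
                     paste(unique(class[bad]), collapse = ", "))
  class %in% c("NSY", "EE", "IF", "ESS", "SG", "FS")
}

#' @rdname protein_altering
#' @export
protein_truncating <- function(class) {
  bad <- !(class %in% consequence_classes)
  if (any(bad)) stop("unknown consequence class: ",
                     paste(unique(class[bad]), collapse = ", "))
  class %in% c("ESS", "SG", "FS")
}

#' Load a reference genome for slicing
#'
#' Reads a FASTA into memory and returns an accessor suitable for
#' [shift_indel()] and [assign_class()]. Sequence names are truncated at the
#' first whitespace, matching samtools/BAM conventions.
#'
#' @param path FASTA path.
#' @return A named list of upper-case sequence strings, class
#'   `"reference_genome"`.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(lapply(as.character(seqs), toupper), class = "reference_genome")
}

ref_slice <- function(ref, chrom, start, end) {
  s <- ref[[chrom]]
  if (is.null(s)) stop("contig ", chrom, " not in reference")
  if (start < 1L || end > nchar(s)) stop("slice outside contig ", chrom)
  substr(s, start, end)
}

check_ref_allele <- function(ref, chrom, pos, allele) {
  obs <- ref_slice(ref, chrom, pos, pos + nchar(allele) - 1L)
  if (obs != toupper(allele))
    stop("reference mismatch at ", chrom, ":", pos, ": VCF REF '", allele,
         "' vs genome '", obs, "'")
  invisible(TRUE)
}

#' Most-5' and most-3' representations of an indel
#'
#' An insertion or deletion inside a repeat has several equally correct
#' VCF representations. This walks the edit left and right through the
#' repeat (the standard normalization shift) and returns both extreme
#' anchored representations; applying either to the reference yields the
#' identical edited sequence. Clinical annotation conventions typically
#' want the most-3' form while VCF normalization wants the most-5' form,
#' so both are reported.
#'
#' @param ref A [load_reference()] genome.
#' @param chrom Contig.
#' @param pos 1-based VCF position of the anchor base.
#' @param ref_allele,alt_allele VCF-anchored alleles; one must be a prefix
#'   of the other (pure insertion or deletion).
#' @return List with `type`, `pos_5prime`, `ref_5prime`, `alt_5prime`,
#'   `pos_3prime`, `ref_3prime`, `alt_3prime`, and `seq` (the
#'   inserted/deleted bases of the most-5' representation).
#' @export
shift_indel <- function(ref, chrom, pos, ref_allele, alt_allele) {
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  lr <- nchar(ref_allele); la <- nchar(alt_allele)
  is_ins <- la > lr && substr(alt_allele, 1L, lr) == ref_allele
  is_del <- lr > la && substr(ref_allele, 1L, la) == alt_allele
  if (!is_ins && !is_del)
    stop("shift_indel requires a VCF-anchored pure insertion or deletion")
  check_ref_allele(ref, chrom, pos, ref_allele)
  s <- ref[[chrom]]
  n <- nchar(s)
  base_at <- function(i) substr(s, i, i)
  L <- abs(la - lr)
  if (is_del) {
    # deleted block starts after the matching anchor prefix of length la
    left <- pos + la
    right <- left
    # deleting [b, b+L-1] == deleting [b-1, b+L-2] iff s[b-1] == s[b+L-1];
    # a VCF-representable block needs an anchor base, so block start >= 2
    while (left >= 3L && base_at(left - 1L) == base_at(left + L - 1L))
      left <- left - 1L
    while (right + L <= n && base_at(right) == base_at(right + L))
      right <- right + 1L
    mk <- function(block_start) {
      anchor <- block_start - 1L
      list(pos = anchor,
           ref = ref_slice(ref, chrom, anchor, anchor + L),
           alt = base_at(anchor))
    }
    r5 <- mk(left); r3 <- mk(right)
    out <- list(type = "deletion",
                pos_5prime = r5$pos, ref_5prime = r5$ref, alt_5prime = r5$alt,
                pos_3prime = r3$pos, ref_3prime = r3$ref, alt_3prime = r3$alt,
                seq = ref_slice(ref, chrom, left, left + L - 1L))
  } else {
    # inserted sequence S goes after the last anchor base
    S <- substr(alt_allele, lr + 1L, la)
    after <- pos + lr - 1L
    left_after <- after; Sl <- S
    # inserting S after a == inserting s[a]+S[1..L-1] after a-1 iff s[a]==S[L]
    while (left_after >= 2L && base_at(left_after) == substr(Sl, L, L)) {
      Sl <- paste0(base_at(left_after), substr(Sl, 1L, L - 1L))
      left_after <- left_after - 1L
    }
    right_after <- after; Sr <- S
    while (right_after + 1L <= n &&
           base_at(right_after + 1L) == substr(Sr, 1L, 1L)) {
      Sr <- paste0(substr(Sr, 2L, L), base_at(right_after + 1L))
      right_after <- right_after + 1L
    }
    mk <- function(after_pos, Sx) {
      list(pos = after_pos,
           ref = base_at(after_pos),
           alt = paste0(base_at(after_pos), Sx))
    }
    r5 <- mk(left_after, Sl); r3 <- mk(right_after, Sr)
    out <- list(type = "insertion",
                pos_5prime = r5$pos, ref_5prime = r5$ref, alt_5prime = r5$alt,
                pos_3prime = r3$pos, ref_3prime = r3$ref, alt_3prime = r3$alt,
                seq = Sl)
  }
  stopifnot(out$pos_5prime <= out$pos_3prime)
  out
}

# Apply a VCF-anchored edit to a contig string (oracle-grade helper, also
# used to verify representation equivalence in tests).
apply_edit <- function(seq, pos, ref_allele, alt_allele) {
  stopifnot(substr(seq, pos, pos + nchar(ref_allele) - 1L) == ref_allele)
  paste0(substr(seq, 1L, pos - 1L), alt_allele,
         substr(seq, pos + nchar(ref_allele), nchar(seq)))
}

# Zone of a single genomic position relative to a transcript: list(kind,
# edge, intron_dist). edge is TRUE for the first/last 3 bases of an internal
# exon; intron_dist is the distance to the nearest exon boundary for
# intronic positions.
position_zone <- function(t, pos) {
  i <- tx_index(t, pos)
  if (!is.na(i)) {
    ab <- cds_tx_bounds(t)
    ek <- exonic_kind_index(i, ab[1L], ab[2L])
    j <- findInterval(pos, t$exon_starts + 1L)
    n_ex <- length(t$exon_starts)
    near_start <- pos - t$exon_starts[j] <= 3L      # first 3 bases (genomic)
    near_end <- t$exon_ends[j] - pos < 3L           # last 3 bases
    internal_left <- j > 1L                          # has an upstream intron
    internal_right <- j < n_ex
    edge <- (near_start && internal_left) || (near_end && internal_right)
    list(kind = ek$kind, edge = edge, intron_dist = NA_integer_)
  } else {
    j <- findInterval(pos, t$exon_starts + 1L)
    d <- min(pos - t$exon_ends[j], t$exon_starts[j + 1L] + 1L - pos)
    list(kind = "intronic", edge = FALSE, intron_dist = as.integer(d))
  }
}

# Extract the spliced CDS sequence of a transcript (translation orientation).
cds_sequence <- function(ref, t) {
  parts <- character(0L)
  for (k in seq_along(t$exon_starts)) {
    lo <- max(t$exon_starts[k], t$cds_start) + 1L
    hi <- min(t$exon_ends[k], t$cds_end)
    if (lo <= hi) parts <- c(parts, ref_slice(ref, t$chrom, lo, hi))
  }
  s <- paste(parts, collapse = "")
  if (t$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Assign a consequence class to one variant on one transcript
#'
#' Substitutions in the CDS are translated (standard genetic code) to SY,
#' NSY or SG. Coding indels are FS when the length is not a multiple of 3,
#' else IF. Intronic positions within 1-2 bp of an exon boundary are ESS,
#' within 3-8 bp SS, otherwise INT; untranslated exonic positions are UTR.
#' Positions in the first/last 3 bases of an internal exon are flagged EE
#' unless a more severe class applies (SG always wins; coding indels keep
#' FS). Indels are classified at their most-5' representation; variants
#' spanning several zones take the most severe applicable class
#' (SG > FS > ESS > NSY > EE > IF > SS > SY > UTR > INT).
#'
#' @param v List or one-row data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param t A [transcript()] on the same contig.
#' @param ref A [load_reference()] genome.
#' @return A single class string.
#' @export
assign_class <- function(v, t, ref) {
  chrom <- v$chrom; pos <- as.integer(v$pos)
  ra <- toupper(v$ref); aa <- toupper(v$alt)
  check_ref_allele(ref, chrom, pos, ra)
  cls <- classify_variant_type(ra, aa)
  sp <- transcript_span(t)

  # use the most-5' representation for pure indels
  if (cls$vtype %in% c("insertion", "deletion")) {
    sh <- shift_indel(ref, chrom, pos, ra, aa)
    pos <- sh$pos_5prime; ra <- sh$ref_5prime; aa <- sh$alt_5prime
  }

  # affected genomic positions
  affected <- switch(cls$vtype,
    substitution = pos,
    insertion = c(pos, pos + 1L),
    deletion = seq.int(pos + 1L, pos + cls$indel_len),
    complex = seq.int(pos, pos + nchar(ra) - 1L))
  affected <- affected[affected >= sp[1L] & affected <= sp[2L]]
  if (length(affected) == 0L)
    stop("variant does not overlap transcript span of ", t$transcript_id)

  zones <- lapply(affected, function(p) position_zone(t, p))
  kinds <- vapply(zones, `[[`, character(1L), "kind")
  edges <- vapply(zones, `[[`, logical(1L), "edge")
  dists <- vapply(zones, `[[`, integer(1L), "intron_dist")

  candidates <- character(0L)
  if (any(kinds == "coding")) {
    if (cls$vtype == "substitution") {
      candidates <- c(candidates, substitution_codon_class(v, t, ref))
    } else {
      candidates <- c(candidates,
                      if (cls$indel_len %% 3L != 0L) "FS" else "IF")
    }
  }
  if (any(kinds %in% c("utr5", "utr3"))) candidates <- c(candidates, "UTR")
  intron_d <- dists[kinds == "intronic"]
  if (length(intron_d)) {
    if (any(intron_d <= 2L)) candidates <- c(candidates, "ESS")
    if (any(intron_d >= 3L & intron_d <= 8L)) candidates <- c(candidates, "SS")
    if (any(intron_d > 8L)) candidates <- c(candidates, "INT")
  }
  if (any(edges)) candidates <- c(candidates, "EE")

  # exon-edge rule: EE supersedes SY/NSY (but never SG) for substitutions
  if (any(edges) && cls$vtype == "substitution" &&
      !("SG" %in% candidates))
    candidates <- setdiff(candidates, c("SY", "NSY"))

  candidates <- unique(candidates)
  candidates[which.min(match(candidates, consequence_classes))]
}

# SY/NSY/SG for a CDS substitution by codon translation.
substitution_codon_class <- function(v, t, ref) {
  i <- tx_index(t, as.integer(v$pos))
  ab <- cds_tx_bounds(t)
  c_index <- i - ab[1L] + 1L  # position within the CDS, 1-based
  cds <- cds_sequence(ref, t)
  alt_base <- toupper(v$alt)
  if (t$strand == "-")
    alt_base <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(alt_base)))
  codon_i <- (c_index - 1L) %/% 3L
  off <- (c_index - 1L) %% 3L
  codon_start <- codon_i * 3L + 1L
  if (codon_start + 2L > nchar(cds)) return("NSY")  # truncated terminal codon
  codon <- substr(cds, codon_start, codon_start + 2L)
  new_codon <- codon
  substr(new_codon, off + 1L, off + 1L) <- alt_base
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(new_codon)
  if (is.na(aa_ref) || is.na(aa_alt)) return("NSY")
  if (aa_alt == aa_ref) "SY" else if (aa_alt == "*") "SG" else "NSY"
}
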