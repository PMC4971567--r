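# Shared fixture builders and independent oracles.

# Toy two-exon transcript used throughout: exons [100,200)+[300,400),
# CDS [150,350), so c.1 sits at 1-based position 151 on "+".
toy_transcript <- function(strand = "+") {
  transcript("G", paste0("TOY", strand), "chr1", strand,
             exon_starts = c(100L, 300L), exon_ends = c(200L, 400L),
             cds_start = 150L, cds_end = 350L)
}

# In-memory reference accessor from a named list of strings.
mini_ref <- function(...) {
  structure(lapply(list(...), toupper), class = "reference_genome")
}

# Independent c.-map enumerator: walks exonic bases in transcript order and
# assigns labels by position in the walk; introns labelled per the declared
# anchoring convention. Deliberately string/cumsum-based, separate from the
# package's arithmetic mapping.
naive_csn_map <- function(t) {
  ex <- mapply(function(s, e) seq.int(s + 1L, e), t$exon_starts, t$exon_ends,
               SIMPLIFY = FALSE)
  tx <- unlist(ex)
  if (t$strand == "-") tx <- rev(tx)
  coding <- tx >= t$cds_start + 1L & tx <= t$cds_end
  a <- which(coding)[1L]
  b <- max(which(coding))
  lab <- character(length(tx))
  lab[coding] <- paste0("c.", cumsum(coding)[coding])
  idx <- seq_along(tx)
  lab[idx < a] <- paste0("c.-", a - idx[idx < a])
  lab[idx > b] <- paste0("c.*", idx[idx > b] - b)
  exonic <- stats::setNames(lab, tx)

  labels <- exonic
  n_ex <- length(t$exon_starts)
  if (n_ex > 1L) {
    for (k in seq_len(n_ex - 1L)) {
      gl <- t$exon_ends[k]
      gr <- t$exon_starts[k + 1L] + 1L
      for (p in seq.int(gl + 1L, gr - 1L)) {
        kl <- p - gl
        kr <- gr - p
        lab_p <- if (t$strand == "+") {
          if (kl <= kr) paste0(exonic[[as.character(gl)]], "+", kl)
          else paste0(exonic[[as.character(gr)]], "-", kr)
        } else {
          if (kr <= kl) paste0(exonic[[as.character(gr)]], "+", kr)
          else paste0(exonic[[as.character(gl)]], "-", kl)
        }
        labels[as.character(p)] <- lab_p
      }
    }
  }
  pos <- as.integer(names(labels))
  o <- order(pos)
  data.frame(pos = pos[o], csn = unname(labels)[o], stringsAsFactors = FALSE)
}

# Independent per-base pileup recount from an alignment truth table
# (plain loops over read spans; no alignment parsing).
oracle_profile <- function(truth, start, end, mq_good = 20L, bq_low = 10L) {
  len <- end - start + 1L
  cov <- integer(len); qcov <- integer(len)
  mq_at <- vector("list", len); bq_at <- vector("list", len)
  use <- !truth$dup
  for (i in which(use)) {
    lo <- max(truth$start[i], start)
    hi <- min(truth$end[i], end)
    if (lo > hi) next
    ix <- (lo:hi) - start + 1L
    cov[ix] <- cov[ix] + 1L
    if (truth$mapq[i] >= mq_good) qcov[ix] <- qcov[ix] + 1L
    for (j in ix) {
      mq_at[[j]] <- c(mq_at[[j]], truth$mapq[i])
      bq_at[[j]] <- c(bq_at[[j]], truth$bq[i])
    }
  }
  list(COV = cov, QCOV = qcov,
       MEDMQ = vapply(mq_at, function(v) if (length(v)) stats::median(v) else NA_real_, numeric(1L)),
       FLMQ = vapply(mq_at, function(v) if (length(v)) mean(v < mq_good) else NA_real_, numeric(1L)),
       MEDBQ = vapply(bq_at, function(v) if (length(v)) stats::median(v) else NA_real_, numeric(1L)),
       FLBQ = vapply(bq_at, function(v) if (length(v)) mean(v < bq_low) else NA_real_, numeric(1L)))
}

# Random reference string of length n.
random_seq <- function(n, seed) {
  clinexome:::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = ""))
}
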