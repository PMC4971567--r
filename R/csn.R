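# Genomic -> transcript (c.) coordinate mapping.
#
# Coding exonic bases map to c.1..c.L in translation order; 5'UTR bases to
# c.-N counting away from c.1; 3'UTR bases to c.*N; intronic bases anchor to
# the nearest exon-boundary base with a signed offset (c.N+k downstream of the
# donor, c.N-k upstream of the acceptor). Positions in the 5' half of an
# intron (transcript orientation) anchor to the upstream exon; the exact
# midpoint anchors upstream.

# Exonic 1-based positions <= g / >= g.
count_exonic_le <- function(t, g) {
  sum(pmax(0L, pmin(t$exon_ends, g) - t$exon_starts))
}
count_exonic_ge <- function(t, g) {
  sum(pmax(0L, t$exon_ends - pmax(t$exon_starts, g - 1L)))
}

# Transcript-space index (1 = transcript-first base) of exonic 1-based
# positions; NA for intronic positions. Vectorized over pos.
tx_index <- function(t, pos) {
  j <- findInterval(pos, t$exon_starts + 1L)
  exonic <- j >= 1L & pos <= t$exon_ends[pmax(j, 1L)]
  lens <- t$exon_ends - t$exon_starts
  idx <- rep(NA_integer_, length(pos))
  jj <- j[exonic]
  if (t$strand == "+") {
    cum_before <- c(0L, cumsum(lens))[jj]
    idx[exonic] <- cum_before + (pos[exonic] - t$exon_starts[jj])
  } else {
    cum_after <- (sum(lens) - cumsum(lens))[jj]
    idx[exonic] <- cum_after + (t$exon_ends[jj] - pos[exonic] + 1L)
  }
  idx
}

# Transcript-space indices [a, b] of the first/last coding base.
cds_tx_bounds <- function(t) {
  if (t$strand == "+") {
    a <- count_exonic_le(t, t$cds_start) + 1L
    b <- count_exonic_le(t, t$cds_end)
  } else {
    a <- count_exonic_ge(t, t$cds_end + 1L) + 1L
    b <- count_exonic_ge(t, t$cds_start + 1L)
  }
  c(a, b)
}

# kind/index for exonic transcript-space indices.
exonic_kind_index <- function(i, a, b) {
  kind <- ifelse(i < a, "utr5", ifelse(i > b, "utr3", "coding"))
  index <- ifelse(i < a, a - i, ifelse(i > b, i - b, i - a + 1L))
  list(kind = kind, index = as.integer(index))
}

render_csn <- function(kind, index, offset, anchor_kind) {
  base_kind <- ifelse(kind == "intronic", anchor_kind, kind)
  core <- ifelse(base_kind == "coding", sprintf("c.%d", index),
                 ifelse(base_kind == "utr5", sprintf("c.-%d", index),
                        sprintf("c.*%d", index)))
  ifelse(kind == "intronic", sprintf("%s%+d", core, offset), core)
}

#' Map genomic positions to transcript (c.) coordinates
#'
#' @param t A [transcript()].
#' @param pos Vector of 1-based genomic positions; every position must lie
#'   within the transcript span (first exon start to last exon end).
#' @return A data.frame with one row per position and columns `pos`, `kind`
#'   (`coding`, `utr5`, `utr3` or `intronic`), `index` (the c. index of the
#'   base itself, or of the anchoring exon-boundary base for intronic
#'   positions), `offset` (signed intron offset, 0 for exonic positions) and
#'   `csn` (the rendered coordinate, e.g. `"c.1"`, `"c.-12"`, `"c.*3"`,
#'   `"c.50+1"`).
#' @examples
#' t <- transcript("G", "T1", "chr1", "+", c(100, 300), c(200, 400), 150, 350)
#' genomic_to_csn(t, c(151, 150, 201, 300, 351))$csn
#' @export
genomic_to_csn <- function(t, pos) {
  pos <- as.integer(pos)
  sp <- transcript_span(t)
  if (any(pos < sp[1L] | pos > sp[2L]))
    stop("position outside transcript span of ", t$transcript_id,
         " (", sp[1L], "-", sp[2L], ")")
  ab <- cds_tx_bounds(t)
  i <- tx_index(t, pos)
  exonic <- !is.na(i)

  kind <- character(length(pos))
  index <- integer(length(pos))
  offset <- integer(length(pos))
  anchor_kind <- rep(NA_character_, length(pos))

  if (any(exonic)) {
    ek <- exonic_kind_index(i[exonic], ab[1L], ab[2L])
    kind[exonic] <- ek$kind
    index[exonic] <- ek$index
  }

  if (any(!exonic)) {
    p <- pos[!exonic]
    j <- findInterval(p, t$exon_starts + 1L)  # exon to the left
    g_left <- t$exon_ends[j]
    g_right <- t$exon_starts[j + 1L] + 1L
    k_left <- p - g_left
    k_right <- g_right - p
    if (t$strand == "+") use_left <- k_left <= k_right
    else use_left <- k_left < k_right
    anchor <- ifelse(use_left, g_left, g_right)
    off <- ifelse(xor(use_left, t$strand == "-"), 1L, -1L) *
      ifelse(use_left, k_left, k_right)
    ai <- tx_index(t, anchor)
    ak <- exonic_kind_index(ai, ab[1L], ab[2L])
    kind[!exonic] <- "intronic"
    index[!exonic] <- ak$index
    offset[!exonic] <- as.integer(off)
    anchor_kind[!exonic] <- ak$kind
  }

  csn <- render_csn(kind, index, offset,
                    ifelse(is.na(anchor_kind), kind, anchor_kind))
  data.frame(pos = pos, kind = kind, index = index, offset = offset,
             csn = csn, stringsAsFactors = FALSE)
}

#' Enumerate the full base-to-c. map of a transcript
#'
#' @param t A [transcript()].
#' @return [genomic_to_csn()] output for every position in the span.
#' @export
csn_map <- function(t) {
  sp <- transcript_span(t)
  genomic_to_csn(t, seq.int(sp[1L], sp[2L]))
}

#' Label a genomic interval in transcript coordinates
#'
#' Renders `"GENE:c.X-c.Y"` where X and Y are the c. coordinates of the
#' interval's first and last base in transcript (strand) order, clipped to the
#' transcript span. This is the annotation attached to failing coverage
#' subregions.
#'
#' @param t A [transcript()].
#' @param start,end 1-based inclusive genomic interval; must overlap the span.
#' @return A label string such as `"BRCA1:c.1500-c.1550"`.
#' @export
region_to_csn_label <- function(t, start, end) {
  if (end < start) stop("interval end < start")
  sp <- transcript_span(t)
  if (end < sp[1L] || start > sp[2L])
    stop("interval does not overlap transcript span of ", t$transcript_id)
  lo <- max(start, sp[1L])
  hi <- min(end, sp[2L])
  ends <- if (t$strand == "+") c(lo, hi) else c(hi, lo)
  csn <- genomic_to_csn(t, ends)$csn
  sprintf("%s:%s-%s", t$gene_symbol, csn[1L], csn[2L])
}
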