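# A deterministic reference around the toy transcript so codon content is
# known: exon bases are filled with a repeating ATG pattern, then specific
# codons are overwritten per test.
toy_ref <- function(seq = NULL) {
  if (is.null(seq)) {
    s <- strsplit(random_seq(1000L, seed = 55L), "")[[1L]]
    seq <- paste(s, collapse = "")
  }
  mini_ref(chr1 = seq)
}

test_that("indel representations apply to identical edited sequences", {
  # deletion of CA inside TACACAG has four equivalent anchored forms
  ref <- mini_ref(chr1 = "TACACAGTT")
  sh <- shift_indel(ref, "chr1", 2L, "ACA", "A")
  expect_identical(sh$pos_5prime, 1L)
  expect_identical(sh$pos_3prime, 4L)
  e5 <- clinexome:::apply_edit(ref$chr1, sh$pos_5prime, sh$ref_5prime,
                               sh$alt_5prime)
  e3 <- clinexome:::apply_edit(ref$chr1, sh$pos_3prime, sh$ref_3prime,
                               sh$alt_3prime)
  expect_identical(e5, e3)
  expect_identical(e5, "TACAGTT")

  # insertion of A into an A-homopolymer shifts across the whole run
  ref2 <- mini_ref(chr1 = "TTGAAAACCT")
  sh2 <- shift_indel(ref2, "chr1", 4L, "A", "AA")
  expect_identical(sh2$pos_5prime, 3L)  # anchored on the base before the run
  expect_identical(sh2$pos_3prime, 7L)  # after the run
  expect_identical(
    clinexome:::apply_edit(ref2$chr1, sh2$pos_5prime, sh2$ref_5prime,
                           sh2$alt_5prime),
    clinexome:::apply_edit(ref2$chr1, sh2$pos_3prime, sh2$ref_3prime,
                           sh2$alt_3prime))

  # non-repetitive context: both representations coincide
  ref3 <- mini_ref(chr1 = "TTGACTGACT")
  sh3 <- shift_indel(ref3, "chr1", 3L, "GA", "G")
  expect_identical(sh3$pos_5prime, sh3$pos_3prime)

  expect_error(shift_indel(ref, "chr1", 2L, "GCA", "G"), "mismatch")
  expect_error(shift_indel(ref, "chr1", 2L, "A", "G"), "insertion or deletion")
})

test_that("random indels keep apply-edit equivalence and pos5 <= pos3", {
  ref <- mini_ref(chr1 = random_seq(5000L, seed = 61L))
  set.seed(62)
  for (k in 1:200) {
    pos <- sample(50:4900, 1L)
    len <- sample(1:12, 1L)
    if (runif(1) < 0.5) {
      ra <- clinexome:::ref_slice(ref, "chr1", pos, pos + len)
      aa <- substr(ra, 1L, 1L)
    } else {
      ra <- clinexome:::ref_slice(ref, "chr1", pos, pos)
      aa <- paste0(ra, random_seq(len, seed = 5000L + k))
    }
    sh <- shift_indel(ref, "chr1", pos, ra, aa)
    expect_lte(sh$pos_5prime, sh$pos_3prime)
    expect_identical(
      clinexome:::apply_edit(ref$chr1, sh$pos_5prime, sh$ref_5prime,
                             sh$alt_5prime),
      clinexome:::apply_edit(ref$chr1, sh$pos_3prime, sh$ref_3prime,
                             sh$alt_3prime))
    # the original representation edits to the same sequence too
    expect_identical(
      clinexome:::apply_edit(ref$chr1, pos, ra, aa),
      clinexome:::apply_edit(ref$chr1, sh$pos_5prime, sh$ref_5prime,
                             sh$alt_5prime))
  }
})

test_that("CDS substitutions translate to SY/NSY/SG via the genetic code", {
  # toy transcript "+": c.1 at 151; place codons explicitly
  s <- strsplit(random_seq(1000L, seed = 63L), "")[[1L]]
  # codon 1 at 151..153 = ATG; codon 2 at 154..156 = TAC (Tyr)
  s[151:156] <- c("A", "T", "G", "T", "A", "C")
  ref <- mini_ref(chr1 = paste(s, collapse = ""))
  t <- toy_transcript("+")
  # TAC -> TAA: stop gained
  expect_identical(
    assign_class(list(chrom = "chr1", pos = 156L, ref = "C", alt = "A"),
                 t, ref), "SG")
  # TAC -> TAT: synonymous (Tyr)
  expect_identical(
    assign_class(list(chrom = "chr1", pos = 156L, ref = "C", alt = "T"),
                 t, ref), "SY")
  # TAC -> GAC: missense (Tyr -> Asp)
  expect_identical(
    assign_class(list(chrom = "chr1", pos = 154L, ref = "T", alt = "G"),
                 t, ref), "NSY")
})

test_that("minus-strand codon classes use the reverse complement", {
  # toy "-": c.1 at genomic 350, codon 1 read 350,349,348 complemented.
  s <- strsplit(random_seq(1000L, seed = 64L), "")[[1L]]
  # genomic 348..350 = CAT -> transcript ATG; genomic 345..347 = ATA -> TAT (Tyr)
  s[348:350] <- c("C", "A", "T")
  s[345:347] <- c("A", "T", "A")
  ref <- mini_ref(chr1 = paste(s, collapse = ""))
  t <- toy_transcript("-")
  # transcript TAT -> TAA stop: genomic A345 -> T
  expect_identical(
    assign_class(list(chrom = "chr1", pos = 345L, ref = "A", alt = "T"),
                 t, ref), "SG")
  # transcript TAT -> TAC (still Tyr): genomic A345 -> G
  expect_identical(
    assign_class(list(chrom = "chr1", pos = 345L, ref = "A", alt = "G"),
                 t, ref), "SY")
})

test_that("coding indels are FS iff their length is not a multiple of 3", {
  ref <- toy_ref()
  t <- toy_transcript("+")
  mid <- 170L  # mid-exon coding position away from edges
  base <- clinexome:::ref_slice(ref, "chr1", mid, mid)
  del4 <- list(chrom = "chr1", pos = mid,
               ref = clinexome:::ref_slice(ref, "chr1", mid, mid + 4L),
               alt = base)
  expect_identical(assign_class(del4, t, ref), "FS")
  del3 <- list(chrom = "chr1", pos = mid,
               ref = clinexome:::ref_slice(ref, "chr1", mid, mid + 3L),
               alt = base)
  expect_identical(assign_class(del3, t, ref), "IF")
  ins2 <- list(chrom = "chr1", pos = mid, ref = base,
               alt = paste0(base, "TG"))
  expect_identical(assign_class(ins2, t, ref), "FS")
})

test_that("splice windows and UTR/intron zones classify by distance", {
  ref <- toy_ref()
  t <- toy_transcript("+")
  sub_at <- function(pos) {
    b <- clinexome:::ref_slice(ref, "chr1", pos, pos)
    list(chrom = "chr1", pos = pos, ref = b,
         alt = setdiff(c("A", "C", "G", "T"), b)[1L])
  }
  expect_identical(assign_class(sub_at(201L), t, ref), "ESS")  # intron +1
  expect_identical(assign_class(sub_at(202L), t, ref), "ESS")  # intron +2
  expect_identical(assign_class(sub_at(203L), t, ref), "SS")   # intron +3
  expect_identical(assign_class(sub_at(208L), t, ref), "SS")   # intron +8
  expect_identical(assign_class(sub_at(209L), t, ref), "INT")  # intron +9
  expect_identical(assign_class(sub_at(299L), t, ref), "ESS")  # acceptor -2
  expect_identical(assign_class(sub_at(120L), t, ref), "UTR")  # 5'UTR
  expect_identical(assign_class(sub_at(390L), t, ref), "UTR")  # 3'UTR
})

test_that("exon-edge positions report EE unless a more severe class applies", {
  # make the last exon-1 codon non-stop-forming so the edge rule decides
  s <- strsplit(random_seq(1000L, seed = 65L), "")[[1L]]
  s[196:200] <- c("C", "C", "C", "C", "C")
  ref <- mini_ref(chr1 = paste(s, collapse = ""))
  t <- toy_transcript("+")
  got <- assign_class(list(chrom = "chr1", pos = 199L, ref = "C", alt = "G"),
                      t, ref)
  expect_identical(got, "EE")
})

test_that("the truncating classes are a subset of the altering classes", {
  expect_true(protein_altering("NSY"))
  expect_false(protein_truncating("NSY"))
  expect_false(protein_altering("SY"))
  expect_true(protein_altering("FS") && protein_truncating("FS"))
  all_classes <- c("SY", "NSY", "SG", "FS", "IF", "ESS", "EE", "SS", "INT",
                   "UTR")
  expect_true(all(protein_altering(all_classes[protein_truncating(all_classes)])))
  expect_identical(all_classes[protein_altering(all_classes)],
                   c("NSY", "SG", "FS", "IF", "ESS", "EE"))
  expect_identical(all_classes[protein_truncating(all_classes)],
                   c("SG", "FS", "ESS"))
  expect_error(protein_altering("XX"), "unknown")
})
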