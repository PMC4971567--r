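write_test_vcf <- function(lines, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=100000>",
           "##INFO=<ID=TR,Number=A,Type=Integer,Description=\"x\">",
           "##INFO=<ID=TC,Number=1,Type=Integer,Description=\"x\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, lines), path)
  path
}

test_that("VCF records parse with QUAL/FILTER/TR/TC and split multi-allelics", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(c(
    "chr1\t500\t.\tA\tG\t120\tPASS\tTR=30;TC=60",
    "chr1\t700\t.\tC\tA,T\t80\tPASS\tTR=10,20;TC=50",
    "chr1\t900\t.\tG\tGA\t99\tbadReads\tTR=12;TC=40"), path)
  recs <- parse_vcf(path)
  expect_identical(nrow(recs), 4L)  # multi-allelic split conserves alleles
  expect_identical(recs$pos, c(500L, 700L, 700L, 900L))
  expect_identical(recs$tr, c(30L, 10L, 20L, 12L))
  expect_identical(recs$tc, c(60L, 50L, 50L, 40L))
  expect_identical(recs$qual[1L], 120)
  expect_identical(recs$filter[4L], "badReads")
  expect_identical(recs$line, c(1L, 2L, 2L, 3L))
})

test_that("records lacking TR/TC warn and end up flagged low", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf("chr1\t500\t.\tA\tG\t500\tPASS\tTC=60", path)
  expect_warning(recs <- parse_vcf(path), "missing TR/TC")
  expect_true(is.na(recs$tr))
  fl <- flag_variants(recs)
  expect_identical(fl$flag, "high")  # substitution: QUAL rule still applies
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf("chr1\t500\t.\tA\tAGG\t500\tPASS\tTC=60", path2)
  suppressWarnings(fl2 <- flag_variants(parse_vcf(path2)))
  expect_identical(fl2$flag, "low")  # indel without TR can never be high
})

test_that("the variant allele fraction is TR/TC with guarded edge cases", {
  expect_equal(variant_allele_fraction(10L, 50L), 0.2)
  expect_equal(variant_allele_fraction(0L, 30L), 0)
  expect_equal(variant_allele_fraction(30L, 30L), 1)
  expect_warning(v <- variant_allele_fraction(0L, 0L), "TC == 0")
  expect_equal(v, 0)
  expect_error(variant_allele_fraction(31L, 30L), "TR > TC")
  # monotone non-decreasing in TR at fixed TC
  vafs <- variant_allele_fraction(0:40, rep(40L, 41L))
  expect_true(all(diff(vafs) >= 0))
})

test_that("variant types and the 10-bp short/long boundary classify correctly", {
  expect_identical(classify_variant_type("A", "G")$vtype, "substitution")
  ins <- classify_variant_type("A", "ACTTT")
  expect_identical(ins$vtype, "insertion")
  expect_identical(ins$indel_len, 4L)
  expect_identical(ins$length_class, "short")
  del11 <- classify_variant_type(paste0("A", strrep("C", 11)), "A")
  expect_identical(del11$vtype, "deletion")
  expect_identical(del11$indel_len, 11L)
  expect_identical(del11$length_class, "long")
  # boundary: 10 is short, 11 is long
  expect_identical(
    classify_variant_type(paste0("A", strrep("C", 10)), "A")$length_class,
    "short")
  cx <- classify_variant_type("ACG", "TTT")
  expect_identical(cx$vtype, "complex")
  expect_identical(cx$indel_len, 3L)
  expect_error(classify_variant_type("", "A"), "empty")
  expect_error(classify_variant_type("A", "A"), "REF equals ALT")
})

test_that("type classification is invariant under 3'-shifting of the alleles", {
  ref <- mini_ref(chr1 = random_seq(2000L, seed = 77L))
  set.seed(78)
  for (k in 1:50) {
    pos <- sample(100:1800, 1L)
    len <- sample(1:10, 1L)
    if (k %% 2L == 0L) {
      ra <- clinexome:::ref_slice(ref, "chr1", pos, pos + len)
      aa <- substr(ra, 1L, 1L)
    } else {
      ra <- clinexome:::ref_slice(ref, "chr1", pos, pos)
      aa <- paste0(ra, random_seq(len, seed = 1000L + k))
    }
    sh <- shift_indel(ref, "chr1", pos, ra, aa)
    a <- classify_variant_type(ra, aa)
    b <- classify_variant_type(sh$ref_3prime, sh$alt_3prime)
    expect_identical(a$vtype, b$vtype)
    expect_identical(a$indel_len, b$indel_len)
  }
})

test_that("the flag rule matches the stated thresholds with inclusive bounds", {
  expect_identical(assign_quality_flag("substitution", 100, "PASS", 1L, 10L),
                   "high")
  expect_identical(assign_quality_flag("substitution", 99.9, "PASS", 10L, 10L),
                   "low")
  expect_identical(assign_quality_flag("deletion", 5, "PASS", 10L, 50L),
                   "high")
  expect_identical(assign_quality_flag("deletion", 500, "badReads", 10L, 50L),
                   "low")
  expect_identical(assign_quality_flag("insertion", 500, "PASS", 9L, 50L),
                   "low")
  # missing values always yield low
  expect_identical(assign_quality_flag("substitution", NA, "PASS", 30L, 60L),
                   "low")
  expect_identical(assign_quality_flag("deletion", 200, "PASS", NA, 60L),
                   "low")
})

test_that("intergenic removal partitions records by transcript span", {
  t <- toy_transcript("+")
  recs <- data.frame(chrom = "chr1", pos = c(150L, 250L, 5000L, 101L, 400L),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  res <- remove_intergenic(recs, list(t))
  expect_identical(res$kept$pos, c(150L, 250L, 101L, 400L))  # intron kept
  expect_identical(res$removed$pos, 5000L)
  expect_identical(nrow(res$kept) + nrow(res$removed), nrow(recs))

  # random positions vs a fixture db equal the linear-scan oracle
  db <- random_transcripts(10L, "chr1", 100000L, seed = 8L)
  spans <- vapply(db, clinexome:::transcript_span, integer(2L))
  set.seed(12)
  recs2 <- data.frame(chrom = "chr1", pos = sample(1:90000, 300L),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  res2 <- remove_intergenic(recs2, db)
  oracle <- vapply(recs2$pos, function(p)
    any(spans[1L, ] <= p & spans[2L, ] >= p), logical(1L))
  expect_identical(res2$kept$pos, recs2$pos[oracle])
})

test_that("the variant TSV has the fixed column set and closed flag vocabulary", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(c(
    "chr1\t500\t.\tA\tG\t120\tPASS\tTR=30;TC=60",
    "chr1\t700\t.\tC\tCAT\t80\tPASS\tTR=25;TC=50",
    "chr1\t900\t.\tGAAC\tG\t90\tbadReads\tTR=5;TC=50"), path)
  fl <- flag_variants(parse_vcf(path))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_variant_tsv(fl, out)
  tab <- read.delim(out, colClasses = "character")
  expect_identical(names(tab),
                   c("CHROM", "POS", "REF", "ALT", "TYPE", "QUAL", "FILTER",
                     "TR", "TC", "VAF", "FLAG", "GENE", "TRANSCRIPT",
                     "CLASS", "CSN_5PRIME", "CSN_3PRIME"))
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$FLAG %in% c("high", "low")))
  expect_identical(as.integer(tab$POS), fl$pos)
  expect_identical(tab$GENE, rep(".", 3L))
  # empty input writes a header-only file
  write_variant_tsv(fl[0L, ], out)
  expect_identical(nrow(read.delim(out)), 0L)
})
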