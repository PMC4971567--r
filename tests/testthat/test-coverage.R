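# Shared small alignment fixture: one 1-kb region on a 20-kb contig.
cov_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    d <- file.path(tempdir(), "covfix")
    spec <- fixture_spec(seed = 17L, contig_lengths = c(chr1 = 20000L),
                         depth = 30, low_mq_fraction = 0.2,
                         low_bq_fraction = 0.1, dup_fraction = 0.1)
    refp <- make_reference(spec, d)
    regions <- data.frame(chrom = "chr1", start = 5001L, end = 6000L)
    al <- simulate_alignments(spec, refp, regions, file.path(d, "s1"))
    cache <<- list(spec = spec, ref = refp, region = regions, bam = al$bam,
                   truth = al$truth, dir = d)
    cache
  }
})

test_that("pileup metrics equal a brute-force recount from the read layout", {
  fx <- cov_fixture()
  p <- pileup_profile(fx$bam, "chr1", 5001L, 6000L)
  o <- oracle_profile(fx$truth, 5001L, 6000L)
  expect_identical(p$COV, o$COV)
  expect_identical(p$QCOV, o$QCOV)
  expect_equal(p$FLMQ, o$FLMQ)
  expect_equal(p$FLBQ, o$FLBQ)
  expect_equal(p$MEDMQ, o$MEDMQ)
  expect_equal(p$MEDBQ, o$MEDBQ)
  # declared low-MQ fraction shows up in the profile
  expect_lt(abs(mean(p$FLMQ, na.rm = TRUE) - 0.2), 0.05)
  expect_true(all(p$QCOV <= p$COV))
})

test_that("duplicate and low-quality reads shift metrics the declared way", {
  fx <- cov_fixture()
  p <- pileup_profile(fx$bam, "chr1", 5001L, 6000L)
  # duplicates are invisible: recount including them differs
  t2 <- fx$truth
  t2$dup <- FALSE
  o_with_dups <- oracle_profile(t2, 5001L, 6000L)
  expect_true(any(o_with_dups$COV > p$COV))
  # mean usable depth near the declared 30x
  expect_lt(abs(mean(p$COV) - 30), 3)
})

test_that("an empty region yields zero coverage and undefined medians", {
  fx <- cov_fixture()
  p <- pileup_profile(fx$bam, "chr1", 15001L, 15100L)
  expect_true(all(p$COV == 0L))
  expect_true(all(is.na(p$MEDBQ)) && all(is.na(p$MEDMQ)))
  expect_error(pileup_profile(fx$bam, "chrZ", 1, 10), "contig")
})

test_that("profiles of adjacent regions concatenate to the unsplit profile", {
  fx <- cov_fixture()
  whole <- pileup_profile(fx$bam, "chr1", 5001L, 6000L)
  left <- pileup_profile(fx$bam, "chr1", 5001L, 5400L)
  right <- pileup_profile(fx$bam, "chr1", 5401L, 6000L)
  for (m in c("COV", "QCOV", "MEDBQ", "FLBQ", "MEDMQ", "FLMQ"))
    expect_equal(c(left[[m]], right[[m]]), whole[[m]], info = m)
})

test_that("failing subregions are the maximal runs below threshold", {
  mk_prof <- function(qcov) {
    structure(list(chrom = "chr1", start = 101L,
                   end = 100L + length(qcov), QCOV = qcov,
                   COV = qcov, MEDBQ = NA, FLBQ = NA, MEDMQ = NA,
                   FLMQ = NA), class = "region_profile")
  }
  expect_identical(nrow(failed_subregions(mk_prof(rep(20L, 10)), 15L)), 0L)
  all_fail <- failed_subregions(mk_prof(rep(3L, 10)), 15L)
  expect_identical(all_fail$start, 101L)
  expect_identical(all_fail$end, 110L)
  mid <- failed_subregions(mk_prof(c(20L, 14L, 14L, 20L)), 15L)
  expect_identical(mid$start, 102L)
  expect_identical(mid$end, 103L)

  # random masks match an RLE oracle
  set.seed(99)
  for (k in 1:20) {
    qcov <- sample(c(5L, 30L), 200L, replace = TRUE)
    got <- failed_subregions(mk_prof(qcov), 15L)
    r <- rle(qcov < 15L)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    expect_identical(got$start, 100L + s[r$values])
    expect_identical(got$end, 100L + e[r$values])
    # union of runs is exactly the failing bases
    mask <- logical(200L)
    for (i in seq_len(nrow(got)))
      mask[(got$start[i]:got$end[i]) - 100L] <- TRUE
    expect_identical(mask, qcov < 15L)
  }
})

test_that("region summaries pass exactly when no base fails (15x inclusive)", {
  mk_prof <- function(qcov) {
    structure(list(chrom = "chr1", start = 151L,
                   end = 150L + length(qcov), QCOV = qcov, COV = qcov,
                   MEDBQ = NA_real_, FLBQ = NA_real_, MEDMQ = NA_real_,
                   FLMQ = NA_real_), class = "region_profile")
  }
  s <- region_summary(mk_prof(rep(15L, 50)))
  expect_true(s$pass_flag)
  expect_identical(nrow(s$failed), 0L)
  s2 <- region_summary(mk_prof(c(rep(30L, 10), 14L, rep(30L, 10))))
  expect_false(s2$pass_flag)
  expect_identical(s2$failed$start, 161L)
  expect_identical(s2$failed$end, 161L)
  expect_identical(s2$min_qcov, 14L)
})

test_that("failing intervals get transcript-coordinate labels", {
  t <- toy_transcript("+")
  fails <- data.frame(chrom = c("chr1", "chr1"),
                      start = c(151L, 5000L), end = c(160L, 5100L),
                      stringsAsFactors = FALSE)
  ann <- annotate_failed_regions(fails, list(t))
  expect_identical(ann$csn, c("G:c.1-c.10", "."))
  # labels match endpoint-wise coordinate mapping across a splice boundary
  ann2 <- annotate_failed_regions(
    data.frame(chrom = "chr1", start = 195L, end = 205L), list(t))
  ends <- genomic_to_csn(t, c(195L, 205L))$csn
  expect_identical(ann2$csn, sprintf("G:%s-%s", ends[1L], ends[2L]))
})

test_that("coverage reports round-trip the summary fields", {
  fx <- cov_fixture()
  p <- pileup_profile(fx$bam, "chr1", 5001L, 6000L)
  s <- region_summary(p, qcov_threshold = 15L)
  out <- file.path(fx$dir, "report")
  files <- write_coverage_report(list(s), out, profiles = list(p))
  reg <- read.delim(paste0(out, "_regions.tsv"))
  expect_identical(nrow(reg), 1L)
  expect_identical(reg$MIN_QCOV, min(p$QCOV))
  expect_identical(reg$PASS, if (s$pass_flag) "PASS" else "FAIL")
  prof <- read.delim(paste0(out, "_profiles.tsv"))
  expect_identical(nrow(prof), 1000L)
  expect_identical(prof$COV, p$COV)
  fl <- read.delim(paste0(out, "_failed.tsv"))
  expect_identical(nrow(fl), nrow(s$failed))
})
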