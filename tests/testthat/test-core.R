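test_that("interaction tables convert the 1-based dialect and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom1\tstart1\tend1\tstrand1\tchrom2\tstart2\tend2\tstrand2\tscore",
    "chr1\t101\t150\t+\tchr2\t501\t540\t-\t2.5"
  ), path)
  rec <- read_interactions(path, "repA")
  expect_equal(rec$start1, 100L)
  expect_equal(rec$end1, 150L)
  expect_equal(rec$start2, 500L)
  expect_equal(rec$end2, 540L)
  expect_equal(rec$strand2, "-")
  expect_equal(rec$score, 2.5)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(rec, out)
  again <- read_interactions(out, "repA")
  expect_equal(as.data.frame(again), as.data.frame(rec))
})

test_that("interaction parsing reports row-level and column-level errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom1\tstart1\tend1\tstrand1\tchrom2\tstart2\tend2\tstrand2\tscore",
             path)
  expect_equal(nrow(read_interactions(path, "r")), 0)

  writeLines(c(
    "chrom1\tstart1\tend1\tstrand1\tchrom2\tstart2\tend2\tstrand2\tscore",
    "chr1\t10\t20\t+\tchr1\t30\t40\t+\tNA"
  ), path)
  expect_error(read_interactions(path, "r"), "non-numeric score.*row 1")

  writeLines(c(
    "chrom1\tstart1\tend1\tstrand1\tchrom2\tstart2\tend2\tstrand2",
    "chr1\t10\t20\t+\tchr1\t30\t40\t+"
  ), path)
  expect_error(read_interactions(path, "r"), "missing required column: score")

  writeLines(c(
    "chrom1\tstart1\tend1\tstrand1\tchrom2\tstart2\tend2\tstrand2\tscore",
    "chr1\t30\t20\t+\tchr1\t30\t40\t+\t1"
  ), path)
  expect_error(read_interactions(path, "r"), "start1 > end1.*row 1")
})

test_that("BED parsing is pass-through 0-based with strand handling", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tx\t0\t+", "chr2\t5\t9\ty\t0\t."), path)
  bed <- read_bed(path)
  expect_equal(bed$start, c(10L, 5L))
  expect_equal(bed$end, c(20L, 9L))
  expect_equal(bed$strand, c("+", "*"))

  writeLines("chr1\t10\t20", path)
  expect_equal(read_bed(path)$strand, "*")

  writeLines("chr1\t20\t10", path)
  expect_error(read_bed(path), "invalid BED interval.*row 1")
  writeLines("chr1\t10\t20\tx\t0\t?", path)
  expect_error(read_bed(path), "unknown strand")
})

test_that("sequence extraction is RNA, strand-aware and bounds-checked", {
  g <- tiny_genome(c(chr1 = "ACGTACGT"))
  expect_equal(extract_sequence(g, interval_tbl("chr1", 0, 4, "+")), "ACGU")
  expect_equal(extract_sequence(g, interval_tbl("chr1", 0, 4, "-")), "ACGU")
  expect_equal(extract_sequence(g, interval_tbl("chr1", 1, 4, "-")), "ACG")
  expect_error(extract_sequence(g, interval_tbl("chr1", 6, 12, "+")),
               "out of bounds")
  expect_error(extract_sequence(g, interval_tbl("chrX", 0, 4, "+")),
               "unknown chromosome")
})

test_that("plus-strand sequence is the reverse complement of minus-strand", {
  set.seed(7)
  g <- sim_genome(1, 500, seed = 7)
  for (t in 1:20) {
    s <- sample(0:450, 1)
    iv_p <- interval_tbl("chr1", s, s + sample(5:40, 1), "+")
    iv_m <- iv_p
    iv_m$strand <- "-"
    fwd <- extract_sequence(g, iv_p)
    rev <- extract_sequence(g, iv_m)
    expect_equal(rriclass:::revcomp_rna(rev), fwd)
  }
})

test_that("context extension clips at bounds, records the core, is monotone", {
  cl <- c(chr1 = 10000L)
  w <- add_context(interval_tbl("chr1", 200, 250, "+"), 150, cl)
  expect_equal(c(w$start, w$end), c(50L, 400L))
  expect_equal(c(w$core_start, w$core_end), c(200L, 250L))

  w2 <- add_context(interval_tbl("chr1", 10, 60, "+"), 150, cl)
  expect_equal(c(w2$start, w2$end), c(0L, 210L))

  w3 <- add_context(interval_tbl("chr1", 200, 250, "-"), 0, cl)
  expect_equal(c(w3$start, w3$end), c(200L, 250L))

  widths <- vapply(c(0, 10, 50, 150, 500), function(ctx) {
    w <- add_context(interval_tbl("chr1", 200, 250, "+"), ctx, cl)
    w$end - w$start
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("overlap fraction is reciprocal-to-shorter and strand-aware", {
  expect_equal(overlap_fraction(interval_tbl("chr1", 0, 100),
                                interval_tbl("chr1", 70, 170)), 0.30)
  expect_equal(overlap_fraction(interval_tbl("chr1", 0, 10),
                                interval_tbl("chr1", 10, 20)), 0)
  expect_equal(overlap_fraction(interval_tbl("chr1", 5, 50),
                                interval_tbl("chr1", 5, 50)), 1)
  expect_equal(overlap_fraction(interval_tbl("chr1", 0, 100, "+"),
                                interval_tbl("chr1", 0, 100, "-")), 0)
  expect_equal(overlap_fraction(interval_tbl("chr1", 0, 100, "*"),
                                interval_tbl("chr1", 0, 100, "-")), 1)
})
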