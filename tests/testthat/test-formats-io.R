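# File-format boundaries: coordinate conventions, dialect rules, round trips.

test_that("read_gtf converts 1-based inclusive to 0-based half-open and validates", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  ), gtf)
  ex <- read_gtf(gtf)
  expect_equal(ex$start, c(100L, 300L))
  expect_equal(ex$end, c(200L, 400L))
  expect_equal(ex$gene_id, c("g1", "g1"))

  # overlapping exons within a transcript are rejected, naming the transcript
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "tbad";',
    'chr1\tx\texon\t150\t250\t.\t+\t.\tgene_id "g1"; transcript_id "tbad";'
  ), gtf)
  expect_error(read_gtf(gtf), "tbad")

  # malformed line is reported with its line number
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "garbage line"
  ), gtf)
  expect_error(read_gtf(gtf), "line 2")

  # unknown strand is a validation error
  writeLines('chr1\tx\texon\t101\t200\t.\t.\t.\tgene_id "g1"; transcript_id "t1";', gtf)
  expect_error(read_gtf(gtf), "strand")

  # empty annotation: empty table with a warning
  writeLines(character(0), gtf)
  expect_warning(ex0 <- read_gtf(gtf), "no features")
  expect_equal(nrow(ex0), 0)
})

test_that("GTF write/read round-trips coordinates exactly", {
  ex <- make_gene(list(t1 = c(0, 100, 200, 300), t2 = c(0, 300)), strand = "-")
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(ex, gtf)
  back <- read_gtf(gtf)
  ord <- function(d) {
    d <- d[order(d$transcript_id, d$start), c("chrom", "start", "end", "strand",
                                              "gene_id", "transcript_id")]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(back), ord(ex))
})

test_that("junction BED parsing follows the two-block overhang dialect", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t400\tJUNC1\t25\t+\t100\t400\t255,0,0\t2\t50,50\t0,250"
  ), bed)
  counts <- read_junction_bed(bed, "s1")
  expect_equal(names(counts), jx_key("chr1", 150, 350, "+"))
  expect_equal(as.vector(counts), 25)
  expect_equal(attr(counts, "sample_id"), "s1")

  # duplicate junctions sum
  writeLines(c(
    "chr1\t100\t400\tJ1\t10\t+\t100\t400\t255,0,0\t2\t50,50\t0,250",
    "chr1\t90\t410\tJ2\t5\t+\t90\t410\t255,0,0\t2\t60,60\t0,260"
  ), bed)
  counts <- read_junction_bed(bed, "s1")
  expect_equal(unname(counts[jx_key("chr1", 150, 350, "+")]), 15)

  # records with block count != 2 are skipped with a warning
  writeLines(c(
    "chr1\t100\t400\tJ1\t10\t+\t100\t400\t255,0,0\t3\t50,20,50\t0,100,250",
    "chr1\t100\t400\tJ2\t7\t+\t100\t400\t255,0,0\t2\t50,50\t0,250"
  ), bed)
  expect_warning(counts <- read_junction_bed(bed, "s1"), "block count")
  expect_equal(length(counts), 1L)
  expect_equal(as.vector(counts), 7)

  # unstranded junctions are rejected: alt5'/alt3' polarity needs strand
  writeLines("chr1\t100\t400\tJ1\t10\t.\t100\t400\t255,0,0\t2\t50,50\t0,250", bed)
  expect_error(read_junction_bed(bed, "s1"), "strand")
})

test_that("junction BED parsing is insensitive to line order and round-trips", {
  lines <- c(
    "chr1\t100\t400\tJ1\t10\t+\t100\t400\t255,0,0\t2\t50,50\t0,250",
    "chr1\t500\t900\tJ2\t4\t-\t500\t900\t255,0,0\t2\t50,50\t0,350",
    "chr2\t100\t400\tJ3\t8\t+\t100\t400\t255,0,0\t2\t50,50\t0,250"
  )
  bed <- tempfile(fileext = ".bed")
  writeLines(lines, bed)
  fwd <- read_junction_bed(bed, "s")
  writeLines(rev(lines), bed)
  rev_ <- read_junction_bed(bed, "s")
  expect_equal(fwd[sort(names(fwd))], rev_[sort(names(rev_))])

  out <- tempfile(fileext = ".bed")
  write_junction_bed(fwd, out)
  back <- read_junction_bed(out, "s")
  expect_equal(back[sort(names(back))], fwd[sort(names(fwd))])
})

test_that("results TSV round-trips losslessly including missing values and tiers", {
  res <- data.frame(
    event_id = c("e1", "e2"), gene_id = c("g1", "g2"),
    event_type = c("cassette", "retain_intron"), chrom = "chr1",
    start = c(10L, 50L), end = c(20L, 70L), strand = c("+", "-"),
    psi_a = c(0.123456789012345, NA), psi_b = c(0.9, 0),
    p_junction = c(1e-17, 0.5), p_coverage = c(0.02, NA),
    p_combined = c(3.3e-16, 0.5), p_adjusted = c(6.6e-16, 0.5),
    fold = c(7.31707317073171, Inf), breed_exclusive = c(FALSE, TRUE),
    tier = c("EXT", "NS"), stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".tsv")
  write_results_tsv(res, path)
  back <- read_results_tsv(path)
  expect_equal(back, res)

  # empty result set: header-only file
  write_results_tsv(res[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_results_tsv(path)), 0L)
})

test_that("coverage and term-map TSVs parse and deduplicate", {
  cov <- list(A1 = c(e1 = 10, g1 = 40), B1 = c(e1 = 3, g1 = 50))
  path <- tempfile(fileext = ".tsv")
  write_coverage_tsv(cov, path)
  back <- read_coverage_tsv(path)
  expect_equal(back$A1[["e1"]], 10)
  expect_equal(back$B1[["g1"]], 50)

  tm <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tterm_id\tterm_name\tnamespace",
               "g1\tT1\tfoo\tBP", "g2\tT1\tfoo\tBP",
               "g1\tT1\tfoo\tBP", "g3\tT2\tbar\tMF"), tm)
  map <- read_term_map(tm)
  expect_equal(nrow(map), 3L)
  expect_equal(length(unique(map$term_id)), 2L)
  writeLines("gene_id\tterm_id", tm)
  expect_error(read_term_map(tm), "missing columns")
})
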