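test_that("narrowPeak records map to peaks with summit and height", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c(
    "chr1\t100\t400\tp1\t0\t.\t8.0\t5.0\t4.0\t150",
    "chr1\t500\t900\tp2\t0\t.\t12\t-1\t-1\t-1",   # unknown summit -> midpoint
    "chr1\t950\t1050\tp1\t0\t.\t3\t-1\t-1\t10"    # duplicate name
  ), f)
  pk <- read_peaks(f, "narrowPeak")
  expect_equal(pk$name, c("p1", "p2", "p1.2"))
  expect_equal(pk$summit, c(250L, 700L, 960L))
  expect_equal(pk$height, c(8, 12, 3))
  expect_equal(pk$start, c(100L, 500L, 950L))
  expect_equal(pk$end, c(400L, 900L, 1050L))
})

test_that("bed_summit dialect takes height from score and summit at midpoint", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr2\t1000\t1300\tsite\t42\t+", f)
  pk <- read_peaks(f, "bed_summit")
  expect_equal(pk$height, 42)
  expect_equal(pk$summit, 1150L)
})

test_that("malformed peak files raise errors naming the line", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t400\tp1\t0\t.\t8\t1\t1\t150",
               "chr1\t100"), f)
  expect_error(read_peaks(f, "narrowPeak"), "line 2")
  writeLines("chr1\t100\t400\tp1\t0\t.\t8\t1\t1\t500", f)   # summit beyond end
  expect_error(read_peaks(f, "narrowPeak"), "summit")
  writeLines("chr1\t400\t100\tp1\t0\t.\t8\t1\t1\t10", f)
  expect_error(read_peaks(f, "narrowPeak"), "interval")
})

test_that("peaks round-trip through write_peaks/read_peaks exactly", {
  set.seed(11)
  start <- sort(sample.int(1e6, 50))
  pk <- make_peaks("chr3", start, start + 200,
                   summit = start + sample(0:199, 50, replace = TRUE),
                   height = round(runif(50, 1, 500), 3))
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  write_peaks(pk, f)
  back <- read_peaks(f, "narrowPeak")
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$summit, pk$summit)
  expect_equal(back$height, pk$height)
  expect_equal(back$name, pk$name)
})

test_that("refFlat strand conventions give the biological TSS", {
  f <- withr::local_tempfile(fileext = ".refFlat")
  writeLines(c(
    "GenePlus\tgp\tchr1\t+\t1000\t5000\t1000\t5000\t2\t1000,4000,\t1200,5000,",
    "GeneMinus\tgm\tchr1\t-\t1000\t5000\t1000\t5000\t2\t1000,4000,\t1200,5000,"
  ), f)
  g <- read_gene_models(f)
  expect_equal(g$tss, c(1000L, 4999L))
  expect_equal(g$tes, c(4999L, 1000L))
  expect_equal(g$exon_starts[[1]], c(1000L, 4000L))
  expect_equal(g$exon_ends[[2]], c(1200L, 5000L))
  expect_equal(lengths(g$exon_starts), c(2L, 2L))
})

test_that("exonCount mismatch is an error", {
  f <- withr::local_tempfile()
  writeLines("G\tg\tchr1\t+\t1000\t5000\t1000\t5000\t3\t1000,4000,\t1200,5000,", f)
  expect_error(read_gene_models(f), "exonCount")
})

test_that("wiggle and bedGraph parse to identical tracks (1-based vs 0-based)", {
  fw <- withr::local_tempfile(fileext = ".wig")
  fb <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("fixedStep chrom=chr1 start=101 step=1", "5", "5", "5"), fw)
  writeLines("chr1\t100\t103\t5", fb)
  tw <- read_coverage(fw, "wiggle")
  tb <- read_coverage(fb, "bedGraph")
  # value 5 at 0-based positions 100-102 in both
  expect_equal(count_in_window(tw, tibble::tibble(chrom = "chr1", start = 100, end = 103)), 15)
  expect_equal(count_in_window(tb, tibble::tibble(chrom = "chr1", start = 100, end = 103)), 15)
  expect_equal(count_in_window(tw, tibble::tibble(chrom = "chr1", start = 99, end = 101)), 5)
  set.seed(5)
  w <- tibble::tibble(chrom = "chr1", start = sample(0:110, 200, TRUE))
  w$end <- w$start + sample(1:20, 200, TRUE)
  expect_equal(count_in_window(tw, w), count_in_window(tb, w))
  # outside any declared region -> 0
  expect_equal(count_in_window(tw, tibble::tibble(chrom = "chr1", start = 5000, end = 5100)), 0)
  expect_equal(count_in_window(tw, tibble::tibble(chrom = "chrUn", start = 0, end = 50)), 0)
})

test_that("count_in_window sums per-base coverage and counts point reads", {
  fb <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t100\t200\t2", fb)
  t2 <- read_coverage(fb, "bedGraph")
  expect_equal(count_in_window(t2, tibble::tibble(chrom = "chr1", start = 100, end = 200)), 200)
  # point-read mode: 7 single-base reads inside the window
  tr <- make_track(c(100, 100, 110, 120, 130, 140, 199), len = 400)
  expect_equal(count_in_window(tr, tibble::tibble(chrom = "chr1", start = 100, end = 200)), 7)
})

test_that("negative coverage values are rejected", {
  fb <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t10\t-3", fb)
  expect_error(read_coverage(fb, "bedGraph"), "negative")
})

test_that("coverage tracks round-trip through write_coverage", {
  tr <- make_track(c(5, 5, 9, 300, 301, 301, 301), len = 500)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_coverage(tr, f)
  back <- read_coverage(f, "bedGraph", library_size = tr$library_size)
  w <- tibble::tibble(chrom = "chr1", start = seq(0, 490, 7))
  w$end <- w$start + 7
  expect_equal(count_in_window(back, w), count_in_window(tr, w))
})

test_that("duplicate-read filter keeps at most two reads per position+strand", {
  reads <- tibble::tibble(
    chrom = "chr1",
    pos = c(100, 100, 100, 100, 100, 100, 100, 200),
    strand = c("+", "+", "+", "+", "+", "-", "-", "+")
  )
  out <- deduplicate_reads(reads)
  expect_equal(sum(out$pos == 100 & out$strand == "+"), 2)   # 5 -> 2
  expect_equal(sum(out$pos == 100 & out$strand == "-"), 2)   # both kept
  expect_equal(sum(out$pos == 200), 1)
  expect_equal(nrow(deduplicate_reads(reads[0, ])), 0)
})

test_that("dedup rule holds on random read sets and preserves order", {
  set.seed(99)
  for (i in 1:20) {
    reads <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 300, TRUE),
      pos = sample(1:40, 300, TRUE),
      strand = sample(c("+", "-"), 300, TRUE)
    )
    out <- deduplicate_reads(reads, max_per_position = 2)
    key <- paste(out$chrom, out$pos, out$strand)
    expect_true(all(table(key) <= 2))
    # brute-force oracle: walk the rows, keep the first two per key
    key_in <- paste(reads$chrom, reads$pos, reads$strand)
    seen <- new.env(parent = emptyenv())
    keep <- logical(nrow(reads))
    for (j in seq_len(nrow(reads))) {
      k <- key_in[j]
      cnt <- get0(k, envir = seen, ifnotfound = 0L)
      keep[j] <- cnt < 2L
      assign(k, cnt + 1L, envir = seen)
    }
    expect_equal(out, reads[keep, ])
  }
})
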