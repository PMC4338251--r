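test_that("merging coalesces overlapping and book-ended intervals", {
  x <- interval_set(c("chr1", "chr1"), c(100, 150), c(200, 300))
  m <- merge_intervals(x)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100, 300))

  # book-ended
  y <- interval_set(c("chr1", "chr1"), c(100, 200), c(200, 300))
  expect_equal(nrow(merge_intervals(y)), 1)

  # disjoint inputs preserved
  z <- interval_set(c("chr1", "chr2", "chr1"), c(10, 10, 500),
                    c(20, 20, 600))
  mz <- merge_intervals(z)
  expect_equal(nrow(mz), 3)
  expect_true(attr(mz, "merged"))
})

test_that("merge is idempotent and matches a per-base mask union", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 30
    start <- sample(0:9000, n)
    df <- data.frame(chrom = "chr1", start = start,
                     end = start + sample(50:800, n, replace = TRUE))
    x <- as_interval_set(df)
    m <- merge_intervals(x)
    expect_identical(as.data.frame(merge_intervals(m)), as.data.frame(m))
    oracle <- mask_union_oracle(df, 10000)
    expect_equal(m$start, oracle$start)
    expect_equal(m$end, oracle$end)
    expect_equal(sum(m$end - m$start), sum(oracle$end - oracle$start))
  }
})

test_that("BED round trips preserve 0-based half-open coordinates", {
  x <- interval_set(c("chr2", "chr1"), c(100, 5), c(200, 50),
                    name = c("b", "a"), score = c(0.5, 0.25))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path)
  expect_equal(y$start, x$start)
  expect_equal(y$end, x$end)
  expect_equal(y$end - y$start, c(100, 45))
  expect_false(attr(y, "sorted"))  # input order kept, flagged unsorted

  # single BED3 line: length is end - start
  writeLines("chr1\t100\t200", path)
  z <- read_bed(path)
  expect_equal(z$end - z$start, 100)

  # invalid coordinates rejected with a line number
  writeLines(c("chr1\t10\t20", "chr1\t30\t30"), path)
  expect_error(read_bed(path), "line 2")
})

test_that("genome_fraction refuses unmerged sets and sums covered bp", {
  genome <- data.frame(name = c("chr1", "chr2"), length = c(5e6, 5e6))
  one <- merge_intervals(interval_set("chr1", 0, 1e6))
  expect_equal(genome_fraction(one, genome), 0.1)
  expect_equal(genome_fraction(interval_set(), genome), 0)
  overlapping <- as_interval_set(
    data.frame(chrom = "chr1", start = c(0, 100), end = c(1000, 1100)))
  expect_error(genome_fraction(overlapping, genome), "merged")

  # complement partition sums to 1
  cover <- merge_intervals(interval_set(
    c("chr1", "chr1", "chr2"), c(0, 2e6, 1e6), c(1e6, 3e6, 5e6)))
  gaps <- merge_intervals(interval_set(
    c("chr1", "chr1", "chr2"), c(1e6, 3e6, 0), c(2e6, 5e6, 1e6)))
  expect_equal(genome_fraction(cover, genome) + genome_fraction(gaps, genome), 1)
})
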