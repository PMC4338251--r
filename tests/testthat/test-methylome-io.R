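test_that("methylome write -> read round trip is identity", {
  tr <- methylome(chrom = c("chr1", "chr1", "chr2"),
                  pos = c(10, 200, 5), level = c(0.25, NA, 1),
                  reads = c(8, 0, 12), sample_id = "s1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_methylome(tr, path)
  back <- read_methylome(path, sample_id = "s1")
  expect_equal(back$chrom, tr$chrom)
  expect_equal(back$pos, tr$pos)
  expect_equal(back$level, tr$level)
  expect_equal(back$reads, tr$reads)
  expect_identical(attr(back, "sample_id"), "s1")

  # gzip transparently
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_methylome(tr, gz)
  expect_equal(read_methylome(gz)$level, tr$level)
})

test_that("zero-coverage CpGs carry an undefined level, never 0", {
  tr <- methylome(chrom = "chr1", pos = c(1, 2), level = c(0.9, 0.3),
                  reads = c(10, 0))
  expect_true(is.na(tr$level[2]))
  expect_equal(weighted_mean_level(tr$level, tr$reads), 0.9)
})

test_that("malformed methylome lines are rejected with their line number", {
  path <- withr::local_tempfile()
  ok <- "chr1\t%d\t+\tCpG\t0.5\t10"
  lines <- sprintf(ok, seq(10, 60, 10) * 1:6)
  lines[4] <- "chr1\t999\t+\tCpG\t1.5\t10"  # level out of range
  writeLines(lines, path)
  expect_error(read_methylome(path), "line 4")

  lines[4] <- "chr1\t999\t+\tCpG\t0.5\t-3"  # negative coverage
  writeLines(lines, path)
  expect_error(read_methylome(path), "line 4")

  file.create(path)
  expect_warning(tr <- read_methylome(path), "empty")
  expect_equal(nrow(tr), 0)
})

test_that("browser track scores are level - 0.5, bounded in [-0.5, 0.5]", {
  tr <- methylome(chrom = "chr1", pos = c(0, 10, 20, 30),
                  level = c(0.5, 1, 0, 0.73), reads = c(5, 5, 5, 5))
  path <- withr::local_tempfile()
  out <- export_browser_track(tr, path)
  expect_equal(out$score, c(0, 0.5, -0.5, 0.23))
  expect_true(all(out$score >= -0.5 & out$score <= 0.5))
  # sign convention: > 0 means hypermethylated (level > 50%)
  expect_true(all((out$score > 0) == (tr$level > 0.5)))
})
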