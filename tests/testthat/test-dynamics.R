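test_that("matched widths sum overlapping HMR widths; no overlap is lost", {
  nb <- interval_set("chr1", c(0, 5000, 20000), c(1000, 6000, 21000))
  other <- interval_set("chr1", c(500, 4000), c(1500, 13000))
  ch <- match_widths(nb, other)
  expect_equal(ch$matched_width, c(1000, 9000, 0))
  expect_equal(ch$log2_fc[1], 0)
  expect_equal(ch$log2_fc[2], log2(9), tolerance = 1e-12)
  expect_equal(ch$category[3], "lost")

  # two split pieces are summed, not maxed
  nb2 <- interval_set("chr1", 0, 1000)
  pieces <- interval_set("chr1", c(0, 600), c(400, 1000))
  expect_equal(match_widths(nb2, pieces)$matched_width, 800)
})

test_that("width-change bins follow the 0.19 / 1 / 3 rule exactly", {
  lfc <- c(0, 0.1, 0.19, 0.5, -0.5, 1, -1, 2.9, 3, -3, 5, -5,
           0.18999, 0.99999, 2.99999)
  want <- c("unchanged", "unchanged", "+", "+", "-", "++", "--", "++",
            "+++", "---", "+++", "---", "unchanged", "+", "++")
  expect_equal(classify_width_change(lfc), want)
  expect_error(classify_width_change(Inf))

  # mirror symmetry: negating the fold change mirrors the category
  grid <- seq(-6, 6, by = 0.01)
  cat_pos <- classify_width_change(grid)
  cat_neg <- classify_width_change(-grid)
  expect_equal(chartr("+-", "-+", cat_pos), cat_neg)

  # ratio 9 (log2 = 3.17) is an extreme change, more than eightfold
  expect_equal(classify_width_change(log2(9)), "+++")
  expect_equal(classify_width_change(log2(2.5)), "++")
})

test_that("category histogram partitions the reference HMRs", {
  set.seed(9)
  n <- 50
  starts <- seq(0, by = 5000, length.out = n)
  nb <- interval_set("chr1", starts, starts + 1000)
  keep <- runif(n) < 0.8
  o_starts <- starts[keep] + round(runif(sum(keep), -500, 500))
  other <- merge_intervals(interval_set(
    "chr1", pmax(0, o_starts), o_starts + sample(200:8000, sum(keep), TRUE)))
  ch <- classify_width_changes(match_widths(nb, other))
  expect_equal(nrow(ch), n)
  expect_false(any(is.na(ch$category)))
  expect_equal(sum(table(ch$category)), n)
  expect_equal(sum(ch$category == "lost"), sum(ch$matched_width == 0))
})

test_that("CGI annotation is 1 bp-overlap with half-open boundaries", {
  cgis <- interval_set("chr1", 1000, 2000)
  ch <- match_widths(interval_set("chr1", c(0, 500, 1999), c(999, 1001, 3000)),
                     interval_set("chr1", 0, 1))
  ch <- annotate_cgi(ch, cgis)
  expect_equal(ch$has_cgi, c(FALSE, TRUE, TRUE))
  # brute-force check on random toys
  set.seed(2)
  s <- sample(0:9000, 40)
  hm <- interval_set("chr1", s, s + sample(50:500, 40, TRUE))
  cs <- sample(0:9000, 15)
  cg <- merge_intervals(interval_set("chr1", cs, cs + 300))
  got <- annotate_cgi(match_widths(hm, hm), cg)$has_cgi
  for (i in seq_len(40)) {
    want <- any(hm$start[i] < cg$end & hm$end[i] > cg$start)
    expect_identical(got[i], want)
  }
})
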