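test_that("differential methylation is a - b at shared assessable sites", {
  a <- flat_track(c(0, 10, 20, 30), c(0.8, 0.5, NA, 0.2),
                  reads = c(10, 10, 0, 10))
  b <- flat_track(c(0, 10, 40), c(0.3, 0.5, 0.9))
  dm <- differential_methylation(a, b)
  expect_equal(dm$delta, c(0.5, 0))
  expect_equal(attr(dm, "n_excluded"), 1 + 1)
  expect_true(all(dm$delta >= -1 & dm$delta <= 1))
  # identical tracks -> all zero
  expect_true(all(differential_methylation(a, a)$delta == 0))
  # disjoint tracks -> error
  expect_error(differential_methylation(a, flat_track(1000, 0.5)), "share")
})

test_that("promoter methylation is the weighted mean over TSS +/- 1 kb", {
  genes <- data.frame(id = c("g1", "g2"), chrom = "chr1",
                      tss = c(5000, 50000))
  pos <- seq(4000, 6000, by = 100)
  tr <- flat_track(pos, rep(0.1, length(pos)))
  pm <- promoter_methylation(tr, genes)
  expect_equal(unname(pm["g1"]), 0.1)
  expect_true(is.na(pm["g2"]))  # too few CpGs -> undefined

  # brute-force mean on an uneven toy
  tr2 <- flat_track(c(4500, 5100, 5900, 6001), c(0.2, 0.6, 1, 0),
                    reads = c(10, 30, 10, 99))
  pm2 <- promoter_methylation(tr2, genes[1, ], min_cpg = 1)
  expect_equal(unname(pm2), (0.2 * 10 + 0.6 * 30 + 1 * 10) / 50)
})

test_that("Cohen's d uses the (n-1)-weighted pooled SD and bins magnitudes", {
  r <- cohens_d(c(0.2, 0.4), c(0.6, 0.8))
  expect_equal(r$d, 0.4 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(r$magnitude, "large")

  same <- cohens_d(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$d, 0)
  expect_equal(same$magnitude, "negligible")

  # antisymmetry and affine invariance
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20, 0.4)
  expect_equal(cohens_d(a, b)$d, -cohens_d(b, a)$d)
  expect_equal(cohens_d(2 * a + 5, 2 * b + 5)$d, cohens_d(a, b)$d,
               tolerance = 1e-12)

  expect_true(cohens_d(rep(1, 3), rep(1, 3))$undefined)
})

test_that("CPM columns sum to one million", {
  set.seed(1)
  counts <- matrix(rpois(60, 50), 10, 6)
  expect_equal(colSums(cpm(counts)), rep(1e6, 6), tolerance = 1e-6)
})

test_that("the simple DE test is calibrated under the null and finds shifts", {
  set.seed(12)
  null_counts <- matrix(rnbinom(500 * 10, mu = 100, size = 10), 500, 10)
  rownames(null_counts) <- paste0("g", 1:500)
  de0 <- simple_de_test(null_counts, rep(c("a", "b"), each = 5))
  expect_lte(sum(de0$de_label != "no_de"), 0.05 * 500 + 5)

  shifted <- null_counts
  shifted[1:20, 6:10] <- matrix(rnbinom(20 * 5, mu = 1000, size = 10), 20)
  de1 <- simple_de_test(shifted, rep(c("a", "b"), each = 5))
  expect_gte(mean(de1$de_label[1:20] == "over"), 0.9)

  # identical groups -> all no_de
  dup <- cbind(null_counts[, 1:5], null_counts[, 1:5])
  de2 <- simple_de_test(dup, rep(c("a", "b"), each = 5))
  expect_true(all(de2$de_label == "no_de"))
})

test_that("stratifying deltas by expression class partitions the genes", {
  dm <- c(a = 0.5, b = 0.4, c = -0.1, d = 0, e = 0.02, f = -0.3)
  lab <- c("under", "under", "over", "no_de", "no_de", "over")
  st <- stratify_dm_by_expression(dm, lab)
  expect_equal(sum(lengths(st$strata)), 6)
  expect_equal(unname(st$medians["under"]), 0.45)
  expect_equal(unname(st$median_diff), 0.45 - (-0.2))
  # label-independent deltas: median difference near zero
  set.seed(3)
  dm2 <- rnorm(300, 0, 0.1)
  lab2 <- sample(c("under", "over", "no_de"), 300, TRUE)
  st2 <- stratify_dm_by_expression(dm2, lab2)
  expect_lt(abs(st2$median_diff), 0.05)
})

test_that("feature methylation comparison matches the t closed form", {
  x <- c(0.30, 0.35, 0.28, 0.32); y <- c(0.80, 0.78, 0.82, 0.84)
  pos <- seq(0, 7999, by = 100)
  level <- rep(NA_real_, length(pos))
  feats <- interval_set("chr1", seq(0, 7000, by = 1000),
                        seq(0, 7000, by = 1000) + 500)
  lv <- c(x, y)
  for (i in seq_len(8)) {
    level[pos >= feats$start[i] & pos < feats$end[i]] <- lv[i]
  }
  tr <- flat_track(pos[!is.na(level)], level[!is.na(level)])
  part <- interval_set("chr1", 0, 4000)  # first 4 features overlap
  r <- compare_feature_methylation(tr, feats, part, student = TRUE)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(r$p, tt$p.value, tolerance = 1e-9)
  expect_lt(r$p, 0.01)
  expect_equal(r$mean_in, mean(x), tolerance = 1e-12)

  # identical groups -> p = 1
  lvl_same <- rep(0.5, length(pos))
  tr_same <- flat_track(pos, lvl_same)
  r2 <- compare_feature_methylation(tr_same, feats, part)
  expect_true(is.na(r2$t) || r2$p > 0.99)
})
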