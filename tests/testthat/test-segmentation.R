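test_that("weighted mean level is coverage-weighted and NA-safe", {
  expect_equal(weighted_mean_level(c(1, 0), c(10, 10)), 0.5)
  expect_equal(weighted_mean_level(0.6, 5), 0.6)
  expect_equal(weighted_mean_level(c(1, 0), c(30, 10)), 0.75)
  expect_true(is.na(weighted_mean_level(c(NA, NA), c(0, 0))))
  expect_equal(weighted_mean_level(c(0.2, NA), c(5, 0)), 0.2)
})

test_that("level categories use <0.2 / 0.2-0.8 / >0.8 with inclusive middle", {
  tr <- flat_track(c(0, 10, 20), c(0.1, 0.5, 0.9))
  expect_equal(unname(level_categories(tr)), c(1, 1, 1))
  tr2 <- flat_track(c(0, 10, 20, 30), c(0.2, 0.8, 0.19999, 0.80001))
  cats <- level_categories(tr2)
  expect_equal(unname(cats), c(1, 2, 1))
  # restriction to regions; empty region set gives zero counts
  regions <- interval_set("chr1", 5, 25)
  expect_equal(sum(level_categories(tr, regions)), 2)
  expect_equal(sum(level_categories(tr, interval_set())), 0)
})

test_that("window summaries tile the genome and measure density", {
  genome <- data.frame(name = "chr1", length = 1e6)
  pos <- seq(0, 1e6 - 1, by = 200)
  tr <- flat_track(pos, 0.8)
  ws <- window_summary(tr, genome, window_size = 1e4)
  expect_equal(nrow(ws), 100)
  expect_true(all(ws$end - ws$start == 1e4))
  expect_true(all(abs(ws$mean_level - 0.8) < 1e-12))
  expect_true(all(ws$cpg_density == 50 / 100))  # 50 CpGs / 100 hundred-bp
  # windows without CpGs flagged undefined
  tr2 <- flat_track(c(5, 100), c(0.5, 0.5))
  ws2 <- window_summary(tr2, genome, window_size = 1e4)
  expect_true(is.na(ws2$mean_level[2]))
})

test_that("a clean low block in high background is called as one exact HMR", {
  pos <- seq(0, 99) * 100  # 100 CpGs every 100 bp
  level <- rep(0.9, 100)
  level[41:60] <- 0.05  # 20-CpG block
  tr <- flat_track(pos, level)
  h <- call_hmrs(tr, min_separation = 0.2)
  expect_equal(nrow(h), 1)
  expect_equal(h$n_cpg, 20)
  expect_equal(h$start, pos[41])
  expect_equal(h$end, pos[60] + 2)
  expect_lt(h$mean_level, 0.1)
})

test_that("HMRs are never merged across a CpG desert wider than the gap limit", {
  low1 <- seq(0, 19) * 100          # ends at 1,900
  low2 <- 4000 + seq(0, 19) * 100   # desert 1,900 -> 4,000 (2,100 bp)
  bg <- 6000 + seq(1, 200) * 100
  tr <- flat_track(c(low1, low2, bg),
                   c(rep(0.05, 40), rep(0.9, 200)))
  h <- call_hmrs(tr, max_cpg_gap = 1000)
  expect_equal(nrow(h), 2)
  gaps_ok <- TRUE
  for (i in seq_len(nrow(h))) {
    inside <- tr$pos[tr$pos >= h$start[i] & tr$pos < h$end[i]]
    if (length(inside) > 1 && max(diff(inside)) > 1000) gaps_ok <- FALSE
  }
  expect_true(gaps_ok)
})

test_that("segmentation is deterministic and monotone in the block level", {
  g <- small_genome()
  sim <- generate_methylome(g, archetype_spec("normal"), seed = 21)
  h1 <- call_hmrs(sim$track)
  h2 <- call_hmrs(sim$track)
  expect_identical(as.data.frame(h1), as.data.frame(h2))

  # lowering a called HMR's level never removes it
  pos <- seq(0, 199) * 100
  level <- rep(0.85, 200)
  level[81:100] <- 0.25
  tr <- flat_track(pos, level)
  h_before <- call_hmrs(tr)
  expect_equal(nrow(h_before), 1)
  level[81:100] <- 0.02
  h_after <- call_hmrs(flat_track(pos, level))
  expect_gte(nrow(h_after), nrow(h_before))
  expect_true(any(h_after$start <= pos[81] & h_after$end >= pos[100]))
})

test_that("planted HMRs are recovered from noisy depth-19 tracks", {
  g <- small_genome()
  sim <- generate_methylome(g, archetype_spec("normal"), seed = 33)
  h <- call_hmrs(sim$track)
  truth <- as.data.frame(sim$truth$hmrs)
  low <- truth[truth$level <= 0.2, ]
  rec <- reciprocal_recovery(low, as.data.frame(h))
  expect_gte(rec$recall, 0.9)
  spurious <- mean(!overlaps_any(h, sim$truth$hmrs))
  expect_lte(spurious, 0.05)
})

test_that("a clean partially methylated block is recovered within 2 bins", {
  pos <- seq(0, 4e6, by = 250)
  level <- rep(0.8, length(pos))
  inside <- pos >= 1e6 & pos < 3e6
  level[inside] <- 0.45
  tr <- flat_track(pos, level)
  p <- call_pmds(tr)
  expect_equal(nrow(p), 1)
  expect_lte(abs(p$start - 1e6), 2000)
  expect_lte(abs(p$end - 3e6), 2000)
  expect_lt(abs(p$mean_level - 0.45), 0.02)

  # uniform fully methylated track: no PMDs
  p0 <- call_pmds(flat_track(pos, rep(0.85, length(pos))))
  expect_equal(nrow(p0), 0)
})

test_that("PMD genome fraction tracks the archetype: <1% normal, 25-35% cell line", {
  g <- small_genome()
  norm <- generate_methylome(g, archetype_spec("normal"), seed = 44)
  pn <- call_pmds(norm$track)
  fn <- if (nrow(pn)) genome_fraction(merge_intervals(pn), g) else 0
  expect_lt(fn, 0.01)

  cl <- generate_methylome(g, archetype_spec("cell_line"), seed = 44)
  pc <- call_pmds(cl$track)
  fc <- genome_fraction(merge_intervals(pc), g)
  expect_gte(fc, 0.25 * 0.9)
  expect_lte(fc, 0.35 * 1.1)
})
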