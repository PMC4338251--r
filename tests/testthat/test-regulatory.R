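test_that("feature-overlap counting is set-level, not element-level", {
  hmr <- interval_set("chr1", 1000, 2000)
  sets <- list(
    a = interval_set("chr1", c(900, 1100, 1500), c(1050, 1200, 1600)),
    b = interval_set("chr1", 5000, 6000),
    c = interval_set("chr1", 1999, 2100))
  expect_equal(count_feature_overlaps(hmr, sets), 2L)
  # five elements of one set still count once
  expect_equal(count_feature_overlaps(hmr, sets["a"]), 1L)

  # brute-force per-set check on random toys
  set.seed(17)
  hs <- sample(0:20000, 30)
  hmrs <- interval_set("chr1", hs, hs + 400)
  fsets <- lapply(1:5, function(i) {
    s <- sample(0:20000, 10)
    interval_set("chr1", s, s + sample(100:800, 10, TRUE))
  })
  got <- count_feature_overlaps(hmrs, fsets)
  for (i in 1:30) {
    want <- sum(vapply(fsets, function(fs) {
      any(hmrs$start[i] < fs$end & hmrs$end[i] > fs$start)
    }, logical(1)))
    expect_equal(got[i], want)
  }
})

test_that("regulatory potential is High at four or more features, monotone", {
  expect_equal(regulatory_potential(3), "Low")
  expect_equal(regulatory_potential(4), "High")
  expect_equal(regulatory_potential(8), "High")
  is_high <- regulatory_potential(0:8) == "High"
  expect_true(all(diff(is_high) >= 0))  # monotone in the count
})

test_that("top-quantile flags pick the top 20% with ties at the cut", {
  expect_equal(which(top_quantile_flags(1:10, 0.2)), c(9L, 10L))
  expect_true(all(top_quantile_flags(rep(3, 10), 0.2)))
  # exactly ceiling(q*n) flags for distinct scores
  set.seed(23)
  for (n in c(5, 8, 10, 37, 100)) {
    x <- sample(seq_len(1000), n)
    expect_equal(sum(top_quantile_flags(x, 0.2)), ceiling(0.2 * n))
  }
  expect_error(top_quantile_flags(1:3))
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # fully concentrated table: p = 2 / choose(20, 10)
  cl <- rep(c("k1", "k2"), each = 10)
  st <- c(rep(TRUE, 10), rep(FALSE, 10))
  res <- state_enrichment(cl, st)
  r1 <- res[res$cluster == "k1", ]
  expect_equal(r1$p_value, 2 / choose(20, 10), tolerance = 1e-9)
  expect_true(is.infinite(r1$odds_ratio) || r1$odds_ratio > 100)

  # balanced table: OR 1, p 1
  cl2 <- rep(c("k1", "k2"), each = 10)
  st2 <- rep(c(TRUE, FALSE), 10)
  res2 <- state_enrichment(cl2, st2)
  expect_equal(res2$p_value, c(1, 1))

  # enumeration oracle across tables with margins <= 30
  for (m in c(3, 7, 12)) {
    for (n in c(4, 9, 15)) {
      for (k in unique(pmin(m + n, c(2, 5, m, n)))) {
        for (a in max(0, k - n):min(k, m)) {
          got <- stats::fisher.test(matrix(c(a, m - a, k - a, n - k + a),
                                           2))$p.value
          expect_equal(got, fisher_oracle(a, m - a, k - a, n - k + a),
                       tolerance = 1e-9)
        }
      }
    }
  }

  # BH adjustment is never below the raw p
  expect_true(all(res$adjusted_p >= res$p_value - 1e-15))
})

test_that("two-proportion z-test matches the pooled closed form", {
  eq <- state_proportion_difference(50, 100, 50, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  r <- state_proportion_difference(900, 1000, 100, 1000)
  pool <- 0.5
  z_hand <- (0.9 - 0.1) / sqrt(pool * (1 - pool) * (2 / 1000))
  expect_equal(r$z, z_hand, tolerance = 1e-9)
  expect_lt(r$p, 1e-50)

  swap <- state_proportion_difference(100, 1000, 900, 1000)
  expect_equal(swap$z, -r$z)

  degenerate <- state_proportion_difference(0, 10, 0, 10)
  expect_true(degenerate$undefined)
})
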