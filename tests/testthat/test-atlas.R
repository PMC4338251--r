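test_that("reference merging matches the mergeBed semantics", {
  a <- interval_set("chr1", 100, 200)
  b <- interval_set("chr1", 150, 300)
  m <- merge_hmr_sets(list(a, b))
  expect_equal(as.data.frame(m)[, c("start", "end")],
               data.frame(start = 100, end = 300))
  # disjoint inputs: count preserved
  c2 <- interval_set(c("chr1", "chr2"), c(1000, 50), c(1200, 80))
  m2 <- merge_hmr_sets(list(a, c2))
  expect_equal(nrow(m2), 3)
})

test_that("score_reference equals per-interval brute force", {
  tr <- flat_track(c(10, 20, 30, 100, 110, 500),
                   c(1, 0, 0.5, 0.2, NA, 0.9),
                   reads = c(10, 10, 20, 5, 0, 7))
  ref <- interval_set("chr1", c(0, 90, 400, 600), c(50, 200, 520, 700))
  m <- score_reference(ref, list(tr), min_cpg = 1)
  expect_equal(unname(m[1, 1]), (1 * 10 + 0 * 10 + 0.5 * 20) / 40)
  expect_equal(unname(m[2, 1]), 0.2)   # the reads-0 CpG is excluded
  expect_equal(unname(m[3, 1]), 0.9)
  expect_true(is.na(m[4, 1]))  # no covered CpGs -> missing

  # brute-force oracle on a random toy
  set.seed(5)
  pos <- sort(sample(0:5000, 200))
  tr2 <- flat_track(pos, runif(200), reads = sample(1:30, 200, TRUE))
  starts <- seq(0, 4500, by = 500)
  ref2 <- interval_set("chr1", starts, starts + 400)
  m2 <- score_reference(ref2, list(tr2), min_cpg = 1)
  for (i in seq_along(starts)) {
    sel <- pos >= starts[i] & pos < starts[i] + 400
    want <- if (!any(sel)) NA_real_ else
      sum(tr2$level[sel] * tr2$reads[sel]) / sum(tr2$reads[sel])
    expect_equal(unname(m2[i, 1]), want, tolerance = 1e-12)
  }
})

test_that("location classification uses promoter > intragenic > intergenic", {
  genes <- data.frame(id = "g1", chrom = "chr1", strand = "+",
                      tss = 10000, start = 10000, end = 30000)
  # overlaps both the TSS window and the gene body -> promoter
  x <- interval_set("chr1", c(10500, 20000, 500000), c(11500, 21000, 501000))
  expect_equal(classify_location(x, genes),
               c("promoter", "intragenic", "intergenic"))
  # gene-free chromosome -> intergenic
  y <- interval_set("chr9", 100, 200)
  expect_equal(classify_location(y, genes), "intergenic")
})

test_that("Gower dissimilarity: formula, bounds, and brute-force agreement", {
  m <- rbind(c(0, 0.5, 1), c(1, 0.5, 0))
  d <- gower_dissimilarity(m, ranges = c(1, 1, 1))
  expect_equal(d[1, 2], 2 / 3)
  expect_equal(diag(d), c(0, 0))

  m2 <- rbind(c(0.3, 0.7), c(0.3, 0.7), c(0.9, 0.1))
  d2 <- gower_dissimilarity(m2)
  expect_equal(d2[1, 2], 0)

  set.seed(11)
  m3 <- matrix(runif(700), 100, 7)
  m3[sample(700, 40)] <- NA
  d3 <- gower_dissimilarity(m3)
  expect_equal(d3, gower_oracle(m3), tolerance = 1e-12)
  expect_true(all(d3[!is.na(d3)] >= 0 & d3[!is.na(d3)] <= 1))
  expect_identical(d3, t(d3))

  # independent library cross-check (range-scaled manhattan = Gower here)
  skip_if_not_installed("cluster")
  dd <- as.matrix(cluster::daisy(as.data.frame(m3), metric = "gower"))
  dimnames(dd) <- NULL
  expect_equal(unname(d3), dd, tolerance = 1e-10)

  expect_error(gower_dissimilarity(rbind(c(1, 1), c(1, 1))), "degenerate")
})

test_that("Ward clustering recovers separated groups and handles edge k", {
  set.seed(3)
  m <- rbind(matrix(rnorm(50, 0, 0.05), 10, 5),
             matrix(rnorm(50, 1, 0.05), 10, 5))
  d <- gower_dissimilarity(m)
  lab <- ward_cluster(d, 2)
  expect_equal(mclust::adjustedRandIndex(lab, rep(1:2, each = 10)), 1)
  expect_equal(sort(unique(ward_cluster(d, nrow(m)))), 1:20)
  expect_error(ward_cluster(d, 21), "exceeds")
})

test_that("the full atlas finds 8 clusters per location class", {
  g <- small_genome()
  samples <- c(NB = "normal", BT089 = "benign", BT126 = "invasive",
               BT198 = "invasive", HMEC = "cell_line", MCF7 = "cell_line",
               HCC1954 = "cell_line")
  sims <- lapply(seq_along(samples), function(i) {
    generate_methylome(g, archetype_spec(samples[[i]]), seed = 300 + i,
                       sample_id = names(samples)[i])
  })
  tracks <- lapply(sims, `[[`, "track")
  hmrs <- lapply(tracks, call_hmrs)
  atlas <- build_atlas(hmrs, tracks, g$genes, k = 8)
  expect_s3_class(atlas$intervals, "interval_set")
  expect_equal(nrow(atlas$matrix), nrow(atlas$intervals))
  expect_length(atlas$cluster, nrow(atlas$matrix))
  tab <- table(substr(atlas$cluster, 1, 1))
  expect_setequal(names(tab), c("A", "B", "C"))
  for (letter in c("A", "B", "C")) {
    ks <- unique(atlas$cluster[substr(atlas$cluster, 1, 1) == letter])
    expect_lte(length(ks), 8)
    expect_gte(length(ks), 2)
  }
  # cluster 1 is the most hypomethylated within each class
  rm_mean <- rowMeans(atlas$matrix, na.rm = TRUE)
  a_means <- tapply(rm_mean[substr(atlas$cluster, 1, 1) == "A"],
                    atlas$cluster[substr(atlas$cluster, 1, 1) == "A"], mean)
  expect_equal(names(which.min(a_means)), "A-1")

  # permuting the sample order leaves row memberships unchanged
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  atlas_p <- build_atlas(hmrs[perm], tracks[perm], g$genes, k = 8)
  expect_equal(atlas_p$cluster, atlas$cluster)
})

test_that("a category with one shared profile collapses to one cluster", {
  m <- matrix(rep(c(0.1, 0.4, 0.9), each = 20), 20, 3)
  lab <- methatlas:::.cluster_category(m, k_eff = 1, max_rows = 100)
  expect_true(all(lab == 1))
})
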