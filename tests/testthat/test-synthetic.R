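test_that("genome generation is deterministic and validates its config", {
  cfg <- genome_config(chromosomes = data.frame(
    name = c("chr1", "chrX"), length = c(4e5, 4e5)), n_genes = 20,
    intragenic_sites = 6, intergenic_sites = 6)
  g1 <- generate_genome(cfg, seed = 1)
  g2 <- generate_genome(cfg, seed = 1)
  expect_identical(g1, g2)
  g3 <- generate_genome(cfg, seed = 2)
  expect_false(identical(g1$cpg_positions, g3$cpg_positions))

  expect_error(genome_config(chromosomes = data.frame(
    name = c("chr1", "chrX"), length = c(1e4, 4e5))), "invalid")
  expect_error(genome_config(chromosomes = data.frame(
    name = "chr1", length = 4e5)), "X-like")
})

test_that("zero-gene genomes still carry CpGs", {
  cfg <- genome_config(chromosomes = data.frame(
    name = c("chr1", "chrX"), length = c(3e5, 3e5)), n_genes = 0,
    intragenic_sites = 0, intergenic_sites = 0)
  g <- generate_genome(cfg, seed = 3)
  expect_equal(nrow(g$genes), 0)
  expect_gt(sum(lengths(g$cpg_positions)), 100)
})

test_that("CpG densities approximate their configured targets", {
  cfg <- genome_config(chromosomes = data.frame(
    name = c("chr1", "chrX"), length = c(2e6, 1e6)),
    n_genes = 60, background_density = 0.01, cgi_density = 0.10,
    desert_fraction = 0, intragenic_sites = 0, intergenic_sites = 0)
  g <- generate_genome(cfg, seed = 11)
  cgis <- as.data.frame(g$cgis)
  cgi_cpgs <- 0; cgi_bp <- sum(cgis$end - cgis$start)
  for (i in seq_len(nrow(cgis))) {
    pos <- g$cpg_positions[[cgis$chrom[i]]]
    cgi_cpgs <- cgi_cpgs + sum(pos >= cgis$start[i] & pos < cgis$end[i])
  }
  d_cgi <- cgi_cpgs / cgi_bp
  expect_lt(abs(d_cgi - 0.10) / 0.10, 0.2)
  total_bp <- sum(cfg$chromosomes$length)
  d_bg <- (sum(lengths(g$cpg_positions)) - cgi_cpgs) / (total_bp - cgi_bp)
  expect_lt(abs(d_bg - 0.01) / 0.01, 0.2)
  # every promoter has >= 5 CpGs
  for (i in seq_len(nrow(g$genes))) {
    pos <- g$cpg_positions[[g$genes$chrom[i]]]
    expect_gte(sum(pos >= g$genes$tss[i] - 1000 & pos < g$genes$tss[i] + 1000), 5)
  }
})

test_that("methylome noise model: depth, bounds, determinism, noiseless limit", {
  g <- small_genome()
  arch <- archetype_spec("normal")
  s1 <- generate_methylome(g, arch, seed = 5)
  s2 <- generate_methylome(g, arch, seed = 5)
  expect_identical(s1, s2)

  tr <- s1$track
  lv <- tr$level[!is.na(tr$level)]
  expect_true(all(lv >= 0 & lv <= 1))
  expect_true(all(tr$reads >= 0))
  expect_gt(nrow(tr), 1e4)
  expect_lt(abs(mean(tr$reads) - 19) / 19, 0.05)

  # planted truth sorted and disjoint per class
  th <- s1$truth$hmrs
  expect_true(attr(th, "sorted"))

  # noiseless limit: zero dispersion, infinite depth -> exact plant
  exact <- generate_methylome(
    g, archetype_spec("normal", dispersion = 0, mean_depth = Inf), seed = 5)
  site1 <- as.data.frame(exact$truth$hmrs)[1, ]
  sel <- exact$track$chrom == site1$chrom &
    exact$track$pos >= site1$start & exact$track$pos < site1$end
  expect_true(all(exact$track$level[sel] == site1$level))
  bg <- exact$track$chrom == site1$chrom & exact$track$pos >= site1$end
  bg_lv <- exact$track$level[bg]
  expect_true(any(bg_lv == s1$truth$background_level))
})

test_that("archetype PMD fractions: none in normal, 25-35% in cell lines", {
  g <- small_genome()
  norm <- generate_methylome(g, archetype_spec("normal"), seed = 8)
  expect_equal(nrow(norm$truth$pmds), 0)
  cl <- generate_methylome(g, archetype_spec("cell_line"), seed = 8)
  frac <- genome_fraction(cl$truth$pmds, g)
  expect_gte(frac, 0.25)
  expect_lte(frac, 0.35)
})

test_that("expression generator: no-link null, strong negative link, determinism", {
  g <- small_genome()
  genes <- rep(g$genes$id, length.out = 1000)
  set.seed(31)
  pm <- matrix(runif(length(genes) * 6, 0.05, 0.9), length(genes), 6,
               dimnames = list(genes, paste0("s", 1:6)))
  # slope 0: promoter delta and logFC uncorrelated
  e0 <- generate_expression(g, pm, link_spec(slope = 0), seed = 9)
  de <- simple_de_test(e0$counts, rep(c("a", "b"), each = 3))
  dm <- rowMeans(pm[, 4:6]) - rowMeans(pm[, 1:3])
  expect_lt(abs(cor(dm, de$logFC)), 0.1)

  # strong negative link among linked genes
  e1 <- generate_expression(g, pm, link_spec(slope = 6), seed = 9)
  expect_gt(sum(e1$linked), 5)
  de1 <- simple_de_test(e1$counts, rep(c("a", "b"), each = 3))
  r <- cor(dm[e1$linked], de1$logFC[e1$linked], method = "spearman")
  expect_lt(r, -0.5)

  expect_identical(generate_expression(g, pm, link_spec(), seed = 4)$counts,
                   generate_expression(g, pm, link_spec(), seed = 4)$counts)
})

test_that("paired cohort plants the exact affected count and shift", {
  g <- small_genome()
  spec <- cohort_spec(n_patients = 78, xci_loss_fraction = 36 / 78)
  co <- generate_paired_cohort(g, spec, seed = 13)
  expect_length(co$truth$affected_patients, 36)
  expect_true(all(co$meth_tumor >= 0 & co$meth_tumor <= 1))

  aff <- co$truth$affected_patients
  xg <- setdiff(co$x_genes, co$xist_gene_id)
  dm <- colMeans(co$meth_tumor[xg, aff] - co$meth_normal[xg, aff])
  expect_lt(abs(mean(dm) - (-0.3)), 0.02)

  # null cohort: deltas centred at 0
  co0 <- generate_paired_cohort(g, cohort_spec(xci_loss_fraction = 0),
                                seed = 14)
  expect_length(co0$truth$affected_patients, 0)
  d0 <- colMeans(co0$meth_tumor[xg, ] - co0$meth_normal[xg, ])
  expect_lt(abs(mean(d0)), 0.01)

  expect_error(cohort_spec(xci_loss_fraction = 1.2), "invalid")
  expect_error(cohort_spec(n_patients = 1), "invalid")
})
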