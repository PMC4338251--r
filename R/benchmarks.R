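#' Simulation studies of pipeline recovery performance
#'
#' Each `benchmark_*` function runs one self-contained simulation study
#' against planted truth and returns the recovery metrics. They define the
#' package's reference evaluation scenarios and are used by the test suite
#' and the reproduction script; the problem sizes are chosen to run on a
#' single desktop core in seconds to a couple of minutes.
#'
#' @name benchmarks
NULL

#' HMR recovery on a ~5 Mb chromosome with ~100 planted HMRs
#'
#' Simulates one 5 Mb chromosome (~25,000 CpGs at ~19x depth) whose planted
#' HMR sites all sit at level 0.05 in a 0.78 background, calls HMRs, and
#' scores recovery at reciprocal overlap >= 0.8.
#'
#' @param seed integer seed.
#' @return list: `recall`, `spurious_rate`, `gap_rule_ok` (no called HMR
#'   contains an internal CpG gap over 1 kb), `n_cpg`, `n_planted`,
#'   `n_called`.
#' @export
benchmark_hmr_recovery <- function(seed = 1) {
  cfg <- genome_config(
    chromosomes = data.frame(name = c("chr1", "chrX"),
                             length = c(5e6, 5e5)),
    n_genes = 54, intragenic_sites = 24, intergenic_sites = 24,
    background_density = 0.0027, desert_fraction = 0)
  genome <- generate_genome(cfg, seed = derive_seed(seed, "genome"))
  flat <- stats::setNames(rep(0.05, 24),
                          rownames(default_cluster_profiles()))
  arch <- archetype_spec("normal", cluster_profiles = flat,
                         x_promoter_level = NULL)
  sim <- generate_methylome(genome, arch,
                            seed = derive_seed(seed, "methylome"))
  called <- call_hmrs(sim$track)
  truth <- as.data.frame(sim$truth$hmrs)

  rec <- .reciprocal_matches(truth, as.data.frame(called), 0.8)
  spurious <- if (nrow(called)) {
    mean(!overlaps_any(called, sim$truth$hmrs))
  } else 0

  gap_ok <- TRUE
  tr <- sim$track[!is.na(sim$track$level), ]
  for (i in seq_len(nrow(called))) {
    inside <- tr$pos[tr$chrom == called$chrom[i] &
                       tr$pos >= called$start[i] & tr$pos < called$end[i]]
    if (length(inside) > 1 && max(diff(inside)) > 1000) gap_ok <- FALSE
  }
  list(recall = rec$recall, spurious_rate = spurious, gap_rule_ok = gap_ok,
       n_cpg = nrow(sim$track), n_planted = nrow(truth),
       n_called = nrow(called))
}

.reciprocal_matches <- function(truth, called, min_frac) {
  if (nrow(truth) == 0 || nrow(called) == 0) {
    return(list(recall = 0))
  }
  gt <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start + 1, truth$end))
  gc <- GenomicRanges::GRanges(called$chrom,
                               IRanges::IRanges(called$start + 1, called$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gt, gc))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(gt[qi], gc[si]))
  ok <- ov >= min_frac * GenomicRanges::width(gt[qi]) &
    ov >= min_frac * GenomicRanges::width(gc[si])
  list(recall = length(unique(qi[ok])) / length(gt))
}

#' PMD recovery: planted domains, archetype genome fractions
#'
#' Simulates a tumour-like track with 10 planted PMDs (level 0.45 in a 0.8
#' background) and scores boundary accuracy; then measures the called PMD
#' genome fraction of a normal and of a cell-line archetype on the same
#' genome.
#'
#' @param seed integer seed.
#' @return list: `max_boundary_error_bp` over the matched planted
#'   domains, `n_planted`, `n_recovered`, `fraction_normal`,
#'   `fraction_cell_line`.
#' @export
benchmark_pmd_recovery <- function(seed = 1) {
  cfg <- genome_config(desert_fraction = 0.45, desert_density = 0.006)
  genome <- generate_genome(cfg, seed = derive_seed(seed, "genome"))
  cand <- as.data.frame(genome$pmd_candidates)
  stopifnot(nrow(cand) >= 10)
  planted <- sort_intervals(as_interval_set(
    cand[seq_len(10), c("chrom", "start", "end")]))

  tumor <- archetype_spec("invasive", background_level = 0.8,
                          pmd_level = 0.45, pmd_blocks = planted)
  sim <- generate_methylome(genome, tumor,
                            seed = derive_seed(seed, "methylome"))
  called <- call_pmds(sim$track)

  errs <- rep(Inf, nrow(planted))
  for (i in seq_len(nrow(planted))) {
    cand_rows <- which(called$chrom == planted$chrom[i] &
                         called$end > planted$start[i] &
                         called$start < planted$end[i])
    if (length(cand_rows)) {
      errs[i] <- min(pmax(abs(called$start[cand_rows] - planted$start[i]),
                          abs(called$end[cand_rows] - planted$end[i])))
    }
  }

  norm <- generate_methylome(genome, archetype_spec("normal"),
                             seed = derive_seed(seed, "methylome") + 1)
  pn <- call_pmds(norm$track)
  fn <- if (nrow(pn)) genome_fraction(merge_intervals(pn), genome) else 0
  cl <- generate_methylome(genome, archetype_spec("cell_line"),
                           seed = derive_seed(seed, "methylome") + 2)
  pc <- call_pmds(cl$track)
  fc <- if (nrow(pc)) genome_fraction(merge_intervals(pc), genome) else 0

  list(max_boundary_error_bp = max(errs), n_planted = nrow(planted),
       n_recovered = sum(is.finite(errs)), fraction_normal = fn,
       fraction_cell_line = fc)
}

#' Atlas clustering recovery across seeds
#'
#' Draws 2,400 reference HMRs (24 planted archetypes x `n_per_cluster`)
#' across the 7 default samples, clusters each location class with
#' Gower + Ward at k = 8, and reports the per-seed minimum (over the three
#' classes) adjusted Rand index against the planted labels.
#'
#' @param seeds integer vector of seeds.
#' @param n_per_cluster reference HMRs per archetype.
#' @return numeric vector of per-seed minimum ARI values.
#' @export
benchmark_atlas_clustering <- function(seeds = 1:20, n_per_cluster = 100) {
  vapply(seeds, function(s) {
    sim <- simulate_atlas_matrix(n_per_cluster = n_per_cluster, seed = s)
    min(vapply(c("A", "B", "C"), function(cat) {
      idx <- sim$category == cat
      d <- gower_dissimilarity(sim$matrix[idx, , drop = FALSE])
      lab <- ward_cluster(d, 8)
      mclust::adjustedRandIndex(lab, sim$cluster[idx])
    }, 0))
  }, 0)
}

#' Effect-size estimation accuracy
#'
#' Two unit-variance Gaussian groups shifted by 0.5 at n = 1,000 each;
#' reports the fraction of replicates whose Cohen's d estimate lands in
#' \[0.4, 0.6\] and the mean estimate.
#'
#' @param n_rep replicates.
#' @param seed integer seed.
#' @return list: `fraction_in_band`, `mean_d`.
#' @export
benchmark_effect_size <- function(n_rep = 100, seed = 1) {
  with_seed(seed, {
    d <- vapply(seq_len(n_rep), function(i) {
      cohens_d(stats::rnorm(1000), stats::rnorm(1000, 0.5))$d
    }, 0)
    list(fraction_in_band = mean(d >= 0.4 & d <= 0.6), mean_d = mean(d))
  })
}

#' Methylation-expression asymmetry recovery
#'
#' For each seed, simulates six methylomes (three normal-like, three
#' tumour-like) on a small genome, an expression table with the
#' methylation-repressed promoter clusters, runs the two-group DE test and
#' stratifies the promoter methylation change (tumour - normal) by DE
#' label. Under the planted negative link the under-expressed stratum
#' should have the higher median methylation gain; with the link switched
#' off the difference should be centred at zero.
#'
#' @param seeds integer vector of seeds.
#' @param slope link slope (0 switches the link off).
#' @param label_all label every gene by the sign of its logFC instead of
#'   by the FDR call; used for the no-link null, where nothing reaches
#'   significance but the label-independent median difference should
#'   still be centred at zero.
#' @return data.frame per seed: `median_diff` (under - over), `n_under`,
#'   `n_over`.
#' @export
benchmark_expression_asymmetry <- function(seeds = 1:40, slope = 5,
                                           label_all = FALSE) {
  cfg <- genome_config(
    chromosomes = data.frame(name = c("chr1", "chrX"),
                             length = c(2.5e6, 1e6)),
    n_genes = 130, intragenic_sites = 0, intergenic_sites = 0,
    desert_fraction = 0)
  genome <- generate_genome(cfg, seed = 2024)
  # normals (NB, HMEC) vs cancer cell lines (MCF7, HCC1954), two replicate
  # methylomes each, so within-group methylation is homogeneous
  archetypes <- list(
    nb_1 = archetype_spec("normal"),
    nb_2 = archetype_spec("normal"),
    hmec_1 = archetype_spec("normal", profile_column = "HMEC"),
    hmec_2 = archetype_spec("normal", profile_column = "HMEC"),
    mcf7_1 = archetype_spec("cell_line", pmd_fraction = 0),
    mcf7_2 = archetype_spec("cell_line", pmd_fraction = 0),
    hcc_1 = archetype_spec("cell_line", pmd_fraction = 0,
                           profile_column = "HCC1954"),
    hcc_2 = archetype_spec("cell_line", pmd_fraction = 0,
                           profile_column = "HCC1954"))
  groups <- rep(c("normal", "tumor"), each = 4)
  out <- lapply(seeds, function(s) {
    pm <- vapply(seq_along(archetypes), function(i) {
      sim <- generate_methylome(genome, archetypes[[i]],
                                seed = derive_seed(s, "methylome") + i)
      promoter_methylation(sim$track, genome$genes)
    }, numeric(nrow(genome$genes)))
    rownames(pm) <- genome$genes$id
    colnames(pm) <- names(archetypes)
    expr <- generate_expression(genome, pm, link_spec(slope = slope),
                                seed = derive_seed(s, "expression"))
    de <- simple_de_test(expr$counts, groups)
    labels <- if (label_all) {
      ifelse(de$logFC < 0, "under", "over")
    } else de$de_label
    dm <- rowMeans(pm[, groups == "tumor"], na.rm = TRUE) -
      rowMeans(pm[, groups == "normal"], na.rm = TRUE)
    st <- stratify_dm_by_expression(dm, labels)
    data.frame(seed = s, median_diff = unname(st$median_diff),
               n_under = length(st$strata$under),
               n_over = length(st$strata$over))
  })
  do.call(rbind, out)
}

#' XCI dysregulation recovery in a planted paired cohort
#'
#' Simulates the 78-patient paired cohort with 36 planted XCI-loss
#' patients (X-promoter shift -0.3, noise SD 0.05), classifies patients,
#' calls escapee-like genes, and repeats with a null (no-loss) cohort.
#'
#' @param seed integer seed.
#' @return list: `patient_accuracy`, `n_dysregulated`, `escapee_recall`,
#'   `escapee_false_rate`, `null_calls`, `xist_p`.
#' @export
benchmark_xci_recovery <- function(seed = 1) {
  cfg <- genome_config(
    chromosomes = data.frame(name = c("chr1", "chrX"),
                             length = c(1e6, 1.5e6)),
    n_genes = 90, intragenic_sites = 0, intergenic_sites = 0)
  genome <- generate_genome(cfg, seed = derive_seed(seed, "genome"))
  co <- generate_paired_cohort(genome, cohort_spec(),
                               seed = derive_seed(seed, "cohort"))
  calls <- classify_xci_status(x_promoter_deltas(co))
  truth_aff <- calls$patient %in% co$truth$affected_patients
  acc <- mean((calls$status == "xci_dysregulated") == truth_aff)
  esc <- call_escapee_like(co, calls)
  called <- esc$gene[esc$called]
  recall <- mean(co$truth$affected_genes %in% called)
  unaff <- setdiff(esc$gene, co$truth$affected_genes)
  false_rate <- if (length(unaff)) mean(unaff %in% called) else 0
  xt <- xist_group_test(co, calls)

  co0 <- generate_paired_cohort(genome, cohort_spec(xci_loss_fraction = 0),
                                seed = derive_seed(seed, "cohort") + 1)
  c0 <- classify_xci_status(x_promoter_deltas(co0))

  list(patient_accuracy = acc,
       n_dysregulated = sum(calls$status == "xci_dysregulated"),
       escapee_recall = recall, escapee_false_rate = false_rate,
       null_calls = sum(c0$status == "xci_dysregulated"), xist_p = xt$p)
}
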