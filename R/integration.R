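#' Differential methylation between two tracks at shared CpGs
#'
#' delta = level(a) - level(b) at every CpG assessable in both tracks, so
#' positive values mark hypermethylation in `a` and negative values
#' hypomethylation; deltas lie in \[-1, 1\]. Sites missing on either side
#' are excluded and counted.
#'
#' @param track_a,track_b `methylome`s on the same genome.
#' @return data.frame `chrom`, `pos`, `delta`; the number of excluded
#'   sites in attribute `n_excluded`.
#' @export
differential_methylation <- function(track_a, track_b) {
  a <- track_a[!is.na(track_a$level), c("chrom", "pos", "level")]
  b <- track_b[!is.na(track_b$level), c("chrom", "pos", "level")]
  mg <- merge(a, b, by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  if (nrow(mg) == 0) stop("tracks share no assessable CpG sites")
  mg <- mg[order(mg$chrom, mg$pos), , drop = FALSE]
  out <- data.frame(chrom = mg$chrom, pos = mg$pos,
                    delta = mg$level_a - mg$level_b,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- (nrow(a) - nrow(mg)) + (nrow(b) - nrow(mg))
  out
}

#' Promoter methylation of genes (TSS +/- halfwidth)
#'
#' Coverage-weighted mean level over `[tss - halfwidth, tss + halfwidth)`;
#' `NA` when fewer than `min_cpg` assessable CpGs fall in the window.
#'
#' @param track a `methylome`.
#' @param genes gene data.frame with `id`, `chrom`, `tss`.
#' @param halfwidth promoter half-width in bp.
#' @param min_cpg minimum assessable CpGs.
#' @return named numeric vector along genes.
#' @export
promoter_methylation <- function(track, genes, halfwidth = 1000,
                                 min_cpg = 3) {
  prom <- interval_set(genes$chrom, pmax(0, genes$tss - halfwidth),
                       genes$tss + halfwidth)
  m <- score_reference(prom, list(track), min_cpg = min_cpg)
  stats::setNames(m[, 1], genes$id)
}

#' Cohen's d standardised mean difference
#'
#' d = (mean_b - mean_a) / pooled SD, the pooled variance weighted by
#' (n - 1). Magnitude bins at |d| = 0.2 / 0.5 / 0.8 (negligible, small,
#' medium, large). With the tumour-vs-normal convention, pass the normal
#' group as `a` and the tumour group as `b`, so positive d means
#' hypermethylated in tumours.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list: `d`, `n_a`, `n_b`, `magnitude`; `d` is `NA` (flagged)
#'   when the pooled variance is zero.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) {
    return(list(d = NA_real_, n_a = length(a), n_b = length(b),
                magnitude = NA_character_, undefined = TRUE))
  }
  d <- (mean(b) - mean(a)) / sqrt(sp2)
  mag <- c("negligible", "small", "medium", "large")[
    findInterval(abs(d), c(0.2, 0.5, 0.8)) + 1]
  list(d = d, n_a = length(a), n_b = length(b), magnitude = mag,
       undefined = FALSE)
}

#' Simple two-group differential expression on log-CPM
#'
#' A plumbing stand-in for a full count model: Welch's t-test per gene on
#' log2(CPM + 0.5), Benjamini-Hochberg FDR, and labels `under` / `over`
#' (by sign of the group-b minus group-a log-CPM difference at
#' FDR <= `fdr_cutoff`) or `no_de`. Genes with degenerate variance in both
#' groups are labelled `no_de` and flagged. Externally supplied DE labels
#' can be used instead wherever a `de_label` vector is accepted.
#'
#' @param counts genes x samples count matrix.
#' @param groups factor/vector with two levels along the columns; the
#'   first level is the reference (group a).
#' @param fdr_cutoff FDR threshold for calling DE.
#' @return data.frame: `gene`, `logFC` (b - a), `p`, `fdr`, `de_label`,
#'   `degenerate`.
#' @export
simple_de_test <- function(counts, groups, fdr_cutoff = 0.05) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  ga <- which(groups == levels(groups)[1])
  gb <- which(groups == levels(groups)[2])
  stopifnot(length(ga) >= 2, length(gb) >= 2)
  lc <- log2(cpm(counts) + 0.5)
  xa <- lc[, ga, drop = FALSE]; xb <- lc[, gb, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  na <- length(ga); nb <- length(gb)
  se2 <- va / na + vb / nb
  degenerate <- se2 <= 0
  tstat <- ifelse(degenerate, 0, (mb - ma) / sqrt(se2))
  df <- ifelse(degenerate, 1,
               se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1))))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  label <- rep("no_de", nrow(counts))
  label[fdr <= fdr_cutoff & mb > ma] <- "over"
  label[fdr <= fdr_cutoff & mb < ma] <- "under"
  label[degenerate] <- "no_de"
  data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
             logFC = mb - ma, p = p, fdr = fdr, de_label = label,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Stratify promoter differential methylation by expression class
#'
#' Splits per-gene promoter methylation deltas by DE label (under / over /
#' no_de), reports the stratum medians and a Wilcoxon rank-sum test
#' between the under- and over-expressed strata.
#'
#' @param promoter_dm named per-gene methylation delta.
#' @param de_label per-gene label (`under`, `over`, `no_de`).
#' @return list: `strata` (named list of delta vectors), `medians`,
#'   `median_diff` (under - over), `p_under_vs_over` (NA when a stratum
#'   is empty).
#' @export
stratify_dm_by_expression <- function(promoter_dm, de_label) {
  stopifnot(length(promoter_dm) == length(de_label))
  ok <- !is.na(promoter_dm)
  promoter_dm <- promoter_dm[ok]; de_label <- de_label[ok]
  strata <- split(promoter_dm, factor(de_label,
                                      levels = c("under", "no_de", "over")))
  medians <- vapply(strata, function(x) {
    if (length(x)) stats::median(x) else NA_real_
  }, 0)
  p <- NA_real_
  if (length(strata$under) >= 1 && length(strata$over) >= 1) {
    p <- stats::wilcox.test(strata$under, strata$over)$p.value
  }
  list(strata = strata, medians = medians,
       median_diff = medians["under"] - medians["over"],
       p_under_vs_over = p)
}

#' Compare feature methylation between partition-overlapping and other
#' features
#'
#' Each feature interval gets a mean methylation level (coverage-weighted,
#' averaged across tracks when several are given); features are split by
#' whether they overlap `partition_by` (e.g. fragile sites split by PMD
#' content), and the two groups are compared with an unpaired two-sided
#' t-test (Welch by default; `student = TRUE` pools the variance).
#'
#' @param tracks a `methylome` or list of them.
#' @param features feature `interval_set`.
#' @param partition_by `interval_set` defining the split.
#' @param student use the pooled-variance Student's t-test.
#' @param min_cpg minimum CpGs per feature level.
#' @return list: `levels` (per feature), `in_partition` (flag), group
#'   means, `t`, `p`; `untestable` when a group has < 2 features.
#' @export
compare_feature_methylation <- function(tracks, features, partition_by,
                                        student = FALSE, min_cpg = 1) {
  if (inherits(tracks, "methylome")) tracks <- list(tracks)
  m <- score_reference(features, tracks, min_cpg = min_cpg)
  lvl <- rowMeans(m, na.rm = TRUE)
  flag <- overlaps_any(features, partition_by)
  g1 <- lvl[flag & !is.na(lvl)]; g0 <- lvl[!flag & !is.na(lvl)]
  if (length(g1) < 2 || length(g0) < 2) {
    return(list(levels = lvl, in_partition = flag,
                mean_in = mean(g1), mean_out = mean(g0),
                t = NA_real_, p = NA_real_, untestable = TRUE))
  }
  if (stats::var(g1) + stats::var(g0) == 0) {
    # constant levels: identical groups are indistinguishable (p = 1)
    same <- isTRUE(all.equal(mean(g1), mean(g0)))
    return(list(levels = lvl, in_partition = flag,
                mean_in = mean(g1), mean_out = mean(g0),
                t = if (same) 0 else NA_real_,
                p = if (same) 1 else NA_real_, untestable = !same))
  }
  tt <- stats::t.test(g1, g0, var.equal = student)
  list(levels = lvl, in_partition = flag,
       mean_in = mean(g1), mean_out = mean(g0),
       t = unname(tt$statistic), p = tt$p.value, untestable = FALSE)
}
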