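#' Per-patient mean X-promoter methylation change
#'
#' For every patient, the mean over assessable X-gene promoters of
#' tumour - normal methylation. The XIST promoter is excluded: it moves
#' in the opposite direction to the rest of the X when inactivation is
#' lost.
#'
#' @param cohort a `paired_cohort`.
#' @param min_promoters patients with fewer assessable X promoters are
#'   excluded (reported in attribute `excluded`).
#' @return named numeric vector of per-patient deltas in \[-1, 1\].
#' @export
x_promoter_deltas <- function(cohort, min_promoters = 5) {
  xg <- setdiff(cohort$x_genes, cohort$xist_gene_id)
  dn <- cohort$meth_tumor[xg, , drop = FALSE] -
    cohort$meth_normal[xg, , drop = FALSE]
  n_ok <- colSums(!is.na(dn))
  deltas <- colMeans(dn, na.rm = TRUE)
  keep <- n_ok >= min_promoters
  out <- deltas[keep]
  attr(out, "excluded") <- names(deltas)[!keep]
  out
}

#' Classify patients into XCI-dysregulated vs XCI-normal
#'
#' Fits a one-dimensional two-component Gaussian mixture to the
#' per-patient deltas and assigns the lower-mean (hypomethylated)
#' component as `xci_dysregulated`. If the fitted component means are
#' closer than `min_separation` the populations are considered
#' unseparated and every patient is called `xci_normal`. A simple
#' threshold mode (`method = "threshold"`: dysregulated iff
#' delta < `threshold`) is available as a fallback.
#'
#' @param deltas named per-patient deltas from [x_promoter_deltas()].
#' @param min_separation minimum component-mean gap (default 0.1).
#' @param method `"mixture"` or `"threshold"`.
#' @param threshold cut for the threshold mode.
#' @return data.frame: `patient`, `mean_x_delta`, `status`.
#' @importFrom mclust Mclust mclustBIC
#' @export
classify_xci_status <- function(deltas, min_separation = 0.1,
                                method = c("mixture", "threshold"),
                                threshold = -0.1) {
  method <- match.arg(method)
  if (length(deltas) < 4) stop("need >= 4 patients to classify")
  status <- rep("xci_normal", length(deltas))
  if (method == "threshold") {
    status[deltas < threshold] <- "xci_dysregulated"
  } else {
    fit <- mclust::Mclust(as.numeric(deltas), G = 2,
                          modelNames = c("E", "V"), verbose = FALSE)
    if (!is.null(fit)) {
      mu <- fit$parameters$mean
      if (abs(diff(mu)) >= min_separation) {
        low_comp <- which.min(mu)
        status[fit$classification == low_comp] <- "xci_dysregulated"
      }
    }
  }
  data.frame(patient = names(deltas), mean_x_delta = as.numeric(deltas),
             status = status, stringsAsFactors = FALSE)
}

#' Compare tumour XIST expression between XCI groups
#'
#' Two-sided t-test (Welch by default) of tumour XIST expression,
#' dysregulated vs normal patients.
#'
#' @param cohort a `paired_cohort`.
#' @param calls output of [classify_xci_status()].
#' @param student pooled-variance Student's t-test instead of Welch.
#' @return list: `t`, `p`, `mean_dysregulated`, `mean_normal`;
#'   `untestable` when a group has < 2 patients.
#' @export
xist_group_test <- function(cohort, calls, student = FALSE) {
  xs <- cohort$expr_tumor[cohort$xist_gene_id, calls$patient]
  g1 <- xs[calls$status == "xci_dysregulated"]
  g0 <- xs[calls$status == "xci_normal"]
  if (length(g1) < 2 || length(g0) < 2) {
    return(list(t = NA_real_, p = NA_real_,
                mean_dysregulated = mean(g1), mean_normal = mean(g0),
                untestable = TRUE))
  }
  tt <- stats::t.test(g1, g0, var.equal = student)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_dysregulated = mean(g1), mean_normal = mean(g0),
       untestable = FALSE)
}

#' Call escapee-like X genes
#'
#' Per X-linked gene (XIST excluded), two between-group tests on the
#' tumour tissue: promoter methylation must be significantly LOWER in the
#' dysregulated group and expression significantly HIGHER, both at
#' p < `p_cutoff` (default 0.01). Only genes satisfying the conjunction
#' are called.
#'
#' @param cohort a `paired_cohort`.
#' @param calls output of [classify_xci_status()].
#' @param p_cutoff per-test p-value threshold.
#' @param student pooled-variance Student's t-tests instead of Welch.
#' @return data.frame per X gene: group methylation difference, the two
#'   p-values, and `called`.
#' @export
call_escapee_like <- function(cohort, calls, p_cutoff = 0.01,
                              student = FALSE) {
  g1 <- calls$patient[calls$status == "xci_dysregulated"]
  g0 <- calls$patient[calls$status == "xci_normal"]
  if (length(g1) < 2 || length(g0) < 2) {
    stop("both XCI groups need >= 2 patients")
  }
  xg <- setdiff(cohort$x_genes, cohort$xist_gene_id)
  res <- lapply(xg, function(g) {
    m1 <- cohort$meth_tumor[g, g1]; m0 <- cohort$meth_tumor[g, g0]
    e1 <- cohort$expr_tumor[g, g1]; e0 <- cohort$expr_tumor[g, g0]
    if (stats::var(m1) + stats::var(m0) == 0 ||
        stats::var(e1) + stats::var(e0) == 0) {
      return(data.frame(gene = g, delta_meth = mean(m1) - mean(m0),
                        delta_expr = mean(e1) - mean(e0),
                        p_meth = NA_real_, p_expr = NA_real_,
                        called = FALSE, skipped = TRUE))
    }
    pm <- stats::t.test(m1, m0, var.equal = student)$p.value
    pe <- stats::t.test(e1, e0, var.equal = student)$p.value
    data.frame(gene = g, delta_meth = mean(m1) - mean(m0),
               delta_expr = mean(e1) - mean(e0), p_meth = pm, p_expr = pe,
               called = mean(m1) < mean(m0) && mean(e1) > mean(e0) &&
                 pm < p_cutoff && pe < p_cutoff,
               skipped = FALSE)
  })
  do.call(rbind, res)
}

#' XCI signature in a female-vs-reference promoter scatter
#'
#' Compares X-promoter methylation of a female sample against a male-like
#' (or XCI-lost) reference. Promoters under XCI sit near 50% in the
#' female but near 0 in the reference (off-diagonal); promoters with
#' comparable levels sit on the diagonal.
#'
#' @param female,reference named per-promoter methylation levels sharing
#'   >= 20 X promoters.
#' @param mid_band female level band counted as allelic (default
#'   0.35-0.65).
#' @param low_cut reference level below which a promoter counts as
#'   unmethylated.
#' @param diag_tol |female - reference| tolerance for the diagonal.
#' @return list: `off_diagonal_fraction`, `diagonal_fraction`, `n`.
#' @export
male_pattern_similarity <- function(female, reference,
                                    mid_band = c(0.35, 0.65),
                                    low_cut = 0.2, diag_tol = 0.2) {
  shared <- intersect(names(female), names(reference))
  if (length(shared) < 20) stop("need >= 20 shared X promoters")
  f <- female[shared]; r <- reference[shared]
  ok <- !is.na(f) & !is.na(r)
  f <- f[ok]; r <- r[ok]
  off <- f >= mid_band[1] & f <= mid_band[2] & r < low_cut
  diag <- abs(f - r) <= diag_tol
  list(off_diagonal_fraction = mean(off),
       diagonal_fraction = mean(diag), n = length(f))
}
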