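#' Merge per-sample HMR sets into a reference set
#'
#' Union of all inputs as maximal disjoint intervals (the mergeBed
#' operation); overlapping and book-ended regions are coalesced.
#' Idempotent.
#'
#' @param per_sample_hmrs list of `interval_set`s.
#' @return merged `interval_set`.
#' @export
merge_hmr_sets <- function(per_sample_hmrs) {
  dfs <- lapply(per_sample_hmrs, function(x) {
    as.data.frame(x)[, c("chrom", "start", "end"), drop = FALSE]
  })
  merge_intervals(as_interval_set(do.call(rbind, dfs)))
}

#' Re-score a reference interval set against per-sample tracks
#'
#' Entry (i, j) is the coverage-weighted mean methylation of sample j's
#' CpGs inside reference interval i; `NA` when fewer than `min_cpg`
#' assessable CpGs fall inside.
#'
#' @param reference an `interval_set` (the merged reference HMRs).
#' @param tracks list of `methylome`s.
#' @param min_cpg minimum assessable CpGs per entry.
#' @return matrix, rows = reference intervals, columns = samples.
#' @export
score_reference <- function(reference, tracks, min_cpg = 1) {
  ids <- vapply(seq_along(tracks), function(i) {
    attr(tracks[[i]], "sample_id") %||% paste0("sample", i)
  }, "")
  m <- matrix(NA_real_, nrow(reference), length(tracks),
              dimnames = list(NULL, ids))
  if (nrow(reference) == 0) return(m)
  ref_gr <- as_granges(reference)
  for (j in seq_along(tracks)) {
    t <- tracks[[j]]
    ok <- !is.na(t$level) & t$reads > 0
    t <- t[ok, , drop = FALSE]
    if (nrow(t) == 0) next
    cpg_gr <- GenomicRanges::GRanges(t$chrom,
                                     IRanges::IRanges(t$pos + 1, t$pos + 1))
    hits <- GenomicRanges::findOverlaps(cpg_gr, ref_gr)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (length(qi) == 0) next
    num <- rowsum(t$level[qi] * t$reads[qi], si)
    den <- rowsum(t$reads[qi], si)
    cnt <- rowsum(rep(1, length(qi)), si)
    rows <- as.integer(rownames(num))
    val <- num[, 1] / den[, 1]
    val[cnt[, 1] < min_cpg] <- NA_real_
    m[rows, j] <- val
  }
  m
}

#' Classify intervals into promoter / intragenic / intergenic
#'
#' Priority: promoter (overlaps any TSS +/- `promoter_halfwidth` window) >
#' intragenic (overlaps any gene span) > intergenic.
#'
#' @param intervals an `interval_set`.
#' @param genes gene data.frame with `chrom`, `tss`, `start`, `end`.
#' @param promoter_halfwidth promoter half-width in bp (default 1 kb).
#' @return character vector along the intervals.
#' @export
classify_location <- function(intervals, genes, promoter_halfwidth = 1000) {
  n <- nrow(intervals)
  if (n == 0) return(character(0))
  out <- rep("intergenic", n)
  if (nrow(genes) > 0) {
    prom <- interval_set(genes$chrom,
                         pmax(0, genes$tss - promoter_halfwidth),
                         genes$tss + promoter_halfwidth)
    span <- interval_set(genes$chrom, genes$start, genes$end)
    out[overlaps_any(intervals, span)] <- "intragenic"
    out[overlaps_any(intervals, prom)] <- "promoter"
  }
  out
}

#' Gower dissimilarity between rows of a methylation matrix
#'
#' d(i, j) = mean over columns assessable in both rows of
#' |x_ic - x_jc| / range_c. Columns with zero range (or no data) are
#' dropped with a message; missing entries are excluded pairwise.
#' Row pairs sharing no assessable column get `NA`.
#'
#' @param m numeric matrix (rows = regions, columns = samples).
#' @param ranges optional per-column ranges; defaults to observed
#'   max - min.
#' @return symmetric dissimilarity matrix with zero diagonal, entries in
#'   \[0, 1\] (or NA).
#' @export
gower_dissimilarity <- function(m, ranges = NULL) {
  if (nrow(m) < 2) stop("need at least 2 rows")
  if (is.null(ranges)) {
    ranges <- apply(m, 2, function(x) {
      r <- suppressWarnings(diff(range(x, na.rm = TRUE)))
      if (!is.finite(r)) 0 else r
    })
  }
  keep <- ranges > 0
  if (!any(keep)) stop("all columns degenerate (zero range)")
  if (!all(keep)) {
    message("dropping ", sum(!keep), " zero-range column(s) from Gower")
  }
  m <- m[, keep, drop = FALSE]
  ranges <- ranges[keep]
  n <- nrow(m)
  acc <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (c in seq_len(ncol(m))) {
    x <- m[, c]
    ok <- !is.na(x)
    d <- abs(outer(x, x, "-")) / ranges[c]
    w <- outer(ok, ok, "&")
    d[!w] <- 0
    acc <- acc + d
    cnt <- cnt + w
  }
  out <- ifelse(cnt > 0, acc / cnt, NA_real_)
  diag(out) <- 0
  if (!is.null(rownames(m))) dimnames(out) <- list(rownames(m), rownames(m))
  out
}

#' Ward-linkage hierarchical clustering of a precomputed dissimilarity
#'
#' Agglomerative clustering with the Ward criterion (Lance-Williams
#' update, the classic `hclust` implementation the field uses on Gower
#' matrices) cut into exactly `k` groups. Deterministic: `hclust` breaks
#' ties by the lowest pair index.
#'
#' @param d dissimilarity matrix or `dist`.
#' @param k number of clusters, 1 <= k <= rows.
#' @param method linkage, default `"ward.D"`.
#' @return integer labels (1..k); the `hclust` tree in attribute `tree`.
#' @export
ward_cluster <- function(d, k, method = "ward.D") {
  dd <- stats::as.dist(d)
  n <- attr(dd, "Size")
  if (k > n) stop("k exceeds the number of rows")
  if (anyNA(dd)) stop("dissimilarity matrix contains NA; drop sparse rows first")
  if (k == n) {
    labels <- seq_len(n)
    return(labels)
  }
  tree <- stats::hclust(dd, method = method)
  labels <- stats::cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Build the clustered reference-HMR atlas
#'
#' The full pipeline behind the cluster map: merge per-sample HMRs into a
#' reference set, re-score every reference region in every sample,
#' classify each region as promoter / intragenic / intergenic, and cluster
#' each location class separately (Gower dissimilarity + Ward linkage,
#' `k` clusters per class). Cluster numbers are ordered by ascending mean
#' methylation, so "A-1" is the most hypomethylated promoter cluster.
#' Rows missing in more than half the samples are dropped (reported).
#'
#' @param per_sample_hmrs list of per-sample HMR `interval_set`s.
#' @param tracks list of `methylome`s (same genome).
#' @param genes gene model data.frame.
#' @param k clusters per location class (default 8).
#' @param min_cpg minimum CpGs for a matrix entry.
#' @param promoter_halfwidth promoter half-width (bp).
#' @param max_rows scaling cap: above it, the tree is built on an evenly
#'   spaced row subsample and remaining rows join their nearest cluster
#'   mean profile.
#' @return list of class `reference_hmr_set`: `intervals`, `matrix`,
#'   `location`, `cluster` (labels like "A-3"), `dropped` (row filter
#'   report).
#' @export
build_atlas <- function(per_sample_hmrs, tracks, genes, k = 8,
                        min_cpg = 3, promoter_halfwidth = 1000,
                        max_rows = 50000) {
  reference <- merge_hmr_sets(per_sample_hmrs)
  m <- score_reference(reference, tracks, min_cpg = min_cpg)
  location <- classify_location(reference, genes, promoter_halfwidth)

  n_missing <- rowSums(is.na(m))
  keep <- n_missing <= ncol(m) / 2
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " reference HMR(s) missing in more than half the ",
            "samples were dropped from clustering")
  }
  reference <- as_interval_set(as.data.frame(reference)[keep, , drop = FALSE])
  m <- m[keep, , drop = FALSE]
  location <- location[keep]
  rownames(m) <- sprintf("ref%06d", seq_len(nrow(m)))

  letter <- c(promoter = "A", intragenic = "B", intergenic = "C")
  cluster <- rep(NA_character_, nrow(m))
  for (cat in names(letter)) {
    idx <- which(location == cat)
    if (length(idx) == 0) next
    sub <- m[idx, , drop = FALSE]
    k_eff <- min(k, length(idx))
    n_profiles <- nrow(unique(round(sub, 6)))
    if (k_eff > n_profiles) k_eff <- n_profiles
    if (length(idx) < k) {
      warning("category ", cat, " has fewer rows than k; using k = ", k_eff)
    }
    labels <- .cluster_category(sub, k_eff, max_rows)
    # order clusters by ascending mean methylation across samples
    cl_mean <- tapply(rowMeans(sub, na.rm = TRUE), labels, mean)
    rank_of <- rank(cl_mean, ties.method = "first")
    cluster[idx] <- paste0(letter[cat], "-", rank_of[as.character(labels)])
  }
  structure(list(intervals = reference, matrix = m, location = location,
                 cluster = cluster, dropped = dropped, k = k),
            class = "reference_hmr_set")
}

.cluster_category <- function(sub, k_eff, max_rows) {
  if (k_eff <= 1) return(rep(1L, nrow(sub)))
  if (nrow(sub) <= max_rows) {
    d <- gower_dissimilarity(sub)
    if (anyNA(d)) {
      # pairs with no shared column: fall back to the overall mean distance
      d[is.na(d)] <- mean(d, na.rm = TRUE)
    }
    return(as.integer(ward_cluster(d, k_eff)))
  }
  # scaling guard: tree on an evenly spaced subsample, remaining rows join
  # the nearest cluster mean profile (range-normalised L1)
  sel <- unique(round(seq(1, nrow(sub), length.out = max_rows)))
  d <- gower_dissimilarity(sub[sel, , drop = FALSE])
  d[is.na(d)] <- mean(d, na.rm = TRUE)
  lab_sel <- as.integer(ward_cluster(d, k_eff))
  centers <- apply(sub[sel, , drop = FALSE], 2, function(x) {
    tapply(x, lab_sel, mean, na.rm = TRUE)
  })
  labels <- integer(nrow(sub))
  labels[sel] <- lab_sel
  rest <- setdiff(seq_len(nrow(sub)), sel)
  if (length(rest)) {
    rng <- apply(sub, 2, function(x) {
      r <- suppressWarnings(diff(range(x, na.rm = TRUE)))
      if (!is.finite(r) || r == 0) 1 else r
    })
    for (i in rest) {
      dd <- rowMeans(abs(sweep(centers, 2, as.numeric(sub[i, ]), "-")) /
                       rep(rng, each = nrow(centers)), na.rm = TRUE)
      labels[i] <- which.min(dd)
    }
  }
  labels
}
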