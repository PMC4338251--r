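#' Count distinct regulatory feature sets overlapped by each HMR
#'
#' Set-level counting: an HMR overlapping five elements of one feature
#' track still counts that track once. The default atlas uses eight
#' tracks, so counts run 0..8.
#'
#' @param hmrs an `interval_set`.
#' @param feature_sets named list of `interval_set`s.
#' @return integer vector along the HMRs.
#' @export
count_feature_overlaps <- function(hmrs, feature_sets) {
  n <- nrow(hmrs)
  acc <- integer(n)
  for (fs in feature_sets) {
    acc <- acc + as.integer(overlaps_any(hmrs, fs))
  }
  acc
}

#' Regulatory potential from a feature-overlap count
#'
#' `"High"` when the HMR intersects `threshold` (default 4) or more of the
#' feature sets, `"Low"` otherwise.
#'
#' @param count feature-set overlap counts.
#' @param threshold minimum count for High potential.
#' @return character vector `"Low"`/`"High"`.
#' @export
regulatory_potential <- function(count, threshold = 4) {
  ifelse(count >= threshold, "High", "Low")
}

#' Flag scores in the top quantile
#'
#' A score is flagged when it is at or above the (1 - q) quantile of the
#' score vector, so with q = 0.20 the top 20% are flagged. Ties at the cut
#' are all flagged (with all-equal scores, everything is flagged).
#'
#' @param scores numeric scores (>= 5 values).
#' @param q top fraction to flag.
#' @return logical vector along scores.
#' @export
top_quantile_flags <- function(scores, q = 0.20) {
  stopifnot(length(scores) >= 5)
  cut <- stats::quantile(scores, probs = 1 - q, na.rm = TRUE, names = FALSE)
  !is.na(scores) & scores >= cut
}

#' Cluster / chromatin-state enrichment by Fisher's exact test
#'
#' For every (cluster, state) pair, a 2x2 table of in-cluster vs not
#' against overlapping-the-state vs not, a two-sided Fisher's exact test,
#' and multiple-testing adjustment (Benjamini-Hochberg by default) across
#' all pairs.
#'
#' @param cluster per-HMR cluster label.
#' @param state_flags logical matrix (HMRs x states) or a single logical
#'   vector; column names name the states.
#' @param adjust p-adjustment method (see [stats::p.adjust()]).
#' @return data.frame with counts, odds ratio, p and adjusted p per pair;
#'   pairs with an empty margin are flagged `untestable`.
#' @export
state_enrichment <- function(cluster, state_flags, adjust = "BH") {
  if (is.vector(state_flags)) {
    state_flags <- matrix(state_flags, ncol = 1,
                          dimnames = list(NULL, "state"))
  }
  if (length(unique(cluster)) < 2) stop("need >= 2 clusters")
  res <- list()
  for (cl in sort(unique(cluster))) {
    for (st in colnames(state_flags)) {
      inc <- cluster == cl; ov <- state_flags[, st]
      a <- sum(inc & ov); b <- sum(inc & !ov)
      c_ <- sum(!inc & ov); d <- sum(!inc & !ov)
      untestable <- (a + b == 0) || (c_ + d == 0) ||
        (a + c_ == 0) || (b + d == 0)
      if (untestable) {
        or <- NA_real_; p <- NA_real_
      } else {
        ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
        or <- unname(ft$estimate); p <- ft$p.value
      }
      res[[length(res) + 1]] <- data.frame(
        cluster = cl, state = st, in_state = a, in_not = b,
        out_state = c_, out_not = d, odds_ratio = or, p_value = p,
        untestable = untestable, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = adjust)
  out
}

#' Two-proportion z-test with pooled variance
#'
#' @param x_a,n_a successes and total in group A.
#' @param x_b,n_b successes and total in group B.
#' @return list: `z`, `p` (two-sided), `prop_a`, `prop_b`; `z` is `NA`
#'   (flagged `undefined`) when the pooled proportion is 0 or 1.
#' @export
state_proportion_difference <- function(x_a, n_a, x_b, n_b) {
  stopifnot(n_a > 0, n_b > 0)
  pa <- x_a / n_a; pb <- x_b / n_b
  pool <- (x_a + x_b) / (n_a + n_b)
  if (pool <= 0 || pool >= 1) {
    return(list(z = NA_real_, p = NA_real_, prop_a = pa, prop_b = pb,
                undefined = TRUE))
  }
  se <- sqrt(pool * (1 - pool) * (1 / n_a + 1 / n_b))
  z <- (pa - pb) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), prop_a = pa, prop_b = pb,
       undefined = FALSE)
}
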