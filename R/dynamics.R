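#' Match reference-sample HMR widths against another sample's HMRs
#'
#' For each HMR of the reference (normal) sample, `matched_width` is the
#' total width of all other-sample HMRs overlapping it by >= 1 bp — summed,
#' not the maximum, so an HMR split into pieces has not "contracted" in
#' covered bases. Zero overlap marks the HMR as lost.
#'
#' @param nb_hmrs reference-sample HMR `interval_set`.
#' @param other_hmrs other-sample HMR `interval_set`.
#' @return data.frame: one row per reference HMR with `matched_width`,
#'   `log2_fc` (`-Inf` when lost) and `category` (`"lost"` or `NA`, to be
#'   filled by [classify_width_change()]).
#' @export
match_widths <- function(nb_hmrs, other_hmrs) {
  n <- nrow(nb_hmrs)
  out <- data.frame(chrom = nb_hmrs$chrom, start = nb_hmrs$start,
                    end = nb_hmrs$end,
                    nb_width = nb_hmrs$end - nb_hmrs$start,
                    matched_width = 0, stringsAsFactors = FALSE)
  if (n > 0 && nrow(other_hmrs) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges(nb_hmrs),
                                        as_granges(other_hmrs))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (length(qi)) {
      w <- other_hmrs$end[si] - other_hmrs$start[si]
      agg <- rowsum(w, qi)
      out$matched_width[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  out$log2_fc <- ifelse(out$matched_width > 0,
                        log2(out$matched_width / out$nb_width), -Inf)
  out$category <- ifelse(out$matched_width == 0, "lost", NA_character_)
  out
}

#' Classify an HMR width change by its log2 fold change
#'
#' Bin edges 0.19, 1 and 3 on |log2 fold change|: below 0.19 unchanged;
#' 0.19 up to 1 a small change (+/-); 1 up to 3 a large change (++/--);
#' 3 and above an extreme change (+++/---, i.e. more than eight times the
#' reference width). A boundary value lands in the higher-|change| bin.
#' The sign gives expansion (+) vs contraction (-).
#'
#' @param log2_fc finite log2(matched width / reference width).
#' @param bins the three |log2FC| bin edges.
#' @return character vector of categories: `"unchanged"`, `"+"`, `"++"`,
#'   `"+++"`, `"-"`, `"--"`, `"---"`.
#' @export
classify_width_change <- function(log2_fc, bins = c(0.19, 1, 3)) {
  stopifnot(all(is.finite(log2_fc)))
  a <- abs(log2_fc)
  depth <- findInterval(a, bins)  # 0..3, boundary -> higher bin
  sign_chr <- ifelse(log2_fc > 0, "+", "-")
  ifelse(depth == 0, "unchanged", strrep(sign_chr, depth))
}

#' Fill width-change categories on a matched-widths table
#'
#' @param changes output of [match_widths()].
#' @param bins passed to [classify_width_change()].
#' @return the table with `category` completed (lost rows untouched).
#' @export
classify_width_changes <- function(changes, bins = c(0.19, 1, 3)) {
  todo <- is.na(changes$category)
  changes$category[todo] <- classify_width_change(changes$log2_fc[todo],
                                                  bins)
  changes
}

#' Flag width-change rows whose reference HMR intersects a CpG island
#'
#' @param changes output of [match_widths()].
#' @param cgis CGI `interval_set`.
#' @return the table with a logical `has_cgi` column (>= 1 bp overlap).
#' @export
annotate_cgi <- function(changes, cgis) {
  iv <- as_interval_set(changes[, c("chrom", "start", "end")])
  changes$has_cgi <- overlaps_any(iv, cgis)
  changes
}
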