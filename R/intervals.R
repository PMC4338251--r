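#' BED-style genomic interval sets
#'
#' Intervals are kept as plain data frames with columns `chrom`, `start`,
#' `end` (0-based, half-open, the BED convention) plus optional `name` and
#' `score`. A set carries two logical attributes: `sorted` (rows ordered by
#' chrom then start) and `merged` (sorted and pairwise disjoint).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `start < end`.
#' @param name,score optional per-interval annotation columns.
#' @return A data.frame of class `interval_set`.
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), name = NULL, score = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval start must be < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  as_interval_set(df)
}

#' @rdname interval_set
#' @param df a data.frame with at least chrom/start/end columns.
#' @export
as_interval_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  attr(df, "sorted") <- is_sorted_intervals(df)
  attr(df, "merged") <- isTRUE(attr(df, "sorted")) && is_disjoint_intervals(df)
  df
}

is_sorted_intervals <- function(df) {
  if (nrow(df) < 2) return(TRUE)
  o <- order(df$chrom, df$start, df$end)
  identical(o, seq_len(nrow(df)))
}

is_disjoint_intervals <- function(df) {
  if (nrow(df) < 2) return(TRUE)
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  all(!same | df$start[-1] >= df$end[-nrow(df)])
}

#' Sort an interval set by (chrom, start, end)
#' @param x an `interval_set`.
#' @return the sorted set, `sorted` attribute TRUE.
#' @export
sort_intervals <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  as_interval_set(x)
}

# 0-based half-open -> GRanges (1-based closed) and back. All interval
# arithmetic goes through GenomicRanges; coordinates exposed to the user are
# always BED-convention.
as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

granges_to_intervals <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  as_interval_set(df)
}

#' Merge (union) an interval set into maximal disjoint intervals
#'
#' Overlapping or book-ended intervals are coalesced, as `mergeBed` does.
#' Idempotent: merging a merged set is a no-op.
#'
#' @param x an `interval_set`.
#' @return a merged `interval_set` (sorted, pairwise disjoint).
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0) return(as_interval_set(x[, c("chrom", "start", "end")]))
  gr <- GenomicRanges::reduce(as_granges(x))
  out <- granges_to_intervals(GenomicRanges::sort(gr))
  attr(out, "merged") <- TRUE
  out
}

#' Indices of intervals in `x` overlapping any interval in `y` by >= 1 bp
#' @param x,y interval sets.
#' @return logical vector along rows of `x`.
#' @export
overlaps_any <- function(x, y) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  # disjoint chromosome sets between x and y are expected, not a problem
  suppressWarnings(IRanges::overlapsAny(as_granges(x), as_granges(y)))
}

#' Read a BED3/BED6 file
#'
#' @param path path to a BED file (plain or gzipped).
#' @return an `interval_set`; extra columns `name`/`score` kept when present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(interval_set())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 3)) {
    stop("BED line ", which(ncol < 3)[1], ": fewer than 3 columns")
  }
  chrom <- vapply(parts, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    stop("BED line ", bad[1], ": invalid coordinates (need 0 <= start < end)")
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(ncol >= 4)) df$name <- vapply(parts, `[`, "", 4)
  if (all(ncol >= 5)) {
    df$score <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 5)))
  }
  as_interval_set(df)
}

#' Write an interval set as BED
#'
#' @param x an `interval_set`.
#' @param path output path; `.gz` suffix writes gzipped.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  if (!is.null(x$name)) cols <- c(cols, "name")
  if (!is.null(x$score)) {
    if (is.null(x$name)) x$name <- "."
    cols <- c("chrom", "start", "end", "name", "score")
  }
  df <- as.data.frame(x)[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fraction of the genome covered by a merged interval set
#'
#' Refuses unmerged sets: summing widths of overlapping intervals would
#' double-count bases.
#'
#' @param x a merged `interval_set`.
#' @param genome a `genome_annotation` or a data.frame with `name`,`length`.
#' @return covered bp / genome bp, in \[0, 1\].
#' @export
genome_fraction <- function(x, genome) {
  chroms <- genome_chromosomes(genome)
  if (nrow(x) == 0) return(0)
  if (!isTRUE(attr(x, "merged")) && !(is_sorted_intervals(x) && is_disjoint_intervals(x))) {
    stop("genome_fraction() needs a merged interval set; call merge_intervals() first")
  }
  sum(x$end - x$start) / sum(chroms$length)
}

genome_chromosomes <- function(genome) {
  if (inherits(genome, "genome_annotation")) return(genome$chromosomes)
  stopifnot(all(c("name", "length") %in% names(genome)))
  genome
}
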