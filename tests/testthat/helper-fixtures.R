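# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env()

# Small 3-chromosome genome (one X-like) used across module tests.
small_genome <- function() {
  if (is.null(.fixture_cache$genome)) {
    cfg <- genome_config(
      chromosomes = data.frame(name = c("chr1", "chr2", "chrX"),
                               length = c(1.2e6, 1e6, 1.2e6)),
      n_genes = 60, intragenic_sites = 24, intergenic_sites = 24)
    .fixture_cache$genome <- generate_genome(cfg, seed = 42)
  }
  .fixture_cache$genome
}

# Deterministic noiseless track: piecewise-constant levels at given CpGs.
flat_track <- function(pos, level, chrom = "chr1", reads = 20,
                       sample_id = "toy") {
  methylome(chrom = chrom, pos = pos, level = level,
            reads = rep_len(reads, length(pos)), sample_id = sample_id)
}

# Reciprocal-overlap recovery between two interval data.frames.
reciprocal_recovery <- function(truth, called, min_frac = 0.8) {
  if (nrow(truth) == 0 || nrow(called) == 0) {
    return(list(recall = 0, matched_called = integer()))
  }
  gt <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start + 1, truth$end))
  gc <- GenomicRanges::GRanges(called$chrom,
                               IRanges::IRanges(called$start + 1, called$end))
  hits <- GenomicRanges::findOverlaps(gt, gc)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(gt[qi], gc[si]))
  ok <- ov >= min_frac * GenomicRanges::width(gt[qi]) &
    ov >= min_frac * GenomicRanges::width(gc[si])
  list(recall = length(unique(qi[ok])) / length(gt),
       matched_called = unique(si[ok]))
}

# Scalar double-loop Gower oracle (independent of the vectorized path).
gower_oracle <- function(m) {
  ranges <- apply(m, 2, function(x) diff(range(x, na.rm = TRUE)))
  keep <- which(ranges > 0)
  n <- nrow(m)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0; cnt <- 0
      for (c in keep) {
        if (!is.na(m[i, c]) && !is.na(m[j, c])) {
          s <- s + abs(m[i, c] - m[j, c]) / ranges[c]
          cnt <- cnt + 1
        }
      }
      d[i, j] <- if (cnt > 0) s / cnt else NA_real_
    }
  }
  diag(d) <- 0
  d
}

# Per-base mask union oracle for interval merging on small coordinates.
mask_union_oracle <- function(df, max_bp) {
  mask <- rep(FALSE, max_bp)
  for (i in seq_len(nrow(df))) {
    mask[(df$start[i] + 1):df$end[i]] <- TRUE
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values] - 1, end = ends[r$values])
}

# Two-sided Fisher p by full hypergeometric enumeration (R's rule: sum the
# probabilities of tables at most as likely as the observed one).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(x, m, n, k)
  sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}
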