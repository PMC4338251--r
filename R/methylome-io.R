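#' Per-CpG methylome tracks
#'
#' A methylome track is a data.frame with one row per (symmetric) CpG:
#' `chrom`, `pos` (0-based bp), `strand`, `context`, `level` (methylated
#' fraction in \[0,1\], `NA` when `reads == 0`), `reads` (coverage). Rows are
#' sorted by (chrom, pos) with no duplicate positions. The methcounts-style
#' on-disk format is the same six columns, tab-delimited, no header.
#'
#' A CpG with zero reads has an undefined level: it is stored as `NA` and
#' excluded from every mean, never treated as 0.
#'
#' @param chrom,pos,strand,context,level,reads column vectors.
#' @param sample_id sample label carried as an attribute.
#' @return data.frame of class `methylome`.
#' @export
methylome <- function(chrom = character(), pos = integer(),
                      strand = "+", context = "CpG",
                      level = numeric(), reads = integer(),
                      sample_id = "sample") {
  n <- length(pos)
  df <- data.frame(chrom = as.character(chrom),
                   pos = as.numeric(pos),
                   strand = rep_len(as.character(strand), n),
                   context = rep_len(as.character(context), n),
                   level = as.numeric(level),
                   reads = as.numeric(reads),
                   stringsAsFactors = FALSE)
  df$level[df$reads == 0] <- NA_real_
  bad <- which(!is.na(df$level) & (df$level < 0 | df$level > 1))
  if (length(bad) > 0) stop("methylation level outside [0,1] at row ", bad[1])
  if (any(df$reads < 0)) stop("negative read count")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  if (anyDuplicated(df[, c("chrom", "pos")])) {
    stop("duplicate CpG positions in track")
  }
  rownames(df) <- NULL
  class(df) <- c("methylome", "data.frame")
  attr(df, "sample_id") <- sample_id
  df
}

#' Read a methcounts-style per-CpG track
#'
#' Six tab-delimited columns: chrom, position (0-based), strand, context,
#' methylation level, read count. Gzipped input is handled transparently.
#' Malformed lines abort with the offending line number.
#'
#' @param path input path.
#' @param sample_id sample label to attach; defaults to the file stem.
#' @return a `methylome`.
#' @export
read_methylome <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(gz|txt|tsv|meth)+$", "", basename(path))
  }
  lines <- readLines(path)
  if (length(lines) == 0) {
    warning("empty methylome file: ", path)
    return(methylome(sample_id = sample_id))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6)
  if (length(bad) > 0) {
    stop("line ", bad[1], ": expected 6 tab-delimited columns, got ",
         lengths(parts)[bad[1]])
  }
  m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(m[, 2]))
  level <- suppressWarnings(as.numeric(m[, 5]))
  reads <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(pos) | pos < 0)
  if (length(bad) > 0) stop("line ", bad[1], ": invalid position")
  bad <- which(is.na(reads) | reads < 0)
  if (length(bad) > 0) stop("line ", bad[1], ": invalid read count")
  bad <- which(reads > 0 & (is.na(level) | level < 0 | level > 1))
  if (length(bad) > 0) {
    stop("line ", bad[1], ": methylation level outside [0,1]")
  }
  level[reads == 0] <- NA_real_
  methylome(chrom = m[, 1], pos = pos, strand = m[, 3], context = m[, 4],
            level = level, reads = reads, sample_id = sample_id)
}

#' Write a methylome track in the methcounts-style format
#'
#' @param track a `methylome`.
#' @param path output path; `.gz` writes gzipped.
#' @export
write_methylome <- function(track, path) {
  df <- as.data.frame(track)
  lvl <- ifelse(is.na(df$level), 0, df$level)
  out <- paste(df$chrom,
               format(df$pos, scientific = FALSE, trim = TRUE),
               df$strand, df$context,
               formatC(lvl, digits = 17, format = "g"),  # bit-exact round trip
               format(df$reads, scientific = FALSE, trim = TRUE),
               sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Export a browser track of centred methylation scores
#'
#' Writes a bedGraph-dialect file with one row per assessable CpG and score
#' `level - 0.5`, so 0 marks 50% methylation, positive scores (up to +0.5)
#' mark hypermethylated CpGs and negative scores (down to -0.5)
#' hypomethylated ones — the upward-red / downward-green browser semantics.
#'
#' @param track a `methylome`.
#' @param path output path.
#' @return invisibly, the data.frame written (chrom, start, end, score).
#' @export
export_browser_track <- function(track, path) {
  df <- as.data.frame(track)
  df <- df[!is.na(df$level), , drop = FALSE]
  out <- data.frame(chrom = df$chrom, start = df$pos, end = df$pos + 1,
                    score = df$level - 0.5, stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.table(format(out, scientific = FALSE, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  close(con)
  invisible(out)
}

#' Read/write a numeric matrix as TSV with row and column names
#'
#' @param x numeric matrix.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix; writers return the path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
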