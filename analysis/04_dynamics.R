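#!/usr/bin/env Rscript
# HMR expansion / contraction: compare the normal-breast (NB) HMRs against
# each other sample, classify width log2 fold changes into the
# unchanged / + / ++ / +++ / - / -- / --- / lost bins, and flag which NB
# HMRs contain a CpG island.

source("analysis/00_config.R")
seg_dir <- dir_for("segmentation")
out <- dir_for("dynamics")

genome <- study_genome()
nb <- read_bed(file.path(seg_dir, "NB.hmr.bed"))

hist_rows <- list()
for (sid in setdiff(names(SAMPLES), "NB")) {
  other <- read_bed(file.path(seg_dir, paste0(sid, ".hmr.bed")))
  ch <- match_widths(nb, other)
  ch <- classify_width_changes(ch)
  ch <- annotate_cgi(ch, genome$cgis)
  utils::write.table(ch, file.path(out, paste0("NB_vs_", sid, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- table(factor(ch$category,
                      levels = c("---", "--", "-", "unchanged",
                                 "+", "++", "+++", "lost")))
  hist_rows[[sid]] <- data.frame(sample = sid, t(as.matrix(tab)),
                                 check.names = FALSE)
  message(sprintf("NB vs %s: %d/%d unchanged, %d lost, %d with CGI",
                  sid, sum(ch$category == "unchanged"), nrow(ch),
                  sum(ch$category == "lost"), sum(ch$has_cgi)))
}
hist <- do.call(rbind, hist_rows)
utils::write.table(hist, file.path(out, "width_change_histogram.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(hist, row.names = FALSE)
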