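#!/usr/bin/env Rscript
# Segment each simulated methylome into HMRs (1 kb max CpG gap) and PMDs
# (1 kb bins, 20 kb max gap, >= 100 kb), and summarise per-sample genome
# composition: the three methylation level categories and the PMD genome
# fraction, which should be near zero for the normal samples and largest
# for the cell lines.

source("analysis/00_config.R")
sim_dir <- dir_for("simulation")
out <- dir_for("segmentation")

genome <- study_genome()
summary_rows <- list()
for (sid in names(SAMPLES)) {
  track <- read_methylome(file.path(sim_dir, paste0(sid, ".meth.tsv")),
                          sample_id = sid)
  hmrs <- call_hmrs(track)
  pmds <- call_pmds(track)
  hmrs$name <- sprintf("%s_hmr%05d", sid, seq_len(nrow(hmrs)))
  hmrs$score <- hmrs$mean_level
  write_bed(hmrs, file.path(out, paste0(sid, ".hmr.bed")))
  if (nrow(pmds)) {
    pmds$name <- sprintf("%s_pmd%04d", sid, seq_len(nrow(pmds)))
    pmds$score <- pmds$mean_level
  }
  write_bed(pmds, file.path(out, paste0(sid, ".pmd.bed")))

  cats <- level_categories(track)
  pmd_frac <- if (nrow(pmds)) {
    genome_fraction(merge_intervals(pmds), genome)
  } else 0
  summary_rows[[sid]] <- data.frame(
    sample = sid, archetype = SAMPLES[[sid]],
    n_hmr = nrow(hmrs), n_pmd = nrow(pmds),
    pmd_fraction = round(pmd_frac, 4),
    pct_low = round(100 * cats["low"] / sum(cats), 1),
    pct_intermediate = round(100 * cats["intermediate"] / sum(cats), 1),
    pct_high = round(100 * cats["high"] / sum(cats), 1))
  message(sprintf("%s: %d HMRs, %d PMDs (%.1f%% of genome)",
                  sid, nrow(hmrs), nrow(pmds), 100 * pmd_frac))
}
summary <- do.call(rbind, summary_rows)
utils::write.table(summary, file.path(out, "segmentation_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(summary, row.names = FALSE)
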