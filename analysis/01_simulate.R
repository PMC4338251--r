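#!/usr/bin/env Rscript
# Simulate the study's seven breast methylomes (normal breast, benign
# tumour, two invasive carcinomas, three cell lines) on the synthetic
# genome, plus the 78-patient paired tumour-normal cohort.
# Writes methcounts-style tracks, planted-truth BEDs (sidecar files), and
# the cohort matrices under results/simulation/.

source("analysis/00_config.R")
out <- dir_for("simulation")

genome <- study_genome()
message(sprintf("genome: %d chromosomes, %d CpGs, %d genes (%d X-linked)",
                nrow(genome$chromosomes),
                sum(lengths(genome$cpg_positions)),
                nrow(genome$genes), sum(genome$genes$is_x_linked)))

write_bed(genome$cgis, file.path(out, "cgis.bed"))
utils::write.table(genome$genes, file.path(out, "genes.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (i in seq_along(SAMPLES)) {
  sid <- names(SAMPLES)[i]
  sim <- generate_methylome(genome, archetype_spec(SAMPLES[[i]]),
                            seed = derive_seed(SEED, "methylome") + i,
                            sample_id = sid)
  write_methylome(sim$track, file.path(out, paste0(sid, ".meth.tsv")))
  write_bed(sim$truth$hmrs, file.path(out, paste0(sid, ".truth_hmrs.bed")))
  if (nrow(sim$truth$pmds)) {
    write_bed(sim$truth$pmds, file.path(out, paste0(sid, ".truth_pmds.bed")))
  }
  export_browser_track(sim$track, file.path(out, paste0(sid, ".bedgraph")))
  message(sprintf("%s: %d CpGs, mean depth %.1f, mean level %.3f",
                  sid, nrow(sim$track), mean(sim$track$reads),
                  mean(sim$track$level, na.rm = TRUE)))
}

cohort <- generate_paired_cohort(genome, cohort_spec(),
                                 seed = derive_seed(SEED, "cohort"))
for (nm in c("meth_normal", "meth_tumor", "expr_normal", "expr_tumor")) {
  write_matrix_tsv(cohort[[nm]], file.path(out, paste0("cohort_", nm, ".tsv")))
}
writeLines(cohort$truth$affected_patients,
           file.path(out, "cohort_truth_affected_patients.txt"))
message(sprintf("cohort: %d patients, %d planted XCI-loss",
                length(cohort$patients),
                length(cohort$truth$affected_patients)))
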