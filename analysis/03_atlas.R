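#!/usr/bin/env Rscript
# Build the reference-HMR atlas: merge all per-sample HMRs, re-score every
# reference region in every sample, classify promoter / intragenic /
# intergenic, and cluster each class with Gower dissimilarity + Ward
# linkage into eight clusters (A-1..A-8, B-1..B-8, C-1..C-8; cluster 1 is
# the most hypomethylated).

source("analysis/00_config.R")
sim_dir <- dir_for("simulation")
seg_dir <- dir_for("segmentation")
out <- dir_for("atlas")

genome <- study_genome()
tracks <- lapply(names(SAMPLES), function(sid) {
  read_methylome(file.path(sim_dir, paste0(sid, ".meth.tsv")),
                 sample_id = sid)
})
hmrs <- lapply(names(SAMPLES), function(sid) {
  read_bed(file.path(seg_dir, paste0(sid, ".hmr.bed")))
})

atlas <- build_atlas(hmrs, tracks, genome$genes, k = 8)
message(sprintf("reference set: %d regions (%d dropped as too sparse)",
                nrow(atlas$matrix), atlas$dropped))

ref <- atlas$intervals
ref$name <- rownames(atlas$matrix)
ref$score <- round(rowMeans(atlas$matrix, na.rm = TRUE), 4)
write_bed(ref, file.path(out, "reference_hmrs.bed"))
write_matrix_tsv(round(atlas$matrix, 6),
                 file.path(out, "reference_matrix.tsv"))
utils::write.table(
  data.frame(id = rownames(atlas$matrix), location = atlas$location,
             cluster = atlas$cluster),
  file.path(out, "reference_clusters.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

# per-cluster mean methylation across samples (the heatmap table)
keep <- !is.na(atlas$cluster)
means <- apply(atlas$matrix[keep, ], 2, function(x) {
  tapply(x, atlas$cluster[keep], mean, na.rm = TRUE)
})
utils::write.table(data.frame(cluster = rownames(means), round(means, 3)),
                   file.path(out, "cluster_means.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("cluster mean methylation by sample:")
print(round(means, 2))
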