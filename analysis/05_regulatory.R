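#!/usr/bin/env Rscript
# Regulatory potential of the reference HMRs: count how many of the eight
# feature tracks each region intersects (High potential = four or more),
# test cluster / enhancer-state association with Fisher's exact test (BH
# adjusted), and compare enhancer-state proportions between the two
# cell-type chromatin archetypes with the two-proportion z-test.

source("analysis/00_config.R")
atlas_dir <- dir_for("atlas")
out <- dir_for("regulatory")

genome <- study_genome()
ref <- read_bed(file.path(atlas_dir, "reference_hmrs.bed"))
cl <- utils::read.delim(file.path(atlas_dir, "reference_clusters.tsv"))

cnt <- count_feature_overlaps(ref, genome$feature_sets)
pot <- regulatory_potential(cnt)
utils::write.table(
  data.frame(id = cl$id, cluster = cl$cluster, overlap_count = cnt,
             potential = pot),
  file.path(out, "regulatory_potential.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
high_by_cluster <- tapply(pot == "High", cl$cluster, mean)
message("fraction of High-potential HMRs per cluster:")
print(round(high_by_cluster, 2))

keep <- !is.na(cl$cluster)
flags <- cbind(
  hmec_enhancer = overlaps_any(ref, genome$state_segments$hmec_like$enhancer),
  mcf7_enhancer = overlaps_any(ref, genome$state_segments$mcf7_like$enhancer),
  heterochromatin = overlaps_any(ref,
                                 genome$state_segments$hmec_like$heterochromatin))
enr <- state_enrichment(cl$cluster[keep], flags[keep, ])
utils::write.table(enr, file.path(out, "state_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
sig <- enr[!enr$untestable & enr$adjusted_p < 0.05 & enr$odds_ratio > 1, ]
message("clusters enriched (BH-adjusted p < 0.05): ",
        paste(unique(paste0(sig$cluster, "/", sig$state)), collapse = ", "))

z <- state_proportion_difference(sum(flags[keep, "hmec_enhancer"]),
                                 sum(keep),
                                 sum(flags[keep, "mcf7_enhancer"]),
                                 sum(keep))
message(sprintf("HMEC vs MCF7 enhancer-state proportion: %.3f vs %.3f, z = %.2f, p = %.3g",
                z$prop_a, z$prop_b, z$z, z$p))
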