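#!/usr/bin/env Rscript
# Methylation-expression integration: simulate expression linked to
# promoter methylation (repressed clusters A-3 / A-6 / A-8), run the
# two-group DE test (cancer cell lines + invasive tumours vs normals),
# stratify promoter differential methylation by DE label, and score
# per-cluster tumour-vs-normal effect sizes with Cohen's d.

source("analysis/00_config.R")
sim_dir <- dir_for("simulation")
atlas_dir <- dir_for("atlas")
out <- dir_for("integration")

genome <- study_genome()
tracks <- lapply(names(SAMPLES), function(sid) {
  read_methylome(file.path(sim_dir, paste0(sid, ".meth.tsv")),
                 sample_id = sid)
})

pm <- vapply(tracks, function(t) promoter_methylation(t, genome$genes),
             numeric(nrow(genome$genes)))
dimnames(pm) <- list(genome$genes$id, names(SAMPLES))
expr <- generate_expression(genome, pm, link_spec(),
                            seed = derive_seed(SEED, "expression"))
groups <- ifelse(colnames(pm) %in% NORMAL_SAMPLES, "normal", "tumor")
de <- simple_de_test(expr$counts, groups)
utils::write.table(de, file.path(out, "de_results.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

dm <- rowMeans(pm[, groups == "tumor"], na.rm = TRUE) -
  rowMeans(pm[, groups == "normal"], na.rm = TRUE)
st <- stratify_dm_by_expression(dm, de$de_label)
message(sprintf(
  "median promoter dM: under %.3f / no_de %.3f / over %.3f (rank p = %.3g)",
  st$medians["under"], st$medians["no_de"], st$medians["over"],
  st$p_under_vs_over))
utils::write.table(
  data.frame(stratum = names(st$medians),
             n = lengths(st$strata)[names(st$medians)],
             median_delta = round(as.numeric(st$medians), 4)),
  file.path(out, "dm_by_expression.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

# per-cluster effect size of the tumour-normal methylation difference
mat <- read_matrix_tsv(file.path(atlas_dir, "reference_matrix.tsv"))
cl <- utils::read.delim(file.path(atlas_dir, "reference_clusters.tsv"))
rows <- list()
for (k in sort(unique(cl$cluster[!is.na(cl$cluster)]))) {
  sel <- which(cl$cluster == k)
  a <- as.numeric(mat[sel, colnames(mat) %in% NORMAL_SAMPLES])
  b <- as.numeric(mat[sel, !colnames(mat) %in% NORMAL_SAMPLES])
  r <- cohens_d(a[!is.na(a)], b[!is.na(b)])
  rows[[k]] <- data.frame(cluster = k, d = round(r$d, 3),
                          magnitude = r$magnitude, n_hmr = length(sel))
}
effects <- do.call(rbind, rows)
utils::write.table(effects, file.path(out, "cluster_effect_sizes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(effects, row.names = FALSE)
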