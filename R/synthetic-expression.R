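#' Specification of the methylation-to-expression link
#'
#' Designates which promoter-HMR cluster archetypes are methylation
#' repressed and how strongly. For a linked gene the expected log2
#' expression decreases linearly with its promoter methylation; unlinked
#' genes are independent of methylation.
#'
#' @param repressed_clusters cluster archetype ids (e.g. `c("A-3", "A-6",
#'   "A-8")`, the promoter clusters whose methylation change tracks
#'   expression change in breast tumours).
#' @param slope log2-expression decrease per unit promoter methylation
#'   (positive = repression).
#' @param dispersion negative-binomial dispersion of the counts.
#' @param base_log2_mean,base_log2_sd distribution of per-gene baseline
#'   log2 mean counts.
#' @return list of class `link_spec`.
#' @export
link_spec <- function(repressed_clusters = c("A-3", "A-6", "A-8"),
                      slope = 5, dispersion = 0.05,
                      base_log2_mean = 6, base_log2_sd = 1.5) {
  structure(list(repressed_clusters = repressed_clusters, slope = slope,
                 dispersion = dispersion, base_log2_mean = base_log2_mean,
                 base_log2_sd = base_log2_sd),
            class = "link_spec")
}

#' Simulate an expression count table linked to promoter methylation
#'
#' @param genome a `genome_annotation` (supplies the gene-to-promoter-
#'   cluster map).
#' @param promoter_meth genes x samples matrix of promoter methylation
#'   levels; rownames are gene ids, colnames sample ids.
#' @param link a [link_spec()].
#' @param seed integer seed.
#' @return list of class `expression_table`: `counts` (genes x samples),
#'   `linked` (logical per gene), `genes`, `samples`.
#' @export
generate_expression <- function(genome, promoter_meth, link = link_spec(),
                                seed = 1) {
  stopifnot(inherits(genome, "genome_annotation"),
            is.matrix(promoter_meth))
  with_seed(seed, {
    genes <- rownames(promoter_meth)
    cl <- genome$genes$promoter_cluster[match(genes, genome$genes$id)]
    key <- paste0("A-", cl)
    linked <- !is.na(cl) & key %in% link$repressed_clusters
    base <- stats::rnorm(length(genes), link$base_log2_mean,
                         link$base_log2_sd)
    log2mu <- matrix(base, nrow = length(genes), ncol = ncol(promoter_meth))
    pm <- promoter_meth
    pm[is.na(pm)] <- 0.5
    centred <- pm - rowMeans(pm)
    log2mu[linked, ] <- log2mu[linked, ] - link$slope * centred[linked, ]
    mu <- 2^log2mu
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / link$dispersion),
                     nrow = nrow(mu),
                     dimnames = list(genes, colnames(promoter_meth)))
    structure(list(counts = counts, linked = linked, genes = genes,
                   samples = colnames(promoter_meth)),
              class = "expression_table")
  })
}

#' Counts-per-million normalisation
#'
#' @param counts genes x samples count matrix.
#' @return matrix of the same shape; every column sums to 1e6.
#' @export
cpm <- function(counts) {
  sweep(counts, 2, colSums(counts), "/") * 1e6
}
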