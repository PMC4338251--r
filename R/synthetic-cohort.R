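#' Specification of a paired tumour-normal cohort with planted XCI loss
#'
#' Emulates the paired-cohort scenario: a subpopulation of patients whose
#' tumours show X-promoter hypomethylation, reduced XIST expression, and
#' over-expression of a subset of X-linked genes.
#'
#' @param n_patients number of patients (default 78, the paired-cohort
#'   design size).
#' @param xci_loss_fraction fraction of patients with planted XCI loss
#'   (default 36/78).
#' @param x_promoter_delta mean tumour - normal X-promoter methylation
#'   shift in affected patients (default -0.3).
#' @param promoter_noise_sd per-promoter level noise SD (default 0.05).
#' @param affected_gene_fraction fraction of X genes over-expressed in
#'   affected tumours.
#' @param expression_effect planted log2 expression increase of affected
#'   genes in affected tumours.
#' @param xist_effect planted log2 decrease of XIST expression in affected
#'   tumours.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 78, xci_loss_fraction = 36 / 78,
                        x_promoter_delta = -0.3, promoter_noise_sd = 0.05,
                        affected_gene_fraction = 0.4,
                        expression_effect = 1.5, xist_effect = 2) {
  if (xci_loss_fraction < 0 || xci_loss_fraction > 1) {
    stop("invalid cohort config: xci_loss_fraction must lie in [0,1]")
  }
  if (affected_gene_fraction < 0 || affected_gene_fraction > 1) {
    stop("invalid cohort config: affected_gene_fraction must lie in [0,1]")
  }
  if (n_patients < 2) stop("invalid cohort config: n_patients must be >= 2")
  structure(list(n_patients = n_patients,
                 xci_loss_fraction = xci_loss_fraction,
                 x_promoter_delta = x_promoter_delta,
                 promoter_noise_sd = promoter_noise_sd,
                 affected_gene_fraction = affected_gene_fraction,
                 expression_effect = expression_effect,
                 xist_effect = xist_effect),
            class = "cohort_spec")
}

#' Simulate a paired tumour-normal cohort with planted XCI dysregulation
#'
#' Exactly `round(n_patients * xci_loss_fraction)` patients carry the
#' X-promoter hypomethylation shift, hypermethylation and silencing of the
#' XIST stand-in, and over-expression of the affected X-gene subset.
#' Normal-tissue X promoters sit at ~0.5 (allelic methylation of the
#' inactive X); autosomal promoters at a low unmethylated baseline.
#' Expression is on the log2 abundance scale. Truth labels are returned in
#' a sidecar element, never inside the data matrices.
#'
#' @param genome a `genome_annotation` with >= 20 X-linked genes.
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return list of class `paired_cohort`: `patients`, `meth_normal`,
#'   `meth_tumor`, `expr_normal`, `expr_tumor` (genes x patients),
#'   `x_genes`, `xist_gene_id`, and `truth` (affected patients/genes).
#' @export
generate_paired_cohort <- function(genome, spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(genome, "genome_annotation"),
            inherits(spec, "cohort_spec"))
  x_genes <- genome$genes$id[genome$genes$is_x_linked]
  if (length(x_genes) < 20) {
    stop("genome must carry >= 20 X-linked genes; has ", length(x_genes))
  }
  with_seed(seed, .generate_cohort_impl(genome, spec, x_genes))
}

.generate_cohort_impl <- function(genome, spec, x_genes) {
  genes <- genome$genes$id
  n_g <- length(genes)
  n_p <- spec$n_patients
  patients <- sprintf("patient%03d", seq_len(n_p))
  n_aff <- round(n_p * spec$xci_loss_fraction)
  affected <- sort(sample.int(n_p, n_aff))
  xist <- xist_gene_id(genome)
  x_other <- setdiff(x_genes, xist)

  is_x <- genes %in% x_other
  is_xist <- genes == xist
  base_meth <- ifelse(is_x, 0.5, ifelse(is_xist, 0.5, 0.15))

  noise <- function() matrix(stats::rnorm(n_g * n_p, 0,
                                          spec$promoter_noise_sd), n_g, n_p)
  meth_normal <- pmin(pmax(base_meth + noise(), 0), 1)
  shift <- matrix(0, n_g, n_p)
  shift[is_x, affected] <- spec$x_promoter_delta
  shift[is_xist, affected] <- 0.35  # XIST moves opposite: hyper when lost
  meth_tumor <- pmin(pmax(base_meth + shift + noise(), 0), 1)
  dimnames(meth_normal) <- dimnames(meth_tumor) <- list(genes, patients)

  base_expr <- stats::rnorm(n_g, 5, 1)
  base_expr[is_xist] <- 7  # XIST highly expressed when XCI intact
  enoise <- function() matrix(stats::rnorm(n_g * n_p, 0, 0.3), n_g, n_p)
  expr_normal <- base_expr + enoise()
  n_aff_genes <- round(length(x_other) * spec$affected_gene_fraction)
  affected_genes <- sort(sample(x_other, n_aff_genes))
  eshift <- matrix(0, n_g, n_p)
  eshift[genes %in% affected_genes, affected] <- spec$expression_effect
  eshift[is_xist, affected] <- -spec$xist_effect
  expr_tumor <- base_expr + eshift + enoise()
  dimnames(expr_normal) <- dimnames(expr_tumor) <- list(genes, patients)

  structure(list(patients = patients,
                 meth_normal = meth_normal, meth_tumor = meth_tumor,
                 expr_normal = expr_normal, expr_tumor = expr_tumor,
                 x_genes = x_genes, xist_gene_id = xist,
                 truth = list(affected_patients = patients[affected],
                              affected_genes = affected_genes)),
            class = "paired_cohort")
}
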